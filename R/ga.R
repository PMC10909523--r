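#' Fit-score weights
#'
#' Non-negative weights for the three pattern statistics entering the
#' goodness-of-fit score; at least one must be positive.
#'
#' @param w_isi,w_hazard,w_iod component weights.
#' @return A `fit_weights` object.
#' @export
fit_weights <- function(w_isi = 1, w_hazard = 1, w_iod = 1) {
  w <- c(isi = w_isi, hazard = w_hazard, iod = w_iod)
  if (any(w < 0) || !any(w > 0)) {
    stop("weights must be >= 0 with at least one > 0")
  }
  structure(as.list(w), class = "fit_weights")
}

#' Goodness-of-fit score between two pattern summaries
#'
#' The weighted sum of root-mean-square error measures comparing the ISI
#' histogram, hazard function and IoD profile of a candidate against a
#' target; a smaller value indicates a better fit. ISI histograms are
#' compared as per-bin probabilities (counts divided by the number of
#' ISIs); hazard bins undefined in either summary and IoD widths unreliable
#' in either are excluded. The hazard RMSE is precision-weighted: each bin
#' is weighted by the smaller of the two surviving-interval counts, which is
#' the binomial information available for that bin's hazard estimate. Tail
#' bins estimated from a handful of long intervals therefore cannot swamp
#' the well-estimated early bins that carry the afterpotential shape; with
#' equal denominators the weighting reduces to a plain RMSE. With
#' `scale = "target_range"` (the default) each RMSE is divided by the range
#' of the target's statistic, putting the three components on comparable
#' scales; `scale = "none"` uses raw RMSEs.
#'
#' @param target,candidate `pattern_summary` objects with identical bin
#'   structures.
#' @param weights a [fit_weights()] object.
#' @param scale component scaling, `"target_range"` or `"none"`.
#' @return A list with `score` (the weighted sum) and `components` (the
#'   per-statistic scaled RMSEs entering the sum).
#' @export
fit_score <- function(target, candidate, weights = fit_weights(),
                      scale = c("target_range", "none")) {
  scale <- match.arg(scale)
  if (!inherits(target, "pattern_summary") ||
      !inherits(candidate, "pattern_summary")) {
    stop("target and candidate must be pattern_summary objects")
  }
  if (target$isi$bin_width != candidate$isi$bin_width ||
      target$isi$max_interval != candidate$isi$max_interval) {
    stop("ISI histograms have mismatched bin structures")
  }
  if (!isTRUE(all.equal(target$iod$width, candidate$iod$width))) {
    stop("IoD profiles have mismatched width grids")
  }
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  scl <- function(x) {
    if (scale == "none") return(1)
    r <- diff(range(x, na.rm = TRUE))
    if (r > 0) r else 1
  }

  p_t <- target$isi$counts / target$isi$n_isi
  p_c <- candidate$isi$counts / candidate$isi$n_isi
  c_isi <- rmse(p_t, p_c) / scl(p_t)

  hz_ok <- target$hazard$defined & candidate$hazard$defined
  if (!any(hz_ok)) stop("no commonly defined hazard bins")
  wts <- pmin(target$hazard$denominators, candidate$hazard$denominators)[hz_ok]
  dh <- target$hazard$values[hz_ok] - candidate$hazard$values[hz_ok]
  c_haz <- sqrt(sum(wts * dh^2) / sum(wts)) /
    scl(target$hazard$values[target$hazard$defined])

  iod_ok <- target$iod$reliable & candidate$iod$reliable
  if (!any(iod_ok)) stop("no commonly reliable IoD widths")
  c_iod <- rmse(target$iod$iod[iod_ok], candidate$iod$iod[iod_ok]) /
    scl(target$iod$iod[target$iod$reliable])

  components <- c(isi = c_isi, hazard = c_haz, iod = c_iod)
  score <- weights$isi * c_isi + weights$hazard * c_haz + weights$iod * c_iod
  list(score = score, components = components)
}

#' Default parameter bounds for fitting
#'
#' Box bounds for the seven free parameters, chosen as envelopes (with
#' margin) of the published per-cell fits.
#'
#' @return A matrix with rows named by parameter and columns `lo`, `hi`.
#' @export
default_param_bounds <- function() {
  b <- rbind(I_re       = c(100, 800),
             k_HAP      = c(5, 120),
             lambda_HAP = c(3, 25),
             k_DAP      = c(0, 10),
             lambda_DAP = c(10, 100),
             k_AHP      = c(0, 2),
             lambda_AHP = c(100, 1500))
  colnames(b) <- c("lo", "hi")
  b
}

#' Genetic-algorithm configuration
#'
#' Settings for the GA used to fit spiking-model variants: real-coded
#' individuals, tournament selection, uniform crossover, Gaussian mutation
#' with standard deviation `mutation_sd` times the bound width, and one
#' elite individual carried over per generation. Each candidate is scored by
#' simulating a train of `eval_duration` seconds at a fixed per-run seed, so
#' scores are comparable within a run and the elite trajectory is
#' non-increasing. `runs` independent restarts are made and the best result
#' kept; the full replication setting is 100 runs per variant, while a
#' handful of runs is often adequate for exploration.
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_sd mutation standard deviation as a fraction of the bound
#'   width.
#' @param crossover_rate probability of uniform crossover.
#' @param bounds parameter bounds matrix, as [default_param_bounds()].
#' @param runs number of GA restarts (best kept).
#' @param seed integer seed; all restarts derive their streams from it.
#' @param eval_duration duration (s) of the simulated train used to score a
#'   candidate.
#' @param tournament_k tournament size.
#' @return A `ga_config` object.
#' @export
ga_config <- function(pop_size = 50, generations = 100, mutation_rate = 0.2,
                      mutation_sd = 0.05, crossover_rate = 0.7,
                      bounds = default_param_bounds(), runs = 5, seed = 1,
                      eval_duration = 600, tournament_k = 3) {
  if (runs < 1) stop("runs must be >= 1")
  if (pop_size < 4) stop("pop_size must be >= 4")
  if (any(bounds[, "hi"] <= bounds[, "lo"])) stop("infeasible bounds")
  structure(list(pop_size = pop_size, generations = generations,
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd,
                 crossover_rate = crossover_rate, bounds = bounds,
                 runs = runs, seed = seed, eval_duration = eval_duration,
                 tournament_k = tournament_k),
            class = "ga_config")
}

# Score one candidate vector of free parameters against the target summary.
# Returns +Inf when the candidate fires too little to yield statistics.
evaluate_candidate <- function(vec, free, variant, target, weights, cfg,
                               eval_seed) {
  params <- consensus_neuron_params()
  params[free] <- as.list(vec)
  params <- apply_variant(params, variant)
  train <- simulate_neuron(params, constant_protocol(params$I_re,
                                                     cfg$eval_duration),
                           seed = eval_seed)
  if (length(train$times) < 10) return(Inf)
  cand <- suppressWarnings(summarise_train(
    train, isi_bin = target$isi$bin_width,
    max_interval = target$isi$max_interval,
    iod_widths = target$iod$width))
  out <- tryCatch(fit_score(target, cand, weights),
                  error = function(e) NULL)
  if (is.null(out)) Inf else out$score
}

#' Fit one spiking-model variant to a pattern summary
#'
#' Genetic-algorithm search over the free parameters of the variant (the
#' synaptic input rate and the `k`/`lambda` pair of each afterpotential the
#' variant contains; absent afterpotentials are held at zero). Each
#' candidate is evaluated by simulating a train at the candidate's input
#' rate and scoring its pattern summary against the target with
#' [fit_score()]. The best individual over `cfg$runs` restarts is returned.
#' Fully reproducible given `cfg$seed`.
#'
#' @param target a `pattern_summary` (the fitting target).
#' @param variant one of [model_variants()].
#' @param cfg a [ga_config()].
#' @param weights a [fit_weights()].
#' @return A `fit_result` with fields `params`, `variant`, `score`,
#'   `components`, `n_runs` and `history` (per-run elite score
#'   trajectories).
#' @export
ga_fit <- function(target, variant, cfg = ga_config(),
                   weights = fit_weights()) {
  variant <- match.arg(variant, model_variants())
  free <- free_parameters(variant)
  bounds <- cfg$bounds[free, , drop = FALSE]
  d <- length(free)
  lo <- bounds[, "lo"]
  hi <- bounds[, "hi"]
  width <- hi - lo

  best <- NULL
  best_eval_seed <- NA_integer_
  history <- vector("list", cfg$runs)
  for (run in seq_len(cfg$runs)) {
    run_seed <- cfg$seed + 104729L * run
    eval_seed <- run_seed + 1L
    run_res <- with_seed(run_seed, {
      pop <- matrix(runif(cfg$pop_size * d, lo, hi), ncol = d, byrow = TRUE)
      scores <- apply(pop, 1, evaluate_candidate, free = free,
                      variant = variant, target = target, weights = weights,
                      cfg = cfg, eval_seed = eval_seed)
      elite_hist <- numeric(cfg$generations)
      for (gen in seq_len(cfg$generations)) {
        newpop <- matrix(0, cfg$pop_size, d)
        ord <- order(scores)
        newpop[1, ] <- pop[ord[1], ]          # elitism
        for (i in 2:cfg$pop_size) {
          pick <- function() {
            cand <- sample.int(cfg$pop_size, cfg$tournament_k)
            cand[which.min(scores[cand])]
          }
          p1 <- pop[pick(), ]
          p2 <- pop[pick(), ]
          child <- if (runif(1) < cfg$crossover_rate) {
            ifelse(runif(d) < 0.5, p1, p2)
          } else {
            p1
          }
          mut <- runif(d) < cfg$mutation_rate
          child[mut] <- child[mut] +
            rnorm(sum(mut), 0, cfg$mutation_sd * width[mut])
          newpop[i, ] <- pmin(pmax(child, lo), hi)
        }
        pop <- newpop
        scores <- apply(pop, 1, evaluate_candidate, free = free,
                        variant = variant, target = target,
                        weights = weights, cfg = cfg, eval_seed = eval_seed)
        elite_hist[gen] <- min(scores)
      }
      i <- which.min(scores)
      list(vec = pop[i, ], score = scores[i], hist = elite_hist)
    })
    history[[run]] <- run_res$hist
    if (is.null(best) || run_res$score < best$score) {
      best <- run_res
      best_eval_seed <- eval_seed
    }
  }

  params <- consensus_neuron_params()
  params[free] <- as.list(best$vec)
  params <- apply_variant(params, variant)
  # re-evaluate the winner at its run's evaluation seed to recover the
  # per-statistic components of the score
  train <- simulate_neuron(params, constant_protocol(params$I_re,
                                                     cfg$eval_duration),
                           seed = best_eval_seed)
  comp <- tryCatch({
    cand <- suppressWarnings(summarise_train(
      train, isi_bin = target$isi$bin_width,
      max_interval = target$isi$max_interval,
      iod_widths = target$iod$width))
    fit_score(target, cand, weights)$components
  }, error = function(e) c(isi = NA_real_, hazard = NA_real_,
                           iod = NA_real_))
  structure(list(params = params, variant = variant, score = best$score,
                 components = comp, n_runs = cfg$runs, history = history),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> variant %s, score %.4g (%d run%s)\n",
              x$variant, x$score, x$n_runs, if (x$n_runs > 1) "s" else ""))
  invisible(x)
}

#' Fit all four model variants and keep the best
#'
#' Runs [ga_fit()] for each variant (HAP only, HAP + AHP, HAP + DAP,
#' HAP + AHP + DAP) and returns the best-scoring result, breaking ties
#' toward the variant with fewer free parameters.
#'
#' @inheritParams ga_fit
#' @return The winning `fit_result`, with attribute `all_fits` holding the
#'   per-variant results.
#' @export
fit_all_variants <- function(target, cfg = ga_config(),
                             weights = fit_weights()) {
  variants <- model_variants()
  nfree <- vapply(variants, function(v) length(free_parameters(v)), numeric(1))
  variants <- variants[order(nfree)]
  fits <- list()
  best <- NULL
  for (i in seq_along(variants)) {
    cfg_v <- cfg
    cfg_v$seed <- cfg$seed + 1000L * i
    f <- ga_fit(target, variants[i], cfg_v, weights)
    fits[[variants[i]]] <- f
    if (is.null(best) || f$score < best$score) best <- f
  }
  attr(best, "all_fits") <- fits
  best
}

# Coerce a list of fit_result objects (or a ready-made data.frame of
# published fits) to the per-cell parameter table used by consensus_params.
# Afterpotentials absent from a fit's variant are recorded as NA.
fits_to_frame <- function(fits) {
  if (is.data.frame(fits)) return(fits)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    p <- f$params
    has_dap <- f$variant %in% c("HAP_DAP", "HAP_AHP_DAP")
    has_ahp <- f$variant %in% c("HAP_AHP", "HAP_AHP_DAP")
    data.frame(cell = paste0("fit", i), I_re = p$I_re, k_HAP = p$k_HAP,
               lambda_HAP = p$lambda_HAP,
               k_DAP = if (has_dap) p$k_DAP else NA_real_,
               lambda_DAP = if (has_dap) p$lambda_DAP else NA_real_,
               k_AHP = if (has_ahp) p$k_AHP else NA_real_,
               lambda_AHP = if (has_ahp) p$lambda_AHP else NA_real_)
  })
  do.call(rbind, rows)
}

#' Consensus parameter set from a collection of fits
#'
#' Builds a "typical cell" parameter set from per-cell fits. For the HAP,
#' whose amplitude and half-life are negatively correlated across cells, a
#' line is regressed through the (`k_HAP`, `lambda_HAP`) points and the
#' consensus pair is the point on that line nearest to the per-parameter
#' medians. The AHP and DAP parameters are medians over the fits that
#' contain them, and the input rate is the median rate; these are rounded
#' (`k_AHP` and `k_DAP` to 0.1 mV, `lambda_AHP` to 100 ms, `lambda_DAP` to
#' 10 ms, `I_re` to 10 Hz). Fixed fields (PSP shape, resting and threshold
#' potentials) take their standard values.
#'
#' @param fits a data.frame of per-cell fits (columns as [oxytocin_fits()])
#'   or a list of `fit_result` objects.
#' @return A `consensus_result` with fields `params` (a `neuron_params`),
#'   `hap_regression` (slope, intercept, r2) and `medians`.
#' @export
consensus_params <- function(fits) {
  tab <- fits_to_frame(fits)
  if (nrow(tab) < 2) stop("at least 2 fits are required")
  k <- tab$k_HAP
  l <- tab$lambda_HAP
  med <- vapply(tab[, c("I_re", "k_HAP", "lambda_HAP", "k_DAP",
                        "lambda_DAP", "k_AHP", "lambda_AHP")],
                median, numeric(1), na.rm = TRUE)

  if (var(k) > 0 && var(l) > 0) {
    fit <- lm(l ~ k)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    r2 <- summary(fit)$r.squared
    # orthogonal projection of the median point onto the regression line
    kc <- (med["k_HAP"] + slope * (med["lambda_HAP"] - intercept)) /
      (1 + slope^2)
    lc <- intercept + slope * kc
  } else {
    slope <- NA_real_
    intercept <- NA_real_
    r2 <- NA_real_
    kc <- med["k_HAP"]
    lc <- med["lambda_HAP"]
  }

  params <- consensus_neuron_params()
  params$I_re <- round(med["I_re"] / 10) * 10
  params$k_HAP <- unname(kc)
  params$lambda_HAP <- unname(lc)
  params$k_DAP <- if (is.finite(med["k_DAP"])) round(med["k_DAP"], 1) else 0
  params$lambda_DAP <- if (is.finite(med["lambda_DAP"])) {
    round(med["lambda_DAP"] / 10) * 10
  } else {
    params$lambda_DAP
  }
  params$k_AHP <- if (is.finite(med["k_AHP"])) round(med["k_AHP"], 1) else 0
  params$lambda_AHP <- if (is.finite(med["lambda_AHP"])) {
    round(med["lambda_AHP"] / 100) * 100
  } else {
    params$lambda_AHP
  }
  params <- lapply(params, unname)
  class(params) <- "neuron_params"
  validate_neuron_params(params)

  structure(list(params = params,
                 hap_regression = list(slope = slope, intercept = intercept,
                                       r2 = r2),
                 medians = med),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> HAP: k = %.2f mV, lambda = %.2f ms (R2 = %.2f)\n",
              x$params$k_HAP, x$params$lambda_HAP, x$hap_regression$r2))
  invisible(x)
}
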
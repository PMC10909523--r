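#' Synthetic-cell specification
#'
#' A labelled ground-truth record for generating a synthetic "recorded"
#' cell: the true parameters, the model variant they correspond to, the
#' record duration and the seed. The free parameters must lie within the
#' fitting bounds so that closed-loop recovery tests are well posed.
#'
#' @param true_params a [neuron_params()] set.
#' @param variant one of [model_variants()].
#' @param duration record duration (s).
#' @param seed integer seed.
#' @return A `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(true_params, variant = "HAP_AHP_DAP",
                                duration = 600, seed = 1) {
  variant <- match.arg(variant, model_variants())
  true_params <- apply_variant(true_params, variant)
  b <- default_param_bounds()
  for (nm in free_parameters(variant)) {
    v <- true_params[[nm]]
    if (v < b[nm, "lo"] || v > b[nm, "hi"]) {
      stop(sprintf("%s = %g outside fitting bounds [%g, %g]",
                   nm, v, b[nm, "lo"], b[nm, "hi"]))
    }
  }
  if (duration <= 0) stop("duration must be > 0")
  structure(list(true_params = true_params, variant = variant,
                 duration = duration, seed = seed),
            class = "synthetic_cell_spec")
}

#' Generate a synthetic cell
#'
#' Simulates a spike train from the spec's true parameters at constant input
#' and returns it together with the truth record, for parameter-recovery
#' experiments.
#'
#' @param spec a [synthetic_cell_spec()].
#' @return A list with `train` (a [spike_train()]) and `truth` (the spec).
#' @export
gen_cell <- function(spec) {
  train <- simulate_neuron(spec$true_params,
                           constant_protocol(spec$true_params$I_re,
                                             spec$duration),
                           seed = spec$seed,
                           label = sprintf("synthetic %s cell", spec$variant))
  list(train = train, truth = spec)
}

#' Sample plausible cell parameters
#'
#' Draws parameter sets uniformly within the per-column ranges of the
#' published per-cell fits, for building synthetic cohorts whose firing
#' rates span the observed range.
#'
#' @param n number of parameter sets.
#' @param seed integer seed.
#' @param variant variant to constrain each draw to.
#' @return A list of `neuron_params`.
#' @export
sample_cell_params <- function(n, seed = 1, variant = "HAP_AHP_DAP") {
  tab <- oxytocin_fits()
  cols <- c("I_re", "k_HAP", "lambda_HAP", "k_DAP", "lambda_DAP",
            "k_AHP", "lambda_AHP")
  lo <- vapply(tab[cols], min, numeric(1), na.rm = TRUE)
  hi <- vapply(tab[cols], max, numeric(1), na.rm = TRUE)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      p <- consensus_neuron_params()
      for (nm in cols) p[[nm]] <- runif(1, lo[nm], hi[nm])
      apply_variant(p, variant)
    })
  })
}

#' Generate a synthetic gavage recording
#'
#' Simulates one cell through a gavage protocol, emulating the structure of
#' the recorded responses: stationary baseline firing followed by an
#' approximately linear rise in the 30-s binned rate after the protocol
#' delay.
#'
#' @param params a [neuron_params()] set.
#' @param protocol a gavage [input_protocol()].
#' @param seed integer seed.
#' @return A [spike_train()].
#' @export
gen_gavage_recording <- function(params, protocol, seed = 1) {
  simulate_neuron(params, protocol, seed = seed,
                  label = "synthetic gavage recording")
}

#' Generate a synthetic measurement cohort
#'
#' Draws per-animal plasma concentrations at each sample time from a normal
#' distribution truncated at zero (concentrations are physical quantities)
#' and reports the sample mean and SEM, emulating the published group
#' tables.
#'
#' @param means per-time population means (pg/mL).
#' @param sds per-time population standard deviations (pg/mL).
#' @param n animals per group.
#' @param times sample times (min).
#' @param group group label.
#' @param seed integer seed.
#' @return A list with `table` (a `measurement_table` of generated means and
#'   SEMs) and `animals` (an `n` x time matrix of per-animal values).
#' @export
gen_measurement_cohort <- function(means, sds, n, times = c(0, 20, 40),
                                   group = "synthetic", seed = 1) {
  if (length(means) != length(times) || length(sds) != length(times)) {
    stop("means and sds must have one value per sample time")
  }
  if (any(sds < 0) || n < 1) stop("sds must be >= 0 and n >= 1")
  animals <- with_seed(seed, {
    vapply(seq_along(times), function(j) {
      draws <- numeric(n)
      for (i in seq_len(n)) {
        repeat {
          v <- rnorm(1, means[j], sds[j])
          if (v >= 0) break
        }
        draws[i] <- v
      }
      draws
    }, numeric(n))
  })
  animals <- matrix(animals, nrow = n,
                    dimnames = list(NULL, paste0("t", times)))
  tab <- data.frame(group = group, time_min = times,
                    mean = colMeans(animals),
                    sem = apply(animals, 2, sd) / sqrt(n),
                    n = n)
  rownames(tab) <- NULL
  class(tab) <- c("measurement_table", "data.frame")
  list(table = tab, animals = animals)
}
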
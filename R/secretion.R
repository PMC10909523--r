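#' Stimulus-secretion coupling parameters
#'
#' Per-spike hormone release with activity-dependent facilitation. A
#' facilitation variable `f` is incremented by `facil_gain` at each spike
#' (capped at `facil_max`) and decays with half-life `facil_halflife`
#' seconds; a spike arriving with facilitation `f` releases
#' `base_release * (1 + f)^facil_power` units. The supralinear power
#' reflects the cooperative dependence of exocytosis on residual calcium,
#' and is what lets a modest rise in firing rate drive a several-fold rise
#' in secretion.
#'
#' @param base_release release per spike at zero facilitation (arbitrary
#'   units).
#' @param facil_gain per-spike facilitation increment (dimensionless).
#' @param facil_halflife facilitation half-life (s).
#' @param facil_max saturation ceiling for `f`.
#' @param facil_power exponent applied to `(1 + f)`.
#' @return A `secretion_params` object.
#' @export
secretion_params <- function(base_release = 1, facil_gain = 0.01,
                             facil_halflife = 60, facil_max = 20,
                             facil_power = 2) {
  if (base_release <= 0) stop("base_release must be > 0")
  if (facil_gain < 0 || facil_max < 0) stop("facil_gain and facil_max must be >= 0")
  if (facil_halflife <= 0) stop("facil_halflife must be > 0")
  if (facil_power < 0) stop("facil_power must be >= 0")
  structure(list(base_release = base_release, facil_gain = facil_gain,
                 facil_halflife = facil_halflife, facil_max = facil_max,
                 facil_power = facil_power),
            class = "secretion_params")
}

#' Secretion signal from a spike train
#'
#' Converts spike times to a binned hormone-release rate using the
#' facilitation model of [secretion_params()]: the facilitation variable
#' decays between spikes, each spike releases
#' `base_release * (1 + f)^facil_power` with `f` evaluated before the
#' spike's own increment, and the releases are accumulated into bins of
#' `dt` seconds.
#'
#' @param train a [spike_train()].
#' @param params a [secretion_params()].
#' @param dt signal resolution (s).
#' @return A `secretion_signal` with fields `dt` and `values` (release rate,
#'   units/s, one value per bin).
#' @export
secretion_from_spikes <- function(train, params, dt = 0.1) {
  n_bins <- round(train$duration / dt)
  values <- .secretion_signal_cpp(train$times, dt, n_bins,
                                  params$facil_gain, params$facil_halflife,
                                  params$facil_max, params$base_release,
                                  params$facil_power)
  structure(list(dt = dt, values = values), class = "secretion_signal")
}

#' Pointwise average of secretion signals
#'
#' Averages the signals of independently simulated neurons to provide a
#' smoothed input to the plasma model.
#'
#' @param signals a list of `secretion_signal` objects with identical `dt`
#'   and length.
#' @return The mean `secretion_signal`.
#' @export
average_signals <- function(signals) {
  if (length(signals) == 0) stop("no signals to average")
  dts <- vapply(signals, function(s) s$dt, numeric(1))
  lens <- vapply(signals, function(s) length(s$values), numeric(1))
  if (length(unique(dts)) != 1 || length(unique(lens)) != 1) {
    stop("signals must share dt and length")
  }
  out <- signals[[1]]
  out$values <- Reduce(`+`, lapply(signals, `[[`, "values")) / length(signals)
  out
}

#' Two-compartment plasma model parameters
#'
#' Linear exchange between plasma and extravascular fluid (EVF) with
#' clearance from plasma only, giving biexponential decay after a bolus.
#' The defaults give a fast distribution phase and a dominant clearance
#' half-life of roughly two minutes, with a plasma distribution volume
#' typical of an adult rat. `scaling` maps the (arbitrary-unit) secretion of
#' one model neuron to whole-gland output in pg; it is normally set by
#' [calibrate_secretion()].
#'
#' @param k_pe plasma-to-EVF transfer rate (1/min).
#' @param k_ep EVF-to-plasma transfer rate (1/min).
#' @param k_clear clearance rate from plasma (1/min).
#' @param v_plasma plasma distribution volume (mL).
#' @param scaling population scaling factor (pg per secretion unit).
#' @return A `plasma_params` object.
#' @export
plasma_params <- function(k_pe = 0.5, k_ep = 0.5, k_clear = 1.2,
                          v_plasma = 10, scaling = 1) {
  for (nm in c("k_pe", "k_ep", "k_clear")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0) stop(nm, " must be > 0")
  }
  if (v_plasma <= 0) stop("v_plasma must be > 0")
  if (scaling <= 0) stop("scaling must be > 0")
  structure(list(k_pe = k_pe, k_ep = k_ep, k_clear = k_clear,
                 v_plasma = v_plasma, scaling = scaling),
            class = "plasma_params")
}

# Rate matrix (per minute) of the two-compartment system in concentration
# units: x = (plasma, evf), dx/dt = M x + (u, 0).
plasma_matrix <- function(params) {
  matrix(c(-(params$k_pe + params$k_clear), params$k_pe,
           params$k_ep, -params$k_ep),
         nrow = 2)
}

#' Steady state of the plasma model under constant secretion
#'
#' Closed-form steady state for a constant secretion rate: the plasma
#' concentration is `scaling * rate * 60 / (v_plasma * k_clear)` and the EVF
#' concentration follows from the transfer balance.
#'
#' @param rate constant secretion rate (units/s).
#' @param params a [plasma_params()].
#' @return Numeric length-2 vector `c(plasma, evf)` (pg/mL).
#' @export
plasma_steady_state <- function(rate, params) {
  u <- c(params$scaling * rate * 60 / params$v_plasma, 0)
  x <- -solve(plasma_matrix(params), u)
  c(plasma = x[1], evf = x[2])
}

#' Integrate the two-compartment plasma model
#'
#' Drives the plasma/EVF system with a secretion signal using an exact
#' exponential-integrator update per step (the matrix exponential applied in
#' the eigenbasis, with the input held constant over each step). The update
#' is unconditionally stable and conserves mass: total input equals cleared
#' mass plus the change of compartment content, to integration rounding.
#'
#' @param secretion a [secretion_from_spikes()] signal (units/s).
#' @param params a [plasma_params()].
#' @param init initial state `c(plasma, evf)` in pg/mL, or `"steady"` to
#'   start at the steady state of the signal's first value.
#' @return A `plasma_series` with fields `dt` (s), `plasma`, `evf` (pg/mL)
#'   and `mass` (inflow, cleared, stored change and the relative balance
#'   error).
#' @export
plasma_dynamics <- function(secretion, params, init = c(0, 0)) {
  if (!inherits(secretion, "secretion_signal")) {
    stop("secretion must be a secretion_signal")
  }
  dt_min <- secretion$dt / 60
  M <- plasma_matrix(params)
  eg <- eigen(M)
  if (abs(diff(eg$values)) < 1e-12) {
    stop("degenerate plasma kinetics (repeated eigenvalue); perturb the rates")
  }
  Q <- eg$vectors
  Qi <- solve(Q)
  a <- exp(eg$values * dt_min)              # per-step decay of each mode
  cc <- (a - 1) / eg$values                 # exact constant-input response

  u <- params$scaling * secretion$values * 60 / params$v_plasma  # conc/min
  x0 <- if (identical(init, "steady")) {
    unname(plasma_steady_state(secretion$values[1], params))
  } else {
    as.numeric(init)
  }

  # modal coordinates: z_k' = lambda_k z_k + w_k, solved per step by a
  # scalar linear recursion
  w <- outer(Qi[, 1], u)                    # 2 x n modal input
  z0 <- Qi %*% x0
  z <- rbind(
    stats::filter(cc[1] * w[1, ], a[1], method = "recursive", init = 0) +
      a[1]^seq_along(u) * z0[1],
    stats::filter(cc[2] * w[2, ], a[2], method = "recursive", init = 0) +
      a[2]^seq_along(u) * z0[2]
  )
  x <- Re(Q %*% z)
  plasma <- x[1, ]
  evf <- x[2, ]

  # exact per-step integral of the state, for the clearance mass balance
  xprev <- cbind(x0, x[, -ncol(x), drop = FALSE])
  zprev <- Qi %*% xprev
  int_z <- (cc * zprev) + ((cc - dt_min) / eg$values) * w
  int_x <- Re(Q %*% int_z)                  # integral of x over each step, conc*min
  inflow <- params$scaling * sum(secretion$values) * secretion$dt
  cleared <- params$v_plasma * params$k_clear * sum(int_x[1, ])
  stored <- params$v_plasma * (sum(x[, ncol(x)]) - sum(x0))
  rel_err <- if (inflow + cleared > 0) {
    abs(inflow - cleared - stored) / max(inflow, cleared + abs(stored))
  } else {
    0
  }

  structure(list(dt = secretion$dt, plasma = plasma, evf = evf,
                 mass = list(inflow = inflow, cleared = cleared,
                             stored = stored, rel_error = rel_err)),
            class = "plasma_series")
}

#' @export
as.data.frame.plasma_series <- function(x, ...) {
  onset <- attr(x, "onset_s")
  if (is.null(onset)) onset <- 0
  data.frame(time_min = (seq_along(x$plasma) * x$dt - onset) / 60,
             plasma_pg_per_ml = x$plasma, evf = x$evf)
}

#' Read a plasma series at given times
#'
#' Nearest-step readout of the predicted concentration, with times given in
#' minutes relative to the series' stimulus onset (attribute `onset_s`, or
#' the start of the series when unset).
#'
#' @param series a `plasma_series`.
#' @param times_min times (min) relative to onset.
#' @return Predicted concentrations (pg/mL).
#' @export
plasma_at <- function(series, times_min) {
  onset <- attr(series, "onset_s")
  if (is.null(onset)) onset <- 0
  idx <- round((onset + times_min * 60) / series$dt)
  idx[idx < 1] <- 1
  if (any(idx > length(series$plasma))) {
    stop("requested time not covered by the series")
  }
  series$plasma[idx]
}

#' Calibrate population scaling and facilitation gain
#'
#' Fixes the two free constants of the secretion-plasma chain from two
#' measured plasma concentrations. The population scaling factor is set so
#' that the steady-state plasma concentration implied by the baseline-window
#' mean secretion rate equals `basal_target` (exact, since the plasma model
#' is linear in scaling). The facilitation gain is then found by bounded
#' one-dimensional root finding so that the simulated concentration at
#' `endpoint_time` equals `endpoint_target`; because changing the gain also
#' changes basal secretion, the scaling is re-derived inside every
#' evaluation.
#'
#' @param trains list of [spike_train()]s (the simulated population, all of
#'   equal duration, spanning baseline and stimulation).
#' @param sec a [secretion_params()]; its `facil_gain` is replaced.
#' @param pk a [plasma_params()]; its `scaling` is replaced.
#' @param basal_target measured basal plasma concentration (pg/mL).
#' @param endpoint_target measured plasma concentration at the endpoint
#'   (pg/mL).
#' @param basal_window `c(from, to)` (s) of the baseline period.
#' @param endpoint_time endpoint readout time (s, absolute).
#' @param gain_bounds search interval for the facilitation gain.
#' @param dt secretion/plasma step (s).
#' @return A list with `scaling`, `facil_gain`, updated `sec` and `pk`,
#'   `basal_rate` (mean secretion rate in the baseline window), `series`
#'   (the calibrated `plasma_series`) and `achieved` (basal and endpoint
#'   concentrations).
#' @export
calibrate_secretion <- function(trains, sec, pk, basal_target,
                                endpoint_target, basal_window,
                                endpoint_time, gain_bounds = c(0, 0.05),
                                dt = 0.1) {
  if (basal_target <= 0 || endpoint_target <= 0) {
    stop("calibration targets must be > 0")
  }
  n_bins <- round(trains[[1]]$duration / dt)
  basal_idx <- seq(floor(basal_window[1] / dt) + 1, floor(basal_window[2] / dt))
  end_idx <- round(endpoint_time / dt)
  if (end_idx > n_bins) stop("endpoint_time not covered by the trains")

  eval_gain <- function(g) {
    s <- sec
    s$facil_gain <- g
    avg <- average_signals(lapply(trains, secretion_from_spikes,
                                  params = s, dt = dt))
    sb <- mean(avg$values[basal_idx])
    p <- pk
    p$scaling <- basal_target * p$v_plasma * p$k_clear / (sb * 60)
    series <- plasma_dynamics(avg, p, init = unname(plasma_steady_state(sb, p)))
    list(endpoint = series$plasma[end_idx], scaling = p$scaling,
         basal_rate = sb, series = series, pk = p, sec = s)
  }

  resid <- function(g) eval_gain(g)$endpoint - endpoint_target
  grid <- seq(gain_bounds[1], gain_bounds[2], length.out = 13)
  vals <- vapply(grid, resid, numeric(1))
  cross <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (length(cross) == 0) {
    stop(sprintf(
      "calibration failure: endpoint %.1f-%.1f pg/mL over gain bounds [%g, %g], target %.1f",
      min(vals) + endpoint_target, max(vals) + endpoint_target,
      gain_bounds[1], gain_bounds[2], endpoint_target))
  }
  i <- cross[1]
  root <- stats::uniroot(resid, c(grid[i], grid[i + 1]), tol = 1e-7)
  fit <- eval_gain(root$root)

  if (abs(fit$endpoint - endpoint_target) / endpoint_target > 0.02) {
    stop(sprintf("calibration did not converge: endpoint %.1f vs target %.1f",
                 fit$endpoint, endpoint_target))
  }
  list(scaling = fit$scaling, facil_gain = root$root, sec = fit$sec,
       pk = fit$pk, basal_rate = fit$basal_rate, series = fit$series,
       achieved = c(basal = basal_target, endpoint = fit$endpoint))
}
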
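#' Published plasma oxytocin measurement tables
#'
#' Group means and SEMs of plasma oxytocin concentration (pg/mL) measured by
#' radioimmunoassay in urethane-anaesthetised rats: sham gavage, gavage of
#' sweetened condensed milk (SCM), gavage of isocaloric cream (sampled at 0,
#' 20 and 40 min after gavage onset), and i.v. insulin injection (sampled at
#' 0, 30 and 60 min after injection). These are fixture tables for comparing
#' model predictions; time 0 is the basal sample.
#'
#' @return A named list of `measurement_table` data.frames with columns
#'   `group`, `time_min`, `mean`, `sem`, `n`.
#' @export
builtin_measurements <- function() {
  mk <- function(group, times, means, sems, n) {
    out <- data.frame(group = group, time_min = times, mean = means,
                      sem = sems, n = n)
    class(out) <- c("measurement_table", "data.frame")
    out
  }
  list(
    sham    = mk("sham",    c(0, 20, 40), c(46, 48, 64),   c(14, 17, 20), 6),
    scm     = mk("scm",     c(0, 20, 40), c(65, 105, 229), c(22, 27, 56), 6),
    cream   = mk("cream",   c(0, 20, 40), c(49, 84, 86),   c(7, 16, 8),   6),
    insulin = mk("insulin", c(0, 30, 60), c(80, 142, 149), c(18, 34, 32), 8)
  )
}

#' Compare a predicted plasma series with a measurement table
#'
#' Reads the predicted concentration at each sample time of the table
#' (nearest simulation step, times in minutes relative to the series onset)
#' and flags predictions lying within one SEM of the measured mean.
#'
#' @param series a `plasma_series` (with attribute `onset_s` set by
#'   [run_population_gavage()]).
#' @param table a `measurement_table`, as from [builtin_measurements()].
#' @return A `prediction_comparison` data.frame with columns `time_min`,
#'   `predicted`, `measured_mean`, `sem`, `residual`, `within_sem`.
#' @export
compare_prediction <- function(series, table) {
  pred <- plasma_at(series, table$time_min)
  out <- data.frame(time_min = table$time_min, predicted = pred,
                    measured_mean = table$mean, sem = table$sem,
                    residual = pred - table$mean,
                    within_sem = abs(pred - table$mean) <= table$sem)
  class(out) <- c("prediction_comparison", "data.frame")
  out
}

#' Run manifest
#'
#' A record sufficient to reproduce a population run exactly: seed, problem
#' size, protocol segments and every parameter group, plus the package
#' version.
#'
#' @param seed,n_neurons run identity.
#' @param protocol an [input_protocol()].
#' @param params,sec,pk parameter groups.
#' @param extra optional named list of further settings.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(seed, n_neurons, protocol, params, sec, pk,
                         extra = list()) {
  m <- c(list(seed = seed, n_neurons = n_neurons,
              protocol = as.data.frame(unclass(protocol)),
              neuron_params = unclass(params),
              secretion_params = unclass(sec),
              plasma_params = unclass(pk),
              package = "oxysim",
              version = as.character(packageVersion("oxysim"))),
         extra)
  class(m) <- "run_manifest"
  m
}

#' Write a run manifest as JSON
#' @param manifest a [run_manifest()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Population gavage simulation
#'
#' Simulates `n_neurons` independent model neurons under an input protocol
#' (neuron `i` uses seed `seed + i`), converts each train to a secretion
#' signal, averages the signals, and integrates the two-compartment plasma
#' model. The plasma series starts at the steady state implied by the mean
#' baseline secretion rate, and carries the protocol onset so that outputs
#' are aligned to minute 0 = stimulus onset.
#'
#' @param params a [neuron_params()] set.
#' @param protocol an [input_protocol()]; its `onset` attribute (set by
#'   [make_gavage_protocol()]) defines minute 0.
#' @param sec a [secretion_params()].
#' @param pk a [plasma_params()].
#' @param n_neurons population size.
#' @param seed integer seed.
#' @param dt integration step of the spiking model (ms).
#' @param secretion_dt secretion/plasma step (s).
#' @param keep_trains keep the simulated spike trains in the result.
#' @return A `population_run` list: `plasma` (a `plasma_series` with
#'   attribute `onset_s`), `secretion` (the averaged signal), `trains`
#'   (optional) and `manifest`.
#' @export
run_population_gavage <- function(params, protocol, sec = secretion_params(),
                                  pk = plasma_params(), n_neurons = 100,
                                  seed = 1, dt = 1, secretion_dt = 0.1,
                                  keep_trains = FALSE) {
  if (n_neurons < 1) stop("n_neurons must be >= 1")
  onset <- attr(protocol, "onset")
  if (is.null(onset)) onset <- 0
  trains <- lapply(seq_len(n_neurons), function(i) {
    simulate_neuron(params, protocol, seed = seed + i, dt = dt,
                    label = sprintf("neuron %d", i))
  })
  avg <- average_signals(lapply(trains, secretion_from_spikes, params = sec,
                                dt = secretion_dt))
  init <- if (onset > 0) {
    basal_idx <- seq_len(floor(onset / secretion_dt))
    unname(plasma_steady_state(mean(avg$values[basal_idx]), pk))
  } else {
    c(0, 0)
  }
  plasma <- plasma_dynamics(avg, pk, init = init)
  attr(plasma, "onset_s") <- onset
  out <- list(plasma = plasma, secretion = avg,
              manifest = run_manifest(seed, n_neurons, protocol, params,
                                      sec, pk,
                                      extra = list(dt_ms = dt,
                                                   secretion_dt = secretion_dt)))
  if (keep_trains) out$trains <- trains
  class(out) <- "population_run"
  out
}

#' Replication gavage protocol
#'
#' The full gavage schedule used for plasma prediction runs: 40-min control
#' at 370 Hz, 3.5-min post-onset delay, a 0.037 Hz/s ramp for 35 min, and a
#' plateau at 447.7 Hz making the total simulated time 6000 s.
#'
#' @return An [input_protocol()] with `onset` at 2400 s.
#' @export
replication_protocol <- function() {
  make_gavage_protocol(baseline_rate = 370, baseline_dur = 2400, delay = 210,
                       ramp_slope = 0.037, ramp_dur = 2100,
                       plateau_dur = 1290)
}

#' Predict plasma oxytocin during gavage
#'
#' The end-to-end replication run: simulates a population of consensus-model
#' neurons under the gavage protocol, calibrates the population scaling
#' factor to the measured basal concentration and the facilitation gain to
#' the measured 40-min concentration of the sweetened-condensed-milk group,
#' and returns the calibrated plasma prediction with its comparison against
#' the measured means. The 20-min concentration is a genuine out-of-sample
#' prediction: nothing in the calibration uses it.
#'
#' @param n_neurons population size (100 for the full replication).
#' @param seed integer seed.
#' @param params a [neuron_params()] set.
#' @param protocol the gavage [input_protocol()].
#' @param sec,pk secretion and plasma parameter groups (their `facil_gain`
#'   and `scaling` are replaced by calibration).
#' @param basal_target,endpoint_target calibration anchors (pg/mL).
#' @param endpoint_min endpoint sample time (min after onset).
#' @param secretion_dt secretion/plasma step (s).
#' @return A list: `comparison` (vs the SCM table), `plasma` (calibrated
#'   series with `onset_s`), `calibration` (scaling, facilitation gain and
#'   achieved anchors) and `manifest`.
#' @export
predict_gavage <- function(n_neurons = 100, seed = 1,
                           params = consensus_neuron_params(),
                           protocol = replication_protocol(),
                           sec = secretion_params(), pk = plasma_params(),
                           basal_target = 65, endpoint_target = 229,
                           endpoint_min = 40, secretion_dt = 0.1) {
  onset <- attr(protocol, "onset")
  if (is.null(onset) || onset <= 0) {
    stop("protocol must carry a positive gavage onset")
  }
  trains <- lapply(seq_len(n_neurons), function(i) {
    simulate_neuron(params, protocol, seed = seed + i,
                    label = sprintf("neuron %d", i))
  })
  cal <- calibrate_secretion(trains, sec, pk,
                             basal_target = basal_target,
                             endpoint_target = endpoint_target,
                             basal_window = c(0, onset),
                             endpoint_time = onset + endpoint_min * 60,
                             dt = secretion_dt)
  plasma <- cal$series
  attr(plasma, "onset_s") <- onset
  comparison <- compare_prediction(plasma, builtin_measurements()$scm)
  list(comparison = comparison, plasma = plasma,
       calibration = list(scaling = cal$scaling,
                          facil_gain = cal$facil_gain,
                          basal_rate = cal$basal_rate,
                          achieved = cal$achieved),
       manifest = run_manifest(seed, n_neurons, protocol, params, cal$sec,
                               cal$pk,
                               extra = list(basal_target = basal_target,
                                            endpoint_target = endpoint_target,
                                            endpoint_min = endpoint_min)))
}
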
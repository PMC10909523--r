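#' Synaptic input protocol
#'
#' A piecewise-linear schedule for the excitatory PSP arrival rate `I_re`.
#' Each segment has a duration (s), a starting rate (Hz) and a slope (Hz/s);
#' the rate within a segment is `rate + slope * (t - segment start)`. The
#' inhibitory arrival rate follows as `I_ratio` times the scheduled rate.
#'
#' @param duration segment durations (s), all positive.
#' @param rate segment starting rates (Hz).
#' @param slope segment slopes (Hz/s); recycled if scalar.
#' @return An `input_protocol`: a data.frame with columns `duration`,
#'   `rate`, `slope`.
#' @examples
#' input_protocol(duration = c(600, 300), rate = c(370, 370), slope = c(0, 0.037))
#' @export
input_protocol <- function(duration, rate, slope = 0) {
  n <- length(duration)
  if (n == 0) stop("protocol must have at least one segment")
  slope <- rep_len(slope, n)
  if (length(rate) != n) stop("rate must have one value per segment")
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stop("segment durations must be positive")
  }
  ends <- rate + slope * duration
  if (any(rate < 0) || any(ends < 0)) {
    stop("input rate must remain >= 0 throughout every segment")
  }
  out <- data.frame(duration = duration, rate = rate, slope = slope)
  class(out) <- c("input_protocol", "data.frame")
  out
}

#' Total duration of a protocol
#' @param protocol an `input_protocol`.
#' @return Duration in seconds.
#' @export
protocol_duration <- function(protocol) sum(protocol$duration)

#' Scheduled input rate at given times
#'
#' Evaluates the piecewise-linear excitatory arrival rate of a protocol.
#'
#' @param protocol an `input_protocol`.
#' @param t times (s) in `[0, protocol_duration(protocol)]`.
#' @return Rates in Hz at each `t`.
#' @export
protocol_rate <- function(protocol, t) {
  starts <- cumsum(c(0, protocol$duration))
  total <- starts[length(starts)]
  if (any(t < 0 | t > total)) stop("t outside the protocol")
  idx <- pmin(findInterval(t, starts), nrow(protocol))
  protocol$rate[idx] + protocol$slope[idx] * (t - starts[idx])
}

#' Gavage stimulation protocol
#'
#' Builds the four-segment input schedule used for simulated gavage: a
#' constant baseline, a post-onset delay at the baseline rate, a linear ramp,
#' and a constant plateau at the end-of-ramp rate. With the defaults
#' (370 Hz baseline, 40-min control, 3.5-min delay, 0.037 Hz/s ramp for
#' 35 min, 20-min plateau) the plateau rate is 370 + 0.037 * 2100 =
#' 447.7 Hz.
#'
#' @param baseline_rate baseline excitatory arrival rate (Hz).
#' @param baseline_dur control-period duration before gavage onset (s).
#' @param delay delay between gavage onset and the ramp (s), at baseline rate.
#' @param ramp_slope ramp slope (Hz/s); negative slopes are allowed provided
#'   the rate stays non-negative.
#' @param ramp_dur ramp duration (s).
#' @param plateau_dur plateau duration (s) at the end-of-ramp rate.
#' @return An `input_protocol` with attribute `onset` (s), the gavage onset
#'   time (= `baseline_dur`).
#' @export
make_gavage_protocol <- function(baseline_rate = 370, baseline_dur = 2400,
                                 delay = 210, ramp_slope = 0.037,
                                 ramp_dur = 2100, plateau_dur = 1200) {
  durs <- c(baseline_dur, delay, ramp_dur, plateau_dur)
  if (any(durs < 0)) stop("durations must be >= 0")
  plateau_rate <- baseline_rate + ramp_slope * ramp_dur
  if (plateau_rate < 0) stop("ramp drives the input rate below zero")
  keep <- durs > 0
  proto <- input_protocol(
    duration = durs[keep],
    rate = c(baseline_rate, baseline_rate, baseline_rate, plateau_rate)[keep],
    slope = c(0, 0, ramp_slope, 0)[keep]
  )
  attr(proto, "onset") <- baseline_dur
  proto
}

#' Constant-rate protocol
#'
#' Convenience wrapper for a single constant-rate segment, used for basal
#' simulations and candidate evaluation during fitting.
#'
#' @param rate excitatory arrival rate (Hz).
#' @param duration duration (s).
#' @return An `input_protocol`.
#' @export
constant_protocol <- function(rate, duration) {
  input_protocol(duration = duration, rate = rate, slope = 0)
}
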
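#' Interspike-interval histogram
#'
#' Bins the interspike intervals (ISIs) of a train into left-closed bins
#' `[t, t + bin_width)` of width `bin_width` ms, up to `max_interval` ms.
#' Intervals of `max_interval` or longer are counted in an overflow bin so
#' that totals are conserved.
#'
#' @param train a [spike_train()] with at least 2 spikes.
#' @param bin_width bin width (ms).
#' @param max_interval analysis window (ms).
#' @return An `isi_histogram` with fields `bin_width`, `max_interval`,
#'   `breaks` (left bin edges, ms), `counts`, `overflow` and `n_isi`.
#' @export
isi_histogram <- function(train, bin_width = 5, max_interval = 1000) {
  if (length(train$times) < 2) {
    stop("at least 2 spikes are required to form interspike intervals")
  }
  # snap to nanosecond precision so intervals that are exact multiples of
  # the bin width (e.g. from fixed-step simulation) bin identically under a
  # global time shift
  isi_ms <- round(diff(train$times) * 1000, 6)
  breaks <- seq(0, max_interval - bin_width, by = bin_width)
  idx <- floor(round(isi_ms / bin_width, 9)) + 1
  n_bins <- length(breaks)
  overflow <- sum(idx > n_bins)
  counts <- tabulate(idx[idx <= n_bins], nbins = n_bins)
  structure(list(bin_width = bin_width, max_interval = max_interval,
                 breaks = breaks, counts = counts, overflow = overflow,
                 n_isi = length(isi_ms)),
            class = "isi_histogram")
}

#' @export
as.data.frame.isi_histogram <- function(x, ...) {
  data.frame(bin_left_ms = x$breaks, bin_right_ms = x$breaks + x$bin_width,
             count = x$counts)
}

#' Hazard function of an ISI histogram
#'
#' Per-bin firing hazard: (number of ISIs in bin `[t, t + w)`) divided by
#' (number of ISIs of length > `t`), where `t` is the left bin edge. Bins
#' whose denominator is zero are marked undefined (`NA`) rather than
#' zero-filled, and the computation stops there.
#'
#' @param hist an [isi_histogram()].
#' @return A `hazard_function` with fields `bin_width`, `breaks`, `values`
#'   (in `[0, 1]`, `NA` where undefined), `defined` (logical) and
#'   `denominators`.
#' @export
hazard <- function(hist) {
  if (!inherits(hist, "isi_histogram")) stop("hist must be an isi_histogram")
  if (hist$n_isi < 1) stop("hazard requires at least one interval")
  surviving <- hist$n_isi - c(0, cumsum(hist$counts)[-length(hist$counts)])
  defined <- surviving > 0
  values <- ifelse(defined, hist$counts / surviving, NA_real_)
  structure(list(bin_width = hist$bin_width, breaks = hist$breaks,
                 values = values, defined = defined,
                 denominators = surviving),
            class = "hazard_function")
}

#' @export
as.data.frame.hazard_function <- function(x, ...) {
  data.frame(bin_left_ms = x$breaks, hazard = x$values, defined = x$defined)
}

#' Index-of-dispersion profile
#'
#' The index of dispersion (IoD) of per-bin spike counts -- variance over
#' mean -- computed at a range of bin widths (default 0.5 to 10 s). An IoD
#' near 1 indicates Poisson-like variability; values above 1 indicate
#' clustered or rate-modulated firing. A width is flagged unreliable when
#' fewer than 10 whole bins fit in the record.
#'
#' @param train a [spike_train()].
#' @param widths bin widths (s).
#' @return An `iod_profile`: a data.frame with columns `width`, `iod`,
#'   `n_bins`, `reliable`.
#' @export
iod_profile <- function(train, widths = c(0.5, 1:10)) {
  rows <- lapply(widths, function(w) {
    n_bins <- floor(train$duration / w)
    if (n_bins < 2) {
      return(data.frame(width = w, iod = NA_real_, n_bins = n_bins,
                        reliable = FALSE))
    }
    idx <- floor(round(train$times / w, 9)) + 1
    counts <- tabulate(idx[idx <= n_bins], nbins = n_bins)
    m <- mean(counts)
    iod <- if (m > 0) var(counts) / m else NA_real_
    data.frame(width = w, iod = iod, n_bins = n_bins,
               reliable = n_bins >= 10 && m > 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("iod_profile", "data.frame")
  out
}

#' Rate-series constructor
#'
#' Assembles a `rate_series` from per-bin values. [binned_rate()] is the
#' usual way to obtain one from a spike train; the constructor is useful for
#' building exact fixtures.
#'
#' @param values per-bin values (counts per bin, or baseline-subtracted
#'   counts when `normalised`).
#' @param bin_width bin width (s).
#' @param t0 time of the first bin's left edge (s).
#' @param normalised whether values are baseline-subtracted.
#' @return A `rate_series`.
#' @export
rate_series <- function(values, bin_width = 30, t0 = 0, normalised = FALSE) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!normalised && any(values < 0)) {
    stop("un-normalised rate values must be >= 0")
  }
  structure(list(bin_width = bin_width, t0 = t0,
                 values = as.numeric(values), normalised = normalised),
            class = "rate_series")
}

#' Binned firing-rate series
#'
#' Counts spikes in consecutive bins of `bin_width` seconds (default 30 s).
#' Only whole bins are kept, so the series has `floor(duration/bin_width)`
#' values and the counts over those bins sum to the number of spikes they
#' cover.
#'
#' @param train a [spike_train()].
#' @param bin_width bin width (s).
#' @param t0 time of the first bin's left edge on the reporting axis (s);
#'   use this to place the series relative to a stimulus onset.
#' @return A `rate_series` with fields `bin_width`, `t0`, `values` (counts
#'   per bin, or baseline-subtracted counts once normalised) and
#'   `normalised`.
#' @export
binned_rate <- function(train, bin_width = 30, t0 = 0) {
  if (train$duration < bin_width) stop("duration must be >= bin_width")
  n_bins <- floor(train$duration / bin_width)
  idx <- floor(round(train$times / bin_width, 9)) + 1
  counts <- tabulate(idx[idx <= n_bins], nbins = n_bins)
  rate_series(counts, bin_width = bin_width, t0 = t0)
}

#' @export
as.data.frame.rate_series <- function(x, ...) {
  data.frame(t = x$t0 + (seq_along(x$values) - 1) * x$bin_width,
             value = x$values)
}

#' Subtract the baseline mean from a rate series
#'
#' Normalises a binned-rate series by subtracting the mean count per bin
#' over a baseline window, as done with the 10-min pre-gavage period of each
#' recorded cell.
#'
#' @param series a [binned_rate()] series.
#' @param baseline_window numeric length-2, `c(from, to)` in seconds on the
#'   series time axis; the bins fully inside it form the baseline.
#' @return The normalised `rate_series` (`normalised = TRUE`).
#' @export
normalise_to_baseline <- function(series, baseline_window) {
  if (length(baseline_window) != 2 || diff(baseline_window) <= 0) {
    stop("baseline_window must be c(from, to) with to > from")
  }
  starts <- series$t0 + (seq_along(series$values) - 1) * series$bin_width
  inside <- starts >= baseline_window[1] &
    (starts + series$bin_width) <= baseline_window[2] + 1e-9
  if (!any(inside)) stop("baseline window lies outside the series")
  series$values <- series$values - mean(series$values[inside])
  series$normalised <- TRUE
  series
}

#' Fixed-intercept linear ramp fit
#'
#' Fits `y = slope * (t - onset)` by least squares to the post-onset part of
#' a normalised rate series, i.e. a straight line constrained to pass
#' through zero at the onset. `y` is expressed in spikes/s (bin counts
#' divided by the bin width) and `t - onset` in minutes, so the slope is in
#' spikes/s per minute. The coefficient of determination is computed against
#' the mean of the post-onset data and truncated at zero.
#'
#' @param series a normalised [binned_rate()] series.
#' @param onset fixed x-intercept (s, on the series time axis).
#' @return A `ramp_fit` with fields `slope` (spikes/s per min), `r2`,
#'   `onset` (s) and `n_points`.
#' @export
fit_ramp <- function(series, onset) {
  if (!isTRUE(series$normalised)) {
    stop("fit_ramp expects a baseline-normalised series")
  }
  centres <- series$t0 + (seq_along(series$values) - 0.5) * series$bin_width
  keep <- centres >= onset
  if (sum(keep) < 3) stop("fewer than 3 points after onset")
  x <- (centres[keep] - onset) / 60
  y <- series$values[keep] / series$bin_width
  slope <- sum(x * y) / sum(x * x)
  res <- y - slope * x
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - sum(res^2) / ss_tot) else NA_real_
  structure(list(slope = slope, r2 = r2, onset = onset,
                 n_points = sum(keep)),
            class = "ramp_fit")
}

#' Pattern summary of a spike train
#'
#' Bundles the three fitting statistics -- ISI histogram, hazard function
#' and IoD profile -- together with the mean firing rate, all computed from
#' the same record. This is the fitting target and score input of the
#' genetic-algorithm procedure.
#'
#' @param train a [spike_train()].
#' @param isi_bin ISI bin width (ms).
#' @param max_interval ISI/hazard analysis window (ms).
#' @param iod_widths IoD bin widths (s).
#' @param min_isi warn when the record yields fewer ISIs than this.
#' @return A `pattern_summary` with fields `isi`, `hazard`, `iod`,
#'   `mean_rate`.
#' @export
summarise_train <- function(train, isi_bin = 5, max_interval = 1000,
                            iod_widths = c(0.5, 1:10), min_isi = 100) {
  isi <- isi_histogram(train, isi_bin, max_interval)
  if (isi$n_isi < min_isi) {
    warning(sprintf("only %d ISIs; pattern statistics will be noisy",
                    isi$n_isi))
  }
  pattern_summary(isi = isi, hazard = hazard(isi),
                  iod = iod_profile(train, iod_widths),
                  mean_rate = mean_rate(train))
}

#' Low-level pattern-summary constructor
#'
#' Assembles a `pattern_summary` from precomputed components. Mainly useful
#' for constructing toy summaries; use [summarise_train()] for real trains.
#'
#' @param isi an `isi_histogram`.
#' @param hazard a `hazard_function`.
#' @param iod an `iod_profile`.
#' @param mean_rate mean firing rate (spikes/s).
#' @return A `pattern_summary`.
#' @export
pattern_summary <- function(isi, hazard, iod, mean_rate) {
  structure(list(isi = isi, hazard = hazard, iod = iod,
                 mean_rate = mean_rate),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf("<pattern_summary> %d ISIs, mean rate %.3f spikes/s\n",
              x$isi$n_isi, x$mean_rate))
  invisible(x)
}
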
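# Shared fixtures, all generated in code. Expensive simulations are memoised
# for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Homogeneous Poisson spike train of a given rate (spikes/s).
poisson_train <- function(rate, duration, seed = 1) {
  set.seed(seed)
  times <- cumsum(rexp(ceiling(rate * duration * 1.5) + 50, rate))
  times <- times[times < duration]
  spike_train(times, duration, label = "poisson fixture")
}

# Perfectly periodic train.
periodic_train <- function(period, duration) {
  spike_train(seq(period / 2, duration - 1e-9, by = period), duration,
              label = "periodic fixture")
}

# Inhomogeneous Poisson train with a linearly rising rate, by thinning.
ramped_poisson_train <- function(r0, r1, duration, seed = 1) {
  set.seed(seed)
  rmax <- max(r0, r1)
  times <- cumsum(rexp(ceiling(rmax * duration * 1.5) + 50, rmax))
  times <- times[times < duration]
  keep <- runif(length(times)) < (r0 + (r1 - r0) * times / duration) / rmax
  spike_train(times[keep], duration, label = "ramped poisson fixture")
}

# One 600-s consensus-cell train, reused by several tests.
consensus_train <- function() {
  memo("consensus600", simulate_neuron(consensus_neuron_params(),
                                       constant_protocol(370, 600),
                                       seed = 1))
}

# A hand-crafted hazard_function with controlled values and denominators.
toy_hazard <- function(values, denominators, bin_width = 5) {
  structure(list(bin_width = bin_width,
                 breaks = seq(0, by = bin_width,
                              length.out = length(values)),
                 values = values,
                 defined = !is.na(values),
                 denominators = denominators),
            class = "hazard_function")
}

# A toy pattern_summary built from hand-set components.
toy_summary <- function(hazard_values, denominators = rep(100, length(hazard_values)),
                        isi_counts = c(5, 5, 5), iod = c(1, 1)) {
  n_isi <- sum(isi_counts)
  isi <- structure(list(bin_width = 5,
                        max_interval = 5 * length(isi_counts),
                        breaks = seq(0, by = 5, length.out = length(isi_counts)),
                        counts = isi_counts, overflow = 0, n_isi = n_isi),
                   class = "isi_histogram")
  iodp <- data.frame(width = seq_along(iod), iod = iod,
                     n_bins = 100, reliable = TRUE)
  class(iodp) <- c("iod_profile", "data.frame")
  pattern_summary(isi = isi,
                  hazard = toy_hazard(hazard_values, denominators),
                  iod = iodp, mean_rate = 3)
}

# Constant secretion signal.
constant_signal <- function(value, duration, dt = 0.1) {
  structure(list(dt = dt, values = rep(value, round(duration / dt))),
            class = "secretion_signal")
}

# Plasma series wrapper for hand-set predictions.
toy_plasma_series <- function(plasma, dt = 60, onset_s = 0) {
  s <- structure(list(dt = dt, plasma = plasma, evf = rep(0, length(plasma)),
                      mass = NULL),
                 class = "plasma_series")
  attr(s, "onset_s") <- onset_s
  s
}
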
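test_that("ISI histogram bins intervals left-closed and conserves totals", {
  tr <- spike_train(c(0, 0.1, 0.2), 1)
  h <- isi_histogram(tr, bin_width = 5, max_interval = 200)
  expect_equal(h$n_isi, 2)
  expect_equal(h$counts[h$breaks == 100], 2)   # both 100-ms ISIs in [100, 105)
  expect_equal(sum(h$counts) + h$overflow, h$n_isi)

  expect_error(isi_histogram(spike_train(0.5, 1)), "2 spikes")

  tr2 <- poisson_train(3, 600, seed = 2)
  h2 <- isi_histogram(tr2)
  expect_equal(sum(h2$counts) + h2$overflow, length(tr2$times) - 1)
})

test_that("ISI histogram of a Poisson train follows the exponential law", {
  r <- 5
  tr <- poisson_train(r, 1200, seed = 3)
  h <- isi_histogram(tr, bin_width = 5, max_interval = 1000)
  emp <- h$counts / h$n_isi
  edges <- h$breaks / 1000
  theo <- exp(-r * edges) - exp(-r * (edges + 0.005))
  expect_lt(max(abs(emp - theo)), 0.012)
})

test_that("hazard matches hand-computed values on a toy histogram", {
  # ISIs of 2, 3, 7 and 12 ms -> 5-ms bin counts (2, 1, 1)
  tr <- spike_train(c(0, 0.002, 0.005, 0.012, 0.024), 1)
  h <- hazard(isi_histogram(tr, bin_width = 5, max_interval = 15))
  expect_equal(h$denominators, c(4, 2, 1))
  expect_equal(h$values, c(2 / 4, 1 / 2, 1 / 1))
  expect_true(all(h$defined))
})

test_that("hazard marks exhausted bins undefined instead of zero", {
  # all ISIs 7 ms: hazard 0 in [0,5), 1 in [5,10), undefined afterwards
  tr <- spike_train(seq(0, 0.028, by = 0.007), 1)
  h <- hazard(isi_histogram(tr, bin_width = 5, max_interval = 20))
  expect_equal(h$values[1:2], c(0, 1))
  expect_true(all(is.na(h$values[3:4])))
  expect_equal(h$defined, c(TRUE, TRUE, FALSE, FALSE))
  # the survivor sequence is non-increasing
  expect_true(all(diff(h$denominators) <= 0))
})

test_that("a Poisson train has a flat hazard at the memoryless level", {
  r <- 5
  tr <- poisson_train(r, 1200, seed = 4)
  h <- hazard(isi_histogram(tr))
  ok <- h$defined & h$denominators >= 300
  theo <- 1 - exp(-r * 0.005)
  expect_lt(abs(mean(h$values[ok]) - theo), 0.004)
  expect_true(all(h$values[h$defined] >= 0 & h$values[h$defined] <= 1))
})

test_that("index of dispersion separates periodic, Poisson and ramped firing", {
  per <- iod_profile(periodic_train(0.5, 200), widths = c(1, 2, 5))
  expect_equal(per$iod, rep(0, 3))

  ram <- iod_profile(ramped_poisson_train(1, 5, 600, seed = 5),
                     widths = c(0.5, 10))
  expect_gt(ram$iod[ram$width == 10], ram$iod[ram$width == 0.5])

  short <- iod_profile(poisson_train(3, 15, seed = 6), widths = c(10))
  expect_false(short$reliable[1])
})

test_that("binned rates count spikes per whole bin and conserve them", {
  tr <- spike_train(c(10, 40, 70), 90)
  rs <- binned_rate(tr, 30)
  expect_equal(rs$values, c(1, 1, 1))

  empty <- binned_rate(spike_train(numeric(0), 90), 30)
  expect_equal(empty$values, c(0, 0, 0))

  tr2 <- poisson_train(3, 305, seed = 7)
  rs2 <- binned_rate(tr2, 30)
  expect_equal(sum(rs2$values), sum(tr2$times < 300))
})

test_that("baseline normalisation zeroes the baseline exactly", {
  rs <- rate_series(rep(4, 20), bin_width = 30, t0 = -300)
  norm <- normalise_to_baseline(rs, c(-300, 0))
  expect_true(norm$normalised)
  expect_equal(norm$values, rep(0, 20))

  rs2 <- rate_series(c(1, 2, 3, 4, 5, 6), bin_width = 30, t0 = 0)
  norm2 <- normalise_to_baseline(rs2, c(0, 90))
  expect_equal(mean(norm2$values[1:3]), 0)
  # subtracting a constant preserves differences (hence any ramp slope)
  expect_equal(diff(norm2$values), diff(rs2$values))
  expect_error(normalise_to_baseline(rs2, c(-600, -300)), "outside")
})

test_that("the constrained ramp fit recovers a noiseless line exactly", {
  onset <- 210
  bw <- 30
  centres <- -600 + (seq_len(80) - 0.5) * bw
  slope_true <- 0.477                       # spikes/s per minute
  y <- ifelse(centres >= onset, slope_true * (centres - onset) / 60, 0)
  rs <- rate_series(y * bw, bin_width = bw, t0 = -600, normalised = TRUE)
  fit <- fit_ramp(rs, onset)
  expect_equal(fit$slope, slope_true, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  zero <- rate_series(rep(0, 40), bin_width = bw, t0 = 0, normalised = TRUE)
  expect_equal(fit_ramp(zero, 0)$slope, 0)

  expect_error(fit_ramp(rate_series(y * bw, bin_width = bw, t0 = -600), onset),
               "normalised")
  expect_error(fit_ramp(rs, 2500), "3 points")
})

test_that("the ramp fit is unbiased under Gaussian noise", {
  onset <- 0
  bw <- 30
  centres <- (seq_len(60) - 0.5) * bw
  x <- centres / 60
  slope_true <- 0.5
  slopes <- vapply(1:100, function(i) {
    set.seed(i)
    y <- slope_true * x + rnorm(60, 0, 0.4)
    rs <- rate_series(y * bw, bin_width = bw, t0 = 0, normalised = TRUE)
    fit_ramp(rs, onset)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - slope_true), 4 * se)
})

test_that("pattern summaries are pure and shift-invariant", {
  tr <- consensus_train()
  s1 <- summarise_train(tr)
  s2 <- summarise_train(tr)
  expect_identical(s1, s2)

  # interval statistics are invariant to a global time shift
  shifted <- spike_train(tr$times + 10, tr$duration + 10)
  a <- summarise_train(tr)
  b <- summarise_train(shifted)
  expect_identical(a$isi$counts, b$isi$counts)
  expect_identical(a$isi$overflow, b$isi$overflow)
  expect_identical(a$hazard$values, b$hazard$values)
})

test_that("short records trigger the low-ISI warning", {
  expect_warning(summarise_train(poisson_train(3, 10, seed = 8)), "noisy")
})
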
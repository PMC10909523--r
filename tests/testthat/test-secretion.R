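test_that("secretion of an empty train is identically zero", {
  sig <- secretion_from_spikes(spike_train(numeric(0), 10),
                               secretion_params())
  expect_equal(sum(sig$values), 0)
  expect_length(sig$values, 100)
})

test_that("a first spike releases exactly the base amount", {
  sec <- secretion_params(base_release = 2.5, facil_gain = 0.5)
  sig <- secretion_from_spikes(spike_train(1.23, 10), sec, dt = 0.1)
  expect_equal(sum(sig$values) * sig$dt, 2.5)
  expect_equal(which(sig$values > 0), 13)   # the bin containing t = 1.23
})

test_that("facilitation makes secretion supralinear in firing rate", {
  sec <- secretion_params()
  lo <- periodic_train(1 / 3.26, 600)
  hi <- periodic_train(1 / 4.8, 600)
  s_lo <- sum(secretion_from_spikes(lo, sec)$values)
  s_hi <- sum(secretion_from_spikes(hi, sec)$values)
  rate_ratio <- mean_rate(hi) / mean_rate(lo)
  expect_gt(s_hi / s_lo, rate_ratio)
})

test_that("averaging signals is the pointwise mean and reduces variance", {
  sec <- secretion_params()
  sig <- secretion_from_spikes(poisson_train(3, 60, seed = 1), sec)
  same <- average_signals(list(sig, sig, sig))
  expect_equal(same$values, sig$values)

  sigs <- lapply(1:8, function(s) {
    secretion_from_spikes(poisson_train(3, 60, seed = s), sec)
  })
  avg <- average_signals(sigs)
  expect_equal(mean(avg$values),
               mean(vapply(sigs, function(s) mean(s$values), numeric(1))))
  expect_lt(var(avg$values), var(sigs[[1]]$values) / 4)

  short <- secretion_from_spikes(poisson_train(3, 30, seed = 9), sec)
  expect_error(average_signals(list(sig, short)), "share")
})

test_that("constant input drives plasma to the closed-form steady state", {
  pk <- plasma_params(scaling = 0.2)
  rate <- 4.7
  sig <- constant_signal(rate, 3600)
  out <- plasma_dynamics(sig, pk)
  target <- pk$scaling * rate * 60 / (pk$v_plasma * pk$k_clear)
  expect_equal(tail(out$plasma, 1), target, tolerance = 1e-6)
  expect_equal(unname(plasma_steady_state(rate, pk)["plasma"]), target)
})

test_that("a bolus decays biexponentially, matching an ODE oracle", {
  pk <- plasma_params()
  sig <- constant_signal(0, 600)
  out <- plasma_dynamics(sig, pk, init = c(100, 0))

  oracle <- deSolve::lsoda(
    y = c(P = 100, E = 0),
    times = seq(0, 10, by = 1),    # minutes
    func = function(t, y, p) {
      list(c(-(pk$k_pe + pk$k_clear) * y[1] + pk$k_ep * y[2],
             pk$k_pe * y[1] - pk$k_ep * y[2]))
    },
    parms = NULL, rtol = 1e-10, atol = 1e-10)
  sim_at <- out$plasma[seq(1, 10) * 600]    # every simulated minute
  expect_equal(sim_at, oracle[-1, "P"], tolerance = 1e-6,
               ignore_attr = TRUE)
  # both eigenvalues of the rate matrix are negative (stable biexponential)
  ev <- eigen(matrix(c(-(pk$k_pe + pk$k_clear), pk$k_pe,
                       pk$k_ep, -pk$k_ep), 2))$values
  expect_true(all(ev < 0))
})

test_that("zero input from a zero state stays identically zero", {
  out <- plasma_dynamics(constant_signal(0, 100), plasma_params())
  expect_equal(max(abs(out$plasma)), 0)
  expect_equal(max(abs(out$evf)), 0)
})

test_that("mass balance holds to integration tolerance", {
  sec <- secretion_params(facil_gain = 0.02)
  sig <- secretion_from_spikes(consensus_train(), sec)
  out <- plasma_dynamics(sig, plasma_params(scaling = 0.15))
  expect_lt(out$mass$rel_error, 1e-6)
})

test_that("the plasma model is monotone and superposable in its input", {
  pk <- plasma_params()
  a <- constant_signal(2, 300)
  b <- a
  set.seed(1)
  b$values <- b$values + runif(length(b$values), 0, 1)
  pa <- plasma_dynamics(a, pk)
  pb <- plasma_dynamics(b, pk)
  expect_true(all(pb$plasma >= pa$plasma - 1e-12))

  s <- a
  s$values <- a$values + b$values
  ps <- plasma_dynamics(s, pk)
  expect_equal(ps$plasma, pa$plasma + pb$plasma, tolerance = 1e-9)
})

test_that("calibration hits its anchors and scales linearly", {
  proto <- make_gavage_protocol(baseline_dur = 600, delay = 60,
                                ramp_slope = 0.2, ramp_dur = 600,
                                plateau_dur = 240)
  trains <- lapply(1:5, function(i) {
    simulate_neuron(consensus_neuron_params(), proto, seed = 20 + i)
  })
  endpoint_time <- 600 + 60 + 600 + 120
  cal <- calibrate_secretion(trains, secretion_params(), plasma_params(),
                             basal_target = 65, endpoint_target = 180,
                             basal_window = c(0, 600),
                             endpoint_time = endpoint_time)
  expect_lt(abs(cal$series$plasma[endpoint_time / 0.1] - 180) / 180, 0.02)

  cal2 <- calibrate_secretion(trains, secretion_params(), plasma_params(),
                              basal_target = 130, endpoint_target = 360,
                              basal_window = c(0, 600),
                              endpoint_time = endpoint_time)
  expect_equal(cal2$scaling / cal$scaling, 2, tolerance = 1e-4)
  expect_equal(cal2$facil_gain, cal$facil_gain, tolerance = 1e-4)

  expect_error(
    calibrate_secretion(trains, secretion_params(), plasma_params(),
                        basal_target = 65, endpoint_target = 5000,
                        basal_window = c(0, 600),
                        endpoint_time = endpoint_time,
                        gain_bounds = c(0, 0.001)),
    "calibration failure")
})
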
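test_that("fit_score is zero on identity and symmetric without target scaling", {
  s <- suppressWarnings(summarise_train(poisson_train(3, 300, seed = 1)))
  self <- fit_score(s, s)
  expect_equal(self$score, 0)
  expect_equal(unname(self$components), c(0, 0, 0))

  s2 <- suppressWarnings(summarise_train(poisson_train(4, 300, seed = 2)))
  a <- fit_score(s, s2, scale = "none")$score
  b <- fit_score(s2, s, scale = "none")$score
  expect_gt(a, 0)
  expect_equal(a, b)
})

test_that("fit_score reproduces hand arithmetic on a toy comparison", {
  target <- toy_summary(hazard_values = c(0.5, 0.4, 0.3))
  cand <- toy_summary(hazard_values = c(0.4, 0.4, 0.4))
  out <- fit_score(target, cand, fit_weights(1, 1, 1), scale = "none")
  # ISI and IoD agree; hazard differs by (0.1, 0, -0.1) at equal denominators
  expect_equal(out$components[["isi"]], 0)
  expect_equal(out$components[["iod"]], 0)
  expect_equal(out$score, sqrt(0.02 / 3))
})

test_that("fit_score weights rescale the components linearly", {
  target <- toy_summary(hazard_values = c(0.5, 0.4, 0.3))
  cand <- toy_summary(hazard_values = c(0.4, 0.4, 0.4))
  base <- fit_score(target, cand, fit_weights(1, 1, 1), scale = "none")$score
  doubled <- fit_score(target, cand, fit_weights(1, 2, 1),
                       scale = "none")$score
  expect_equal(doubled, 2 * base)
  expect_error(fit_weights(0, 0, 0), "at least one")
})

test_that("fit_score rejects mismatched bin structures", {
  tr <- poisson_train(3, 300, seed = 3)
  a <- suppressWarnings(summarise_train(tr, isi_bin = 5))
  b <- suppressWarnings(summarise_train(tr, isi_bin = 10))
  expect_error(fit_score(a, b), "mismatched")
  c <- suppressWarnings(summarise_train(tr, iod_widths = c(1, 2)))
  d <- suppressWarnings(summarise_train(tr, iod_widths = c(1, 3)))
  expect_error(fit_score(c, d), "mismatched")
})

test_that("GA respects variant constraints and is reproducible", {
  target <- suppressWarnings(summarise_train(consensus_train()))
  cfg <- ga_config(pop_size = 8, generations = 2, runs = 1, seed = 5,
                   eval_duration = 60)
  fit <- ga_fit(target, "HAP_only", cfg)
  expect_equal(fit$params$k_DAP, 0)
  expect_equal(fit$params$k_AHP, 0)

  fit2 <- ga_fit(target, "HAP_only", cfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$score, fit2$score)
})

test_that("the elite score trajectory is non-increasing within a run", {
  target <- suppressWarnings(summarise_train(consensus_train()))
  cfg <- ga_config(pop_size = 10, generations = 5, runs = 1, seed = 6,
                   eval_duration = 60)
  fit <- ga_fit(target, "HAP_AHP", cfg)
  expect_true(all(diff(fit$history[[1]]) <= 1e-12))
})

test_that("more GA restarts can only improve the best score", {
  target <- suppressWarnings(summarise_train(consensus_train()))
  cfg1 <- ga_config(pop_size = 8, generations = 2, runs = 1, seed = 7,
                    eval_duration = 60)
  cfg3 <- ga_config(pop_size = 8, generations = 2, runs = 3, seed = 7,
                    eval_duration = 60)
  s1 <- ga_fit(target, "HAP_AHP", cfg1)$score
  s3 <- ga_fit(target, "HAP_AHP", cfg3)$score
  expect_lte(s3, s1)
})

test_that("fit_all_variants returns the best-scoring variant", {
  target <- suppressWarnings(summarise_train(consensus_train()))
  cfg <- ga_config(pop_size = 8, generations = 1, runs = 1, seed = 8,
                   eval_duration = 60)
  best <- fit_all_variants(target, cfg)
  all_fits <- attr(best, "all_fits")
  expect_length(all_fits, 4)
  scores <- vapply(all_fits, function(f) f$score, numeric(1))
  expect_equal(best$score, min(scores))
})

test_that("consensus construction reproduces the published statistics", {
  res <- consensus_params(oxytocin_fits())
  expect_equal(res$hap_regression$r2, 0.6432, tolerance = 1e-3)
  expect_equal(res$params$k_AHP, 0.5)
  expect_equal(res$params$lambda_AHP, 600)
  expect_equal(res$params$I_re, 370)
  # the HAP consensus lies on the regression line, near the medians
  with(res$hap_regression,
       expect_equal(res$params$lambda_HAP,
                    intercept + slope * res$params$k_HAP, tolerance = 1e-9))
  expect_lt(abs(res$params$k_HAP - res$medians[["k_HAP"]]), 5)
  expect_lt(abs(res$params$lambda_HAP - res$medians[["lambda_HAP"]]), 3)
})

test_that("consensus of identical fits returns those parameters", {
  row <- data.frame(cell = c("a", "b"), I_re = 370, k_HAP = 50,
                    lambda_HAP = 8, k_DAP = 3, lambda_DAP = 50,
                    k_AHP = 0.5, lambda_AHP = 600)
  res <- consensus_params(row)
  expect_equal(res$params$k_HAP, 50)
  expect_equal(res$params$lambda_HAP, 8)
  expect_equal(res$params$I_re, 370)
  expect_equal(res$params$k_DAP, 3)
  expect_error(consensus_params(row[1, ]), "at least 2")
})
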
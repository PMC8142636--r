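test_that("a noiseless simulation returns the causal effect exactly", {
  cfg <- sim_config(k = 6, theta = -1.1, se_exp_scale = 0, se_out_scale = 0,
                    seed = 4)
  study <- simulate_study(cfg)
  h <- harmonize(study$exposure, study$outcome)
  expect_equal(nrow(h), 6L)
  est <- mr_ivw(h)
  expect_equal(est$beta, -1.1, tolerance = 1e-9)
  expect_equal(cochran_q(h)$q, 0, tolerance = 1e-12)
})

test_that("identical config and seed reproduce the study byte-for-byte", {
  cfg <- sim_config(k = 11, theta = 0.3, pleiotropy_mode = "balanced",
                    seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  for (f in c("exposure.tsv", "outcome.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the draw
  cfg2 <- cfg
  cfg2$seed <- 78
  expect_false(identical(simulate_study(cfg2)$exposure$beta,
                         simulate_study(cfg)$exposure$beta))
})

test_that("simulated studies flow through the standard pipeline path", {
  study <- simulate_study(sim_config(k = 11, theta = -0.5, seed = 12))
  expect_s3_class(study$exposure, "mr_associations")
  h <- harmonize(study$exposure, study$outcome)
  expect_equal(nrow(h), 11L)  # non-palindromic pairs: nothing dropped
  expect_true(all(h$beta_exp > 0))
})

test_that("IVW recovers the causal effect at fixture-matched noise", {
  ex <- fixture_exposure()
  ao <- read_associations(vitc_pd_example()$pd_aao)
  cfg <- sim_config(k = 11, theta = -1.134,
                    se_exp_scale = ex$se, se_out_scale = ao$se)
  oc <- operating_characteristics(cfg, "ivw", n_reps = 500, seed = 303)
  expect_lt(abs(oc$bias), 0.05)
})

test_that("operating characteristics handle edge cases and bad input", {
  oc <- operating_characteristics(sim_config(k = 5, theta = 1),
                                  "egger", n_reps = 1, seed = 5)
  expect_equal(oc$n_reps, 1)
  expect_true(all(is.finite(c(oc$mean_estimate, oc$mean_se, oc$coverage,
                              oc$rejection_rate))))
  expect_true(is.na(oc$empirical_se))
  expect_error(operating_characteristics(sim_config(), "mode", 10, 1),
               "unknown estimator")
  # a config grid returns one row per configuration
  grid <- list(sim_config(k = 4, theta = 0), sim_config(k = 6, theta = 1))
  oc2 <- operating_characteristics(grid, "ivw", n_reps = 5, seed = 2)
  expect_equal(nrow(oc2), 2L)
  expect_equal(oc2$k, c(4L, 6L))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(k = 2), "k >= 3")
  expect_error(sim_config(gamma_range = c(-0.1, 0.2)))
  expect_error(sim_config(se_out_scale = -1))
  expect_error(sim_config(k = 5, se_exp_scale = c(0.1, 0.2)))
})

test_that("directional pleiotropy shifts the weighted median less than IVW", {
  # 4 of 11 instruments carry a strong positive direct effect; the valid
  # majority keeps the median anchored while IVW absorbs the full bias
  reps <- 60
  bias_ivw <- bias_wm <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(800 + i)
    k <- 11
    gamma <- runif(k, 0.1, 0.4)
    alpha_d <- c(rep(0.3, 4), rep(0, 7))
    bx <- rnorm(k, gamma, 0.01)
    by <- rnorm(k, 0 * gamma + alpha_d, 0.05)
    h <- make_hset(bx, by, se_out = rep(0.05, k), se_exp = rep(0.01, k))
    bias_ivw[i] <- mr_ivw(h)$beta
    bias_wm[i] <- weighted_median(h, n_boot = 20, seed = i)$beta
  }
  expect_lt(abs(mean(bias_wm)), abs(mean(bias_ivw)))
})
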
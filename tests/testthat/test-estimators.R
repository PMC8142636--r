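test_that("the Wald ratio is the outcome/exposure effect quotient", {
  h <- fixture_harmonized("pd_aao")
  est <- wald_ratio(h[h$snp == "rs33972313", ])
  expect_equal(est$beta, -0.751 / 0.36, tolerance = 1e-10)
  expect_equal(est$se, 0.353 / 0.36, tolerance = 1e-10)
  expect_equal(est$beta, -2.0861, tolerance = 1e-4)
  expect_equal(est$se, 0.9806, tolerance = 1e-4)

  zero <- wald_ratio(make_hset(0.5, 0, 0.1))
  expect_equal(zero$beta, 0)
  expect_equal(zero$pvalue, 1)

  ident <- wald_ratio(make_hset(1, 0.3, 0.12))
  expect_equal(ident$beta, 0.3)
  expect_equal(ident$se, 0.12)

  expect_error(wald_ratio(make_hset(0, 0.3, 0.12)), "zero")
})

test_that("IVW equals the weighted through-origin regression", {
  for (seed in 1:5) {
    h <- rand_hset(5, seed)
    fit <- stats::lm(beta_out ~ 0 + beta_exp, data = h,
                     weights = 1 / h$se_out^2)
    est <- mr_ivw(h)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)
    # multiplicative random-effects SE equals the lm SE when Q/(k-1) > 1,
    # and the fixed-effect SE when the dispersion is floored
    lm_se <- summary(fit)$coefficients[1, 2]
    fixed_se <- 1 / sqrt(sum(h$beta_exp^2 / h$se_out^2))
    expect_equal(est$se, max(lm_se, fixed_se), tolerance = 1e-12)
    expect_gte(est$inflation, 1)
  }
})

test_that("IVW with equal outcome SEs is the unweighted origin slope", {
  for (seed in 1:5) {
    set.seed(seed)
    h <- make_hset(runif(5, 0.05, 0.4), rnorm(5, 0, 0.2),
                   se_out = rep(0.17, 5))
    ols <- sum(h$beta_exp * h$beta_out) / sum(h$beta_exp^2)
    expect_equal(mr_ivw(h)$beta, ols, tolerance = 1e-12)
  }
})

test_that("IVW degenerate cases: single instrument and duplicated rows", {
  one <- make_hset(0.2, -0.4, 0.1)
  est1 <- mr_ivw(one)
  w <- wald_ratio(one)
  expect_equal(est1$beta, w$beta)
  expect_equal(est1$se, w$se)
  expect_equal(est1$inflation, 1)

  two <- rbind(one, one)
  class(two) <- class(one)
  est2 <- mr_ivw(two, model = "fixed")
  expect_equal(est2$beta, est1$beta)
  expect_equal(est2$se, est1$se / sqrt(2), tolerance = 1e-12)

  empty <- fixture_harmonized("pd_aao")[0, ]
  expect_error(mr_ivw(empty), "at least 1")
})

test_that("MR-Egger matches the weighted least-squares oracle", {
  # 3-point set solved through the normal equations directly
  h <- make_hset(c(0.1, 0.2, 0.4), c(0.05, 0.3, 0.5),
                 se_out = c(0.1, 0.2, 0.15))
  w <- 1 / h$se_out^2
  xtx <- rbind(c(sum(w), sum(w * h$beta_exp)),
               c(sum(w * h$beta_exp), sum(w * h$beta_exp^2)))
  ab <- solve(xtx, c(sum(w * h$beta_out), sum(w * h$beta_exp * h$beta_out)))
  est <- mr_egger(h)
  expect_equal(est$intercept$beta, ab[1], tolerance = 1e-12)
  expect_equal(est$slope$beta, ab[2], tolerance = 1e-12)

  for (seed in 1:5) {
    hr <- rand_hset(8, seed + 100)
    fit <- stats::lm(beta_out ~ beta_exp, data = hr,
                     weights = 1 / hr$se_out^2)
    er <- mr_egger(hr)
    expect_equal(er$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(er$intercept$beta, unname(coef(fit)[1]), tolerance = 1e-10)
    if (er$q_egger / (nrow(hr) - 2) >= 1) {
      expect_equal(er$slope$se,
                   summary(fit)$coefficients[2, 2], tolerance = 1e-10)
    }
  }
  expect_error(mr_egger(make_hset(c(0.1, 0.2), c(0.1, 0.2), c(0.1, 0.1))),
               "at least 3")
})

test_that("points on a line through the origin give a null Egger intercept", {
  h <- make_hset(c(0.1, 0.2, 0.3, 0.4), 2 * c(0.1, 0.2, 0.3, 0.4),
                 se_out = c(0.1, 0.15, 0.2, 0.25))
  est <- mr_egger(h)
  expect_equal(est$intercept$beta, 0, tolerance = 1e-12)
  expect_equal(est$slope$beta, 2, tolerance = 1e-12)
  expect_equal(est$q_egger, 0, tolerance = 1e-20)
  expect_equal(est$slope$inflation, 1)
})

test_that("Egger constrained to a zero intercept reduces to IVW", {
  for (seed in 1:5) {
    h <- rand_hset(6, seed + 200)
    constrained <- stats::lm(beta_out ~ 0 + beta_exp, data = h,
                             weights = 1 / h$se_out^2)
    expect_equal(mr_ivw(h)$beta, unname(coef(constrained)),
                 tolerance = 1e-12)
  }
})

test_that("the weighted median interpolates the cumulative weight grid", {
  h <- make_hset(c(1, 1, 1), c(1, 2, 9), se_out = c(1, 1, 1))
  est <- weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(est$beta, 2, tolerance = 1e-12)

  # identical ratios collapse to that ratio with a tiny bootstrap SE
  h2 <- make_hset(c(0.1, 0.2, 0.3), 1.5 * c(0.1, 0.2, 0.3),
                  se_out = rep(1e-5, 3), se_exp = rep(1e-6, 3))
  est2 <- weighted_median(h2, n_boot = 200, seed = 1)
  expect_equal(est2$beta, 1.5, tolerance = 1e-9)
  expect_lt(est2$se, 1e-3)
})

test_that("the weighted median always lies inside the ratio range", {
  for (seed in 1:25) {
    h <- rand_hset(7, seed + 300)
    r <- h$beta_out / h$beta_exp
    est <- weighted_median(h, n_boot = 10, seed = seed)
    expect_gte(est$beta, min(r))
    expect_lte(est$beta, max(r))
  }
})

test_that("estimators are scale-equivariant in the outcome units", {
  h <- fixture_harmonized("pd_aao")
  hc <- h
  cf <- 3.7
  hc$beta_out <- cf * hc$beta_out
  hc$se_out <- cf * hc$se_out
  for (f in list(function(d) mr_ivw(d),
                 function(d) mr_egger(d)$slope,
                 function(d) weighted_median(d, n_boot = 100, seed = 9))) {
    a <- f(h)
    b <- f(hc)
    expect_equal(b$beta, cf * a$beta, tolerance = 1e-9)
    expect_equal(b$se, cf * a$se, tolerance = 1e-9)
  }
})

test_that("stochastic estimators are reproducible under a fixed seed", {
  h <- fixture_harmonized("pd_aao")
  a <- weighted_median(h, n_boot = 300, seed = 123)
  b <- weighted_median(h, n_boot = 300, seed = 123)
  expect_identical(a$se, b$se)
  expect_identical(a$pvalue, b$pvalue)
})
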
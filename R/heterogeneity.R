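#' Cochran's Q heterogeneity test with I-squared
#'
#' Measures dispersion of the per-variant ratio estimates
#' `r_j = beta_out/beta_exp` around the fixed-effect inverse-variance
#' weighted estimate, with weights `w_j = (beta_exp/se_out)^2`:
#' `Q = sum w_j (r_j - beta_IVW)^2`, referred to a chi-square with `k - 1`
#' degrees of freedom. `I^2 = max(0, (Q - df)/Q) * 100` quantifies the
#' percentage of variability beyond sampling error. The I-squared confidence
#' interval uses the Higgins-Thompson test-based method on
#' `H = sqrt(Q/df)`: a normal interval for `log H` (with the standard
#' large-Q / small-Q standard-error formulas), back-transformed and
#' truncated to \[0, 100\].
#'
#' @param h a `harmonized_set` with k >= 2.
#' @param alpha two-sided confidence level complement for the I-squared CI.
#' @return object of class `mr_heterogeneity`: list with `q`, `df`, `pvalue`,
#'   `i2`, `i2_ci_low`, `i2_ci_high`, `k`.
#' @examples
#' paths <- vitc_pd_example()
#' h <- harmonize(read_associations(paths$exposure),
#'                read_associations(paths$pd_aao))
#' cochran_q(h)
#' @export
cochran_q <- function(h, alpha = 0.05) {
  check_harmonized(h, 2L, "cochran_q")
  k <- nrow(h)
  r <- h$beta_out / h$beta_exp
  w <- (h$beta_exp / h$se_out)^2
  beta_ivw <- sum(w * r) / sum(w)
  q <- sum(w * (r - beta_ivw)^2)
  df <- k - 1L
  pvalue <- stats::pchisq(q, df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0

  # test-based CI on H = sqrt(Q/df), log scale
  z <- stats::qnorm(1 - alpha / 2)
  se_ln_h <- if (q > k) {
    0.5 * (log(q) - log(df)) / (sqrt(2 * q) - sqrt(2 * df - 1))
  } else if (k > 2L) {
    sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  } else {
    NA_real_
  }
  if (is.finite(se_ln_h) && q > 0) {
    h_stat <- sqrt(q / df)
    h_low <- exp(log(h_stat) - z * se_ln_h)
    h_high <- exp(log(h_stat) + z * se_ln_h)
    i2_from_h <- function(hh) max(0, min(100, (hh^2 - 1) / hh^2 * 100))
    ci <- c(i2_from_h(h_low), i2_from_h(h_high))
  } else {
    ci <- c(0, 100)  # uninformative: no usable dispersion scale
  }
  out <- list(q = q, df = df, pvalue = pvalue, i2 = i2,
              i2_ci_low = ci[1], i2_ci_high = ci[2], k = k)
  class(out) <- "mr_heterogeneity"
  out
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf(
    "Cochran's Q = %.4f (df = %d, p = %.4g); I2 = %.1f%% [%.1f%%, %.1f%%]\n",
    x$q, x$df, x$pvalue, x$i2, x$i2_ci_low, x$i2_ci_high))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept component of [mr_egger()] together with a
#' directional-pleiotropy flag at the given significance threshold. A nonzero
#' intercept indicates that the instruments' direct (non-exposure-mediated)
#' effects on the outcome do not average to zero.
#'
#' @param h a `harmonized_set` with k >= 3.
#' @param alpha significance threshold (default 0.05).
#' @return the intercept `mr_estimate` with an added logical field
#'   `directional_pleiotropy`.
#' @examples
#' paths <- vitc_pd_example()
#' h <- harmonize(read_associations(paths$exposure),
#'                read_associations(paths$pd))
#' egger_intercept_test(h)
#' @export
egger_intercept_test <- function(h, alpha = 0.05) {
  est <- mr_egger(h, alpha = alpha)$intercept
  est$directional_pleiotropy <- est$pvalue < alpha
  est
}
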
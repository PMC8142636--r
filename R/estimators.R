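#' Construct a causal-estimate record
#'
#' Internal constructor shared by all estimators. Confidence intervals are
#' normal-based (`beta +/- z_{1-alpha/2} * se`) for every method, matching
#' how such estimates are conventionally tabulated; the two-sided p-value
#' uses `ref_dist` (standard normal, or Student-t with `df` degrees of
#' freedom for the through-origin regression behind MR-PRESSO).
#'
#' @keywords internal
new_mr_estimate <- function(method, beta, se, k, inflation = 1,
                            ref_dist = c("normal", "t"), df = NA_real_,
                            alpha = 0.05) {
  ref_dist <- match.arg(ref_dist)
  beta <- unname(beta)
  se <- unname(se)
  inflation <- unname(inflation)
  stopifnot(is.finite(beta), is.finite(se), se > 0, inflation >= 1)
  crit <- stats::qnorm(1 - alpha / 2)
  if (ref_dist == "t") {
    stopifnot(is.finite(df), df > 0)
    pvalue <- 2 * stats::pt(-abs(beta / se), df)
  } else {
    pvalue <- 2 * stats::pnorm(-abs(beta / se))
  }
  out <- list(method = method, beta = beta, se = se,
              ci_low = beta - crit * se, ci_high = beta + crit * se,
              pvalue = max(pvalue, .Machine$double.xmin),
              k = as.integer(k), inflation = inflation,
              ref_dist = ref_dist, df = df, alpha = alpha)
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s estimate (k = %d)\n", x$method, x$k))
  cat(sprintf("  beta = %.*f, se = %.*f, %d%% CI [%.*f, %.*f], p = %.4g\n",
              digits, x$beta, digits, x$se,
              round(100 * (1 - x$alpha)), digits, x$ci_low, digits,
              x$ci_high, x$pvalue))
  if (x$inflation > 1) {
    cat(sprintf("  SE inflated by %.3f (multiplicative dispersion)\n",
                x$inflation))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, pvalue = x$pvalue, k = x$k,
             inflation = x$inflation, ref_dist = x$ref_dist, df = x$df,
             stringsAsFactors = FALSE)
}

check_harmonized <- function(h, k_min = 1L, caller = "estimator") {
  stopifnot(is.data.frame(h))
  needed <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(needed %in% names(h))) {
    stop(caller, " requires a harmonized set with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(h) < k_min) {
    stop(caller, " requires at least ", k_min, " variant(s), got ", nrow(h),
         call. = FALSE)
  }
  invisible(h)
}

#' Wald ratio estimate from a single instrument
#'
#' The single-instrument causal estimate: outcome effect divided by exposure
#' effect, with a first-order delta-method standard error
#' `se_out / |beta_exp|` that ignores exposure measurement error.
#'
#' @param v one-row harmonized set (or list) with `beta_exp, se_exp,
#'   beta_out, se_out`.
#' @param alpha two-sided confidence level complement (default 0.05).
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(v, alpha = 0.05) {
  v <- as.data.frame(v)
  check_harmonized(v, 1L, "wald_ratio")
  if (nrow(v) != 1L) stop("wald_ratio takes exactly one variant",
                          call. = FALSE)
  if (v$beta_exp == 0) {
    stop("undefined ratio: exposure effect is zero", call. = FALSE)
  }
  new_mr_estimate("wald_ratio", v$beta_out / v$beta_exp,
                  v$se_out / abs(v$beta_exp), k = 1L, alpha = alpha)
}

#' Inverse-variance weighted causal estimate
#'
#' Combines per-variant Wald ratios with inverse-variance weights,
#' equivalently a weighted regression of outcome effects on exposure effects
#' through the origin with weights `1/se_out^2`. Under the default
#' multiplicative random-effects model the fixed-effect standard error is
#' inflated by `max(1, sqrt(Q/(k-1)))`, where Q is the weighted residual sum
#' of squares of that regression, so that between-instrument heterogeneity
#' widens (never narrows) the interval. Confidence limits and the two-sided
#' p-value use standard-normal quantiles.
#'
#' @param h a `harmonized_set` (k >= 1; k >= 2 recommended for the
#'   random-effects dispersion to be informative).
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @param alpha two-sided confidence level complement.
#' @return an `mr_estimate` with `inflation` recording the dispersion factor.
#' @examples
#' paths <- vitc_pd_example()
#' h <- harmonize(read_associations(paths$exposure),
#'                read_associations(paths$pd_aao))
#' mr_ivw(h)
#' @export
mr_ivw <- function(h, model = c("multiplicative_random", "fixed"),
                   alpha = 0.05) {
  model <- match.arg(model)
  check_harmonized(h, 1L, "mr_ivw")
  k <- nrow(h)
  w <- 1 / h$se_out^2
  sxx <- sum(w * h$beta_exp^2)
  if (sxx <= 0) stop("degenerate weights: no exposure signal", call. = FALSE)
  beta <- sum(w * h$beta_exp * h$beta_out) / sxx
  se_fixed <- 1 / sqrt(sxx)
  inflation <- 1
  if (model == "multiplicative_random" && k >= 2L) {
    q <- sum(w * (h$beta_out - beta * h$beta_exp)^2)
    inflation <- max(1, sqrt(q / (k - 1)))
  }
  new_mr_estimate("ivw", beta, se_fixed * inflation, k = k,
                  inflation = inflation, alpha = alpha)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects *with* a
#' free intercept (weights `1/se_out^2`), on data oriented so every exposure
#' effect is positive. The slope estimates the causal effect under the
#' InSIDE assumption (instrument strength independent of direct effects);
#' the intercept estimates the average directional pleiotropic effect.
#' Both standard errors come from the WLS information matrix, inflated by
#' `max(1, sqrt(Q_egger/(k-2)))` with `Q_egger` the weighted residual sum of
#' squares of the fit; intervals and p-values are normal-based.
#'
#' @param h a `harmonized_set` with k >= 3 and all `beta_exp > 0`.
#' @param alpha two-sided confidence level complement.
#' @return an object of class `mr_egger`: list with `mr_estimate` components
#'   `slope` and `intercept`, plus `q_egger` and `k`.
#' @examples
#' paths <- vitc_pd_example()
#' h <- harmonize(read_associations(paths$exposure),
#'                read_associations(paths$pd_aao))
#' mr_egger(h)
#' @export
mr_egger <- function(h, alpha = 0.05) {
  check_harmonized(h, 3L, "mr_egger")
  if (any(h$beta_exp <= 0)) {
    stop("mr_egger requires exposure-raising orientation (all beta_exp > 0)",
         call. = FALSE)
  }
  k <- nrow(h)
  w <- 1 / h$se_out^2
  x <- cbind(intercept = rep(1, k), slope = h$beta_exp)
  xtwx <- crossprod(x, w * x)
  coefs <- solve(xtwx, crossprod(x, w * h$beta_out))
  resid <- h$beta_out - drop(x %*% coefs)
  q_egger <- sum(w * resid^2)
  inflation <- max(1, sqrt(q_egger / (k - 2)))
  ses <- sqrt(diag(solve(xtwx))) * inflation
  out <- list(
    slope = new_mr_estimate("egger_slope", coefs["slope", 1], ses["slope"],
                            k = k, inflation = inflation, alpha = alpha),
    intercept = new_mr_estimate("egger_intercept", coefs["intercept", 1],
                                ses["intercept"], k = k,
                                inflation = inflation, alpha = alpha),
    q_egger = q_egger, k = k
  )
  class(out) <- "mr_egger"
  out
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope, ...)
  print(x$intercept, ...)
  invisible(x)
}

#' Interpolated weighted median of the per-variant ratio estimates
#'
#' @param r ratio estimates.
#' @param w positive weights.
#' @return the weighted median under the `(S_j - w_j/2)/S_total`
#'   interpolation convention: ratios are sorted, each assigned the
#'   standardized midpoint of its cumulative weight span, and the estimate is
#'   the linear interpolation of ratio against that grid at probability 0.5
#'   (clamped to the extreme ratios when 0.5 falls outside the grid).
#' @keywords internal
weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o]
  s <- cumsum(w)
  p <- (s - w / 2) / s[length(s)]
  if (length(r) == 1L) return(r)
  stats::approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-variant Wald ratios
#' `r_j = beta_out/beta_exp` under weights `w_j = (beta_exp/se_out)^2`,
#' consistent when valid instruments carry more than half the total weight.
#' The standard error comes from a parametric bootstrap: exposure and outcome
#' effects are resampled from normal distributions centred on the observed
#' values with their standard errors, and the weighted median (ratios and
#' weights both recomputed) is re-evaluated `n_boot` times; the SE is the
#' standard deviation of the replicates. CI and p-value are normal-based on
#' the point estimate and bootstrap SE.
#'
#' @param h a `harmonized_set` with k >= 3.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @param alpha two-sided confidence level complement.
#' @return an `mr_estimate`.
#' @examples
#' paths <- vitc_pd_example()
#' h <- harmonize(read_associations(paths$exposure),
#'                read_associations(paths$pd_aao))
#' weighted_median(h, seed = 42)
#' @export
weighted_median <- function(h, n_boot = 1000, seed = NULL, alpha = 0.05) {
  check_harmonized(h, 3L, "weighted_median")
  if (n_boot < 1L) stop("'n_boot' must be >= 1", call. = FALSE)
  k <- nrow(h)
  w <- (h$beta_exp / h$se_out)^2
  if (sum(w) <= 0) stop("degenerate weights: total weight is zero",
                        call. = FALSE)
  est <- weighted_median_point(h$beta_out / h$beta_exp, w)
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(k, h$beta_exp, h$se_exp)
    by <- stats::rnorm(k, h$beta_out, h$se_out)
    weighted_median_point(by / bx, (bx / h$se_out)^2)
  }, numeric(1))
  se <- stats::sd(reps)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  new_mr_estimate("weighted_median", est, se, k = k, alpha = alpha)
}
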
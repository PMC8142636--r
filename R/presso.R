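loo_slopes <- function(bx, by, w) {
  # fixed-effect through-origin slopes, each leaving one variant out
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

origin_fit <- function(h, alpha = 0.05, ref_dist = "t") {
  # through-origin WLS with residual-scale (>= 1) SE and Student-t reference
  k <- nrow(h)
  w <- 1 / h$se_out^2
  sxx <- sum(w * h$beta_exp^2)
  beta <- sum(w * h$beta_exp * h$beta_out) / sxx
  q <- sum(w * (h$beta_out - beta * h$beta_exp)^2)
  inflation <- max(1, sqrt(q / (k - 1)))
  new_mr_estimate("presso_raw", beta, inflation / sqrt(sxx), k = k,
                  inflation = inflation, ref_dist = ref_dist, df = k - 1,
                  alpha = alpha)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based test for horizontal pleiotropy. The observed statistic is
#' the weighted residual sum of squares
#' `RSS = sum_j w_j (beta_out_j - b_(-j) * beta_exp_j)^2`
#' with `w_j = 1/se_out_j^2` and `b_(-j)` the leave-one-out fixed-effect IVW
#' slope. Its null distribution is built by parametric simulation: in each
#' replicate, exposure effects are drawn around their observed values and
#' outcome effects around the leave-one-out predictions, each with the
#' observed standard errors, and the RSS is recomputed (including the
#' leave-one-out slopes) on the simulated data. The global empirical p-value
#' is `(1 + #\{RSS_sim >= RSS_obs\})/(n_sim + 1)`.
#'
#' Per-variant outlier p-values compare each variant's observed weighted
#' residual against its own simulated distribution; a variant is flagged when
#' its empirical p-value falls below `outlier_alpha / k` (Bonferroni). The
#' raw causal estimate is the through-origin weighted regression with a
#' Student-t reference on `k - 1` degrees of freedom; the outlier-corrected
#' estimate refits after removing flagged variants (degrees of freedom
#' reduced accordingly) and equals the raw estimate when nothing is flagged.
#' When outliers are flagged, a distortion test compares the shift from raw
#' to corrected slope against slopes obtained after removing random subsets
#' of the same size.
#'
#' @param h a `harmonized_set` with k >= 4.
#' @param n_sim number of null simulations (>= 100; default 1000).
#' @param seed optional integer seed; identical seed and inputs reproduce the
#'   result exactly.
#' @param outlier_alpha family-wise outlier threshold before the
#'   Bonferroni division by k (default 0.05).
#' @param n_distortion random subsets for the distortion test (default 1000).
#' @param alpha two-sided confidence level complement for the estimates.
#' @return object of class `mr_presso`: list with `rss_obs`,
#'   `global_pvalue`, `n_sim`, `outlier_pvalues` (named by snp),
#'   `outlier_indices`, `raw_estimate`, `corrected_estimate`,
#'   `distortion_pvalue` (NA when no outliers) and `k`.
#' @examples
#' paths <- vitc_pd_example()
#' h <- harmonize(read_associations(paths$exposure),
#'                read_associations(paths$pd_aao))
#' mr_presso(h, n_sim = 200, seed = 7)
#' @export
mr_presso <- function(h, n_sim = 1000, seed = NULL, outlier_alpha = 0.05,
                      n_distortion = 1000, alpha = 0.05) {
  check_harmonized(h, 4L, "mr_presso")
  if (n_sim < 100) stop("'n_sim' must be >= 100", call. = FALSE)
  k <- nrow(h)
  bx <- h$beta_exp
  by <- h$beta_out
  w <- 1 / h$se_out^2

  slopes_loo <- loo_slopes(bx, by, w)
  res_obs <- w * (by - slopes_loo * bx)^2
  rss_obs <- sum(res_obs)

  if (!is.null(seed)) set.seed(seed)
  # R x k matrices of simulated effects under the no-pleiotropy null
  mu_out <- slopes_loo * bx
  bxs <- matrix(stats::rnorm(n_sim * k, rep(bx, each = n_sim),
                             rep(h$se_exp, each = n_sim)), n_sim, k)
  bys <- matrix(stats::rnorm(n_sim * k, rep(mu_out, each = n_sim),
                             rep(h$se_out, each = n_sim)), n_sim, k)
  wm <- matrix(w, n_sim, k, byrow = TRUE)
  mxy <- wm * bxs * bys
  mxx <- wm * bxs^2
  slopes_sim <- (rowSums(mxy) - mxy) / (rowSums(mxx) - mxx)
  res_sim <- wm * (bys - slopes_sim * bxs)^2

  rss_sim <- rowSums(res_sim)
  global_pvalue <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_pvalues <- (1 + colSums(res_sim >=
                                    matrix(res_obs, n_sim, k, byrow = TRUE))) /
    (n_sim + 1)
  names(outlier_pvalues) <- h$snp
  outlier_indices <- which(outlier_pvalues < outlier_alpha / k)

  raw <- origin_fit(h, alpha = alpha)
  if (length(outlier_indices) > 0L) {
    hc <- h[-outlier_indices, , drop = FALSE]
    if (nrow(hc) < 2L) {
      stop("outlier removal leaves fewer than 2 variants", call. = FALSE)
    }
    corrected <- origin_fit(hc, alpha = alpha)
    corrected$method <- "presso_corrected"
    # distortion: shift raw -> corrected vs removal of random subsets
    m <- length(outlier_indices)
    shift_obs <- abs(corrected$beta - raw$beta)
    shifts <- vapply(seq_len(n_distortion), function(i) {
      idx <- sample.int(k, m)
      hs <- h[-idx, , drop = FALSE]
      ws <- 1 / hs$se_out^2
      abs(sum(ws * hs$beta_exp * hs$beta_out) / sum(ws * hs$beta_exp^2) -
            raw$beta)
    }, numeric(1))
    distortion_pvalue <- (1 + sum(shifts >= shift_obs)) / (n_distortion + 1)
  } else {
    corrected <- raw
    corrected$method <- "presso_corrected"
    distortion_pvalue <- NA_real_
  }

  out <- list(rss_obs = rss_obs, global_pvalue = global_pvalue,
              n_sim = as.integer(n_sim), outlier_pvalues = outlier_pvalues,
              outlier_indices = outlier_indices, raw_estimate = raw,
              corrected_estimate = corrected,
              distortion_pvalue = distortion_pvalue, k = k)
  class(out) <- "mr_presso"
  out
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (k = %d, %d simulations)\n", x$k, x$n_sim))
  cat(sprintf("  global test: RSS = %.4f, p = %.4g\n", x$rss_obs,
              x$global_pvalue))
  if (length(x$outlier_indices) > 0L) {
    cat("  outliers: ", paste(names(x$outlier_pvalues)[x$outlier_indices],
                              collapse = ", "),
        sprintf(" (distortion p = %.4g)\n", x$distortion_pvalue))
  } else {
    cat("  outliers: none\n")
  }
  print(x$raw_estimate, ...)
  if (length(x$outlier_indices) > 0L) print(x$corrected_estimate, ...)
  invisible(x)
}
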
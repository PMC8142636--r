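#' Variance in the exposure explained by the instruments
#'
#' Per-variant variance explained from summary statistics via the
#' F-statistic identity `R2_i = F_i / (F_i + n_i - 2)` with
#' `F_i = (beta_i / se_i)^2`, summed over instruments for the total. The
#' alternative large-sample approximation
#' `R2_i = beta_i^2 / (beta_i^2 + 2 * n_i * se_i^2)` is available as
#' `method = "approx"`; it is roughly half the F-based value for strong
#' instruments and is provided for comparison only.
#'
#' @param instruments an `mr_associations` data frame with `beta`, `se` and
#'   per-variant sample size `n`.
#' @param method `"f"` (default) or `"approx"`.
#' @return object of class `mr_r2`: list with `per_variant` (data frame of
#'   `snp`, `f_stat`, `r2`, `r2_pct`), `r2_total` (proportion) and
#'   `r2_total_pct`.
#' @examples
#' exposure <- read_associations(vitc_pd_example()$exposure)
#' variance_explained(exposure)
#' @export
variance_explained <- function(instruments, method = c("f", "approx")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(instruments))
  needed <- c("snp", "beta", "se", "n")
  if (!all(needed %in% names(instruments))) {
    stop("instruments must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  miss_n <- !is.finite(instruments$n) | instruments$n <= 2
  if (any(miss_n)) {
    stop("missing or invalid sample size for: ",
         paste(instruments$snp[miss_n], collapse = ", "), call. = FALSE)
  }
  f_stat <- (instruments$beta / instruments$se)^2
  r2 <- switch(method,
    f = f_stat / (f_stat + instruments$n - 2),
    approx = instruments$beta^2 /
      (instruments$beta^2 + 2 * instruments$n * instruments$se^2)
  )
  out <- list(
    per_variant = data.frame(snp = instruments$snp, f_stat = f_stat,
                             r2 = r2, r2_pct = 100 * r2,
                             stringsAsFactors = FALSE),
    r2_total = sum(r2), r2_total_pct = 100 * sum(r2), method = method
  )
  class(out) <- "mr_r2"
  out
}

#' @export
print.mr_r2 <- function(x, ...) {
  cat(sprintf("Variance explained (%s): total R2 = %.4f%% over %d variants\n",
              x$method, x$r2_total_pct, nrow(x$per_variant)))
  print(x$per_variant, digits = 4)
  invisible(x)
}

#' Statistical power of an MR analysis with a binary outcome
#'
#' Non-centrality-parameter approximation for a two-stage instrumental-
#' variable analysis of a case-control outcome (the approach of the mRnd
#' calculator). With case fraction `K = n_cases/n_total`, the attenuated
#' log-odds slope is `b = K * (OR / (1 + K * (OR - 1)) - 1)`, its variance
#' `v = (K * (1 - K) - b^2) / (n_total * r2)`, and power is the upper-tail
#' probability of a noncentral chi-square(1, `b^2/v`) beyond the central
#' chi-square quantile at `1 - alpha`. At `or = 1` the power equals `alpha`
#' exactly.
#'
#' @param n_total total outcome-GWAS sample size.
#' @param n_cases number of cases (0 < n_cases < n_total).
#' @param r2 proportion of exposure variance explained by the instruments.
#' @param or odds ratio per 1 SD of the exposure (vectorized).
#' @param alpha two-sided type-I error rate (default 0.05).
#' @return power in (0, 1), same length as `or`.
#' @examples
#' binary_power(1474097, 56306, 0.0179, or = 0.91)
#' @export
binary_power <- function(n_total, n_cases, r2, or, alpha = 0.05) {
  stopifnot(n_cases > 0, n_cases < n_total, r2 > 0, r2 < 1,
            alpha > 0, alpha < 1, all(or > 0))
  k_frac <- n_cases / n_total
  b <- k_frac * (or / (1 + k_frac * (or - 1)) - 1)
  v <- (k_frac * (1 - k_frac) - b^2) / (n_total * r2)
  ncp <- b^2 / v
  stats::pchisq(stats::qchisq(1 - alpha, df = 1), df = 1, ncp = ncp,
                lower.tail = FALSE)
}

#' Smallest detectable odds ratio at a target power
#'
#' Bisection on the odds ratio, in (0.5, 1) for a protective effect or
#' (1, 2) for a risk effect, until the binary-outcome power matches
#' `target_power` to within `tol`.
#'
#' @inheritParams binary_power
#' @param target_power power to achieve, in (`alpha`, 1).
#' @param direction `"protective"` or `"risk"`.
#' @param tol convergence tolerance on power (default 1e-6).
#' @return the detectable odds ratio.
#' @examples
#' preset <- pd_power_presets()$full_meta
#' detectable_or(preset$n_total, preset$n_cases, r2 = 0.0179,
#'               target_power = 0.80)
#' @export
detectable_or <- function(n_total, n_cases, r2, target_power = 0.80,
                          direction = c("protective", "risk"), alpha = 0.05,
                          tol = 1e-6) {
  direction <- match.arg(direction)
  stopifnot(target_power > alpha, target_power < 1)
  bracket <- if (direction == "protective") c(0.5, 1) else c(1, 2)
  pw <- function(or) binary_power(n_total, n_cases, r2, or, alpha)
  # power decreases toward or = 1 from either side
  far <- if (direction == "protective") bracket[1] else bracket[2]
  if (pw(far) < target_power) {
    stop("target power unreachable within the bracket (",
         bracket[1], ", ", bracket[2], ")", call. = FALSE)
  }
  lo <- bracket[1]
  hi <- bracket[2]
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    p_mid <- pw(mid)
    if (abs(p_mid - target_power) < tol) return(mid)
    exceeds <- p_mid > target_power
    if (direction == "protective") {
      if (exceeds) lo <- mid else hi <- mid
    } else {
      if (exceeds) hi <- mid else lo <- mid
    }
  }
  (lo + hi) / 2
}

#' Case/control presets for the Parkinson's disease power analysis
#'
#' Two sample-size configurations for [binary_power()] and
#' [detectable_or()]: `full_meta`, the complete PD case-control
#' meta-analysis (56,306 cases including proxy cases, 1,417,791 controls),
#' and `analysis_subset`, the 14-study subset whose summary statistics the
#' bundled outcome fixture reports (33,674 cases, 449,056 controls). The
#' full-meta counts are the configuration under which the 11 instruments
#' (R2 = 1.79%) give 80% power for a protective OR of 0.91; the subset
#' preset is provided for sensitivity analysis.
#'
#' @return named list of lists with `n_cases`, `n_controls`, `n_total`.
#' @export
pd_power_presets <- function() {
  list(
    full_meta = list(n_cases = 56306, n_controls = 1417791,
                     n_total = 56306 + 1417791),
    analysis_subset = list(n_cases = 33674, n_controls = 449056,
                           n_total = 33674 + 449056)
  )
}
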
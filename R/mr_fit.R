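#' Fit the full suite of two-sample MR estimators
#'
#' The central fitting function: applies the requested causal estimators
#' (inverse-variance weighted, weighted median, MR-Egger, MR-PRESSO) and the
#' pleiotropy/heterogeneity diagnostics (Cochran's Q with I-squared, the
#' MR-Egger intercept test) to a harmonized exposure/outcome set. Estimators
#' whose instrument-count preconditions are not met (Egger and weighted
#' median need k >= 3, MR-PRESSO k >= 4) are skipped with a recorded
#' warning rather than failing the fit.
#'
#' @param h a `harmonized_set` from [harmonize()].
#' @param methods subset of `c("ivw", "weighted_median", "egger", "presso")`.
#' @param model IVW dispersion model, see [mr_ivw()].
#' @param n_boot bootstrap replicates for the weighted median.
#' @param n_sim null simulations for MR-PRESSO.
#' @param seed optional master seed; the weighted-median bootstrap uses
#'   `seed` and MR-PRESSO `seed + 1`.
#' @param alpha significance threshold and CI level complement (default
#'   0.05).
#' @return an object of class `mr_fit`: list with the harmonized `data`, an
#'   `estimates` data frame (one row per method, with a `significant` flag at
#'   `alpha`), `heterogeneity`, `egger`, `presso`, recorded `warnings`, and
#'   the matched `call`.
#' @examples
#' paths <- vitc_pd_example()
#' h <- harmonize(read_associations(paths$exposure),
#'                read_associations(paths$pd_aao))
#' fit <- mr_fit(h, seed = 42)
#' fit
#' coef(fit)
#' @seealso [mr_ivw()], [mr_egger()], [weighted_median()], [mr_presso()],
#'   [cochran_q()]
#' @export
mr_fit <- function(h, methods = c("ivw", "weighted_median", "egger",
                                  "presso"),
                   model = "multiplicative_random", n_boot = 1000,
                   n_sim = 1000, seed = NULL, alpha = 0.05) {
  methods <- match.arg(methods, several.ok = TRUE)
  check_harmonized(h, 1L, "mr_fit")
  k <- nrow(h)
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)
  try_est <- function(expr) {
    tryCatch(expr, error = function(e) {
      note(conditionMessage(e))
      NULL
    })
  }

  estimates <- list()
  if ("ivw" %in% methods) {
    estimates$ivw <- try_est(mr_ivw(h, model = model, alpha = alpha))
  }
  if ("weighted_median" %in% methods) {
    estimates$weighted_median <- try_est(
      weighted_median(h, n_boot = n_boot, seed = seed, alpha = alpha))
  }
  egger <- if ("egger" %in% methods) try_est(mr_egger(h, alpha = alpha)) else
    NULL
  if (!is.null(egger)) estimates$egger <- egger$slope
  presso <- if ("presso" %in% methods) {
    try_est(mr_presso(h, n_sim = n_sim,
                      seed = if (is.null(seed)) NULL else seed + 1L,
                      alpha = alpha))
  } else NULL
  if (!is.null(presso)) {
    estimates$presso <- presso$raw_estimate
    if (length(presso$outlier_indices) > 0L) {
      estimates$presso_corrected <- presso$corrected_estimate
    }
  }
  heterogeneity <- if (k >= 2L) try_est(cochran_q(h, alpha = alpha)) else NULL
  intercept <- if (!is.null(egger)) {
    est <- egger$intercept
    est$directional_pleiotropy <- est$pvalue < alpha
    est
  } else NULL

  tab <- do.call(rbind, lapply(estimates, as.data.frame))
  if (!is.null(tab)) {
    rownames(tab) <- NULL
    tab$significant <- tab$pvalue < alpha
  }
  out <- list(data = h, estimates = tab, heterogeneity = heterogeneity,
              egger = egger, egger_intercept = intercept, presso = presso,
              alpha = alpha, seed = seed, warnings = warnings,
              exposure_label = attr(h, "exposure_label"),
              outcome_label = attr(h, "outcome_label"),
              call = match.call())
  class(out) <- "mr_fit"
  out
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-sample MR fit: %s on %s (k = %d)\n",
              x$exposure_label, x$outcome_label, nrow(x$data)))
  if (!is.null(x$estimates)) {
    tab <- x$estimates
    tab$beta <- round(tab$beta, digits)
    tab$ci <- sprintf("[%.*f, %.*f]", digits, tab$ci_low, digits,
                      tab$ci_high)
    tab$pvalue <- signif(tab$pvalue, 3)
    tab$sig <- ifelse(tab$significant, "*", "")
    print(tab[, c("method", "beta", "ci", "pvalue", "k", "sig")],
          row.names = FALSE)
  }
  if (length(x$warnings) > 0L) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  - ", w, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(object, class = c("summary.mr_fit", "mr_fit"))
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print.mr_fit(x, ...)
  if (!is.null(x$heterogeneity)) print(x$heterogeneity)
  if (!is.null(x$egger_intercept)) {
    e <- x$egger_intercept
    cat(sprintf(
      "Egger intercept %.4f [%.4f, %.4f], p = %.4g (%sdirectional pleiotropy at alpha = %g)\n",
      e$beta, e$ci_low, e$ci_high, e$pvalue,
      if (e$directional_pleiotropy) "" else "no ", x$alpha))
  }
  if (!is.null(x$presso)) {
    cat(sprintf("MR-PRESSO global p = %.4g (%d simulations, %d outlier(s))\n",
                x$presso$global_pvalue, x$presso$n_sim,
                length(x$presso$outlier_indices)))
  }
  dropped <- dropped_variants(x$data)
  if (nrow(dropped) > 0L) {
    cat("dropped during harmonization:\n")
    print(dropped, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  if (is.null(object$estimates)) return(numeric(0))
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  tab <- object$estimates
  if (is.null(tab)) return(NULL)
  if (!missing(parm)) tab <- tab[tab$method %in% parm, , drop = FALSE]
  out <- as.matrix(tab[, c("ci_low", "ci_high")])
  dimnames(out) <- list(tab$method,
                        sprintf("%g %%", c((1 - level) / 2,
                                           1 - (1 - level) / 2) * 100))
  out
}

#' Scatter plot of instrument effects with fitted MR lines
#'
#' Plots per-variant outcome effects against exposure effects with +/- 1 SE
#' error bars, the IVW through-origin line and, when fitted, the MR-Egger
#' regression line.
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, ...) {
  h <- x$data
  graphics::plot(h$beta_exp, h$beta_out,
                 xlim = range(0, h$beta_exp + h$se_exp),
                 ylim = range(h$beta_out - h$se_out,
                              h$beta_out + h$se_out, 0),
                 xlab = sprintf("effect on %s (SD per allele)",
                                x$exposure_label),
                 ylab = sprintf("effect on %s", x$outcome_label),
                 pch = 19, ...)
  graphics::arrows(h$beta_exp, h$beta_out - h$se_out, h$beta_exp,
                   h$beta_out + h$se_out, angle = 90, code = 3,
                   length = 0.02, col = "grey50")
  graphics::arrows(h$beta_exp - h$se_exp, h$beta_out,
                   h$beta_exp + h$se_exp, h$beta_out, angle = 90, code = 3,
                   length = 0.02, col = "grey50")
  graphics::abline(h = 0, v = 0, col = "grey80")
  legend_txt <- character(0)
  legend_lty <- integer(0)
  ivw_row <- x$estimates[x$estimates$method == "ivw", , drop = FALSE]
  if (nrow(ivw_row) == 1L) {
    graphics::abline(0, ivw_row$beta, lty = 2)
    legend_txt <- c(legend_txt, "IVW")
    legend_lty <- c(legend_lty, 2L)
  }
  if (!is.null(x$egger)) {
    graphics::abline(x$egger$intercept$beta, x$egger$slope$beta, lty = 1)
    legend_txt <- c(legend_txt, "MR-Egger")
    legend_lty <- c(legend_lty, 1L)
  }
  if (length(legend_txt) > 0L) {
    graphics::legend("topright", legend = legend_txt, lty = legend_lty,
                     bty = "n")
  }
  invisible(x)
}
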
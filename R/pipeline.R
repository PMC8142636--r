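#' Run a complete two-sample MR analysis
#'
#' End-to-end orchestration over one exposure and one or more outcomes:
#' instrument selection at `p_threshold`, allele harmonization per outcome,
#' the full estimator suite via [mr_fit()], heterogeneity and pleiotropy
#' diagnostics, and an optional binary-outcome power block. All stochastic
#' components receive sub-seeds derived deterministically from `seed`, so
#' two runs with identical inputs and seed produce identical reports.
#'
#' @param exposure path to an exposure TSV or an `mr_associations` table.
#' @param outcomes named character vector of outcome TSV paths, or a named
#'   list of `mr_associations` tables (names become outcome labels).
#' @param p_threshold instrument-selection p-value threshold (default 5e-8).
#' @param palindrome_eaf_window see [harmonize()].
#' @param methods estimators to run, see [mr_fit()].
#' @param n_boot,n_sim,alpha passed to [mr_fit()].
#' @param seed master seed; outcome `i` uses `seed + 1000 * i`.
#' @param power optional list with `n_total`, `n_cases` (and optionally
#'   `target_power`) enabling the variance-explained / detectable-OR block.
#' @param out_dir optional directory; when given the report is written via
#'   [write_report()].
#' @return an object of class `mr_report`: list with `metadata` (package
#'   version, seed, input digests, timestamp), `instruments`, `r2`,
#'   `harmonization` (per outcome: k retained, dropped table), `fits`
#'   (per-outcome `mr_fit`), and `power`.
#' @examples
#' paths <- vitc_pd_example()
#' rep <- run_analysis(paths$exposure,
#'                     c(pd = paths$pd, pd_aao = paths$pd_aao), seed = 42)
#' rep$fits$pd_aao
#' @export
run_analysis <- function(exposure, outcomes, p_threshold = 5e-8,
                         palindrome_eaf_window = 0.08,
                         methods = c("ivw", "weighted_median", "egger",
                                     "presso"),
                         n_boot = 1000, n_sim = 1000, seed = NULL,
                         alpha = 0.05, power = NULL, out_dir = NULL) {
  digests <- list()
  load_side <- function(x, default_label) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        stop("input file not found: ", x, call. = FALSE)
      }
      digests[[default_label]] <<- unname(tools::md5sum(x))
      read_associations(x, label = default_label)
    } else {
      as_associations(as.data.frame(x), label = default_label)
    }
  }
  if (length(outcomes) < 1L) stop("at least one outcome is required",
                                  call. = FALSE)
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes)))) {
    if (is.character(outcomes)) {
      names(outcomes) <- sub("\\.[^.]*$", "", basename(outcomes))
    } else {
      stop("'outcomes' must be named", call. = FALSE)
    }
  }
  # check all paths before any computation
  if (is.character(exposure) && !file.exists(exposure)) {
    stop("input file not found: ", exposure, call. = FALSE)
  }
  if (is.character(outcomes)) {
    missing_files <- outcomes[!file.exists(outcomes)]
    if (length(missing_files) > 0L) {
      stop("input file not found: ", paste(missing_files, collapse = ", "),
           call. = FALSE)
    }
  }

  exp_label <- if (is.character(exposure)) {
    sub("\\.[^.]*$", "", basename(exposure))
  } else {
    attr(exposure, "label") %||% "exposure"
  }
  exp_assoc <- load_side(exposure, exp_label)
  instruments <- select_instruments(exp_assoc, p_threshold)
  if (nrow(instruments) == 0L) {
    stop("no instruments pass p < ", p_threshold, call. = FALSE)
  }
  r2 <- if (all(is.finite(instruments$n))) variance_explained(instruments)
    else NULL

  fits <- list()
  harmonization <- list()
  power_blocks <- list()
  for (i in seq_along(outcomes)) {
    out_label <- names(outcomes)[i]
    out_assoc <- load_side(outcomes[[i]], out_label)
    h <- harmonize(instruments, out_assoc,
                   palindrome_eaf_window = palindrome_eaf_window,
                   exposure_label = exp_label, outcome_label = out_label)
    sub_seed <- if (is.null(seed)) NULL else {
      (seed + 1000L * i) %% .Machine$integer.max
    }
    fit <- mr_fit(h, methods = methods, n_boot = n_boot, n_sim = n_sim,
                  seed = sub_seed, alpha = alpha)
    fits[[out_label]] <- fit
    harmonization[[out_label]] <- list(k = nrow(h),
                                       dropped = dropped_variants(h))
    if (!is.null(power) && !is.null(r2)) {
      target_power <- power$target_power %||% 0.80
      power_blocks[[out_label]] <- list(
        n_total = power$n_total, n_cases = power$n_cases,
        r2_total = r2$r2_total, target_power = target_power,
        detectable_or_protective = detectable_or(
          power$n_total, power$n_cases, r2$r2_total,
          target_power = target_power, direction = "protective",
          alpha = alpha)
      )
    }
  }

  report <- list(
    metadata = list(package = "ivmr",
                    version = as.character(utils::packageVersion("ivmr")),
                    seed = seed, alpha = alpha, p_threshold = p_threshold,
                    n_boot = n_boot, n_sim = n_sim,
                    input_digests = digests,
                    timestamp = format(Sys.time(), tz = "UTC")),
    instruments = as.data.frame(instruments),
    r2 = r2, harmonization = harmonization, fits = fits,
    power = if (length(power_blocks) > 0L) power_blocks else NULL
  )
  class(report) <- "mr_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR analysis report (%d instrument(s), %d outcome(s))\n",
              nrow(x$instruments), length(x$fits)))
  if (!is.null(x$r2)) {
    cat(sprintf("  total variance explained: %.2f%%\n", x$r2$r2_total_pct))
  }
  for (label in names(x$fits)) {
    cat("\n")
    print(x$fits[[label]], ...)
  }
  invisible(x)
}

report_estimates_table <- function(report) {
  do.call(rbind, lapply(names(report$fits), function(label) {
    tab <- report$fits[[label]]$estimates
    if (is.null(tab)) return(NULL)
    cbind(outcome = label, tab, stringsAsFactors = FALSE)
  }))
}

report_diagnostics_table <- function(report) {
  do.call(rbind, lapply(names(report$fits), function(label) {
    fit <- report$fits[[label]]
    het <- fit$heterogeneity
    ego <- fit$egger_intercept
    data.frame(
      outcome = label,
      q = het$q %||% NA_real_, df = het$df %||% NA_integer_,
      q_pvalue = het$pvalue %||% NA_real_, i2 = het$i2 %||% NA_real_,
      i2_ci_low = het$i2_ci_low %||% NA_real_,
      i2_ci_high = het$i2_ci_high %||% NA_real_,
      egger_intercept = ego$beta %||% NA_real_,
      intercept_ci_low = ego$ci_low %||% NA_real_,
      intercept_ci_high = ego$ci_high %||% NA_real_,
      intercept_pvalue = ego$pvalue %||% NA_real_,
      presso_global_pvalue = fit$presso$global_pvalue %||% NA_real_,
      stringsAsFactors = FALSE
    )
  }))
}

#' Export per-variant scatter data with the MR-Egger line
#'
#' One row per harmonized variant with the effects and standard errors on
#' both axes, plus the fitted MR-Egger slope and intercept repeated on each
#' row (NA when fewer than three instruments were available). This is the
#' content of the classic MR scatter figure; rendering is left downstream.
#'
#' @param x an `mr_report` or `mr_fit`.
#' @param outcome outcome label (required for reports with several).
#' @param path optional TSV output path.
#' @return the scatter data frame, invisibly when `path` is given.
#' @export
export_scatter <- function(x, outcome = NULL, path = NULL) {
  fit <- if (inherits(x, "mr_fit")) {
    x
  } else if (inherits(x, "mr_report")) {
    if (is.null(outcome)) {
      if (length(x$fits) == 1L) outcome <- names(x$fits)[1]
      else stop("specify 'outcome': report has ",
                length(x$fits), " outcomes", call. = FALSE)
    }
    if (!outcome %in% names(x$fits)) {
      stop("unknown outcome label: ", outcome, call. = FALSE)
    }
    x$fits[[outcome]]
  } else {
    stop("'x' must be an mr_report or mr_fit", call. = FALSE)
  }
  h <- fit$data
  out <- data.frame(
    snp = h$snp, beta_exp = h$beta_exp, se_exp = h$se_exp,
    beta_out = h$beta_out, se_out = h$se_out,
    egger_slope = if (!is.null(fit$egger)) fit$egger$slope$beta else
      NA_real_,
    egger_intercept = if (!is.null(fit$egger)) fit$egger$intercept$beta else
      NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

report_json <- function(report, include_timestamp = TRUE) {
  meta <- report$metadata
  if (!include_timestamp) meta$timestamp <- NULL
  fits <- lapply(report$fits, function(fit) {
    list(
      k = nrow(fit$data),
      estimates = fit$estimates,
      heterogeneity = unclass(fit$heterogeneity),
      egger_intercept = unclass(fit$egger_intercept),
      presso = if (!is.null(fit$presso)) {
        list(rss_obs = fit$presso$rss_obs,
             global_pvalue = fit$presso$global_pvalue,
             n_sim = fit$presso$n_sim,
             outlier_pvalues = fit$presso$outlier_pvalues,
             outliers = names(fit$presso$outlier_pvalues)[
               fit$presso$outlier_indices],
             distortion_pvalue = fit$presso$distortion_pvalue)
      },
      warnings = fit$warnings,
      variants = as.data.frame(fit$data),
      dropped = dropped_variants(fit$data)
    )
  })
  jsonlite::toJSON(list(
    metadata = meta,
    r2 = if (!is.null(report$r2)) {
      list(per_variant = report$r2$per_variant,
           r2_total = report$r2$r2_total,
           r2_total_pct = report$r2$r2_total_pct)
    },
    outcomes = fits,
    power = report$power
  ), auto_unbox = TRUE, digits = NA, na = "null")
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (the full report), `estimates.tsv` (one row per
#' outcome x method), `diagnostics.tsv` (heterogeneity, Egger intercept and
#' MR-PRESSO global p per outcome) and one `scatter_<outcome>.tsv` per
#' outcome.
#'
#' @param report an `mr_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  est <- report_estimates_table(report)
  if (!is.null(est)) {
    utils::write.table(est, file.path(dir, "estimates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  diag <- report_diagnostics_table(report)
  if (!is.null(diag)) {
    utils::write.table(diag, file.path(dir, "diagnostics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (label in names(report$fits)) {
    export_scatter(report, label,
                   path = file.path(dir, paste0("scatter_", label, ".tsv")))
  }
  invisible(dir)
}
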
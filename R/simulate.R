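#' Configuration for the summary-statistic simulator
#'
#' Describes a synthetic two-sample MR study: `k` independent instruments
#' with true exposure effects `gamma_j` drawn uniformly from `gamma_range`
#' (strictly positive, mirroring the exposure-raising orientation of
#' harmonized data), direct (pleiotropic) outcome effects `alpha_j`, true
#' outcome effects `theta * gamma_j + alpha_j`, and observed effects drawn
#' from normal sampling distributions with the given standard errors.
#'
#' Pleiotropy modes: `"none"` sets all `alpha_j = 0`; `"balanced"` draws
#' them from `N(0, pleiotropy_scale)`; `"directional"` from
#' `N(pleiotropy_mean, pleiotropy_scale)`. With `inside_violation = TRUE`
#' the direct effects are generated with correlation 0.5 with the instrument
#' strengths `gamma_j`, breaking the InSIDE assumption.
#'
#' The defaults mirror the bundled vitamin C instrument panel: 11 variants
#' with exposure effects between 0.036 and 0.36 SD per allele, exposure
#' standard errors around 0.01 (n = 52,018) and outcome standard errors
#' around 0.15 (n = 28,568, an age-at-onset-sized quantitative GWAS).
#' `se_exp_scale` and `se_out_scale` accept a scalar or a length-`k` vector,
#' so noise can be matched variant-by-variant to a real panel.
#'
#' @param k number of instruments (>= 3).
#' @param theta true causal effect (outcome units per SD of exposure).
#' @param gamma_range range of true exposure effects, strictly positive.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_scale SD of the direct effects (>= 0).
#' @param pleiotropy_mean mean direct effect under `"directional"`.
#' @param inside_violation correlate direct effects with instrument strength.
#' @param se_exp_scale,se_out_scale sampling-noise magnitudes (scalar or
#'   length-`k`).
#' @param n_exp,n_out nominal sample sizes written to the output tables.
#' @param seed optional integer seed; identical config and seed reproduce
#'   the simulated tables byte-for-byte.
#' @return a `sim_config` list.
#' @examples
#' cfg <- sim_config(k = 11, theta = -1.1, seed = 1)
#' study <- simulate_study(cfg)
#' mr_ivw(harmonize(study$exposure, study$outcome))
#' @export
sim_config <- function(k = 11, theta = 0, gamma_range = c(0.036, 0.36),
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_scale = 0.05, pleiotropy_mean = 0.1,
                       inside_violation = FALSE, se_exp_scale = 0.01,
                       se_out_scale = 0.15, n_exp = 52018, n_out = 28568,
                       seed = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(k >= 3, length(gamma_range) == 2, all(gamma_range > 0),
            gamma_range[1] <= gamma_range[2], pleiotropy_scale >= 0,
            all(se_exp_scale >= 0), all(se_out_scale >= 0),
            length(se_exp_scale) %in% c(1L, k),
            length(se_out_scale) %in% c(1L, k))
  structure(list(k = as.integer(k), theta = theta,
                 gamma_range = gamma_range,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_scale = pleiotropy_scale,
                 pleiotropy_mean = pleiotropy_mean,
                 inside_violation = inside_violation,
                 se_exp_scale = se_exp_scale, se_out_scale = se_out_scale,
                 n_exp = n_exp, n_out = n_out, seed = seed),
            class = "sim_config")
}

# non-palindromic allele pairs only, so simulated studies never hit the
# frequency-ambiguity drop rule on their way through harmonize()
SIM_ALLELE_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                          c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))

#' Simulate a two-sample MR study
#'
#' Draws instrument-level summary statistics under a [sim_config()] and
#' returns exposure and outcome association tables in the same layout as
#' [read_associations()], plus the generating ground truth. Observed
#' exposure effects are `N(gamma_j, se_exp_j)` and outcome effects
#' `N(theta * gamma_j + alpha_j, se_out_j)`; p-values are the two-sided
#' normal p of each observed effect, allele pairs are non-palindromic and
#' effect-allele frequencies are shared between the two studies.
#'
#' @param config a `sim_config`.
#' @return object of class `mr_simulation`: list with `exposure`, `outcome`
#'   (both `mr_associations`) and `truth` (list of `theta`, `gamma`,
#'   `alpha_direct`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- config$k
  gamma <- stats::runif(k, config$gamma_range[1], config$gamma_range[2])
  alpha_direct <- switch(config$pleiotropy_mode,
    none = rep(0, k),
    balanced = stats::rnorm(k, 0, config$pleiotropy_scale),
    directional = stats::rnorm(k, config$pleiotropy_mean,
                               config$pleiotropy_scale)
  )
  if (config$inside_violation && config$pleiotropy_mode != "none" &&
      config$pleiotropy_scale > 0) {
    rho <- 0.5
    zg <- as.vector(scale(gamma))
    mu <- if (config$pleiotropy_mode == "directional") {
      config$pleiotropy_mean
    } else 0
    alpha_direct <- mu + config$pleiotropy_scale *
      (rho * zg + sqrt(1 - rho^2) * stats::rnorm(k))
  }
  se_exp <- rep_len(config$se_exp_scale, k)
  se_out <- rep_len(config$se_out_scale, k)
  big_gamma <- config$theta * gamma + alpha_direct
  beta_exp <- if (all(se_exp == 0)) gamma else stats::rnorm(k, gamma, se_exp)
  beta_out <- if (all(se_out == 0)) big_gamma else {
    stats::rnorm(k, big_gamma, se_out)
  }
  pairs <- SIM_ALLELE_PAIRS[sample.int(nrow(SIM_ALLELE_PAIRS), k,
                                       replace = TRUE), , drop = FALSE]
  eaf <- stats::runif(k, 0.05, 0.95)
  pnorm_2s <- function(b, s) {
    p <- ifelse(s > 0, 2 * stats::pnorm(-abs(b / s)), .Machine$double.xmin)
    pmax(p, .Machine$double.xmin)
  }
  snp <- sprintf("sim%03d", seq_len(k))
  exposure <- as_associations(data.frame(
    snp = snp, chr = "1", pos = seq_len(k) * 1000L,
    ea = pairs[, 1], nea = pairs[, 2], eaf = eaf, beta = beta_exp,
    se = ifelse(se_exp > 0, se_exp, .Machine$double.eps), n = config$n_exp,
    pval = pnorm_2s(beta_exp, se_exp), stringsAsFactors = FALSE
  ), label = "simulated_exposure")
  outcome <- as_associations(data.frame(
    snp = snp, chr = "1", pos = seq_len(k) * 1000L,
    ea = pairs[, 1], nea = pairs[, 2], eaf = eaf, beta = beta_out,
    se = ifelse(se_out > 0, se_out, .Machine$double.eps), n = config$n_out,
    pval = pnorm_2s(beta_out, se_out), stringsAsFactors = FALSE
  ), label = "simulated_outcome")
  structure(list(exposure = exposure, outcome = outcome,
                 truth = list(theta = config$theta, gamma = gamma,
                              alpha_direct = alpha_direct)),
            class = "mr_simulation")
}

#' Write a simulated study to disk
#'
#' Writes `exposure.tsv` and `outcome.tsv` in the standard association
#' dialect plus `truth.json` holding the generating parameters.
#'
#' @param study an `mr_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mr_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_associations(study$exposure, file.path(dir, "exposure.tsv"))
  write_associations(study$outcome, file.path(dir, "outcome.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Operating characteristics of an estimator over simulated studies
#'
#' Repeatedly simulates studies, pushes each through the same harmonization
#' path as real data, applies the requested estimator and summarizes bias,
#' empirical and mean model standard error, confidence-interval coverage of
#' the truth, and the rejection rate at level `alpha`. For
#' `estimator = "egger_intercept"` the target parameter is the mean direct
#' effect rather than `theta`.
#'
#' @param configs a `sim_config` or a list of them.
#' @param estimator one of `"ivw"`, `"weighted_median"`, `"egger"`,
#'   `"egger_intercept"`.
#' @param n_reps replicates per configuration (>= 1).
#' @param seed master seed; replicate seeds are derived deterministically.
#' @param alpha test level for coverage and rejection (default 0.05).
#' @param n_boot bootstrap replicates for the weighted median (default 200,
#'   smaller than the analysis default to keep replicate grids affordable).
#' @return data frame with one row per configuration: `k`, `theta`,
#'   `pleiotropy_mode`, `target`, `n_reps`, `mean_estimate`, `bias`,
#'   `empirical_se`, `mean_se`, `coverage`, `rejection_rate`.
#' @examples
#' oc <- operating_characteristics(sim_config(k = 5), "ivw", n_reps = 50,
#'                                 seed = 1)
#' oc$coverage
#' @export
operating_characteristics <- function(configs, estimator, n_reps, seed,
                                      alpha = 0.05, n_boot = 200) {
  known <- c("ivw", "weighted_median", "egger", "egger_intercept")
  if (!is.character(estimator) || length(estimator) != 1L ||
      !estimator %in% known) {
    stop("unknown estimator; use one of: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1L, n_reps >= 1)
  rows <- lapply(seq_along(configs), function(ci) {
    cfg <- configs[[ci]]
    stopifnot(inherits(cfg, "sim_config"))
    target <- if (estimator == "egger_intercept") {
      if (cfg$pleiotropy_mode == "directional") cfg$pleiotropy_mean else 0
    } else {
      cfg$theta
    }
    est <- matrix(NA_real_, n_reps, 4,
                  dimnames = list(NULL, c("beta", "se", "lo", "hi")))
    pv <- numeric(n_reps)
    for (i in seq_len(n_reps)) {
      cfg$seed <- (seed + 100003L * (ci - 1L) + i) %% .Machine$integer.max
      study <- simulate_study(cfg)
      h <- harmonize(study$exposure, study$outcome)
      e <- switch(estimator,
        ivw = mr_ivw(h, alpha = alpha),
        weighted_median = weighted_median(h, n_boot = n_boot,
                                          seed = cfg$seed + 1L,
                                          alpha = alpha),
        egger = mr_egger(h, alpha = alpha)$slope,
        egger_intercept = mr_egger(h, alpha = alpha)$intercept
      )
      est[i, ] <- c(e$beta, e$se, e$ci_low, e$ci_high)
      pv[i] <- e$pvalue
    }
    data.frame(
      k = cfg$k, theta = cfg$theta, pleiotropy_mode = cfg$pleiotropy_mode,
      estimator = estimator, target = target, n_reps = n_reps,
      mean_estimate = mean(est[, "beta"]),
      bias = mean(est[, "beta"]) - target,
      empirical_se = if (n_reps > 1) stats::sd(est[, "beta"]) else NA_real_,
      mean_se = mean(est[, "se"]),
      coverage = mean(est[, "lo"] <= target & target <= est[, "hi"]),
      rejection_rate = mean(pv < alpha),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
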
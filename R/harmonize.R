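#' Complement alleles across DNA strands
#'
#' @param allele character vector of single bases (A/C/G/T).
#' @return the strand-complemented alleles.
#' @keywords internal
complement_allele <- function(allele) chartr("ACGT", "TGCA", allele)

#' Swap the effect and other allele of association records
#'
#' Reverses the allele orientation of each record: effect and other allele
#' are exchanged, the effect size is negated and the effect-allele frequency
#' becomes its complement. The transform is an involution: applying it twice
#' returns the original records exactly.
#'
#' @param x data frame with columns `ea, nea, beta, eaf`.
#' @return `x` with orientation reversed.
#' @export
swap_alleles <- function(x) {
  stopifnot(all(c("ea", "nea", "beta", "eaf") %in% names(x)))
  tmp <- x$ea
  x$ea <- x$nea
  x$nea <- tmp
  x$beta <- -x$beta
  x$eaf <- 1 - x$eaf
  x
}

is_palindromic <- function(ea, nea) ea == complement_allele(nea)

#' Harmonize exposure and outcome summary statistics
#'
#' Places each shared variant's exposure and outcome effects on a common
#' effect allele, the exposure-raising allele:
#'
#' 1. the exposure record is oriented so that `beta_exp > 0` (alleles
#'    swapped, beta negated, frequency complemented where needed);
#' 2. outcome alleles matching the exposure pair directly are copied; a
#'    swapped pair is sign-flipped (`flipped = TRUE`); a strand-complemented
#'    pair is complemented first, then matched; anything else is dropped with
#'    reason `"allele mismatch"`;
#' 3. palindromic variants (A/T or C/G), whose alleles are strand-ambiguous,
#'    are resolved by allele frequency: the orientation minimizing
#'    `|eaf_exp - eaf_out|` is chosen, and the variant is dropped with reason
#'    `"ambiguous palindrome"` when its exposure minor-allele frequency is
#'    within `palindrome_eaf_window` of 0.5;
#' 4. variants present on only one side are dropped with reason
#'    `"missing in outcome"` / `"missing in exposure"`.
#'
#' @param exposure,outcome `mr_associations` data frames keyed by `snp`.
#' @param palindrome_eaf_window half-width of the frequency ambiguity zone
#'   around 0.5 (default 0.08: palindromes with exposure MAF > 0.42 are
#'   considered unresolvable).
#' @param exposure_label,outcome_label study labels; default to the `label`
#'   attribute of the inputs.
#' @return a `harmonized_set`: a data frame with one row per retained variant
#'   (`snp, beta_exp, se_exp, beta_out, se_out, eaf_exp, eaf_out, flipped,
#'   palindromic`) carrying attributes `exposure_label`, `outcome_label` and
#'   `dropped` (data frame of `snp`, `reason`).
#' @examples
#' paths <- vitc_pd_example()
#' h <- harmonize(read_associations(paths$exposure),
#'                read_associations(paths$pd_aao))
#' h
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                      exposure_label = NULL, outcome_label = NULL) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  if (!is.numeric(palindrome_eaf_window) || palindrome_eaf_window < 0 ||
      palindrome_eaf_window >= 0.5) {
    stop("'palindrome_eaf_window' must be in [0, 0.5)", call. = FALSE)
  }
  if (is.null(exposure_label)) {
    exposure_label <- attr(exposure, "label") %||% "exposure"
  }
  if (is.null(outcome_label)) {
    outcome_label <- attr(outcome, "label") %||% "outcome"
  }
  if (anyDuplicated(exposure$snp)) {
    stop("duplicate snp ids in exposure", call. = FALSE)
  }
  if (anyDuplicated(outcome$snp)) {
    stop("duplicate snp ids in outcome", call. = FALSE)
  }

  dropped <- data.frame(snp = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  add_drop <- function(snp, reason) {
    if (length(snp) > 0L) {
      dropped <<- rbind(dropped, data.frame(snp = snp, reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }
  add_drop(setdiff(exposure$snp, outcome$snp), "missing in outcome")
  add_drop(setdiff(outcome$snp, exposure$snp), "missing in exposure")

  shared <- intersect(exposure$snp, outcome$snp)
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp), , drop = FALSE]

  # orient the exposure to its raising allele
  neg <- ex$beta < 0
  if (any(neg)) ex[neg, ] <- swap_alleles(ex[neg, , drop = FALSE])

  k <- length(shared)
  flipped <- logical(k)
  keep <- rep(TRUE, k)
  reason <- character(k)
  pal <- is_palindromic(ex$ea, ex$nea)

  ou_ea <- ou$ea
  ou_nea <- ou$nea
  direct <- ou_ea == ex$ea & ou_nea == ex$nea
  swapped <- ou_ea == ex$nea & ou_nea == ex$ea
  comp_direct <- complement_allele(ou_ea) == ex$ea &
    complement_allele(ou_nea) == ex$nea
  comp_swapped <- complement_allele(ou_ea) == ex$nea &
    complement_allele(ou_nea) == ex$ea

  for (j in seq_len(k)) {
    if (pal[j]) {
      # same allele set on both sides, possibly reordered; strand labels
      # carry no information, so frequency decides the orientation
      if (!(direct[j] || swapped[j] || comp_direct[j] || comp_swapped[j])) {
        keep[j] <- FALSE
        reason[j] <- "allele mismatch"
        next
      }
      maf <- min(ex$eaf[j], 1 - ex$eaf[j])
      if (maf > 0.5 - palindrome_eaf_window) {
        keep[j] <- FALSE
        reason[j] <- "ambiguous palindrome"
        next
      }
      flipped[j] <- abs(ex$eaf[j] - (1 - ou$eaf[j])) <
        abs(ex$eaf[j] - ou$eaf[j])
    } else if (direct[j]) {
      flipped[j] <- FALSE
    } else if (swapped[j]) {
      flipped[j] <- TRUE
    } else if (comp_direct[j]) {
      flipped[j] <- FALSE
    } else if (comp_swapped[j]) {
      flipped[j] <- TRUE
    } else {
      keep[j] <- FALSE
      reason[j] <- "allele mismatch"
    }
  }
  add_drop(shared[!keep], reason[!keep])

  beta_out <- ifelse(flipped, -ou$beta, ou$beta)
  eaf_out <- ifelse(flipped, 1 - ou$eaf, ou$eaf)

  res <- data.frame(
    snp = shared,
    ea = ex$ea,
    nea = ex$nea,
    beta_exp = ex$beta,
    se_exp = ex$se,
    beta_out = beta_out,
    se_out = ou$se,
    eaf_exp = ex$eaf,
    eaf_out = eaf_out,
    flipped = flipped,
    palindromic = pal,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(res) <- NULL
  if (nrow(res) < 1L) {
    stop("no variants retained after harmonization", call. = FALSE)
  }
  attr(res, "exposure_label") <- exposure_label
  attr(res, "outcome_label") <- outcome_label
  attr(res, "dropped") <- dropped
  class(res) <- unique(c("harmonized_set", class(res)))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s on %s (%d variant%s",
              attr(x, "exposure_label"), attr(x, "outcome_label"), nrow(x),
              if (nrow(x) == 1L) "" else "s"))
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && nrow(dropped) > 0L) {
    cat(sprintf(", %d dropped", nrow(dropped)))
  }
  cat(")\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Variants dropped during harmonization
#'
#' @param h a `harmonized_set`.
#' @return data frame with columns `snp` and `reason`.
#' @export
dropped_variants <- function(h) {
  attr(h, "dropped") %||%
    data.frame(snp = character(0), reason = character(0))
}

#' Serialize a harmonized set
#'
#' `write_harmonized()` writes one TSV row per retained variant;
#' `harmonized_json()` returns a JSON document including labels and the
#' dropped-variant table.
#'
#' @param h a `harmonized_set`.
#' @param path output file path.
#' @return `path` invisibly, or a JSON string.
#' @export
write_harmonized <- function(h, path) {
  utils::write.table(as.data.frame(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_harmonized
#' @export
harmonized_json <- function(h) {
  jsonlite::toJSON(list(
    exposure_label = attr(h, "exposure_label"),
    outcome_label = attr(h, "outcome_label"),
    k = nrow(h),
    variants = as.data.frame(h),
    dropped = dropped_variants(h)
  ), auto_unbox = TRUE, digits = NA)
}
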
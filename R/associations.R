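#' @keywords internal
ASSOC_COLUMNS <- c("snp", "chr", "pos", "ea", "nea", "eaf", "beta", "se",
                   "pval", "n")
ASSOC_REQUIRED <- c("snp", "ea", "nea", "eaf", "beta", "se", "pval")

#' Validate a table of variant associations
#'
#' Checks the per-variant summary-statistic invariants: alleles are single
#' bases in A/C/G/T with effect allele distinct from the other allele,
#' standard errors are positive, allele frequencies lie in \[0, 1\] and
#' p-values in (0, 1]. All failing rows are reported together; nothing is
#' silently dropped.
#'
#' @param x data frame with at least the columns
#'   `snp, ea, nea, eaf, beta, se, pval` (optionally `chr, pos, n`).
#' @param label optional study label attached as an attribute.
#' @return `x` with alleles upper-cased, numeric columns coerced, and class
#'   `mr_associations` prepended.
#' @export
as_associations <- function(x, label = NULL) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(ASSOC_REQUIRED, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$snp <- as.character(x$snp)
  x$ea <- toupper(trimws(as.character(x$ea)))
  x$nea <- toupper(trimws(as.character(x$nea)))
  for (col in c("eaf", "beta", "se", "pval")) x[[col]] <- as.numeric(x[[col]])
  if (!"n" %in% names(x)) x$n <- NA_real_ else x$n <- as.numeric(x$n)

  bases <- c("A", "C", "G", "T")
  bad <- !(x$ea %in% bases) | !(x$nea %in% bases) | x$ea == x$nea |
    !is.finite(x$se) | x$se <= 0 |
    !is.finite(x$eaf) | x$eaf < 0 | x$eaf > 1 |
    !is.finite(x$beta) |
    !is.finite(x$pval) | x$pval <= 0 | x$pval > 1
  if (any(bad)) {
    stop("invalid association row(s) for: ",
         paste(x$snp[bad], collapse = ", "), call. = FALSE)
  }
  attr(x, "label") <- label
  class(x) <- unique(c("mr_associations", class(x)))
  x
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Reads one association per row from a TSV with a header line. Column names
#' can be remapped through `dialect` when the file uses a different naming
#' convention; the canonical names are
#' `snp, chr, pos, ea, nea, eaf, beta, se, pval, n`.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect named character vector mapping canonical column names to
#'   the file's column names, e.g. `c(snp = "rsid", pval = "p")`. Unmapped
#'   canonical names are looked up verbatim.
#' @param label study label; defaults to the file name without extension.
#' @return an `mr_associations` data frame (possibly zero rows).
#' @seealso [select_instruments()], [harmonize()]
#' @examples
#' exposure <- read_associations(vitc_pd_example()$exposure)
#' head(exposure)
#' @export
read_associations <- function(path, dialect = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || any(!nzchar(names(dialect)))) {
      stop("'dialect' must be a named character vector (canonical = file)",
           call. = FALSE)
    }
    for (canon in names(dialect)) {
      file_col <- dialect[[canon]]
      if (!file_col %in% names(raw)) {
        stop("missing mandatory column: '", file_col,
             "' (mapped to '", canon, "')", call. = FALSE)
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  keep <- intersect(ASSOC_COLUMNS, names(raw))
  missing_cols <- setdiff(ASSOC_REQUIRED, keep)
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[, keep, drop = FALSE]
  if (nrow(out) == 0L) {
    out$n <- if ("n" %in% names(out)) numeric(0) else NULL
    attr(out, "label") <- label
    class(out) <- unique(c("mr_associations", class(out)))
    return(out)
  }
  as_associations(out, label = label)
}

#' Write variant associations to a tab-separated file
#'
#' @param x an `mr_associations` data frame (or compatible data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select genome-wide significant instruments
#'
#' Filters variants on the exposure association p-value. The conventional
#' genome-wide significance threshold 5e-8 is the default. Linkage-
#' disequilibrium pruning is *not* performed: instruments are assumed to
#' arrive pre-selected as independent variants.
#'
#' @param assocs an `mr_associations` data frame.
#' @param p_threshold retain variants with `pval < p_threshold`; must lie in
#'   (0, 1].
#' @return the retained rows, original order preserved.
#' @examples
#' exposure <- read_associations(vitc_pd_example()$exposure)
#' nrow(select_instruments(exposure))  # all 11 pass 5e-8
#' @export
select_instruments <- function(assocs, p_threshold = 5e-8) {
  stopifnot(is.data.frame(assocs))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold <= 0 || p_threshold > 1) {
    stop("'p_threshold' must be a single number in (0, 1]", call. = FALSE)
  }
  if (p_threshold == 1) return(assocs)
  assocs[assocs$pval < p_threshold, , drop = FALSE]
}

#' Paths to the bundled vitamin C / Parkinson's disease summary statistics
#'
#' The package ships the 11-instrument plasma vitamin C exposure GWAS
#' (n = 52,018) together with the corresponding Parkinson's disease risk
#' (33,674 cases / 449,056 controls) and PD age-at-onset (n = 28,568)
#' outcome associations as plain TSV files, already oriented to the
#' vitamin C raising allele.
#'
#' @return named list with elements `exposure`, `pd` and `pd_aao`, each a
#'   file path.
#' @examples
#' vitc_pd_example()
#' @export
vitc_pd_example <- function() {
  list(
    exposure = system.file("extdata", "vitc_exposure.tsv", package = "ivmr",
                           mustWork = TRUE),
    pd = system.file("extdata", "pd_outcome.tsv", package = "ivmr",
                     mustWork = TRUE),
    pd_aao = system.file("extdata", "pd_aao_outcome.tsv", package = "ivmr",
                         mustWork = TRUE)
  )
}
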
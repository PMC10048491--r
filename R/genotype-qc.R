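#' Minor allele frequency from a dosage vector
#'
#' Allele frequency is computed over non-missing calls only; the returned
#' value is `min(p, 1 - p)`, so it lies in \[0, 0.5\].
#'
#' @param calls Dosage vector (ALT-allele counts in `{0, 1, 2}`, `NA` missing).
#' @return Minor allele frequency.
#' @export
compute_maf <- function(calls) {
  ok <- !is.na(calls)
  if (!any(ok)) stop("undefined MAF: all calls missing")
  p <- sum(calls[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

# vectorised per-column alt frequency / call rate over a dosage matrix
col_alt_freq <- function(dosage) {
  n_ok <- colSums(!is.na(dosage))
  colSums(dosage, na.rm = TRUE) / (2 * n_ok)
}

col_call_rate <- function(dosage) colMeans(!is.na(dosage))

#' Variant quality control
#'
#' Reproduces standard chip/WGS variant filtering: keep biallelic variants
#' with minor allele frequency >= `maf_min` and call rate >= `call_rate_min`
#' (both inclusive). Surviving dosages are re-oriented to count the minor
#' allele; a tie at frequency 0.5 keeps the ALT allele as minor, so
#' orientation is deterministic.
#'
#' @param geno A [geno_matrix()] with ALT-dosage coding.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param call_rate_min Minimum fraction of non-missing calls (default 0.90).
#' @param biallelic_only Drop records with more than one ALT allele.
#' @return A list of class `qc_result`: `geno` (filtered, minor-allele
#'   oriented; variant table gains `ma` — the minor allele label — and `maf`)
#'   and `report` (tibble of removal counts per criterion).
#' @export
filter_variants <- function(geno, maf_min = 0.05, call_rate_min = 0.90,
                            biallelic_only = TRUE) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- geno$dosage
  biallelic <- !grepl(",", geno$variants$alt, fixed = TRUE)
  cr <- col_call_rate(d)
  all_missing <- cr == 0
  p_alt <- col_alt_freq(d)
  maf <- pmin(p_alt, 1 - p_alt)
  pass_bi <- biallelic | !biallelic_only
  pass_cr <- cr >= call_rate_min
  pass_maf <- !all_missing & maf >= maf_min
  keep <- pass_bi & pass_cr & pass_maf
  report <- tibble::tibble(
    criterion = c("input", "multiallelic", "call_rate", "maf", "retained"),
    n = c(length(keep), sum(!pass_bi), sum(pass_bi & !pass_cr),
          sum(pass_bi & pass_cr & !pass_maf), sum(keep))
  )
  if (!any(keep)) stop("no variants survive QC")
  d <- d[, keep, drop = FALSE]
  v <- geno$variants[keep, ]
  # orient to minor allele: flip dosage where ALT is the major allele
  flip <- p_alt[keep] > 0.5
  if (any(flip)) d[, flip] <- 2L - d[, flip, drop = FALSE]
  if (!"ma" %in% names(v)) v$ma <- v$alt
  v$ma[flip] <- ifelse(v$ma[flip] == v$alt[flip], v$ref[flip], v$alt[flip])
  v$maf <- unname(maf[keep])
  structure(list(geno = geno_matrix(d, v), report = report),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$report)
  invisible(x)
}
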
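#' Genotype matrix container
#'
#' Bundles an individuals-by-variants dosage matrix with its variant metadata.
#' Dosages count copies of the ALT allele (0, 1, 2) with `NA` for missing
#' calls; after [filter_variants()] dosages are re-oriented so they count the
#' minor allele. Positions are 1-based and strictly increasing within each
#' chromosome.
#'
#' @param dosage Integer matrix, individuals in rows (rownames = cow ids),
#'   variants in columns (colnames = variant ids). Values in `{0, 1, 2, NA}`.
#' @param variants Tibble with one row per column of `dosage`:
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`. Multi-allelic records carry a
#'   comma-separated `alt` string.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  variants <- tibble::as_tibble(variants)
  req <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants))) {
    stop("variants must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant ids: ",
         paste(utils::head(variants$variant_id[duplicated(variants$variant_id)], 5),
               collapse = ", "))
  }
  bad <- variants |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    stop("positions must be strictly increasing within chromosome: ",
         paste(bad$chrom[!bad$ok], collapse = ", "))
  }
  colnames(dosage) <- variants$variant_id
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("id%04d", seq_len(nrow(dosage)))
  }
  structure(list(dosage = dosage, variants = variants), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d variants (%d chromosome%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              dplyr::n_distinct(x$variants$chrom),
              if (dplyr::n_distinct(x$variants$chrom) == 1) "" else "s"))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param i Individual (row) index, id vector, or logical mask.
#' @param j Variant (column) index, variant-id vector, or logical mask.
#' @param ... Unused.
#' @return A `geno_matrix` restricted to the selected individuals/variants.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, x$variants$variant_id)
  d <- x$dosage[i, j, drop = FALSE]
  v <- if (is.logical(j)) x$variants[which(j), ] else x$variants[j, ]
  geno_matrix(d, v)
}

# chromosome class used for per-class genomic control
chrom_class <- function(chrom) {
  ifelse(toupper(as.character(chrom)) %in% c("X", "CHRX"), "X", "autosome")
}
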
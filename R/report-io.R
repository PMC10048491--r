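#' Write genotypes as VCF v4.2
#'
#' GT-only records, `./.` for missing calls. Coordinates are 1-based; dosage
#' counts the ALT allele as stored (re-orientation by QC is a dosage-level
#' operation and does not alter REF/ALT labels).
#'
#' @param geno A [geno_matrix()].
#' @param path Output file (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  d <- geno$dosage
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0L] <- "0/0"
  gt[!is.na(d) & d == 1L] <- "0/1"
  gt[!is.na(d) & d == 2L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=herdgwas",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  v <- geno$variants
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses GT fields of a (plain or gzipped) VCF v4.2 with vcfR; any phased or
#' unphased diploid GT is converted to an ALT-allele dosage, `.` to missing.
#' Multi-allelic records are retained with their comma-separated ALT string
#' and dosage `NA` (they are removed by [filter_variants()]).
#'
#' @param path VCF file.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  gt <- vcfR::extract.gt(v, element = "GT")
  alt1 <- substr(gt, 1, 1)
  alt2 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  okcall <- !is.na(gt) & alt1 %in% c("0", "1") & alt2 %in% c("0", "1")
  dos[okcall] <- as.integer(alt1[okcall]) + as.integer(alt2[okcall])
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  dos[multi, ] <- NA_integer_
  variants <- tibble::tibble(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT)
  geno_matrix(t(dos), variants)
}

#' Read gene annotation from GFF3 or BED
#'
#' GFF3 is parsed with rtracklayer (gene-type features kept); BED is read as
#' 0-based half-open and converted to 1-based inclusive coordinates.
#'
#' @param path Annotation file (`.gff3`/`.gff` or `.bed`).
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @return Tibble: `gene_id`, `name`, `chrom`, `start`, `stop`, `strand`.
#' @export
read_annotation <- function(path, feature_type = "gene") {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           comment = "#")
    return(tibble::tibble(
      gene_id = if (ncol(bed) >= 4) as.character(bed[[4]]) else
        paste0("bed", seq_len(nrow(bed))),
      name = if (ncol(bed) >= 4) as.character(bed[[4]]) else NA_character_,
      chrom = as.character(bed[[1]]),
      start = as.numeric(bed[[2]]) + 1,     # 0-based half-open -> 1-based
      stop = as.numeric(bed[[3]]),
      strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "+"))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) == feature_type]
  }
  meta <- S4Vectors::mcols(gr)
  tibble::tibble(
    gene_id = if ("ID" %in% names(meta)) as.character(meta$ID) else
      paste0("gene", seq_along(gr)),
    name = if ("Name" %in% names(meta)) as.character(meta$Name) else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), stop = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
}

#' Genes overlapping QTL region cores
#'
#' A gene is reported when its `[start, stop]` interval overlaps the region
#' core by at least 1 bp (inclusive ends; strand ignored), ordered by start.
#'
#' @param regions A `qtl_regions` tibble (or any tibble with `chrom`,
#'   `core_start`, `core_stop`).
#' @param annotation Gene tibble from [read_annotation()].
#' @return Input regions with `genes` (list-column of gene tibbles),
#'   `gene_names` and `n_genes` columns.
#' @export
genes_in_region <- function(regions, annotation) {
  if (nrow(annotation) == 0) {
    warning("empty annotation; no genes reported")
  }
  genes <- purrr::pmap(
    list(regions$chrom, regions$core_start, regions$core_stop),
    function(ch, lo, hi) {
      annotation |>
        dplyr::filter(.data$chrom == ch, .data$start <= hi,
                      .data$stop >= lo) |>
        dplyr::arrange(.data$start)
    })
  regions |>
    dplyr::mutate(genes = genes) |>
    dplyr::mutate(
      gene_names = purrr::map_chr(.data$genes, function(g) {
        paste(dplyr::coalesce(g$name, g$gene_id), collapse = ",")
      }),
      n_genes = purrr::map_int(.data$genes, nrow))
}

#' Manhattan plot data
#'
#' Adds a cumulative genome coordinate (chromosomes laid end to end in input
#' order), a chromosome parity key for alternating colors, and carries the
#' threshold lines for the three alpha levels.
#'
#' @param results A corrected `gwas_result`.
#' @param thresholds Tibble from [bonferroni_thresholds()].
#' @return List of class `manhattan_data`: `points` (per-variant tibble with
#'   `cum_pos`, `neg_log10_p`, `parity`), `thresholds`, `chrom_breaks`
#'   (axis midpoints).
#' @export
export_manhattan <- function(results, thresholds) {
  stopifnot("neg_log10_p" %in% names(results))
  chroms <- unique(results$chrom)
  offs <- results |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos), .groups = "drop") |>
    dplyr::mutate(chrom = factor(.data$chrom, levels = chroms)) |>
    dplyr::arrange(.data$chrom) |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  pts <- results |>
    dplyr::left_join(offs |> dplyr::mutate(chrom = as.character(.data$chrom)),
                     by = "chrom") |>
    dplyr::mutate(cum_pos = .data$pos + .data$offset,
                  parity = (match(.data$chrom, chroms) - 1) %% 2)
  breaks <- pts |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(mid = mean(range(.data$cum_pos)), .groups = "drop")
  structure(list(points = pts, thresholds = thresholds,
                 chrom_breaks = breaks),
            class = "manhattan_data")
}

#' Top-SNP summary table
#'
#' One row per (trait, region): the trait's top SNP with its minor allele,
#' frequency, allele-substitution effect and significance, in the layout of a
#' top-associations table.
#'
#' @param results A corrected `gwas_result`.
#' @param regions A `qtl_regions` tibble from [define_qtl()].
#' @return Tibble with columns `Trait`, `Lactation`, `rsID`, `Chr`,
#'   `Position`, `MA`, `MAF`, `beta`, `SE`, `neg_log10_p`.
#' @export
top_snp_table <- function(results, regions) {
  if (nrow(regions) == 0) {
    return(tibble::tibble(Trait = character(), Lactation = character(),
                          rsID = character(), Chr = character(),
                          Position = double(), MA = character(),
                          MAF = double(), beta = double(), SE = double(),
                          neg_log10_p = double()))
  }
  regions |>
    dplyr::left_join(results,
                     by = c(top_variant_id = "variant_id", trait = "trait",
                            chrom = "chrom"),
                     relationship = "many-to-many") |>
    dplyr::group_by(.data$chrom, .data$group, .data$trait) |>
    dplyr::slice_max(.data$neg_log10_p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(Trait = .data$trait, Lactation = .data$lactation,
                     rsID = .data$top_variant_id, Chr = .data$chrom,
                     Position = .data$top_pos, MA = .data$ma,
                     MAF = .data$maf, beta = .data$beta, SE = .data$se,
                     neg_log10_p = .data$neg_log10_p) |>
    dplyr::arrange(.data$Trait, .data$Chr, .data$Position)
}

#' Write QTL regions as BED
#'
#' Core intervals are exported 0-based half-open (BED convention); reading
#' them back with `start + 1` recovers the 1-based inclusive cores exactly.
#'
#' @param regions A `qtl_regions` or merged-region tibble.
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_qtl_bed <- function(regions, path) {
  name <- if ("trait" %in% names(regions)) {
    paste0(regions$chrom, ":", regions$group, ":", regions$trait)
  } else {
    paste0(regions$chrom, ":", regions$group)
  }
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$core_start - 1, scientific = FALSE,
                                   trim = TRUE),
                    stop = format(regions$core_stop, scientific = FALSE,
                                  trim = TRUE),
                    name = name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read tab-separated tables
#'
#' Thin wrappers standardising TSV I/O across the pipeline (header, no
#' quoting, `NA` as literal).
#'
#' @param x Data frame.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
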
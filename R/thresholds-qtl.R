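#' Pairwise linkage disequilibrium statistics
#'
#' `r2` is the squared Pearson correlation of dosages over jointly non-missing
#' calls. `dprime` is the normalized disequilibrium |D'| computed from
#' two-locus haplotype frequencies estimated by EM over the unphased genotype
#' table (double heterozygotes are the ambiguous class), iterated to
#' `|delta freq| < 1e-8` or 1000 iterations.
#'
#' @param g1,g2 Dosage vectors.
#' @return Tibble: `r2`, `dprime`, `n` (jointly called). Monomorphic input
#'   gives `NA` statistics.
#' @export
ld_pair <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("need at least 2 jointly called individuals")
  a <- g1[ok]; b <- g2[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    return(tibble::tibble(r2 = NA_real_, dprime = NA_real_, n = sum(ok)))
  }
  r2 <- stats::cor(a, b)^2
  tibble::tibble(r2 = r2, dprime = em_dprime(a, b), n = sum(ok))
}

# EM estimate of |D'| for two unphased biallelic loci
em_dprime <- function(a, b, tol = 1e-8, max_iter = 1000L) {
  n <- length(a)
  pA <- mean(a) / 2   # freq of the allele counted by dosage at locus 1
  pB <- mean(b) / 2
  n_dh <- sum(a == 1L & b == 1L)   # double heterozygotes: phase-ambiguous
  # unambiguous haplotype counts (each individual carries two haplotypes)
  cAB <- sum((a == 2) * (b == 2) * 2 + (a == 2) * (b == 1) + (a == 1) * (b == 2))
  cAb <- sum((a == 2) * (b == 0) * 2 + (a == 2) * (b == 1) + (a == 1) * (b == 0))
  caB <- sum((a == 0) * (b == 2) * 2 + (a == 0) * (b == 1) + (a == 1) * (b == 2))
  cab <- sum((a == 0) * (b == 0) * 2 + (a == 0) * (b == 1) + (a == 1) * (b == 0))
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  for (i in seq_len(max_iter)) {
    # E step: split double hets between AB/ab and Ab/aB phases
    denom <- unname(f["AB"] * f["ab"] + f["Ab"] * f["aB"])
    w <- if (denom > 0) unname(f["AB"] * f["ab"]) / denom else 0.5
    new <- stats::setNames(
      c(cAB + w * n_dh, cAb + (1 - w) * n_dh,
        caB + (1 - w) * n_dh, cab + w * n_dh) / (2 * n),
      c("AB", "Ab", "aB", "ab"))
    if (max(abs(new - f)) < tol) { f <- new; break }
    f <- new
  }
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  D <- f[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(NA_real_)
  unname(abs(D) / dmax)
}

#' LD pruning and effective number of independent tests
#'
#' Sliding-window greedy pruning in the indep-pairwise style: within each
#' window of `window` variants (advanced by `step` variants, per chromosome),
#' pairs of retained variants with `r2 > r2_max` are visited in position
#' order and the member with the lower MAF is removed (tie: the later
#' position). Removals persist across windows. Missing calls are mean-imputed
#' for the window correlations. The survivor count `M` is the effective
#' number of independent tests used for Bonferroni thresholds.
#'
#' @param geno A post-QC [geno_matrix()] (needs the `maf` column).
#' @param window,step Window and step sizes in variant counts.
#' @param r2_max Pairwise squared-correlation cutoff.
#' @return List of class `ld_prune`: `kept` (variant ids), `M` (count),
#'   `n_removed`.
#' @export
prune_ld <- function(geno, window = 500L, step = 100L, r2_max = 0.6) {
  stopifnot(inherits(geno, "geno_matrix"))
  v <- geno$variants
  maf <- if ("maf" %in% names(v)) v$maf else
    apply(geno$dosage, 2, compute_maf)
  keep <- rep(TRUE, nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)         # position-sorted by construction
    m <- length(idx)
    if (m < 2) next
    bw <- min(window, m) - 1L           # band width: max index distance
    B <- band_r2(geno$dosage[, idx, drop = FALSE], bw)
    alive <- rep(TRUE, m)
    maf_c <- maf[idx]
    starts <- seq(1L, max(m - 1L, 1L), by = step)
    for (s in starts) {
      wend <- min(s + window - 1L, m)
      for (i in s:(wend - 1L)) {
        if (!alive[i]) next
        dmax <- min(wend - i, bw)
        hot <- which(B[i, seq_len(dmax)] > r2_max) + i
        for (j in hot) {
          if (!alive[i]) break
          if (!alive[j]) next
          if (maf_c[j] <= maf_c[i]) {   # lower MAF removed; tie: later pos
            alive[j] <- FALSE
          } else {
            alive[i] <- FALSE
          }
        }
      }
      if (wend >= m) break
    }
    keep[idx[!alive]] <- FALSE
  }
  structure(list(kept = v$variant_id[keep], M = sum(keep),
                 n_removed = sum(!keep)),
            class = "ld_prune")
}

# banded squared correlations: B[i, d] = r2(variant i, variant i + d) for
# d = 1..bw. Missing calls are mean-imputed per variant, columns centered and
# L2-normalised, and the band filled chunk-wise with BLAS cross-products so
# each pair is computed exactly once.
band_r2 <- function(d, bw) {
  d <- d * 1
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    na_idx <- which(is.na(d))
    d[na_idx] <- mu[(na_idx - 1L) %/% nrow(d) + 1L]
  }
  d <- sweep(d, 2, colMeans(d))
  nrm <- sqrt(colSums(d^2))
  nrm[nrm == 0] <- NA_real_   # monomorphic: r2 undefined
  d <- sweep(d, 2, nrm, "/")
  m <- ncol(d)
  B <- matrix(NA_real_, m, bw)
  chunk <- 512L
  for (a in seq(1L, m, by = chunk)) {
    b <- min(a + chunk - 1L, m)
    hi <- min(b + bw, m)
    R <- crossprod(d[, a:b, drop = FALSE], d[, a:hi, drop = FALSE])^2
    for (i in a:b) {
      dd <- min(bw, m - i)
      if (dd >= 1) {
        B[i, seq_len(dd)] <- R[i - a + 1L, i - a + 1L + seq_len(dd)]
      }
    }
  }
  B
}

#' Bonferroni significance thresholds from the effective test count
#'
#' Divides each alpha level by the number of independent variants `M` and
#' reports the genome-wide threshold on the -log10 scale, exactly and rounded
#' to one decimal as used for reporting (alpha 0.01 = highly significant,
#' 0.05 = significant, 0.1 = suggestive).
#'
#' @param M Number of independent tests (LD-pruned survivor count).
#' @param alphas Significance levels.
#' @return Tibble: `alpha`, `label`, `threshold` (-log10(alpha / M)),
#'   `threshold_1dp`.
#' @export
bonferroni_thresholds <- function(M, alphas = c(0.01, 0.05, 0.1)) {
  if (length(M) != 1 || is.na(M) || M < 1) stop("M must be a positive count")
  if (any(alphas <= 0 | alphas > 1)) stop("alphas must be in (0, 1]")
  labs <- dplyr::case_when(alphas <= 0.01 ~ "highly significant",
                           alphas <= 0.05 ~ "significant",
                           TRUE ~ "suggestive")
  tibble::tibble(alpha = alphas, label = labs,
                 threshold = -log10(alphas / M),
                 threshold_1dp = round(-log10(alphas / M), 1))
}

#' Two-stage QTL region definition
#'
#' Stage 1 (coarse): variants exceeding the suggestive threshold are pooled
#' across all traits (a variant suggestive for several traits counts once) and
#' chained per chromosome by single linkage — consecutive pooled variants at
#' most `coarse_gap` apart share a group; groups with fewer than
#' `min_variants` pooled variants are discarded. Stage 2 (per trait): within
#' each surviving group, the trait's top SNP (smallest corrected p, tie:
#' smaller position) seeds a region that grows by repeatedly adding suggestive
#' variants within `chain_gap` of the current region bounds. The core interval
#' spans the member positions; display bounds add `flank` up- and downstream
#' (floored at 1).
#'
#' @param results A corrected `gwas_result` (needs `neg_log10_p`).
#' @param cutoff Suggestive threshold on the -log10 p scale (e.g.
#'   `bonferroni_thresholds(M)$threshold` at alpha 0.1).
#' @param coarse_gap Stage-1 chaining distance in bp (default 2.5 Mb).
#' @param min_variants Minimum pooled variants per coarse group (default 3).
#' @param chain_gap Stage-2 growth distance in bp (default 500 kb).
#' @param flank Display flank in bp (default 100 kb).
#' @return Tibble of class `qtl_regions`: one row per (coarse group, trait)
#'   with `chrom`, `group`, `trait`, `core_start`, `core_stop`,
#'   `display_start`, `display_stop`, `n_variants` (region members),
#'   `top_variant_id`, `top_pos`, `top_neg_log10_p`. Empty tibble when no
#'   variant is suggestive.
#' @export
define_qtl <- function(results, cutoff, coarse_gap = 2.5e6, min_variants = 3L,
                       chain_gap = 5e5, flank = 1e5) {
  if (!"neg_log10_p" %in% names(results)) {
    stop("run genomic_control() before define_qtl()")
  }
  sug <- dplyr::filter(results, !is.na(.data$neg_log10_p),
                       .data$neg_log10_p >= cutoff)
  empty <- tibble::tibble(chrom = character(), group = integer(),
                          trait = character(), core_start = double(),
                          core_stop = double(), display_start = double(),
                          display_stop = double(), n_variants = integer(),
                          top_variant_id = character(), top_pos = double(),
                          top_neg_log10_p = double())
  if (nrow(sug) == 0) return(structure(empty, class = c("qtl_regions", class(empty))))

  # stage 1: pooled single-linkage chaining per chromosome
  pooled <- sug |>
    dplyr::distinct(.data$chrom, .data$pos, .data$variant_id) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(group = cumsum(c(1, diff(.data$pos) > coarse_gap))) |>
    dplyr::group_by(.data$chrom, .data$group) |>
    dplyr::filter(dplyr::n() >= min_variants) |>
    dplyr::ungroup()
  if (nrow(pooled) == 0) return(structure(empty, class = c("qtl_regions", class(empty))))

  sug2 <- dplyr::inner_join(sug, pooled[, c("chrom", "variant_id", "group")],
                            by = c("chrom", "variant_id"))
  # stage 2: grow a region per (group, trait) from the trait's top SNP
  out <- sug2 |>
    dplyr::group_by(.data$chrom, .data$group, .data$trait) |>
    dplyr::group_map(function(g, key) {
      top <- g |>
        dplyr::arrange(dplyr::desc(.data$neg_log10_p), .data$pos) |>
        dplyr::slice(1)
      pool_pos <- sort(unique(
        pooled$pos[pooled$chrom == key$chrom & pooled$group == key$group]))
      lo <- hi <- top$pos
      repeat {
        sel <- pool_pos >= lo - chain_gap & pool_pos <= hi + chain_gap
        new_lo <- min(pool_pos[sel], lo)
        new_hi <- max(pool_pos[sel], hi)
        if (new_lo == lo && new_hi == hi) break
        lo <- new_lo; hi <- new_hi
      }
      members <- pool_pos[pool_pos >= lo & pool_pos <= hi]
      tibble::tibble(chrom = key$chrom, group = key$group, trait = key$trait,
                     core_start = lo, core_stop = hi,
                     display_start = max(lo - flank, 1),
                     display_stop = hi + flank,
                     n_variants = length(members),
                     top_variant_id = top$variant_id, top_pos = top$pos,
                     top_neg_log10_p = top$neg_log10_p)
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$chrom, .data$core_start, .data$trait)
  structure(out, class = c("qtl_regions", class(out)))
}

#' Merge per-trait QTL regions per coarse group
#'
#' Collapses the per-trait regions of [define_qtl()] into one row per coarse
#' group (union of core bounds, pooled member count, best top SNP over
#' traits) — the layout of a summary QTL table.
#'
#' @param regions A `qtl_regions` tibble.
#' @return Tibble: `chrom`, `group`, `core_start`, `core_stop`,
#'   `display_start`, `display_stop`, `length_mb`, `traits`, `n_traits`,
#'   `top_variant_id`, `top_neg_log10_p`.
#' @export
merge_qtl_regions <- function(regions) {
  if (nrow(regions) == 0) return(tibble::tibble())
  regions |>
    dplyr::group_by(.data$chrom, .data$group) |>
    dplyr::summarise(
      core_start = min(.data$core_start), core_stop = max(.data$core_stop),
      display_start = max(min(.data$core_start) - 1e5, 1),
      display_stop = max(.data$core_stop) + 1e5,
      length_mb = (max(.data$core_stop) - min(.data$core_start) + 1) / 1e6,
      traits = paste(sort(unique(.data$trait)), collapse = ","),
      n_traits = dplyr::n_distinct(.data$trait),
      top_variant_id = .data$top_variant_id[which.max(.data$top_neg_log10_p)],
      top_neg_log10_p = max(.data$top_neg_log10_p),
      .groups = "drop")
}
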
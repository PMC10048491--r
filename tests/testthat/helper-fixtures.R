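# shared fixture builders -----------------------------------------------------

# tiny geno_matrix from an explicit dosage matrix (rows = individuals)
toy_geno <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  variants <- tibble::tibble(variant_id = sprintf("v%03d", seq_len(m)),
                             chrom = chrom, pos = pos, ref = "A", alt = "B")
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("ind%02d", seq_len(nrow(dosage)))
  }
  herdgwas::geno_matrix(dosage, variants)
}

# random biallelic dosages with given allele frequencies (independent variants)
random_geno <- function(n, p, seed = 1, chrom = NULL, pos = NULL) {
  set.seed(seed)
  d <- vapply(p, function(pp) stats::rbinom(n, 2L, pp), integer(n))
  toy_geno(matrix(as.integer(d), n, length(p)), chrom = chrom, pos = pos)
}

# minimal lactation-record table for phenotype-module tests
toy_records <- function(n_cows = 60, seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(cow_id = sprintf("c%03d", seq_len(n_cows)),
                     lactation = 1:3) |>
    dplyr::mutate(
      dim = 300L,
      milk_kg = stats::rnorm(dplyr::n(), 6000, 400),
      fat_kg = stats::rnorm(dplyr::n(), 250, 15),
      protein_kg = stats::rnorm(dplyr::n(), 210, 12),
      farm = rep(rep(c("f1", "f2"), each = ceiling(n_cows / 2))[seq_len(n_cows)], each = 3),
      sire = rep(rep(c("s1", "s2"), ceiling(n_cows / 2))[seq_len(n_cows)], each = 3),
      birth_year = 2010L,
      birth_season = "spring",
      calving_year = 2012L + lactation,
      calving_season = "summer",
      age_first_calving = 780L
    )
}

# One causal variant per chromosome: MAF in [0.2, 0.4], mid-chromosome, and
# embedded in a haplotype block (>= 2 neighbours with r2 >= 0.6), as a
# sequence-level causal variant would be.
pick_tagged_qtl <- function(geno0, effects, trait = "milk_kg") {
  purrr::map2_dfr(as.character(seq_along(effects)), effects, function(ch, eff) {
    v <- geno0$variants[geno0$variants$chrom == ch, ]
    maf <- apply(geno0$dosage[, v$variant_id, drop = FALSE], 2,
                 herdgwas::compute_maf)
    L <- max(v$pos)
    cand <- which(maf >= 0.2 & maf <= 0.4 & v$pos > 0.2 * L & v$pos < 0.8 * L)
    cand <- cand[order(abs(v$pos[cand] - L / 2))]
    for (j in cand) {
      nb <- setdiff(max(1, j - 30):min(nrow(v), j + 30), j)
      d <- geno0$dosage[, v$variant_id[c(j, nb)], drop = FALSE] * 1
      r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs")[1, -1]^2)
      if (sum(r2 >= 0.6, na.rm = TRUE) >= 2) {
        return(tibble::tibble(chrom = ch, pos = v$pos[j], trait = trait,
                              effect = eff))
      }
    }
    stop("no tagged candidate variant on chromosome ", ch)
  })
}

# small simulated study used by several modules (memoised per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- herdgwas::sim_config(
        n_individuals = 400, n_sires = 12, n_chromosomes = 2,
        variants_per_chromosome = 800, missing_rate = 0.02,
        lactation_presence = c(1, 0.85, 0.7), seed = 101)
      cache <<- c(herdgwas::simulate_herd(cfg), list(config = cfg))
    }
    cache
  }
})
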
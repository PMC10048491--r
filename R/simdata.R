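#' Configuration for the structured-population simulator
#'
#' Defines the herd design (cows, sires, farms, birth years), the genome
#' (chromosomes, variant density, LD block scale, MAF spectrum, missingness),
#' the trait architecture (per-trait heritability, planted QTL, covariate
#' effect magnitudes) and the population-structure knobs. Defaults emulate a
#' small closed dual-purpose dairy population: ~2000 cows on 8 farms descending
#' from 37 sires over 10 birth years, with moderate LD blocks and heritabilities
#' in the ranges reported for such herds (milk ~0.40, fat ~0.35, protein ~0.35).
#'
#' @param n_individuals Number of cows.
#' @param n_sires Number of sires (half-sib family heads).
#' @param n_dams Number of dams; each cow draws a dam within its sire's mating
#'   group, so full-sib pairs occur. Default `n_individuals %/% 2`.
#' @param n_farms,birth_years Number of farms and of birth-year cohorts.
#' @param n_chromosomes Autosome count; one extra chromosome labelled `"X"` is
#'   appended when `include_x = TRUE`.
#' @param variants_per_chromosome Variants simulated per chromosome.
#' @param chromosome_length_bp Chromosome length in bp.
#' @param ld_block_mean_kb Mean LD block length (kb); haplotypes are mosaics of
#'   a small founder pool within each block, giving block-wise LD that decays
#'   to zero across block boundaries.
#' @param n_founder_haplotypes Founder pool size per block; smaller pools give
#'   stronger family-level haplotype sharing.
#' @param n_ancestral_haplotypes Number of distinct ancestral haplotypes per
#'   block that the founder pool is copied from; this is the block's haplotype
#'   diversity and the main LD dial (small values emulate the low effective
#'   population size of a closed breed and give strong within-block r2).
#' @param mutation_rate Per-site flip probability when a founder copies an
#'   ancestral haplotype; smooths the allele-frequency spectrum away from the
#'   k/n_ancestral quantisation.
#' @param maf_spectrum Either `"uniform_with_rare_tail"` (90% uniform on
#'   \[0.05, 0.5\], 10% uniform on \[0.005, 0.05\)) or `"uniform"` on
#'   \[0.05, 0.5\].
#' @param missing_rate Fraction of genotype calls set to missing.
#' @param n_clusters Number of relatedness clusters the sires are split into.
#' @param cluster_divergence Dirichlet concentration control in \[0, 1): 0 means
#'   panmixia (all clusters share founder-use frequencies); larger values skew
#'   each cluster's founder-sampling weights, creating allele-frequency
#'   divergence and, when phenotypes are confounded with clusters, genomic
#'   inflation.
#' @param qtl_spec Tibble/data.frame of planted QTL with columns `chrom`,
#'   `pos`, `trait` (one of `"milk_kg"`, `"fat_kg"`, `"protein_kg"`) and
#'   `effect` (trait units per copy of the ALT allele at the nearest simulated
#'   variant). `NULL` for none.
#' @param h2 Named numeric: narrow-sense heritability per yield trait.
#' @param trait_mean,trait_sd Named numerics: 305-day phenotypic mean and SD in
#'   kg per yield trait (defaults: milk 6000/900, fat 255/40, protein 210/30).
#' @param lactation_scale Multiplier on the trait mean for lactations 1-3
#'   (later lactations yield more).
#' @param covariate_sd Named numeric: SD of the random level effects for
#'   `farm`, `birth_year`, `birth_season`, `calving_year`, `calving_season`,
#'   plus the linear slope `age_first_calving` (units per day), expressed as a
#'   fraction of the trait SD.
#' @param cluster_effect_sd SD of a per-cluster phenotype shift (fraction of
#'   trait SD); 0 by default. Set > 0 together with `cluster_divergence` to
#'   produce structure-confounded phenotypes.
#' @param n_background Number of background (polygenic) causal markers per
#'   trait.
#' @param lactation_presence Probability a cow has a record in lactations 1-3.
#' @param include_x Append an X chromosome (simulated as an ordinary diploid
#'   chromosome; it exists so the per-chromosome-class correction pathway is
#'   exercised).
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000,
                       n_sires = 37,
                       n_dams = NULL,
                       n_farms = 8,
                       birth_years = 10,
                       n_chromosomes = 5,
                       variants_per_chromosome = 2000,
                       chromosome_length_bp = 5e7,
                       ld_block_mean_kb = 100,
                       n_founder_haplotypes = 16,
                       n_ancestral_haplotypes = 2,
                       mutation_rate = 0.005,
                       maf_spectrum = c("uniform_with_rare_tail", "uniform"),
                       missing_rate = 0.02,
                       n_clusters = 6,
                       cluster_divergence = 0,
                       qtl_spec = NULL,
                       h2 = c(milk_kg = 0.40, fat_kg = 0.35, protein_kg = 0.35),
                       trait_mean = c(milk_kg = 6000, fat_kg = 255, protein_kg = 210),
                       trait_sd = c(milk_kg = 900, fat_kg = 40, protein_kg = 30),
                       lactation_scale = c(0.92, 1.0, 1.05),
                       covariate_sd = c(farm = 0.25, birth_year = 0.10,
                                        birth_season = 0.05, calving_year = 0.08,
                                        calving_season = 0.05,
                                        age_first_calving = 0.0003),
                       cluster_effect_sd = 0,
                       n_background = 1000,
                       lactation_presence = c(0.95, 0.80, 0.65),
                       include_x = FALSE,
                       seed = 1L) {
  maf_spectrum <- match.arg(maf_spectrum)
  counts <- c(n_individuals = n_individuals, n_sires = n_sires,
              n_farms = n_farms, birth_years = birth_years,
              n_chromosomes = n_chromosomes,
              variants_per_chromosome = variants_per_chromosome,
              chromosome_length_bp = chromosome_length_bp,
              n_founder_haplotypes = n_founder_haplotypes,
              n_ancestral_haplotypes = n_ancestral_haplotypes,
              n_clusters = n_clusters, n_background = n_background)
  if (any(counts <= 0)) {
    stop("configuration error: non-positive count(s): ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  }
  if (is.null(n_dams)) n_dams <- max(n_individuals %/% 2L, 1L)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("configuration error: missing_rate must be in [0, 1)")
  }
  if (any(h2 <= 0 | h2 >= 1)) stop("configuration error: h2 must be in (0, 1)")
  if (!is.null(qtl_spec)) {
    qtl_spec <- tibble::as_tibble(qtl_spec)
    stopifnot(all(c("chrom", "pos", "trait", "effect") %in% names(qtl_spec)))
    if (!all(qtl_spec$trait %in% names(h2))) {
      stop("configuration error: qtl_spec traits must be among ",
           paste(names(h2), collapse = ", "))
    }
    if (any(qtl_spec$pos < 1 | qtl_spec$pos > chromosome_length_bp)) {
      stop("configuration error: QTL position outside chromosome length")
    }
  }
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              n_farms = as.integer(n_farms), birth_years = as.integer(birth_years),
              n_chromosomes = as.integer(n_chromosomes),
              variants_per_chromosome = as.integer(variants_per_chromosome),
              chromosome_length_bp = as.double(chromosome_length_bp),
              ld_block_mean_kb = ld_block_mean_kb,
              n_founder_haplotypes = as.integer(n_founder_haplotypes),
              n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
              mutation_rate = mutation_rate,
              maf_spectrum = maf_spectrum, missing_rate = missing_rate,
              n_clusters = as.integer(n_clusters),
              cluster_divergence = cluster_divergence,
              qtl_spec = qtl_spec, h2 = h2, trait_mean = trait_mean,
              trait_sd = trait_sd, lactation_scale = lactation_scale,
              covariate_sd = covariate_sd, cluster_effect_sd = cluster_effect_sd,
              n_background = as.integer(n_background),
              lactation_presence = lactation_presence,
              include_x = isTRUE(include_x), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

draw_maf <- function(n, spectrum) {
  if (spectrum == "uniform") return(stats::runif(n, 0.05, 0.5))
  rare <- stats::runif(n) < 0.1
  p <- stats::runif(n, 0.05, 0.5)
  p[rare] <- stats::runif(sum(rare), 0.005, 0.05)
  p
}

# Pedigree + cluster layout shared by genotype and phenotype simulation.
# Deterministic given the config seed (uses its own RNG substream).
sim_pedigree <- function(config) {
  n <- config$n_individuals
  sire <- sort(rep_len(seq_len(config$n_sires), n))
  # dams partitioned into mating groups, one group per sire
  dam_group <- split(seq_len(config$n_dams),
                     rep_len(seq_len(config$n_sires), config$n_dams))
  dam <- vapply(sire, function(s) {
    g <- dam_group[[as.character(s)]]
    g[sample.int(length(g), 1L)]
  }, integer(1))
  cluster <- rep_len(seq_len(config$n_clusters), config$n_sires)[sire]
  tibble::tibble(
    cow_id = sprintf("cow%04d", seq_len(n)),
    sire_idx = sire, dam_idx = dam, cluster = cluster,
    sire = sprintf("sire%02d", sire_idx),
    dam = sprintf("dam%04d", dam_idx)
  )
}

#' Simulate structured-population genotypes
#'
#' Generates diploid biallelic genotypes for a herd of half-sib families using
#' a haplotype-copying (mosaic) model: each chromosome is cut into LD blocks
#' (exponential lengths, mean `ld_block_mean_kb`), each block carries a small
#' pool of founder haplotypes, and every parental haplotype picks one founder
#' per block. Offspring inherit one haplotype from their sire and one from
#' their dam with free recombination at block boundaries. Within-block pairs
#' therefore show elevated r-squared while cross-block pairs are independent;
#' half-sib and full-sib pairs share elevated identity-by-state. Cluster
#' divergence, when enabled, skews founder-sampling weights per relatedness
#' cluster.
#'
#' @param config A [sim_config()].
#' @return A list with `geno` (a [geno_matrix()]), `pedigree` (tibble with
#'   `cow_id`, `sire`, `dam`, `cluster`) and `blocks` (per-variant block ids,
#'   used by tests).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ped <- sim_pedigree(config)
  n <- config$n_individuals
  chroms <- as.character(seq_len(config$n_chromosomes))
  if (config$include_x) chroms <- c(chroms, "X")
  m_chr <- config$variants_per_chromosome

  # per-parent haplotype founder choices are drawn block-by-block below
  n_par_hap <- 2L * (config$n_sires + config$n_dams)
  sire_h <- cbind(2L * ped$sire_idx - 1L, 2L * ped$sire_idx)
  dam_h <- 2L * config$n_sires + cbind(2L * ped$dam_idx - 1L, 2L * ped$dam_idx)
  par_cluster <- integer(n_par_hap)
  par_cluster[seq_len(2L * config$n_sires)] <-
    rep(rep_len(seq_len(config$n_clusters), config$n_sires), each = 2L)
  dam_cl <- rep_len(seq_len(config$n_clusters),
                    config$n_sires)[rep_len(seq_len(config$n_sires), config$n_dams)]
  par_cluster[(2L * config$n_sires + 1L):n_par_hap] <- rep(dam_cl, each = 2L)

  K <- config$n_founder_haplotypes
  all_dos <- vector("list", length(chroms))
  all_var <- vector("list", length(chroms))
  all_blk <- vector("list", length(chroms))
  vid0 <- 0L
  for (ci in seq_along(chroms)) {
    pos <- sort(sample.int(config$chromosome_length_bp, m_chr))
    # exponential block boundaries
    mean_bp <- config$ld_block_mean_kb * 1000
    cuts <- cumsum(stats::rexp(ceiling(config$chromosome_length_bp / mean_bp) + 25,
                               rate = 1 / mean_bp))
    cuts <- cuts[cuts < config$chromosome_length_bp]
    block <- findInterval(pos, cuts) + 1L
    p <- draw_maf(m_chr, config$maf_spectrum)
    dos <- matrix(0L, n, m_chr)
    for (b in unique(block)) {
      idx <- which(block == b)
      # ancestral haplotypes carry the block's standing variation; founders
      # copy a random ancestor with rare per-site mutation, so within-block
      # variant pairs co-segregate (strong r2) while blocks stay independent
      A <- config$n_ancestral_haplotypes
      anc <- matrix(stats::rbinom(A * length(idx), 1L, rep(p[idx], each = A)),
                    A, length(idx))
      # ancestor usage is Dirichlet(1), so ancestral segregating sites span
      # the whole frequency spectrum rather than clustering at k/A
      w_anc <- stats::rgamma(A, 1)
      w_anc <- w_anc / sum(w_anc)
      founders <- anc[sample.int(A, K, replace = TRUE, prob = w_anc), ,
                      drop = FALSE]
      if (config$mutation_rate > 0) {
        flips <- stats::runif(length(founders)) < config$mutation_rate
        founders[flips] <- 1L - founders[flips]
      }
      # cluster-specific founder-sampling weights
      if (config$cluster_divergence > 0) {
        alpha <- (1 - config$cluster_divergence) / config$cluster_divergence
        w <- matrix(stats::rgamma(config$n_clusters * K, shape = alpha), config$n_clusters, K)
        w <- w / rowSums(w)
      } else {
        w <- matrix(1 / K, config$n_clusters, K)
      }
      # each parental haplotype copies one founder in this block
      par_choice <- integer(n_par_hap)
      for (cl in seq_len(config$n_clusters)) {
        hsel <- which(par_cluster == cl)
        if (length(hsel) > 0) {
          par_choice[hsel] <- sample.int(K, length(hsel), replace = TRUE,
                                         prob = w[cl, ])
        }
      }
      # offspring: pick one of the two sire haplotypes and one of the two dam
      # haplotypes, independently per block (free recombination across blocks)
      s_pick <- sire_h[cbind(seq_len(n), sample.int(2L, n, replace = TRUE))]
      d_pick <- dam_h[cbind(seq_len(n), sample.int(2L, n, replace = TRUE))]
      dos[, idx] <- founders[par_choice[s_pick], , drop = FALSE] +
        founders[par_choice[d_pick], , drop = FALSE]
    }
    if (config$missing_rate > 0) {
      miss <- stats::runif(length(dos)) < config$missing_rate
      dos[miss] <- NA_integer_
    }
    ids <- sprintf("var%06d", vid0 + seq_len(m_chr))
    vid0 <- vid0 + m_chr
    all_dos[[ci]] <- dos
    all_blk[[ci]] <- paste0(chroms[ci], "_", block)
    all_var[[ci]] <- tibble::tibble(variant_id = ids, chrom = chroms[ci],
                                    pos = pos, ref = "A", alt = "B")
  }
  dosage <- do.call(cbind, all_dos)
  rownames(dosage) <- ped$cow_id
  variants <- dplyr::bind_rows(all_var)
  list(geno = geno_matrix(dosage, variants),
       pedigree = ped[, c("cow_id", "sire", "dam", "cluster")],
       blocks = unlist(all_blk))
}

# exact-variance scaling: center, rescale to sample variance v, and (optionally)
# orthogonalise against g first so realized h2 is exact
scale_to_var <- function(x, v) {
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s < 1e-12) return(x)
  x * sqrt(v) / s
}

#' Simulate multi-lactation milk phenotypes with known truth
#'
#' Builds 305-day lactation records (milk, fat and protein yield in kg) for
#' three lactations on top of simulated genotypes. Each yield trait gets a
#' genetic value = planted QTL effects + a polygenic term from background
#' markers, rescaled so the realized narrow-sense heritability matches the
#' configured h2 exactly; lactation records share the genetic value (scaled per
#' lactation) and draw independent residuals, so cross-lactation trait
#' correlations are ~h2. Genetic and residual deviations are correlated across
#' the three yields, reproducing the high within-lactation yield correlations
#' seen in milk recording data. Covariates (farm, birth year/season, calving
#' year/season, age at first calving) receive random level effects of the
#' configured magnitudes.
#'
#' @param sim Result of [simulate_genotypes()] (list with `geno`, `pedigree`).
#' @param config The same [sim_config()] used to generate the genotypes.
#' @return A list with `records` (lactation-record tibble: one row per cow and
#'   lactation with yields, DIM and covariates) and `truth` (a `sim_truth`
#'   list: `causal` tibble of planted variants with realized effects,
#'   `clusters` per-cow labels, `variance_components` per trait, and the
#'   per-cow genetic values `genetic_values`).
#' @export
simulate_phenotypes <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- sim$geno
  ped <- sim$pedigree
  n <- nrow(geno$dosage)
  set.seed(config$seed + 1000003L)
  traits <- names(config$h2)

  # map planted QTL to nearest simulated variant
  causal <- NULL
  if (!is.null(config$qtl_spec) && nrow(config$qtl_spec) > 0) {
    causal <- config$qtl_spec |>
      dplyr::rowwise() |>
      dplyr::mutate(variant_id = {
        cand <- geno$variants[geno$variants$chrom == as.character(.data$chrom), ]
        if (nrow(cand) == 0) {
          stop("specification error: no simulated variants on chromosome ", .data$chrom)
        }
        cand$variant_id[which.min(abs(cand$pos - .data$pos))]
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(pos = geno$variants$pos[match(.data$variant_id, geno$variants$variant_id)])
  }

  # mean-imputed dosage for genetic-value construction
  Z <- geno$dosage
  if (anyNA(Z)) {
    mu <- colMeans(Z, na.rm = TRUE)
    idx <- which(is.na(Z))
    Z[idx] <- mu[(idx - 1L) %/% nrow(Z) + 1L]
  }

  # correlated polygenic effects across yields: shared + trait-specific markers
  r_g <- 0.8
  # background markers stay >= 1 Mb away from planted QTL so local LD does
  # not confound the planted allele-substitution effects
  bg_pool <- seq_len(ncol(Z))
  if (!is.null(causal)) {
    near <- rep(FALSE, ncol(Z))
    for (r in seq_len(nrow(causal))) {
      near <- near | (geno$variants$chrom == as.character(causal$chrom[r]) &
                        abs(geno$variants$pos - causal$pos[r]) <= 1e6)
    }
    bg_pool <- bg_pool[!near]
  }
  bg <- sample(bg_pool, min(config$n_background, length(bg_pool)))
  a_common <- stats::rnorm(length(bg))
  gv_common <- as.vector(Z[, bg, drop = FALSE] %*% a_common)

  gvalues <- matrix(0, n, length(traits), dimnames = list(ped$cow_id, traits))
  vc <- vector("list", length(traits))
  resid_list <- vector("list", length(traits))
  r_e <- 0.8
  e_common <- matrix(stats::rnorm(n * 3L), n, 3L)
  for (t in seq_along(traits)) {
    tr <- traits[t]
    sdP <- config$trait_sd[[tr]]
    h2 <- config$h2[[tr]]
    var_g <- h2 * sdP^2
    # planted QTL contribution in trait units
    g_qtl <- numeric(n)
    if (!is.null(causal)) {
      rows <- which(causal$trait == tr)
      for (r in rows) {
        g_qtl <- g_qtl + causal$effect[r] * Z[, causal$variant_id[r]]
      }
    }
    v_qtl <- stats::var(g_qtl)
    if (v_qtl >= var_g) {
      stop("specification error: planted QTL variance for ", tr,
           " exceeds h2 * trait variance")
    }
    a_spec <- stats::rnorm(length(bg))
    gv_spec <- as.vector(Z[, bg, drop = FALSE] %*% a_spec)
    unit_scale <- function(x) {
      s <- stats::sd(x)
      if (is.na(s) || s < 1e-12) return(rep(0, length(x)))
      (x - mean(x)) / s
    }
    poly <- sqrt(r_g) * unit_scale(gv_common) + sqrt(1 - r_g) * unit_scale(gv_spec)
    if (v_qtl > 0) {
      # orthogonalise against the QTL part so genetic variance adds exactly
      gq <- g_qtl - mean(g_qtl)
      poly <- poly - gq * sum(poly * gq) / sum(gq^2)
    }
    poly <- scale_to_var(poly, var_g - v_qtl)
    gv <- g_qtl - mean(g_qtl) + poly
    # residuals per lactation, correlated across traits, orthogonalised
    # against gv then rescaled => realized h2 is exact
    var_e <- (1 - h2) * sdP^2
    e_spec <- matrix(stats::rnorm(n * 3L), n, 3L)
    e <- sqrt(r_e) * e_common + sqrt(1 - r_e) * e_spec
    gv2 <- sum(gv^2)
    e <- apply(e, 2, function(col) {
      col <- col - mean(col)
      if (gv2 > 0) col <- col - gv * sum(col * gv) / gv2
      scale_to_var(col, var_e)
    })
    gvalues[, t] <- gv
    resid_list[[t]] <- e
    vc[[t]] <- tibble::tibble(trait = tr, sigma_g2 = var_g,
                              sigma_e2 = var_e, h2 = var_g / (var_g + var_e))
  }

  # covariate layout
  csd <- config$covariate_sd
  farm <- sprintf("farm%d", sample.int(config$n_farms, n, replace = TRUE))
  birth_year <- 2007L + sample.int(config$birth_years, n, replace = TRUE)
  birth_season <- sample(c("winter", "spring", "summer", "autumn"), n, replace = TRUE)
  afc <- as.integer(round(stats::rnorm(n, 790, 60)))
  eff <- function(levels, sd_frac, sdP) {
    u <- sort(unique(levels))
    e <- stats::setNames(stats::rnorm(length(u), 0, sd_frac * sdP), u)
    unname(e[as.character(levels)])
  }
  cl_eff <- if (config$cluster_effect_sd > 0) {
    stats::setNames(stats::rnorm(config$n_clusters), seq_len(config$n_clusters))
  } else {
    stats::setNames(numeric(config$n_clusters), seq_len(config$n_clusters))
  }

  recs <- vector("list", 3L)
  for (la in 1:3) {
    present <- stats::runif(n) < config$lactation_presence[la]
    calving_year <- birth_year + 1L + la
    calving_season <- sample(c("winter", "spring", "summer", "autumn"), n, replace = TRUE)
    dim_days <- pmin(pmax(as.integer(round(stats::rnorm(n, 330, 45))), 120L), 550L)
    row <- tibble::tibble(
      cow_id = ped$cow_id, lactation = la, dim = dim_days,
      farm = farm, sire = ped$sire,
      birth_year = birth_year, birth_season = birth_season,
      calving_year = calving_year, calving_season = calving_season,
      age_first_calving = afc
    )
    for (t in seq_along(traits)) {
      tr <- traits[t]
      sdP <- config$trait_sd[[tr]]
      base <- config$trait_mean[[tr]] * config$lactation_scale[la]
      y <- base +
        eff(farm, csd[["farm"]], sdP) +
        eff(birth_year, csd[["birth_year"]], sdP) +
        eff(birth_season, csd[["birth_season"]], sdP) +
        eff(calving_year, csd[["calving_year"]], sdP) +
        eff(calving_season, csd[["calving_season"]], sdP) +
        csd[["age_first_calving"]] * sdP * (afc - mean(afc)) +
        config$cluster_effect_sd * sdP * cl_eff[as.character(ped$cluster)] +
        gvalues[, t] + resid_list[[t]][, la]
      row[[tr]] <- pmax(y, 1)
    }
    recs[[la]] <- row[present, ]
  }
  records <- dplyr::bind_rows(recs) |> dplyr::arrange(.data$cow_id, .data$lactation)

  truth <- structure(list(
    causal = causal,
    clusters = tibble::tibble(cow_id = ped$cow_id, cluster = ped$cluster),
    variance_components = dplyr::bind_rows(vc),
    genetic_values = tibble::as_tibble(gvalues) |>
      dplyr::mutate(cow_id = ped$cow_id, .before = 1)
  ), class = "sim_truth")
  list(records = records, truth = truth)
}

#' One-call simulation of a complete study data set
#'
#' Convenience wrapper running [simulate_genotypes()] and
#' [simulate_phenotypes()].
#'
#' @inheritParams simulate_genotypes
#' @return List with `geno`, `pedigree`, `records`, `truth`.
#' @export
simulate_herd <- function(config) {
  g <- simulate_genotypes(config)
  p <- simulate_phenotypes(g, config)
  list(geno = g$geno, pedigree = g$pedigree, records = p$records, truth = p$truth)
}

#' Read a simulator configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [sim_config()];
#'   `qtl_spec` may be a list of `{chrom, pos, trait, effect}` entries.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$qtl_spec)) {
    raw$qtl_spec <- dplyr::bind_rows(lapply(raw$qtl_spec, tibble::as_tibble))
  }
  for (nm in c("h2", "trait_mean", "trait_sd", "covariate_sd")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}
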
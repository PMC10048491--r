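test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(n_individuals = 0), "non-positive")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(h2 = c(milk_kg = 1.2, fat_kg = 0.3, protein_kg = 0.3)),
               "h2")
  expect_error(sim_config(qtl_spec = data.frame(chrom = "1", pos = 9e9,
                                                trait = "milk_kg", effect = 1)),
               "position")
  expect_error(sim_config(qtl_spec = data.frame(chrom = "1", pos = 100,
                                                trait = "nope", effect = 1)),
               "traits")
})

test_that("the same seed reproduces genotypes, phenotypes and files bit-identically", {
  cfg <- sim_config(n_individuals = 50, n_sires = 5, n_chromosomes = 1,
                    variants_per_chromosome = 200, seed = 9)
  a <- simulate_herd(cfg)
  b <- simulate_herd(cfg)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$causal, b$truth$causal)
  fa <- tempfile(fileext = ".vcf"); fb <- tempfile(fileext = ".vcf")
  write_vcf(a$geno, fa); write_vcf(b$geno, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("missingness matches the configured rate and zero means zero", {
  cfg0 <- sim_config(n_individuals = 100, n_sires = 10, n_chromosomes = 1,
                     variants_per_chromosome = 400, missing_rate = 0, seed = 2)
  expect_false(anyNA(simulate_genotypes(cfg0)$geno$dosage))
  cfg5 <- sim_config(n_individuals = 100, n_sires = 10, n_chromosomes = 1,
                     variants_per_chromosome = 400, missing_rate = 0.05, seed = 2)
  rate <- mean(is.na(simulate_genotypes(cfg5)$geno$dosage))
  expect_lt(abs(rate - 0.05), 0.01)
})

test_that("LD is block-structured: within-block r2 exceeds cross-block r2", {
  cfg <- sim_config(n_individuals = 300, n_sires = 300, n_dams = 300,
                    n_chromosomes = 1, variants_per_chromosome = 600,
                    ld_block_mean_kb = 500, missing_rate = 0,
                    n_founder_haplotypes = 8, seed = 21)
  sim <- simulate_genotypes(cfg)
  d <- sim$geno$dosage * 1
  blocks <- sim$blocks
  keep <- apply(d, 2, sd) > 0
  r2 <- suppressWarnings(cor(d[, keep]))^2
  blk <- blocks[keep]
  same <- outer(blk, blk, "==") & upper.tri(r2)
  diff <- (!outer(blk, blk, "==")) & upper.tri(r2)
  expect_gt(mean(r2[same], na.rm = TRUE), 5 * mean(r2[diff], na.rm = TRUE))
  expect_gt(mean(r2[same], na.rm = TRUE), 0.1)
  expect_lt(mean(r2[diff], na.rm = TRUE), 0.05)
})

test_that("tiny blocks with unrelated samples give negligible adjacent-pair r2", {
  # Monte-Carlo under independence: block length ~ 0 makes every variant its
  # own block, so adjacent pairs are independent draws
  cfg <- sim_config(n_individuals = 2000, n_sires = 2000, n_dams = 2000,
                    n_chromosomes = 1, variants_per_chromosome = 300,
                    ld_block_mean_kb = 0.001, missing_rate = 0, seed = 31)
  sim <- simulate_genotypes(cfg)
  d <- sim$geno$dosage * 1
  r2adj <- vapply(seq_len(ncol(d) - 1), function(j) {
    suppressWarnings(cor(d[, j], d[, j + 1]))^2
  }, numeric(1))
  expect_lt(median(r2adj, na.rm = TRUE), 0.05)
})

test_that("family members share elevated identity-by-state", {
  cfg <- sim_config(n_individuals = 120, n_sires = 6, n_dams = 12,
                    n_chromosomes = 1, variants_per_chromosome = 800,
                    missing_rate = 0, seed = 13)
  sim <- simulate_genotypes(cfg)
  ibs <- ibs_matrix(sim$geno)$score
  ped <- sim$pedigree
  same_parents <- outer(ped$sire, ped$sire, "==") &
    outer(ped$dam, ped$dam, "==") & upper.tri(ibs)
  unrel <- (!outer(ped$sire, ped$sire, "==")) & upper.tri(ibs)
  # full sibs (brute-force IBS over the emitted matrix) vs population mean
  expect_gt(mean(ibs[same_parents]), mean(ibs[upper.tri(ibs)]))
  expect_gt(mean(ibs[same_parents]), mean(ibs[unrel]))
})

test_that("planted causal variants exist and realized heritability is exact", {
  cfg <- sim_config(n_individuals = 500, n_sires = 15, n_chromosomes = 2,
                    variants_per_chromosome = 600, missing_rate = 0,
                    qtl_spec = data.frame(chrom = c("1", "2"),
                                          pos = c(1e7, 2e7),
                                          trait = c("milk_kg", "fat_kg"),
                                          effect = c(300, 15)),
                    lactation_presence = c(1, 1, 1), seed = 17)
  sim <- simulate_herd(cfg)
  truth <- sim$truth
  expect_true(all(truth$causal$variant_id %in% sim$geno$variants$variant_id))
  # configured variance components reproduce h2 to numerical precision
  vc <- truth$variance_components
  expect_equal(vc$h2, unname(cfg$h2[vc$trait]), tolerance = 1e-6)
  # realized: regression-free check on the emitted genetic values
  gv <- truth$genetic_values$milk_kg
  expect_equal(var(gv), 0.40 * 900^2, tolerance = 1e-6)
})

test_that("a pure-noise trait yields null dosage effects", {
  cfg <- sim_config(n_individuals = 300, n_sires = 300, n_dams = 300,
                    n_chromosomes = 1, variants_per_chromosome = 300,
                    h2 = c(milk_kg = 1e-4, fat_kg = 1e-4, protein_kg = 1e-4),
                    covariate_sd = c(farm = 0, birth_year = 0, birth_season = 0,
                                     calving_year = 0, calving_season = 0,
                                     age_first_calving = 0),
                    missing_rate = 0, lactation_presence = c(1, 0, 0),
                    seed = 23)
  sim <- simulate_herd(cfg)
  y <- sim$records$milk_kg[match(rownames(sim$geno$dosage), sim$records$cow_id)]
  betas <- vapply(seq_len(100), function(j) {
    fit_variant(y, NULL, sim$geno$dosage[, j])$beta
  }, numeric(1))
  # standardized mean effect across variants is ~0
  expect_lt(abs(mean(betas / sd(y), na.rm = TRUE)), 0.05)
})

test_that("a single strong causal variant is recovered in the noiseless limit", {
  cfg <- sim_config(n_individuals = 400, n_sires = 40, n_chromosomes = 1,
                    variants_per_chromosome = 300, missing_rate = 0,
                    h2 = c(milk_kg = 0.999, fat_kg = 0.3, protein_kg = 0.3),
                    covariate_sd = c(farm = 0, birth_year = 0, birth_season = 0,
                                     calving_year = 0, calving_season = 0,
                                     age_first_calving = 0),
                    n_background = 1,
                    lactation_presence = c(1, 0, 0), seed = 29)
  geno0 <- simulate_genotypes(cfg)$geno
  maf <- apply(geno0$dosage, 2, compute_maf)
  target <- geno0$variants[which.min(abs(maf - 0.35)), ]
  cfg$qtl_spec <- tibble::tibble(chrom = "1", pos = target$pos,
                                 trait = "milk_kg", effect = 899)
  sim <- simulate_herd(cfg)
  y <- sim$records$milk_kg[match(rownames(sim$geno$dosage), sim$records$cow_id)]
  fit <- fit_variant(y, NULL, sim$geno$dosage[, sim$truth$causal$variant_id])
  expect_equal(fit$beta, 899, tolerance = 0.05)
  expect_lt(fit$p, 1e-30)
})

test_that("missing causal chromosome raises a specification error", {
  cfg <- sim_config(n_individuals = 50, n_sires = 5, n_chromosomes = 1,
                    variants_per_chromosome = 100,
                    qtl_spec = data.frame(chrom = "1", pos = 100,
                                          trait = "milk_kg", effect = 1),
                    seed = 3)
  sim <- simulate_genotypes(cfg)
  cfg$qtl_spec$chrom <- "7"   # tamper after generation
  expect_error(simulate_phenotypes(sim, cfg), "specification error")
})

test_that("structure-confounded phenotypes inflate lambda; the cluster covariate deflates it", {
  lam <- matrix(NA_real_, 4, 2)
  for (s in 1:4) {
    cfg <- sim_config(n_individuals = 250, n_sires = 10, n_chromosomes = 1,
                      variants_per_chromosome = 1200, missing_rate = 0,
                      n_clusters = 2, cluster_divergence = 0.5,
                      cluster_effect_sd = 1.5, lactation_presence = c(1, 0, 0),
                      seed = 7000 + s)
    sim <- simulate_herd(cfg)
    ph <- build_phenotypes(sim$records, min_per_level = 5)
    qc <- filter_variants(sim$geno)
    no_ps <- tibble::tibble(cow_id = sim$pedigree$cow_id, cluster = 1L)
    gw0 <- suppressWarnings(   # constant cluster column -> no ps adjustment
      run_gwas(ph, qc$geno, no_ps, traits = "milk_kg", lactations = "LA1"))
    gw1 <- run_gwas(ph, qc$geno, sim$truth$clusters, traits = "milk_kg",
                    lactations = "LA1")
    lam[s, ] <- c(inflation_factor(gw0$p_raw), inflation_factor(gw1$p_raw))
  }
  expect_gt(mean(lam[, 1]), 1.2)           # confounding inflates
  expect_true(all(lam[, 2] < lam[, 1]))    # ps covariate reduces inflation
})
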
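test_that("LD statistics: identical, independent and hand-computed cases", {
  set.seed(14)
  g <- rbinom(500, 2, 0.3)
  same <- ld_pair(g, g)
  expect_equal(same$r2, 1)
  expect_equal(same$dprime, 1)
  # independent variants: median r2 over pairs is tiny at n = 1e4
  n <- 1e4
  r2s <- replicate(30, {
    ld_pair(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))$r2
  })
  expect_lt(median(r2s), 0.001)
  # monomorphic input
  expect_true(is.na(ld_pair(rep(1L, 10), rbinom(10, 2, 0.5))$r2))
})

test_that("D-prime matches the exact haplotype-table oracle on phased toys", {
  # build genotypes from known haplotype counts: 60 x AB, 20 x Ab, 10 x aB,
  # 10 x ab (freqs .6/.2/.1/.1); pair haplotypes deterministically so no
  # double heterozygotes are ambiguous in truth, then compare EM to the exact
  # haplotype-frequency D'
  haps <- rbind(matrix(rep(c(1, 1), 60), ncol = 2, byrow = TRUE),
                matrix(rep(c(1, 0), 20), ncol = 2, byrow = TRUE),
                matrix(rep(c(0, 1), 10), ncol = 2, byrow = TRUE),
                matrix(rep(c(0, 0), 10), ncol = 2, byrow = TRUE))
  set.seed(15)
  idx <- sample(nrow(haps))
  h1 <- haps[idx[1:50], ]; h2 <- haps[idx[51:100], ]
  g1 <- h1[, 1] + h2[, 1]
  g2 <- h1[, 2] + h2[, 2]
  # exact-oracle 1: one-parameter profile likelihood over pAB (marginal
  # allele frequencies are fixed by the genotype table), maximised by grid +
  # optimize — fully independent of the EM recursion
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  loglik <- function(pAB) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    h <- c(pAB, pAb, paB, pab)
    if (any(h < 0)) return(-Inf)
    pr <- matrix(0, 3, 3)  # P(genotype pair) from haplotype pairs
    pr[3, 3] <- pAB^2; pr[3, 2] <- 2 * pAB * pAb; pr[3, 1] <- pAb^2
    pr[2, 3] <- 2 * pAB * paB; pr[2, 1] <- 2 * pAb * pab
    pr[2, 2] <- 2 * (pAB * pab + pAb * paB)
    pr[1, 3] <- paB^2; pr[1, 2] <- 2 * paB * pab; pr[1, 1] <- pab^2
    sum(tab * log(pmax(pr, 1e-300)))
  }
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  opt <- optimize(loglik, c(lo, hi), maximum = TRUE, tol = 1e-10)
  D <- opt$maximum - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  oracle_mle <- abs(D) / dmax
  est <- ld_pair(g1, g2)$dprime
  expect_equal(est, oracle_mle, tolerance = 1e-4)
  # exact-oracle 2: realized haplotype counts of the sampled haplotypes give
  # a phase-aware D' the phase-free MLE should approximate
  hf <- table(factor(paste0(c(h1[, 1], h2[, 1]), c(h1[, 2], h2[, 2])),
                     levels = c("11", "10", "01", "00"))) / 100
  Dt <- hf[["11"]] - (hf[["11"]] + hf[["10"]]) * (hf[["11"]] + hf[["01"]])
  expect_equal(sign(D), sign(Dt))
  expect_lt(abs(est - abs(Dt) / dmax), 0.2)
})

test_that("pruning keeps independent variants and removes exact duplicates", {
  g <- random_geno(300, runif(40, 0.2, 0.5), seed = 16)
  g$variants$maf <- apply(g$dosage, 2, compute_maf)
  out <- prune_ld(g, window = 20, step = 5, r2_max = 0.6)
  expect_equal(out$M, 40)            # mutually independent: nothing removed
  # duplicate a column: exactly one copy of the pair is removed
  d <- cbind(g$dosage, g$dosage[, 7])
  g2 <- toy_geno(d)
  g2$variants$maf <- apply(d, 2, compute_maf)
  out2 <- prune_ld(g2, window = 50, step = 10, r2_max = 0.6)
  expect_equal(out2$M, 40)
  expect_true(xor("v007" %in% out2$kept,
                  g2$variants$variant_id[41] %in% out2$kept))
})

test_that("pruning equals the exhaustive within-window oracle on a 50-variant fixture", {
  # 5 planted LD blocks of 10 via shared latent haplotypes
  set.seed(17)
  n <- 200
  d <- matrix(0L, n, 50)
  for (b in 0:4) {
    base <- rbinom(n, 2, runif(1, 0.2, 0.5))
    for (j in 1:10) {
      flip <- runif(n) < 0.15
      col <- ifelse(flip, rbinom(n, 2, 0.3), base)
      d[, b * 10 + j] <- as.integer(col)
    }
  }
  g <- toy_geno(d)
  g$variants$maf <- apply(d, 2, compute_maf)
  window <- 25L; step <- 10L; r2_max <- 0.6
  # independent oracle: same removal rule, literal loops over windows/pairs
  maf <- g$variants$maf
  keep <- rep(TRUE, 50)
  s <- 1L
  repeat {
    win <- (s:min(s + window - 1L, 50L))
    win <- win[keep[win]]
    if (length(win) >= 2) {
      for (i in seq_along(win)) {
        for (j in seq_along(win)) {
          if (j <= i) next
          a <- win[i]; b <- win[j]
          if (!keep[a] || !keep[b]) next
          r2 <- cor(d[, a], d[, b])^2
          if (is.na(r2) || r2 <= r2_max) next
          if (maf[b] < maf[a] || maf[b] == maf[a]) keep[b] <- FALSE
          else keep[a] <- FALSE
        }
      }
    }
    if (s + window - 1L >= 50L) break
    s <- s + step
  }
  out <- prune_ld(g, window = window, step = step, r2_max = r2_max)
  expect_setequal(out$kept, g$variants$variant_id[keep])
})

test_that("pruned count is invariant to individual (row) permutation", {
  g <- small_sim()$geno[, 1:400]
  g <- filter_variants(g)$geno
  out1 <- prune_ld(g, window = 50, step = 10)
  set.seed(18)
  perm <- sample(nrow(g$dosage))
  g2 <- g
  g2$dosage <- g$dosage[perm, ]
  out2 <- prune_ld(g2, window = 50, step = 10)
  expect_identical(out1$kept, out2$kept)
})

test_that("Bonferroni thresholds reproduce the reported genome-wide cutoffs", {
  th <- bonferroni_thresholds(642791)
  expect_equal(th$threshold_1dp[th$alpha == 0.01], 7.8)
  expect_equal(th$threshold_1dp[th$alpha == 0.05], 7.1)
  expect_equal(th$threshold_1dp[th$alpha == 0.1], 6.8)
  expect_equal(bonferroni_thresholds(1, alphas = 1)$threshold, 0)
  # strictly decreasing in alpha, increasing in M
  expect_true(all(diff(th$threshold) < 0))
  expect_true(all(bonferroni_thresholds(1e6)$threshold > th$threshold))
  expect_error(bonferroni_thresholds(0), "positive")
})

test_that("QTL definition follows the two-stage chaining rules", {
  mk <- function(pos, nlp, trait = "milk_kg", chrom = "1") {
    tibble::tibble(variant_id = sprintf("%s_%d", chrom, pos), chrom = chrom,
                   pos = pos, ma = "B", maf = 0.2, beta = 1, se = 0.1,
                   t = 10, p_raw = 10^-nlp, trait = trait, lactation = "LA1",
                   n = 100L, p_gc = 10^-nlp, neg_log10_p = nlp)
  }
  # two suggestive variants 1 kb apart: group of 2 < 3 -> discarded
  r2 <- dplyr::bind_rows(mk(1e6, 8), mk(1e6 + 1000, 7.5))
  expect_equal(nrow(define_qtl(r2, cutoff = 6.8)), 0)
  # three variants at 1.0 / 1.4 / 1.8 Mb, top in the middle: hand-traced core
  r3 <- dplyr::bind_rows(mk(1.0e6, 7), mk(1.4e6, 9), mk(1.8e6, 7.2))
  q3 <- define_qtl(r3, cutoff = 6.8)
  expect_equal(nrow(q3), 1)
  expect_equal(q3$core_start, 1.0e6)
  expect_equal(q3$core_stop, 1.8e6)
  expect_equal(q3$display_start, 0.9e6)
  expect_equal(q3$display_stop, 1.9e6)
  expect_equal(q3$top_variant_id, "1_1400000")
  expect_equal(q3$n_variants, 3L)
  # 3.0 Mb gap exceeds the 2.5 Mb chaining distance: two coarse groups
  far <- dplyr::bind_rows(mk(1.0e6, 7), mk(1.1e6, 7), mk(1.2e6, 7),
                          mk(4.2e6, 7), mk(4.3e6, 7), mk(4.4e6, 7))
  qf <- define_qtl(far, cutoff = 6.8)
  expect_equal(length(unique(qf$group)), 2)
  # stage 2: a variant 600 kb beyond the growing bounds is NOT chained even
  # though it belongs to the same 2.5 Mb coarse group
  rgap <- dplyr::bind_rows(mk(1.0e6, 7), mk(1.2e6, 9), mk(1.4e6, 7),
                           mk(2.0e6, 7))
  qg <- define_qtl(rgap, cutoff = 6.8)
  expect_equal(qg$core_start, 1.0e6)
  expect_equal(qg$core_stop, 1.4e6)
  # no suggestive variants: empty result, not an error
  expect_equal(nrow(define_qtl(mk(1e6, 3), cutoff = 6.8)), 0)
})

test_that("stage-2 growth stops at gaps over 500 kb and flanks floor at 1", {
  mk <- function(pos, nlp, trait = "milk_kg") {
    tibble::tibble(variant_id = paste0("v", pos), chrom = "1", pos = pos,
                   ma = "B", maf = 0.2, beta = 1, se = 0.1, t = 10,
                   p_raw = 10^-nlp, trait = trait, lactation = "LA1",
                   n = 100L, p_gc = 10^-nlp, neg_log10_p = nlp)
  }
  # variants at 1.0, 1.2 (top), 1.9 Mb: 1.9 is 700 kb from the bounds, within
  # the 2.5 Mb coarse group but not chained into the stage-2 region
  r <- dplyr::bind_rows(mk(1.0e6, 7), mk(1.2e6, 9), mk(1.9e6, 7))
  q <- define_qtl(r, cutoff = 6.8)
  expect_equal(q$core_start, 1.0e6)
  expect_equal(q$core_stop, 1.2e6)
  expect_equal(q$n_variants, 2L)
  # near-origin region: display start floored at 1
  r0 <- dplyr::bind_rows(mk(5e4, 7), mk(6e4, 8), mk(7e4, 7))
  q0 <- define_qtl(r0, cutoff = 6.8)
  expect_equal(q0$display_start, 1)
  # every member of an emitted region satisfies the cutoff by construction
  expect_true(all(q0$top_neg_log10_p >= 6.8))
})

test_that("per-trait regions within one coarse group are separated and mergeable", {
  mk <- function(pos, nlp, trait) {
    tibble::tibble(variant_id = paste0("v", pos, trait), chrom = "1",
                   pos = pos, ma = "B", maf = 0.2, beta = 1, se = 0.1, t = 10,
                   p_raw = 10^-nlp, trait = trait, lactation = "LA1",
                   n = 100L, p_gc = 10^-nlp, neg_log10_p = nlp)
  }
  r <- dplyr::bind_rows(mk(1.0e6, 7, "milk_kg"), mk(1.1e6, 9, "milk_kg"),
                        mk(1.3e6, 8, "fat_kg"), mk(1.35e6, 7, "fat_kg"))
  q <- define_qtl(r, cutoff = 6.8)
  expect_setequal(q$trait, c("milk_kg", "fat_kg"))
  m <- merge_qtl_regions(q)
  expect_equal(nrow(m), 1)
  expect_equal(m$core_start, 1.0e6)
  expect_equal(m$core_stop, 1.35e6)
  expect_equal(m$n_traits, 2L)
  expect_equal(m$top_variant_id, "v1100000milk_kg")
})
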
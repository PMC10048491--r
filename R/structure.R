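#' Pairwise identity-by-state matrix
#'
#' For each pair of individuals the mean, over variants non-missing in both,
#' of `2 - |d_i - d_j|` where `d` is the dosage. Scores lie in \[0, 2\] with 2
#' on the diagonal; the associated distance is `1 - score / 2`.
#'
#' Implemented with indicator-matrix cross-products so the full matrix for a
#' ~2000-cow herd is a handful of BLAS calls, not an n-squared loop.
#'
#' @param geno A [geno_matrix()].
#' @return A list of class `ibs_matrix`: `score` (n x n), `distance`,
#'   `n_shared` (non-missing overlap counts).
#' @export
ibs_matrix <- function(geno) {
  d <- geno$dosage
  n <- nrow(d)
  if (n < 2) stop("need at least 2 individuals")
  A0 <- (!is.na(d) & d == 0L) + 0
  A1 <- (!is.na(d) & d == 1L) + 0
  A2 <- (!is.na(d) & d == 2L) + 0
  M <- A0 + A1 + A2                     # non-missing indicator
  n_shared <- tcrossprod(M)
  if (any(n_shared[upper.tri(n_shared)] == 0)) {
    idx <- which(n_shared == 0 & upper.tri(n_shared), arr.ind = TRUE)[1, ]
    stop(sprintf("pair (%s, %s) shares no non-missing variants",
                 rownames(d)[idx[1]], rownames(d)[idx[2]]))
  }
  diff1 <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
    tcrossprod(A1, A2) + tcrossprod(A2, A1)
  diff2 <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  score <- 2 - (diff1 + 2 * diff2) / n_shared
  dimnames(score) <- list(rownames(d), rownames(d))
  structure(list(score = score, distance = 1 - score / 2, n_shared = n_shared),
            class = "ibs_matrix")
}

# two-sided exact binomial p-value (equal to binom.test's "likelihood" rule):
# sum of P(X = j) over all j with P(X = j) <= P(X = k) (1 + 1e-7 slack)
exact_binom_p <- function(k, n, p0) {
  if (n == 0) return(1)
  dens <- stats::dbinom(0:n, n, p0)
  sum(dens[dens <= dens[k + 1] * (1 + 1e-7)])
}

#' Pairwise population concordance (PPC) test
#'
#' Among the informative variant classes for a pair of individuals — sites
#' where both are heterozygous (IBS2-het) versus sites where they are opposite
#' homozygotes (IBS0) — panmixia predicts a 2:1 ratio regardless of allele
#' frequency. The test is a two-sided exact binomial test of the observed
#' IBS2-het count against expected proportion 2/3; small p-values indicate the
#' pair is drawn from discordant populations.
#'
#' @param g1,g2 Dosage vectors of the two individuals.
#' @return p-value in (0, 1\].
#' @export
ppc_test <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  ibs2het <- sum(g1[ok] == 1L & g2[ok] == 1L)
  ibs0 <- sum(abs(g1[ok] - g2[ok]) == 2L)
  if (ibs2het + ibs0 == 0) {
    warning("no informative sites; PPC p-value set to 1")
    return(1)
  }
  exact_binom_p(ibs2het, ibs2het + ibs0, 2 / 3)
}

#' All-pairs PPC p-values
#'
#' Vectorised version of [ppc_test()] over every pair of individuals;
#' the IBS2-het and IBS0 counts come from indicator cross-products.
#'
#' @param geno A [geno_matrix()].
#' @return Symmetric n x n matrix of p-values (diagonal 1).
#' @export
ppc_matrix <- function(geno) {
  d <- geno$dosage
  A0 <- (!is.na(d) & d == 0L) + 0
  A1 <- (!is.na(d) & d == 1L) + 0
  A2 <- (!is.na(d) & d == 2L) + 0
  het2 <- tcrossprod(A1)
  ibs0 <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  n <- nrow(d)
  p <- matrix(1, n, n, dimnames = list(rownames(d), rownames(d)))
  ut <- which(upper.tri(p), arr.ind = TRUE)
  pv <- mapply(function(i, j) {
    tot <- het2[i, j] + ibs0[i, j]
    if (tot == 0) 1 else exact_binom_p(het2[i, j], tot, 2 / 3)
  }, ut[, 1], ut[, 2])
  p[ut] <- pv
  p[cbind(ut[, 2], ut[, 1])] <- pv
  p
}

#' Relatedness clustering with a PPC constraint
#'
#' Agglomerative complete-linkage clustering on IBS distance in which two
#' groups may merge only if no cross-group pair has a PPC p-value below
#' `p_cutoff`. Merging proceeds in ascending complete-linkage distance order
#' (ties broken by the lexicographically smallest member index pair) until no
#' permissible merge remains. The resulting cluster label is the population
#' stratification covariate of the association model.
#'
#' @param ibs An [ibs_matrix()].
#' @param ppc_p Symmetric matrix of pairwise PPC p-values ([ppc_matrix()]).
#' @param p_cutoff Merges are forbidden across pairs with `p < p_cutoff`.
#' @return Tibble of class `cluster_assignment`: `cow_id`, `cluster`
#'   (integer ids contiguous from 1, numbered by smallest member index).
#' @export
cluster_ppc <- function(ibs, ppc_p, p_cutoff = 1e-5) {
  D <- ibs$distance
  n <- nrow(D)
  stopifnot(all(dim(ppc_p) == n))
  members <- as.list(seq_len(n))
  forbidden <- ppc_p < p_cutoff
  active <- rep(TRUE, n)
  # complete-linkage distance between current groups
  gd <- D
  gf <- forbidden
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    sub <- gd[idx, idx, drop = FALSE]
    okm <- !gf[idx, idx, drop = FALSE] & upper.tri(sub)
    if (!any(okm)) break
    cand <- which(okm, arr.ind = TRUE)
    dv <- sub[cand]
    best <- cand[order(dv, cand[, 1], cand[, 2])[1], ]
    a <- idx[best[1]]; b <- idx[best[2]]
    # merge b into a
    members[[a]] <- sort(c(members[[a]], members[[b]]))
    active[b] <- FALSE
    gd[a, ] <- pmax(gd[a, ], gd[b, ])
    gd[, a] <- gd[a, ]
    gf[a, ] <- gf[a, ] | gf[b, ]
    gf[, a] <- gf[a, ]
  }
  groups <- members[active]
  # number clusters by smallest member index
  ord <- order(vapply(groups, min, integer(1)))
  lab <- integer(n)
  for (k in seq_along(ord)) lab[groups[[ord[k]]]] <- k
  structure(tibble::tibble(cow_id = rownames(D), cluster = lab),
            class = c("cluster_assignment", "tbl_df", "tbl", "data.frame"))
}

#' Full stratification estimation from genotypes
#'
#' Convenience wrapper: LD pruning, IBS matrix, PPC matrix and constrained
#' clustering. Pruning matters for the concordance test: the exact binomial
#' assumes informative sites are independent, and running it on a block-LD
#' genome without thinning makes it anti-conservative (fragmenting panmictic
#' samples into spurious clusters).
#'
#' @inheritParams ibs_matrix
#' @inheritParams cluster_ppc
#' @param prune Thin variants by LD before testing (default `TRUE`).
#' @param r2_max Pruning threshold used for the thinning.
#' @return See [cluster_ppc()].
#' @export
estimate_stratification <- function(geno, p_cutoff = 1e-5, prune = TRUE,
                                    r2_max = 0.2) {
  g <- geno
  if (prune) {
    kept <- prune_ld(geno, window = 100L, step = 50L, r2_max = r2_max)$kept
    g <- geno[, kept]
  }
  cluster_ppc(ibs_matrix(g), ppc_matrix(g), p_cutoff)
}
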
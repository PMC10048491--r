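#' Single-variant fixed-effects regression
#'
#' Ordinary least squares of the trait on covariates plus the additive dosage;
#' rows with missing response, covariate or dosage are dropped listwise. The
#' reported effect is the dosage coefficient (trait units per allele copy),
#' with a two-sided p-value from the t distribution on the residual degrees of
#' freedom.
#'
#' @param y Response vector.
#' @param X Covariate design matrix including the intercept (see
#'   `build_design`), or `NULL` for intercept-only.
#' @param g Dosage vector.
#' @return Tibble row: `beta`, `se`, `t`, `p`, `n`. Monomorphic-on-subset
#'   dosages yield an all-`NA` row rather than an error.
#' @export
fit_variant <- function(y, X, g) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  ok <- !is.na(y) & !is.na(g) & stats::complete.cases(X)
  y <- y[ok]; g <- g[ok]; X <- X[ok, , drop = FALSE]
  na_row <- tibble::tibble(beta = NA_real_, se = NA_real_, t = NA_real_,
                           p = NA_real_, n = sum(ok))
  if (length(y) == 0 || stats::var(g) == 0) return(na_row)
  fit <- stats::lm.fit(cbind(X, g = g), y)
  df <- length(y) - fit$rank
  if (df < 1) return(na_row)
  coefs <- fit$coefficients
  if (is.na(coefs["g"])) return(na_row)  # dosage aliased with covariates
  rss <- sum(fit$residuals^2)
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  sigma2 <- rss / df
  se_g <- sqrt(sigma2 * XtXinv[fit$rank, fit$rank])
  tval <- coefs["g"] / se_g
  tibble::tibble(beta = unname(coefs["g"]), se = se_g, t = unname(tval),
                 p = unname(2 * stats::pt(-abs(tval), df)), n = length(y))
}

# Frisch-Waugh-Lovell batch scan: residualise y and every complete dosage
# column on X once, then each beta/t comes from two inner products. Exactly
# equal to per-variant OLS (same projection), but one BLAS pass per chunk.
fwl_scan <- function(y, X, G, chunk = 5000L) {
  qx <- qr(X)
  k <- qx$rank
  n <- length(y)
  ry <- qr.resid(qx, y)
  df <- n - k - 1L
  m <- ncol(G)
  beta <- se <- tval <- rep(NA_real_, m)
  for (s in seq(1L, m, by = chunk)) {
    j <- s:min(s + chunk - 1L, m)
    Gj <- G[, j, drop = FALSE]
    rg <- Gj - qr.fitted(qx, Gj)
    gg <- colSums(rg^2)
    gy <- as.vector(crossprod(rg, ry))
    bad <- gg <= 1e-8          # dosage constant or aliased with covariates
    gg[bad] <- NA_real_
    b <- gy / gg
    rss <- sum(ry^2) - b * gy
    s2 <- rss / df
    beta[j] <- b
    se[j] <- sqrt(s2 / gg)
    tval[j] <- b / sqrt(s2 / gg)
  }
  tibble::tibble(beta = beta, se = se, t = tval,
                 p = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Genome-wide association scan
#'
#' Per-variant fixed-effects linear regression of every trait-lactation cell
#' on minor-allele dosage plus the cell's selected fixed effects (population
#' stratification cluster always included). Cows are matched by id across
#' phenotypes, covariates and genotypes; listwise deletion is applied per
#' trait-lactation, so sample sizes differ between lactations. Complete
#' dosage columns go through a batch Frisch-Waugh-Lovell scan; variants with
#' missing calls fall back to per-variant listwise OLS — both are exact OLS.
#'
#' @param pheno A `pheno_table` from [build_phenotypes()].
#' @param geno A post-QC [geno_matrix()] (minor-allele oriented, `maf` column
#'   present).
#' @param clusters Cluster assignment tibble (`cow_id`, `cluster`).
#' @param selection Covariate-selection tibble from [select_covariates_all()],
#'   or `NULL` to include no optional effects.
#' @param traits,lactations Optional filters restricting the scan.
#' @return Tibble of class `gwas_result`: one row per (variant,
#'   trait-lactation) with `variant_id`, `chrom`, `pos`, `ma`, `maf`, `beta`,
#'   `se`, `t`, `p_raw`, `trait`, `lactation`, `n`, ordered by (chrom, pos,
#'   trait, lactation).
#' @export
run_gwas <- function(pheno, geno, clusters, selection = NULL,
                     traits = NULL, lactations = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (!"maf" %in% names(geno$variants)) {
    stop("genotypes must pass filter_variants() before association")
  }
  cells <- dplyr::distinct(pheno$values, .data$trait, .data$lactation)
  if (!is.null(traits)) cells <- dplyr::filter(cells, .data$trait %in% !!traits)
  if (!is.null(lactations)) {
    cells <- dplyr::filter(cells, .data$lactation %in% !!lactations)
  }
  orphans <- setdiff(unique(pheno$values$cow_id), rownames(geno$dosage))
  if (length(orphans) > 0) {
    stop("cows with phenotypes but no genotypes: ",
         paste(utils::head(orphans, 5), collapse = ", "),
         if (length(orphans) > 5) ", ..." else "")
  }
  out <- purrr::pmap(cells, function(trait, lactation) {
    covars <- character()
    if (!is.null(selection)) {
      covars <- selection |>
        dplyr::filter(.data$trait == !!trait, .data$lactation == !!lactation,
                      .data$included) |>
        dplyr::pull("effect")
    }
    df <- model_frame(pheno, clusters, trait, lactation, covars)
    if (nrow(df) == 0) return(NULL)
    X <- build_design(df, c("cluster", covars))
    G <- geno$dosage[df$cow_id, , drop = FALSE]
    complete <- !matrixStats_colAnyNA(G)
    res <- tibble::tibble(beta = rep(NA_real_, ncol(G)), se = NA_real_,
                          t = NA_real_, p = NA_real_, n = NA_integer_)
    if (any(complete)) {
      res[complete, ] <- fwl_scan(df$value, X, G[, complete, drop = FALSE] * 1)
    }
    if (any(!complete)) {
      res[!complete, ] <- listwise_scan(df$value, X, G[, !complete, drop = FALSE])
    }
    dplyr::bind_cols(
      geno$variants[, c("variant_id", "chrom", "pos", "ma", "maf")], res) |>
      dplyr::rename(p_raw = "p") |>
      dplyr::mutate(trait = trait, lactation = lactation)
  })
  res <- dplyr::bind_rows(out) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$trait, .data$lactation)
  class(res) <- c("gwas_result", class(res))
  res
}

matrixStats_colAnyNA <- function(m) colSums(is.na(m)) > 0

# per-variant listwise OLS for dosage columns with missing calls; exact normal
# equations per variant (k is small), no per-variant allocations beyond the
# row subset. y and X are assumed complete.
listwise_scan <- function(y, X, G) {
  m <- ncol(G)
  k <- ncol(X)
  beta <- se <- tval <- pv <- rep(NA_real_, m)
  nn <- integer(m)
  for (j in seq_len(m)) {
    g <- G[, j]
    ok <- !is.na(g)
    n_ok <- sum(ok)
    nn[j] <- n_ok
    if (n_ok <= k + 1L) next
    gs <- as.numeric(g[ok])
    if (stats::var(gs) == 0) next
    Xs <- cbind(X[ok, , drop = FALSE], gs)
    XtX <- crossprod(Xs)
    ch <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(ch)) next                     # aliased on the subset
    Xty <- crossprod(Xs, y[ok])
    bh <- backsolve(ch, forwardsolve(t(ch), Xty))
    rss <- sum((y[ok] - Xs %*% bh)^2)
    dfres <- n_ok - ncol(Xs)
    if (dfres < 1) next
    inv_last <- chol2inv(ch)[ncol(Xs), ncol(Xs)]
    beta[j] <- bh[ncol(Xs)]
    se[j] <- sqrt(rss / dfres * inv_last)
    tval[j] <- beta[j] / se[j]
    pv[j] <- 2 * stats::pt(-abs(tval[j]), dfres)
  }
  tibble::tibble(beta = beta, se = se, t = tval, p = pv, n = nn)
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`: the ratio of the
#' median association chi-square statistic to its null expectation (~0.4549).
#'
#' @param p Vector of p-values (`NA` dropped).
#' @return Scalar lambda.
#' @export
inflation_factor <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no valid p-values")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Genomic-control correction toward a target lambda
#'
#' Within each chromosome class (autosomes and X, separately) and each
#' trait-lactation, the observed inflation factor is computed; when it exceeds
#' the target, every chi-square statistic is rescaled by `target / lambda_obs`
#' and p-values recomputed, so the corrected set has `lambda = target`. When
#' the observed lambda is at or below the target, statistics are left
#' untouched — the correction never makes p-values smaller. Rescaling by a
#' constant preserves the ranking of variants within a class.
#'
#' @param results A `gwas_result` tibble (needs `p_raw`, `chrom`, `trait`,
#'   `lactation`).
#' @param target Target inflation factor (default 1.2).
#' @return The input with `p_gc` and `neg_log10_p` columns added and an
#'   `inflation` attribute: tibble of `trait`, `lactation`, `chrom_class`,
#'   `lambda_obs`, `lambda_target`, `n_variants`. Retrieve it with
#'   [inflation_report()].
#' @export
genomic_control <- function(results, target = 1.2) {
  results$chrom_class <- chrom_class(results$chrom)
  grp <- dplyr::group_by(results, .data$trait, .data$lactation,
                         .data$chrom_class)
  rep_tbl <- dplyr::summarise(
    grp, lambda_obs = inflation_factor(.data$p_raw),
    n_variants = sum(!is.na(.data$p_raw)), .groups = "drop") |>
    dplyr::mutate(lambda_target = target)
  out <- grp |>
    dplyr::mutate(p_gc = gc_rescale(.data$p_raw, target)) |>
    dplyr::ungroup() |>
    dplyr::mutate(neg_log10_p = -log10(.data$p_gc)) |>
    dplyr::select(-"chrom_class")
  class(out) <- c("gwas_result", setdiff(class(out), "gwas_result"))
  attr(out, "inflation") <- rep_tbl
  out
}

gc_rescale <- function(p, target) {
  lam <- inflation_factor(p)
  if (is.na(lam) || lam <= target) return(p)
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::pchisq(chi * target / lam, df = 1, lower.tail = FALSE)
}

#' @rdname genomic_control
#' @param x A corrected `gwas_result`.
#' @export
inflation_report <- function(x) attr(x, "inflation")

#' Pairwise t-tests between genotype groups
#'
#' For an effect-plot style comparison, the trait is adjusted for the fixed
#' effects (residuals plus the fitted genotype effect added back) and each
#' pair of dosage groups (0/1, 0/2, 1/2) is compared with a two-sided Welch
#' t-test. Pairs involving a group with fewer than 2 cows are reported `NA`.
#'
#' @param y Trait values.
#' @param X Covariate design matrix (with intercept) or `NULL`.
#' @param g Dosage vector.
#' @return Tibble: `group1`, `group2`, `n1`, `n2`, `mean1`, `mean2`, `p`.
#' @export
genotype_group_ttests <- function(y, X, g) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  ok <- !is.na(y) & !is.na(g) & stats::complete.cases(X)
  y <- y[ok]; g <- g[ok]; X <- X[ok, , drop = FALSE]
  groups <- sort(unique(g))
  if (length(groups) < 2) stop("need at least 2 genotype groups")
  # covariate-adjusted phenotype: residual of y on X plus the genotype signal
  qx <- qr(X)
  yadj <- qr.resid(qx, y) + mean(y)
  combos <- utils::combn(groups, 2)
  purrr::map(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    ya <- yadj[g == a]; yb <- yadj[g == b]
    p <- if (length(ya) < 2 || length(yb) < 2) NA_real_ else {
      stats::t.test(ya, yb)$p.value
    }
    tibble::tibble(group1 = a, group2 = b, n1 = length(ya), n2 = length(yb),
                   mean1 = mean(ya), mean2 = mean(yb), p = p)
  }) |> dplyr::bind_rows()
}
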
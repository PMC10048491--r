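#' Genomic relationship matrix
#'
#' Allele-frequency standardized cross-product GRM:
#' `G = Z Z' / (2 * sum(p_i * (1 - p_i)))` with `Z` the per-marker
#' mean-centered dosage matrix. Missing dosages are mean-imputed per marker;
#' monomorphic markers are excluded (count reported). A ridge of 1e-6 is
#' added to the diagonal so the matrix is numerically positive semidefinite.
#'
#' @param geno A post-QC [geno_matrix()].
#' @return List of class `grm`: `G` (n x n, dimnames = cow ids), `m` (markers
#'   used), `n_monomorphic`.
#' @export
build_grm <- function(geno) {
  d <- geno$dosage * 1
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d))
    d[idx] <- mu[(idx - 1L) %/% nrow(d) + 1L]
  }
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  n_mono <- sum(!poly)
  if (n_mono > 0) {
    message(n_mono, " monomorphic marker(s) excluded from the GRM")
    d <- d[, poly, drop = FALSE]
    p <- p[poly]
  }
  Z <- sweep(d, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  diag(G) <- diag(G) + 1e-6
  dimnames(G) <- list(rownames(geno$dosage), rownames(geno$dosage))
  structure(list(G = G, m = ncol(d), n_monomorphic = n_mono), class = "grm")
}

#' REML heritability with a single genomic variance component
#'
#' Fits `y ~ N(X b, sigma_g^2 * G + sigma_e^2 * I)` by restricted maximum
#' likelihood. The GRM is eigendecomposed once; in the rotated basis the
#' covariance is diagonal, so each iteration costs O(n) plus a small solve.
#' Updates are average-information steps with an expectation-maximization
#' fallback whenever an AI step would leave the parameter space; components
#' are clamped at 1e-8. Convergence: `|delta logL| < 1e-6` or 200 iterations.
#' The standard error of `h2` comes from the inverse AI matrix by the delta
#' method.
#'
#' @param y Trait vector (no missing values; subset beforehand).
#' @param X Fixed-effect design matrix with intercept (or `NULL` for
#'   intercept only).
#' @param grm A [build_grm()] result aligned to `y`, or a plain matrix.
#' @return Object of class `herd_h2`: list with `sigma_g2`, `sigma_e2`, `h2`,
#'   `se_h2`, `loglik`, `converged`, `n_iterations`, `n`, `m_markers`.
#' @export
reml_h2 <- function(y, X = NULL, grm) {
  G <- if (inherits(grm, "grm")) grm$G else grm
  n <- length(y)
  stopifnot(nrow(G) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (anyNA(y) || anyNA(X)) stop("subset to complete cases before reml_h2()")
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors
  lam <- pmax(eg$values, 0)
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- qr(X)$rank
  vy <- stats::var(y)
  theta <- c(g = vy / 2, e = vy / 2)      # sigma_g^2, sigma_e^2

  # rotated basis: V = sigma_g^2 * diag(lam) + sigma_e^2 * I is diagonal.
  # logL, Py and the trace terms tr(P A) for diagonal A per evaluation.
  eval_point <- function(th) {
    v <- th[1] * lam + th[2]
    vinv <- 1 / v
    XtVX <- crossprod(Xt, Xt * vinv)
    ch <- chol(XtVX)
    XtVy <- crossprod(Xt, yt * vinv)
    beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
    Py <- as.vector(yt - Xt %*% beta) * vinv
    yPy <- sum(yt * Py)
    ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + yPy)
    # tr(P A) = tr(Vinv A) - tr((X'VinvX)^-1 X'Vinv A Vinv X) for diagonal A
    tr_term <- function(a) {
      sum(a * vinv) - sum(chol2inv(ch) * crossprod(Xt * vinv, Xt * (a * vinv)))
    }
    list(vinv = vinv, ch = ch, Py = Py, ll = ll,
         tr_g = tr_term(lam), tr_e = tr_term(rep(1, n)))
  }

  # P z for an arbitrary vector at state st
  Pz <- function(st, z) {
    w <- backsolve(st$ch, forwardsolve(t(st$ch), crossprod(Xt, z * st$vinv)))
    st$vinv * (z - as.vector(Xt %*% w))
  }

  st <- eval_point(theta)
  ll_old <- st$ll
  converged <- FALSE
  iters <- 0L
  AI <- diag(2)
  for (it in seq_len(200L)) {
    iters <- it
    # dV/dsigma_g^2 = diag(lam), dV/dsigma_e^2 = I in the rotated basis
    PGPy <- Pz(st, lam * st$Py)
    PIPy <- Pz(st, st$Py)
    score <- c(-0.5 * (st$tr_g - sum(st$Py * (lam * st$Py))),
               -0.5 * (st$tr_e - sum(st$Py * st$Py)))
    AI <- 0.5 * matrix(c(sum((lam * st$Py) * PGPy),
                         sum((lam * st$Py) * PIPy),
                         sum(st$Py * PGPy),
                         sum(st$Py * PIPy)), 2, 2)
    AI <- (AI + t(AI)) / 2
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    new_theta <- if (!is.null(step)) theta + step else NULL
    use_em <- is.null(new_theta) || any(new_theta < 0)
    if (use_em) {
      # EM updates (guaranteed in the parameter space)
      new_theta <- c(
        theta[1] + theta[1]^2 * (sum(st$Py * (lam * st$Py)) - st$tr_g) / n,
        theta[2] + theta[2]^2 * (sum(st$Py * st$Py) - st$tr_e) / n)
    }
    new_theta <- pmax(new_theta, 1e-8)
    new_st <- eval_point(new_theta)
    # step-halving if the restricted likelihood decreased
    halvings <- 0L
    while (new_st$ll < ll_old - 1e-10 && halvings < 20L) {
      new_theta <- (theta + new_theta) / 2
      new_theta <- pmax(new_theta, 1e-8)
      new_st <- eval_point(new_theta)
      halvings <- halvings + 1L
    }
    theta <- new_theta
    st <- new_st
    if (abs(st$ll - ll_old) < 1e-6) { converged <- TRUE; break }
    ll_old <- st$ll
  }
  h2 <- theta[1] / sum(theta)
  se_h2 <- tryCatch({
    V <- solve(AI)
    grad <- c(theta[2], -theta[1]) / sum(theta)^2
    sqrt(drop(t(grad) %*% V %*% grad))
  }, error = function(e) NA_real_)
  structure(list(sigma_g2 = unname(theta[1]), sigma_e2 = unname(theta[2]),
                 h2 = unname(h2), se_h2 = se_h2, loglik = st$ll,
                 converged = converged, n_iterations = iters, n = n,
                 m_markers = if (inherits(grm, "grm")) grm$m else NA_integer_),
            class = "herd_h2")
}

#' @export
print.herd_h2 <- function(x, ...) {
  cat(sprintf("<herd_h2> h2 = %.3f (SE %.3f)\n", x$h2, x$se_h2))
  cat(sprintf("  sigma_g2 = %.4g, sigma_e2 = %.4g, logL = %.4f\n",
              x$sigma_g2, x$sigma_e2, x$loglik))
  cat(sprintf("  %s after %d iterations (n = %d)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$n))
  invisible(x)
}

#' Per-trait heritability from a phenotype table
#'
#' Runs [reml_h2()] for each requested trait-lactation cell using the
#' trait's selected fixed effects.
#'
#' @param pheno A `pheno_table`.
#' @param geno Post-QC [geno_matrix()] (GRM built once on all cows).
#' @param clusters Cluster assignment tibble.
#' @param selection Output of [select_covariates_all()] or `NULL`.
#' @param cells Tibble of `trait`/`lactation` to fit (default: all).
#' @return Tibble: trait, lactation, sigma_g2, sigma_e2, h2, se_h2,
#'   converged, n.
#' @export
heritability_all <- function(pheno, geno, clusters, selection = NULL,
                             cells = NULL) {
  grm <- build_grm(geno)
  if (is.null(cells)) {
    cells <- dplyr::distinct(pheno$values, .data$trait, .data$lactation)
  }
  purrr::pmap(cells, function(trait, lactation) {
    covars <- character()
    if (!is.null(selection)) {
      covars <- selection |>
        dplyr::filter(.data$trait == !!trait, .data$lactation == !!lactation,
                      .data$included) |>
        dplyr::pull("effect")
    }
    df <- model_frame(pheno, clusters, trait, lactation, covars)
    ids <- intersect(df$cow_id, rownames(grm$G))
    df <- df[match(ids, df$cow_id), ]
    X <- build_design(df, c("cluster", covars))
    fit <- reml_h2(df$value, X, grm$G[ids, ids])
    tibble::tibble(trait = trait, lactation = lactation,
                   sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                   h2 = fit$h2, se_h2 = fit$se_h2, converged = fit$converged,
                   n = fit$n)
  }) |> dplyr::bind_rows()
}
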
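#' Gaussian OLS Akaike information criterion
#'
#' Fits ordinary least squares of `y` on the design implied by `terms` (an
#' intercept is always included; factors are one-hot expanded) and returns
#' `AIC = n * log(2 * pi * RSS / n) + n + 2 * (k + 1)` where `k` counts the
#' regression parameters and the `+ 1` counts the residual variance. Constant
#' terms are kept — they cancel in differences. The RSS is floored at 1e-12
#' so saturated fits stay finite.
#'
#' @param data Data frame holding the response and covariates.
#' @param response Name of the response column.
#' @param terms Character vector of covariate column names (may be empty:
#'   intercept-only model).
#' @return AIC value (scalar).
#' @export
ols_aic <- function(data, response, terms = character()) {
  y <- data[[response]]
  X <- build_design(data, terms)
  if (nrow(X) <= ncol(X)) stop("need more rows than parameters")
  fit <- stats::lm.fit(X, y)
  rss <- max(sum(fit$residuals^2), 1e-12)
  n <- length(y)
  k <- fit$rank
  n * log(2 * pi * rss / n) + n + 2 * (k + 1)
}

# one-hot design with intercept; drops aliased columns left-to-right with a
# warning naming them (qr pivoting on the cross-product)
build_design <- function(data, terms) {
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  for (t in terms) {
    v <- data[[t]]
    if (is.null(v)) stop("unknown covariate: ", t)
    if (is.numeric(v)) {
      X <- cbind(X, stats::setNames(data.frame(v), t) |> as.matrix())
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) {
        warning("covariate ", t, " has a single level; skipped")
        next
      }
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(t, levels(f)[-1])
      X <- cbind(X, mm)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), sort(qrX$pivot[seq_len(qrX$rank)]))
    warning("dropping aliased design column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  X
}

#' Delta-AIC selection of optional fixed effects
#'
#' Each candidate effect is tested singly against the null model
#' (response ~ stratification cluster): the candidate is included when
#' `AIC(null + effect) - AIC(null) <= threshold` (default -10, i.e. the
#' extended model must improve the AIC by at least 10 points). Candidates are
#' never tested jointly; the stratification covariate is always retained.
#'
#' @param data Data frame with the response, the stratification column and the
#'   candidate covariates.
#' @param response Response column name.
#' @param candidates Character vector of optional covariate names.
#' @param ps Name of the mandatory population-stratification column.
#' @param threshold Inclusion threshold on the AIC difference.
#' @return Tibble with one row per candidate: `effect`, `delta_aic`,
#'   `included`.
#' @export
select_covariates <- function(data, response, candidates,
                              ps = "cluster", threshold = -10) {
  if (!ps %in% names(data)) stop("stratification column not found: ", ps)
  aic0 <- ols_aic(data, response, ps)
  rows <- purrr::map(candidates, function(cand) {
    v <- data[[cand]]
    if (!is.numeric(v) && length(unique(v[!is.na(v)])) < 2) {
      warning("candidate ", cand, " has a single level; skipped")
      return(tibble::tibble(effect = cand, delta_aic = NA_real_,
                            included = FALSE))
    }
    da <- ols_aic(data, response, c(ps, cand)) - aic0
    tibble::tibble(effect = cand, delta_aic = da, included = da <= threshold)
  })
  dplyr::bind_rows(rows)
}

#' Per trait-lactation covariate selection table
#'
#' Runs [select_covariates()] for every (trait, lactation) cell of a
#' [build_phenotypes()] result, on complete cases of the candidate set.
#'
#' @param pheno A `pheno_table`.
#' @param clusters Tibble `cow_id`/`cluster` from [cluster_ppc()] or truth.
#' @param candidates Optional-effect column names (defaults to the full
#'   farm/sire/year/season/age set).
#' @param threshold See [select_covariates()].
#' @return Tibble: `trait`, `lactation`, `effect`, `delta_aic`, `included`.
#' @export
select_covariates_all <- function(pheno, clusters,
                                  candidates = c("farm", "sire", "birth_year",
                                                 "birth_season", "calving_year",
                                                 "calving_season",
                                                 "age_first_calving"),
                                  threshold = -10) {
  cells <- dplyr::distinct(pheno$values, .data$trait, .data$lactation)
  purrr::pmap(cells, function(trait, lactation) {
    df <- model_frame(pheno, clusters, trait, lactation, candidates)
    select_covariates(df, "value", candidates, threshold = threshold) |>
      dplyr::mutate(trait = trait, lactation = lactation, .before = 1)
  }) |>
    dplyr::bind_rows()
}

# assemble the per-cell model frame: value + cluster + covariates, complete cases
model_frame <- function(pheno, clusters, trait, lactation, covars) {
  df <- pheno$values |>
    dplyr::filter(.data$trait == !!trait, .data$lactation == !!lactation) |>
    dplyr::inner_join(clusters, by = "cow_id") |>
    dplyr::inner_join(
      pheno$covariates |> dplyr::filter(.data$lactation == !!lactation) |>
        dplyr::select(-"lactation"),
      by = "cow_id")
  # categorical effects (only age at first calving is continuous)
  for (col in intersect(c("cluster", "farm", "sire", "birth_year",
                          "birth_season", "calving_year", "calving_season"),
                        names(df))) {
    df[[col]] <- factor(df[[col]])
  }
  df <- df[stats::complete.cases(df[, c("value", "cluster", covars)]), ]
  df
}
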
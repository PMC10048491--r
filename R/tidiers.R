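#' Tidy a REML heritability fit
#'
#' @param x A `herd_h2` object from [reml_h2()].
#' @param ... Unused.
#' @return One row per variance component: `term`, `estimate`, plus the
#'   heritability row with its standard error.
#' @export
tidy.herd_h2 <- function(x, ...) {
  tibble::tibble(term = c("sigma_g2", "sigma_e2", "h2"),
                 estimate = c(x$sigma_g2, x$sigma_e2, x$h2),
                 std.error = c(NA_real_, NA_real_, x$se_h2))
}

#' @rdname tidy.herd_h2
#' @return `glance()`: one-row model summary (`h2`, `se_h2`, `logLik`,
#'   `converged`, `n_iterations`, `nobs`).
#' @export
glance.herd_h2 <- function(x, ...) {
  tibble::tibble(h2 = x$h2, se_h2 = x$se_h2, logLik = x$loglik,
                 converged = x$converged, n_iterations = x$n_iterations,
                 nobs = x$n)
}

#' Tidy a QC result
#'
#' @param x A `qc_result` from [filter_variants()].
#' @param ... Unused.
#' @return The per-criterion removal-count report.
#' @export
tidy.qc_result <- function(x, ...) x$report

#' @rdname tidy.qc_result
#' @export
glance.qc_result <- function(x, ...) {
  tibble::tibble(n_input = x$report$n[x$report$criterion == "input"],
                 n_retained = x$report$n[x$report$criterion == "retained"],
                 n_individuals = nrow(x$geno$dosage))
}
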
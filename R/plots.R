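#' Manhattan plot
#'
#' Standard alternating-color Manhattan plot of -log10 corrected p-values
#' with dashed/solid/dotted lines at the suggestive, significant and highly
#' significant thresholds.
#'
#' @param results A corrected `gwas_result` (or a `manhattan_data` from
#'   [export_manhattan()]).
#' @param thresholds Tibble from [bonferroni_thresholds()]; ignored when
#'   `results` is already a `manhattan_data`.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, thresholds = NULL) {
  md <- if (inherits(results, "manhattan_data")) results else
    export_manhattan(results, thresholds)
  lt <- c("highly significant" = "dotted", significant = "solid",
          suggestive = "dashed")
  ggplot2::ggplot(md$points,
                  ggplot2::aes(.data$cum_pos, .data$neg_log10_p,
                               colour = factor(.data$parity))) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(
      data = md$thresholds,
      ggplot2::aes(yintercept = .data$threshold, linetype = .data$label),
      colour = "grey30") +
    ggplot2::scale_linetype_manual(values = lt, name = NULL) +
    ggplot2::scale_colour_manual(values = c("#1f6fb5", "#8bb8dc")) +
    ggplot2::scale_x_continuous(breaks = md$chrom_breaks$mid,
                                labels = md$chrom_breaks$chrom) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of GWAS p-values
#'
#' Observed vs expected -log10 p with the inflation factor in the subtitle.
#'
#' @param p Vector of p-values.
#' @return A ggplot object.
#' @export
plot_qq <- function(p) {
  p <- sort(p[!is.na(p)])
  df <- tibble::tibble(expected = -log10(stats::ppoints(length(p))),
                       observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p)),
                  subtitle = sprintf("lambda = %.3f", inflation_factor(p))) +
    ggplot2::theme_minimal()
}

#' SNP effect plot
#'
#' Covariate-adjusted trait values by genotype group with pairwise Welch
#' t-test p-values in the subtitle.
#'
#' @param y Trait values.
#' @param X Covariate design (or `NULL`).
#' @param g Dosage vector.
#' @param trait Axis label.
#' @return A ggplot object.
#' @export
plot_snp_effect <- function(y, X, g, trait = "trait") {
  tt <- genotype_group_ttests(y, X, g)
  ok <- !is.na(y) & !is.na(g) & (if (is.null(X)) TRUE else stats::complete.cases(X))
  yv <- y[ok]; gv <- g[ok]
  if (!is.null(X)) {
    yv <- qr.resid(qr(X[ok, , drop = FALSE]), yv) + mean(yv)
  }
  lab <- paste(sprintf("%d vs %d: p = %.3g", tt$group1, tt$group2, tt$p),
               collapse = "; ")
  ggplot2::ggplot(tibble::tibble(g = factor(gv), y = yv),
                  ggplot2::aes(.data$g, .data$y)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "#d8e8f5") +
    ggplot2::labs(x = "minor-allele dosage", y = trait, subtitle = lab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gwas_result <- function(object, thresholds = NULL, ...) {
  if (is.null(thresholds)) {
    thresholds <- tibble::tibble(alpha = numeric(), label = character(),
                                 threshold = numeric())
  }
  plot_manhattan(object, thresholds)
}
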
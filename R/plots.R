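#' Manhattan-style plot of a scan
#'
#' @param object A `gwas_scan` tibble (see [run_scan()]).
#' @param threshold Significance line (default the effective-tests
#'   threshold 5e-8 / 2.2).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gwas_scan
#' @export
autoplot.gwas_scan <- function(object, threshold = significance_threshold()$threshold,
                               ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$p))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = -log10(.data$p),
                                    colour = .data$model)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::facet_grid(rows = NULL, cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p)),
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter of GWAS vs eQTL signed scores
#'
#' Visualises the pattern comparison behind the Kendall test: each point
#' is a matched variant, axes are the signed `-log10(p)` scores; an
#' anti-concordant eQTL relationship shows as a decreasing trend.
#'
#' @param matched Output of [harmonize_alleles()] (GWAS `beta`/`p` and
#'   eQTL `effect_b`/`p_b` columns).
#' @return A ggplot.
#' @export
plot_signed_scores <- function(matched) {
  dat <- tibble::tibble(gwas = signed_score(matched$beta, matched$p),
                        eqtl = signed_score(matched$effect_b, matched$p_b))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gwas, y = .data$eqtl)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "GWAS signed -log10(p)", y = "eQTL signed -log10(p)") +
    ggplot2::theme_minimal()
}

#' Per-tissue Kendall correlation plot
#'
#' @param tissue_results Output of [compare_all_tissues()].
#' @return A ggplot of tau by tissue.
#' @export
plot_tissue_correlations <- function(tissue_results) {
  dat <- dplyr::arrange(tissue_results, .data$tau)
  dat$tissue <- factor(dat$tissue, levels = dat$tissue)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$tau, y = .data$tissue)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Kendall tau (GWAS vs eQTL signed scores)", y = NULL) +
    ggplot2::theme_minimal()
}
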
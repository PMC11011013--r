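#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style plot of window genetic-variance shares
#'
#' One point per 1-Mb window, alternating shade by chromosome, with the
#' significance threshold and the infinitesimal expectation drawn as
#' horizontal lines and flagged windows highlighted.
#'
#' @param object a `window_profile`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot window_profile
autoplot.window_profile <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$chr, .data$mb)
  df$x <- seq_len(nrow(df))
  df$chr_parity <- factor(df$chr %% 2)
  thr <- attr(object, "gv_threshold")
  inf_gv <- attr(object, "infinitesimal_gv")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$gv_percent)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chr_parity),
                        show.legend = FALSE, size = 1) +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                        colour = "red", size = 2) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = inf_gv, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c("grey30", "grey60")) +
    ggplot2::labs(x = "1-Mb window (genome order)",
                  y = "Genetic variance explained (%)",
                  title = "Posterior window variance profile") +
    ggplot2::theme_minimal()
}

#' Per-fold prediction accuracy with its standard error band
#'
#' @param object a `cv_accuracy`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot cv_accuracy
autoplot.cv_accuracy <- function(object, ...) {
  g <- glance(object)
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold),
                                   y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = g$mean_accuracy, linetype = "dashed") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = g$mean_accuracy - g$se,
                      ymax = g$mean_accuracy + g$se, alpha = 0.15) +
    ggplot2::labs(x = "Validation fold", y = "Accuracy (cor(MBV, DEBV))",
                  title = sprintf("Mean accuracy %.3f (SE %.3f)",
                                  g$mean_accuracy, g$se)) +
    ggplot2::theme_minimal()
}

#' Summary plot of per-SNP QC statistics
#'
#' Histograms of call rate, minor allele frequency and -log10 HWE
#' p-value with the usual filter thresholds marked.
#'
#' @param stats output of [snp_stats()].
#' @param min_call_rate,min_maf,min_hwe_p thresholds to draw.
#' @return A ggplot object (facetted).
#' @export
plot_snp_qc <- function(stats, min_call_rate = 0.95, min_maf = 0.01,
                        min_hwe_p = 1e-4) {
  long <- dplyr::bind_rows(
    tibble::tibble(metric = "call rate", value = stats$call_rate,
                   threshold = min_call_rate),
    tibble::tibble(metric = "MAF", value = stats$maf, threshold = min_maf),
    tibble::tibble(metric = "-log10 HWE p",
                   value = -log10(pmax(stats$hwe_p, 1e-300)),
                   threshold = -log10(min_hwe_p)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$threshold),
                        colour = "red", linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "SNPs") +
    ggplot2::theme_minimal()
}
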
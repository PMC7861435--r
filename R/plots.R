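#' Plot a joint PCA embedding
#'
#' Scatter of two principal components from a [joint_pca()] fit, coloured by
#' source dataset — the standard visual check that artificial clouds overlap
#' the real one.
#'
#' @param object a `joint_pca` object.
#' @param dims pair of component indices to show (default PC1/PC2).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.joint_pca <- function(object, dims = c(1L, 2L), ...) {
  cols <- paste0("PC", dims)
  ev <- attr(object, "eigenvalues")
  pct <- 100 * ev / sum(ev)
  ggplot2::ggplot(object, ggplot2::aes(.data[[cols[1L]]], .data[[cols[2L]]],
                                       colour = .data$dataset)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", cols[1L], pct[dims[1L]]),
                  y = sprintf("%s (%.1f%%)", cols[2L], pct[dims[2L]]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Diagnostic plots for an evaluation report
#'
#' `plot_freq_comparison()` draws the per-site real-vs-artificial allele
#' frequency scatter with the identity line; `plot_ld_decay()` the binned LD
#' decay curves of both datasets; `plot_pairwise_distances()` the within-set
#' pairwise Hamming-distance histograms.
#'
#' @param report an [evaluate_pair()] result.
#' @return a ggplot object.
#' @export
plot_freq_comparison <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  ggplot2::ggplot(report$freq$table,
                  ggplot2::aes(.data$freq_real, .data$freq_art)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "allele frequency (real)",
                  y = "allele frequency (artificial)",
                  subtitle = sprintf("correlation = %.3f",
                                     report$freq$correlation)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_freq_comparison
#' @export
plot_ld_decay <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  if (is.null(report$ld_decay)) stop("report has no LD decay curve",
                                     call. = FALSE)
  df <- report$ld_decay
  long <- rbind(data.frame(dist = df$dist_mid, r2 = df$mean_r2_real,
                           dataset = "real"),
                data.frame(dist = df$dist_mid, r2 = df$mean_r2_art,
                           dataset = "artificial"))
  ggplot2::ggplot(long, ggplot2::aes(.data$dist, .data$r2,
                                     colour = .data$dataset)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "SNP distance", y = expression(mean ~ r^2),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_freq_comparison
#' @export
plot_pairwise_distances <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  pw <- report$pairwise
  long <- rbind(data.frame(d = pw$within_real, dataset = "within real"),
                data.frame(d = pw$within_art, dataset = "within artificial"))
  ggplot2::ggplot(long, ggplot2::aes(.data$d, fill = .data$dataset)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 40) +
    ggplot2::labs(x = "pairwise Hamming distance", y = "pairs", fill = NULL) +
    ggplot2::theme_minimal()
}
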
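#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sweep scan (joint outlier view)
#'
#' Scatter of Z(FST) against the log2 pi-ratio over usable windows, with the
#' two right-tail thresholds as dashed lines and flagged windows
#' highlighted. Windows with an infinite ratio are drawn at the edge of the
#' finite range.
#'
#' @param object A [sweep_scan()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_scan <- function(object, ...) {
  w <- object$windows |> dplyr::filter(.data$usable)
  finite <- w$log2_pi_ratio[is.finite(w$log2_pi_ratio)]
  edge <- if (length(finite) > 0) max(abs(finite)) * 1.05 else 1
  w$ratio_plot <- pmin(pmax(w$log2_pi_ratio, -edge), edge)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$ratio_plot, y = .data$z_fst,
                                  colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = object$thresholds$log2_pi_ratio,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$thresholds$z_fst,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#2166ac"),
                                 guide = "none") +
    ggplot2::labs(
      x = expression(log[2] * "(" * pi[wild] / pi[cultivated] * ")"),
      y = expression(Z(F[ST])),
      title = sprintf("%s vs %s: %d windows flagged",
                      object$wild, object$cultivated,
                      sum(object$windows$flagged))) +
    ggplot2::theme_minimal()
}

#' Plot PCA sample coordinates
#'
#' @param object A [pca_genotypes()] object.
#' @param grouping Optional grouping tibble to colour samples.
#' @param ... Unused.
#' @return A ggplot object of PC1 vs PC2.
#' @export
autoplot.genotype_pca <- function(object, grouping = NULL, ...) {
  df <- object$scores
  if (!is.null(grouping)) {
    df <- dplyr::left_join(df, grouping, by = "sample")
  } else {
    df$group <- "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
}

#' Plot LD decay curves
#'
#' @param curves An LD curve tibble from [ld_decay()], or several stacked
#'   with a `group` column.
#' @return A ggplot object of mean r-squared against distance.
#' @export
plot_ld_decay <- function(curves) {
  if (!"group" %in% names(curves)) curves$group <- "all"
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$mid, y = .data$mean_r2,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (bp)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' Plot windowed statistics along a chromosome
#'
#' Diversity of both groups and FST along one chromosome of a scan, with
#' selected regions shaded -- the per-locus sweep view.
#'
#' @param scan A [sweep_scan()] object.
#' @param chrom Chromosome to plot (default: first).
#' @return A ggplot object.
#' @export
plot_scan_tracks <- function(scan, chrom = NULL) {
  w <- scan$windows
  chrom <- chrom %||% w$chrom[1]
  w <- w[w$chrom == chrom & w$usable, , drop = FALSE]
  long <- tidyr::pivot_longer(
    dplyr::select(w, "start", "pi_wild", "pi_cult", "fst"),
    cols = -"start", names_to = "stat", values_to = "value")
  regs <- scan$regions[scan$regions$chrom == chrom, , drop = FALSE]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$start / 1e6,
                                          y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~stat, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom), y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(regs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regs,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "#b2182b",
      inherit.aes = FALSE)
  }
  p
}
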
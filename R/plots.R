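#' Plot a PCIS-corrected trace
#'
#' Three stacked panels: the analyte signal, the PCIS signal with its LLOQ,
#' and the corrected (ratio) trace with below-LLOQ scans highlighted.
#'
#' @param object A `pcis_corrected` tibble from [pcis_correct()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcis_corrected <- function(object, ...) {
  lloq <- attr(object, "lloq")
  df <- tidyr::pivot_longer(
    dplyr::select(object, "time_min", "analyte", "pcis", "ratio"),
    cols = c("analyte", "pcis", "ratio"),
    names_to = "panel", values_to = "value")
  df$panel <- factor(df$panel, levels = c("analyte", "pcis", "ratio"))
  hl <- dplyr::filter(object, .data$below_lloq)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "retention time (min)", y = NULL) +
    ggplot2::theme_minimal(base_size = 10)
  if (!is.null(lloq)) {
    p <- p + ggplot2::geom_hline(
      data = data.frame(panel = factor("pcis", levels(df$panel)),
                        lloq = lloq),
      ggplot2::aes(yintercept = .data$lloq),
      linetype = "dotted", colour = "red")
  }
  if (nrow(hl) > 0) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(hl, panel = factor("pcis", levels(df$panel)),
                           value = .data$pcis),
      colour = "red", size = 0.6)
  }
  p
}

#' Plot a suppression-profile correlation matrix
#'
#' @param object A `pcis_cor` object.
#' @param ... Unused.
#' @return A ggplot heatmap of pairwise Pearson r.
#' @export
autoplot.pcis_cor <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$label_a, .data$label_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(-1, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Infusion-profile correlation, [%g, %g) min",
                      object$window[1], object$window[2])) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot Method 1 matrix-effect summaries
#'
#' Mean matrix effect per compound with CV error bars, raw vs
#' PCIS-corrected, mirroring the summary pane of the across-matrices
#' evaluation.
#'
#' @param object A `pcis_method1` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcis_method1 <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(.data$name, .data$mean_me,
                                   colour = .data$source)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_me * (1 - .data$cv / 100),
                   ymax = .data$mean_me * (1 + .data$cv / 100)),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "matrix effect (%)", colour = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}
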
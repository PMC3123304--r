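#' Plot decoded per-specificity frequencies
#'
#' Bar chart of the percentage of CD8-gated events assigned to each
#' dual-color code.
#'
#' @param object A `decoded_result` from [decode_events()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoded_result <- function(object, ...) {
  df <- tidy(object)
  df$code <- paste(df$channel_1, df$channel_2, sep = " + ")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$peptide_id,
                                                      -.data$frequency),
                                   y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$code), angle = 90,
                       hjust = -0.05, size = 2.8) +
    ggplot2::labs(x = NULL, y = "% of CD8+ gated events",
                  title = "Decoded multimer-positive frequencies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot an OD triage
#'
#' Histogram of ODs coloured by affinity class with the two cutoffs marked.
#'
#' @param object An `od_triage` from [triage_od()].
#' @param binwidth Histogram bin width (OD units).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.od_triage <- function(object, binwidth = 0.1, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$od, fill = .data$affinity_class)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(object$low_cut, object$high_cut),
                        linetype = "dashed") +
    ggplot2::labs(x = "OD (414 nm)", y = "peptides", fill = "affinity") +
    ggplot2::theme_minimal()
}

#' Clinical-applicability curve with a frequency band
#'
#' Plots the Hardy-Weinberg donor-recipient disparity probability as a
#' function of the MiHA-positive allele frequency and shades the retained
#' band.
#'
#' @param band Length-2 frequency band to shade (default the operational
#'   0.15-0.46 window).
#' @param threshold Horizontal reference line (default 0.20).
#' @return A ggplot object.
#' @export
plot_applicability <- function(band = c(0.15, 0.46), threshold = 0.20) {
  p <- seq(0, 1, by = 0.002)
  df <- tibble(p = p, applicability = clinical_applicability(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$applicability)) +
    ggplot2::annotate("rect", xmin = band[1], xmax = band[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "MiHA-positive allele frequency",
                  y = "P(recipient positive, donor negative)") +
    ggplot2::theme_minimal()
}
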
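# ggplot2 figures for each result type: length distribution,
# first-base and positional nucleotide bias, and the two-library
# expression scatter.

#' Plot a read-length distribution
#' @param ld tibble from [length_distribution()].
#' @return a ggplot.
#' @export
plot_length_distribution <- function(ld) {
  ld$length <- factor(ld$length, levels = ld$length)
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$length, y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "read length (nt)", y = "% of reads",
                  title = "Small RNA length distribution") +
    ggplot2::theme_minimal()
}

#' Plot first-nucleotide bias by read length
#' @param fb tibble from [first_nucleotide_bias()].
#' @return a stacked-bar ggplot.
#' @export
plot_first_nt_bias <- function(fb) {
  ggplot2::ggplot(fb, ggplot2::aes(x = factor(.data$length),
                                   y = 100 * .data$fraction,
                                   fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "read length (nt)", y = "% of reads",
                  fill = "first base",
                  title = "First-nucleotide bias by length") +
    ggplot2::theme_minimal()
}

#' Plot positional nucleotide bias
#' @param pb tibble from [positional_nucleotide_bias()].
#' @return a stacked-bar ggplot over positions.
#' @export
plot_position_bias <- function(pb) {
  long <- tidyr::pivot_longer(pb[, c("position", "a", "c", "g", "u")],
                              -"position", names_to = "base",
                              values_to = "fraction")
  long$base <- toupper(long$base)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position,
                                     y = 100 * .data$fraction,
                                     fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position (nt)", y = "% of reads", fill = "base",
                  title = "Nucleotide bias at each position") +
    ggplot2::theme_minimal()
}

#' Expression scatter plot of a DE table
#'
#' Normalized expression in the two libraries on log10 axes, coloured
#' by fold-change class (ratio > 2; between 1/2 and 2; <= 1/2).
#'
#' @param object a `mir_de` table.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mir_de
#' @export
autoplot.mir_de <- function(object, ...) {
  df <- object[!is.na(object$scatter_class), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ne2, y = .data$ne1,
                                   colour = .data$scatter_class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c("fold>2" = "red",
                                            "1/2<fold<=2" = "blue",
                                            "fold<=1/2" = "green4")) +
    ggplot2::labs(x = "expression, library 2 (TPM)",
                  y = "expression, library 1 (TPM)", colour = "fold change") +
    ggplot2::theme_minimal()
}

#' Enrichment bar plot
#'
#' Top pathways by ascending p as a -log10(p) bar chart.
#'
#' @param object a `mir_enrich` table.
#' @param top number of pathways shown (default 10).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mir_enrich
#' @export
autoplot.mir_enrich <- function(object, top = 10L, ...) {
  df <- head(object, top)
  df$pathway <- factor(df$pathway, levels = rev(df$pathway))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p), y = .data$pathway)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "-log10 p", y = NULL,
                  title = "Pathway enrichment of DE targets") +
    ggplot2::theme_minimal()
}
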
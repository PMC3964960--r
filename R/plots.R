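# ggplot2 views of a classification.

#' Distribution of classified loops by length
#'
#' Bar chart of classified loop counts per length and method, in the style of
#' a classification summary.
#'
#' @param report Output of [classification_report()] (its `by_length` table
#'   is used).
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(report) {
  d <- tidyr::pivot_longer(report$by_length,
                           c("ds_classified", "mcl_classified"),
                           names_to = "method", values_to = "classified")
  d$method <- toupper(sub("_classified", "", d$method))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$length),
                                  y = .data$classified,
                                  fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "loop length (residues)", y = "classified loops",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' RMSD distribution of subclasses by loop length
#'
#' @param hierarchy A `loop_hierarchy`.
#' @return A ggplot object (boxplots of subclass mean RMSD per length level
#'   and method).
#' @export
plot_rmsd_distribution <- function(hierarchy) {
  s <- hierarchy$subclasses
  ggplot2::ggplot(s, ggplot2::aes(x = .data$length_label, y = .data$rmsd_mean,
                                  fill = .data$method)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "loop length", y = "subclass mean RMSD (Å)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_rmsd_distribution
#' @param object A `loop_hierarchy`.
#' @param ... Unused.
#' @export
autoplot.loop_hierarchy <- function(object, ...) {
  plot_rmsd_distribution(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
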
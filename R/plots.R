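#' Plot tandem-repeat counts by unit size
#'
#' Bar chart of repeat counts per unit size, the classic view of a
#' dinucleotide-dominated repeat landscape.
#'
#' @param object A [tr_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tr_summary <- function(object, ...) {
  ggplot2::ggplot(object$unit_counts,
                  ggplot2::aes(x = factor(.data$unit_size), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Unit size (bp)", y = "Number of tandem repeats") +
    ggplot2::theme_minimal()
}

#' Plot contig-terminus attribution
#'
#' Percent of contig termini intersecting each annotation class.
#'
#' @param object Output of [attribute_termini()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_termini_attribution <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$class, -.data$pct),
                               y = .data$pct)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Annotation class", y = "% of contig termini") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot reconciliation event counts
#'
#' @param object A `reconciliation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reconciliation <- function(object, ...) {
  counts <- dplyr::count(object$events, .data$type)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$type, y = .data$n)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = "Event", y = "Count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
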
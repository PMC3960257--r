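# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Genome map of a quadripartite partition
#'
#' @param object A [region_partition()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_partition <- function(object, ...) {
  tbl <- tidy(object)
  tbl$region <- factor(tbl$region, levels = c("LSC", "IRb", "SSC", "IRa"))
  ggplot2::ggplot(tbl, ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = 1, fill = .data$region)) +
    ggplot2::geom_rect(colour = "grey20") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = sprintf("Quadripartite structure (%s bp)",
                                  format(object$genome_length, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Codon usage bar chart, grouped by amino acid
#'
#' @param object A `codon_usage` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.codon_usage <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = stats::reorder(.data$codon, -.data$count),
                                    y = .data$count, fill = .data$amino_acid)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "codon", y = "count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Repeat counts by size bin and orientation
#'
#' @param summary Tibble from [summarize_repeats()].
#' @return A ggplot.
#' @export
plot_repeat_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$size_bin, y = .data$n,
                                        fill = .data$orientation)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "repeat length (bp)", y = "repeats",
                  fill = "orientation") +
    ggplot2::theme_minimal()
}

#' Conversion-type spectrum of called editing sites
#'
#' @param spectrum Tibble from [summarize_conversion_spectrum()].
#' @return A ggplot.
#' @export
plot_editing_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum, ggplot2::aes(x = stats::reorder(.data$conversion, -.data$n),
                                         y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "conversion", y = "sites") +
    ggplot2::theme_minimal()
}

#' Size-stratified small-RNA coverage with called loci
#'
#' @param short_cov,long_cov Per-base coverage vectors.
#' @param loci Optional loci tibble from [call_srna_loci()].
#' @return A ggplot.
#' @export
plot_srna_coverage <- function(short_cov, long_cov, loci = NULL) {
  tbl <- tibble::tibble(
    position = rep(seq_along(short_cov), 2),
    coverage = c(short_cov, long_cov),
    class = rep(c("20-24 nt", "> 30 nt"), each = length(short_cov))
  )
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$position, y = .data$coverage,
                                         colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (bp)", y = "reads", colour = "size class") +
    ggplot2::theme_minimal()
  if (!is.null(loci) && nrow(loci) > 0) {
    p <- p + ggplot2::geom_rect(
      data = loci, inherit.aes = FALSE, alpha = 0.2, fill = "red",
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf)
    )
  }
  p
}
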
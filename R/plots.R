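# ggplot2 views of the main result tables.

#' Plot the classification funnel
#'
#' Stacked counts of removed / low / high confidence transduction calls per
#' element type.
#'
#' @param funnel A [td_funnel()] tibble.
#' @return A ggplot object.
#' @export
plot_funnel <- function(funnel) {
  long <- funnel %>%
    select("me_type", "n_removed_segdup", "n_low", "n_high") %>%
    tidyr::pivot_longer(-"me_type", names_to = "tier", values_to = "n") %>%
    mutate(tier = factor(.data$tier,
                         levels = c("n_removed_segdup", "n_low", "n_high"),
                         labels = c("removed (segdup)", "low confidence",
                                    "high confidence")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$me_type, y = .data$n,
                                     fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "transduction candidates", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.td_classification <- function(object, ...) {
  plot_funnel(td_funnel(object))
}

#' Plot an allele-frequency spectrum
#'
#' @param spectrum An [af_spectrum()] tibble.
#' @return A ggplot object (bars per bin, faceted by group).
#' @export
plot_af_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "allele frequency", y = "loci") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot progenitor productivity
#'
#' Ranked offspring counts per source locus with cumulative share.
#'
#' @param ranked A [rank_sources()] tibble.
#' @param top_k Show at most this many sources (default 20).
#' @return A ggplot object.
#' @export
plot_progenitors <- function(ranked, top_k = 20L) {
  x <- head(ranked, top_k) %>%
    mutate(source_locus = factor(.data$source_locus,
                                 levels = rev(.data$source_locus)))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$n_offspring,
                                  y = .data$source_locus,
                                  fill = .data$me_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "offspring", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
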
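#' Plot the DMR distribution of called sites
#'
#' @param object A `hypo_sites` tibble.
#' @param bin_width DMR bin width (default 0.05).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.hypo_sites <- function(object, bin_width = 0.05, ...) {
  h <- dmr_histogram(object, bin_width = bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.9, fill = "steelblue") +
    ggplot2::labs(x = "differential modification rate (wt - mut)",
                  y = "hypomethylated sites") +
    ggplot2::theme_minimal()
}

#' Metagene profile of site placements
#'
#' Histogram of metagene coordinates on the 0-3 axis with segment
#' boundaries at 1 (start codon) and 2 (stop codon).
#'
#' @param placements Tibble with a `metagene_coord` column.
#' @param bins_per_segment Bins per segment (default 30).
#' @return A ggplot.
#' @export
plot_metagene_profile <- function(placements, bins_per_segment = 30) {
  h <- metagene_histogram(placements, bins_per_segment)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count,
                                  fill = .data$segment)) +
    ggplot2::geom_col(width = 3 / (3 * bins_per_segment)) +
    ggplot2::geom_vline(xintercept = c(1, 2), linetype = "dashed") +
    ggplot2::scale_x_continuous(
      breaks = c(0.5, 1.5, 2.5), labels = c("5'UTR", "CDS", "3'UTR")) +
    ggplot2::labs(x = "metagene coordinate", y = "sites", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of top k-mer frequencies
#'
#' @param freq Output of [kmer_frequencies()].
#' @param top Number of k-mers shown (default 10).
#' @return A ggplot.
#' @export
plot_kmer_frequencies <- function(freq, top = 10) {
  d <- head(freq, top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$kmer, .data$count), y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sites") +
    ggplot2::theme_minimal()
}

#' Plot APA shift directions and distances
#'
#' @param object An `apa_shifts` tibble.
#' @param ... Ignored.
#' @return A ggplot (histogram of signed shift distances, colored by
#'   direction; proximal shifts shown as negative distances).
#' @export
autoplot.apa_shifts <- function(object, ...) {
  d <- filter(as_tibble(object), .data$significant,
              .data$direction %in% c("proximal", "distal"))
  d$signed <- if_else(d$direction == "proximal", -d$distance, d$distance)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signed, fill = .data$direction)) +
    ggplot2::geom_histogram(binwidth = 20, boundary = 0) +
    ggplot2::labs(x = "3'-end shift (nt; negative = proximal)",
                  y = "genes", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of site-to-read-3'-end distances
#'
#' @param distances Output of [site_end_distances()].
#' @param bin_width Bin width in nt (default 25).
#' @return A ggplot.
#' @export
plot_site_end_distances <- function(distances, bin_width = 25) {
  h <- distance_histogram(distances, bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.95, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance from site to read 3' end (nt)",
                  y = "site-read pairs") +
    ggplot2::theme_minimal()
}
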
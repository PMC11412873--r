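# ggplot2 figure helpers. Each returns a ggplot object the caller can theme
# or extend; nothing here is load-bearing for the statistics.

#' Plot a k-mer depth spectrum
#'
#' @param hist Histogram tibble (`depth`, `count`).
#' @param peaks Optional peak tibble from [detect_peaks()]; drawn as dashed
#'   vertical lines.
#' @return A ggplot object.
#' @export
plot_kmer_spectrum <- function(hist, peaks = NULL) {
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$depth, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = "k-mer depth", y = "distinct k-mers",
                  title = "Canonical k-mer spectrum")
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = peaks$depth, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' @export
autoplot.ploidy_report <- function(object, hist = NULL, ...) {
  if (is.null(hist)) {
    return(plot_kmer_spectrum(object$peaks |>
                                dplyr::rename(count = "height"), object$peaks))
  }
  plot_kmer_spectrum(hist, object$peaks) +
    ggplot2::labs(subtitle = sprintf("modality: %s", object$modality))
}

#' Plot the per-contig GC distribution
#'
#' Mirrors the "fraction of scaffolds by GC content" presentation used for
#' assembly composition: binned fractions of contigs per GC band.
#'
#' @param contig_gc Output of [per_contig_gc()].
#' @param binwidth GC bin width (default 0.02).
#' @return A ggplot object.
#' @export
plot_gc_distribution <- function(contig_gc, binwidth = 0.02) {
  h <- gc_histogram(contig_gc, binwidth = binwidth)
  ggplot2::ggplot(h, ggplot2::aes(x = 100 * (.data$bin_low + .data$bin_high) / 2,
                                  y = .data$fraction)) +
    ggplot2::geom_col(width = 100 * binwidth, fill = "darkseagreen4") +
    ggplot2::labs(x = "GC content (%)", y = "Fraction of contigs")
}

#' Plot per-species expansion/contraction counts
#'
#' Diverging bars: expansions up, contractions down, per species.
#'
#' @param shift_counts Output of [per_species_shift_counts()].
#' @return A ggplot object.
#' @export
plot_shift_counts <- function(shift_counts) {
  long <- tidyr::pivot_longer(shift_counts, c("n_expanded", "n_contracted"),
                              names_to = "direction", values_to = "n")
  long$n <- ifelse(long$direction == "n_contracted", -long$n, long$n)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(n_expanded = "purple4",
                                          n_contracted = "springgreen4"),
                               labels = c(n_expanded = "expanded",
                                          n_contracted = "contracted")) +
    ggplot2::labs(x = NULL, y = "orthogroups beyond threshold", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot a species correlation heatmap
#'
#' Species are ordered by the Ward linkage on correlation distance so
#' related species sit together.
#'
#' @param corr Correlation matrix from [species_correlation()].
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(corr) {
  ord <- stats::hclust(stats::as.dist(1 - corr), method = "ward.D2")$order
  lv <- rownames(corr)[ord]
  long <- as_tibble(as.data.frame.table(corr, responseName = "r"))
  names(long)[1:2] <- c("a", "b")
  long$a <- factor(long$a, levels = lv)
  long$b <- factor(long$b, levels = lv)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot RIP composite index along a contig
#'
#' @param windows Window tibble from [scan_rip_windows()].
#' @param contig Contig id to plot (default: first).
#' @return A ggplot object; RIP-positive windows are highlighted.
#' @export
plot_rip_profile <- function(windows, contig = windows$contig[1L]) {
  w <- dplyr::filter(windows, .data$contig == !!contig)
  ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$composite,
                                  colour = .data$rip_positive)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50"),
                                 labels = c(`TRUE` = "RIP positive",
                                            `FALSE` = "negative")) +
    ggplot2::labs(x = sprintf("position on %s (bp)", contig),
                  y = "composite RIP index", colour = NULL)
}
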
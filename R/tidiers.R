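# broom-style tidiers for the package's result objects.

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [anova_oneway()] or [tukey_hsd()].
#' @param ... Unused.
#' @return For [tidy()]: the Tukey pairwise table when present, otherwise
#'   the group means. For [glance()]: a one-row tibble with `metric`, `F`,
#'   `df_between`, `df_within`, `p`.
#' @export
tidy.group_comparison <- function(x, ...) {
  if (!is.null(x$tukey)) x$tukey else x$group_means
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric, F = x$F, df_between = x$df_between,
                 df_within = x$df_within, p = x$p)
}

#' Tidy a RIP summary
#'
#' @param x A `rip_summary` from [summarize_rip()].
#' @param ... Unused.
#' @return For [tidy()]: the LRAR table. For [glance()]: a one-row tibble
#'   with the genome-wide totals.
#' @export
tidy.rip_summary <- function(x, ...) {
  x$lrars
}

#' @rdname tidy.rip_summary
#' @export
glance.rip_summary <- function(x, ...) {
  tibble::tibble(
    genome_rip_percent = x$genome_rip_percent,
    total_rip_bp = x$total_rip_bp,
    genome_bp = x$genome_bp,
    n_regions = x$n_regions,
    n_lrars = nrow(x$lrars),
    lrar_mean_composite = x$lrar_mean_composite
  )
}

#' Tidy a ploidy report
#'
#' @param x A `ploidy_report` from [classify_ploidy()].
#' @param ... Unused.
#' @return For [tidy()]: the peak table. For [glance()]: a one-row tibble
#'   with modality and the heterozygosity estimate.
#' @export
tidy.ploidy_report <- function(x, ...) {
  x$peaks
}

#' @rdname tidy.ploidy_report
#' @export
glance.ploidy_report <- function(x, ...) {
  tibble::tibble(
    modality = x$modality,
    n_peaks = nrow(x$peaks),
    het_kmer_fraction = x$het_kmer_fraction,
    het_estimate = x$het_estimate,
    k = x$k
  )
}

#' Tidy a composition report
#'
#' @param x A `composition_report` from [composition_report()].
#' @param ... Unused.
#' @return For [tidy()]: the per-contig GC table. For [glance()]: a one-row
#'   tibble with the species-level summary values.
#' @export
tidy.composition_report <- function(x, ...) {
  x$contig_gc
}

#' @rdname tidy.composition_report
#' @export
glance.composition_report <- function(x, ...) {
  tibble::tibble(
    species_id = x$species_id,
    genome_gc = x$genome_gc,
    n_contigs = nrow(x$contig_gc),
    cds_gc = x$cds_gc,
    gc3 = x$gc3,
    n_cds = x$n_cds,
    n_partial_codons_trimmed = x$n_partial_codons_trimmed
  )
}
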
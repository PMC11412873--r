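# Base composition: genome GC, per-contig GC distributions, coding-sequence
# GC and third-codon-position GC3, plus ANOVA/Tukey group comparisons of any
# per-species metric.

#' GC content of sequences
#'
#' Fraction (G + C) / (A + C + G + T). Ambiguity codes (including N) are
#' excluded from both numerator and denominator, so assemblies with gap
#' characters are not biased downward.
#'
#' @param seq Character vector of sequences.
#' @return Numeric vector of GC fractions in \[0, 1\].
#' @examples
#' gc_content(c("ACGT", "NNGC")) # 0.5, 1.0
#' @export
gc_content <- function(seq) {
  if (!is.character(seq) || length(seq) == 0L) {
    abort_argument("`seq` must be a non-empty character vector.")
  }
  gc <- stringi::stri_count_regex(seq, "[GCgc]")
  acgt <- stringi::stri_count_regex(seq, "[ACGTacgt]")
  if (any(acgt == 0L)) {
    abort_degenerate(sprintf(
      "sequence %d has no unambiguous A/C/G/T base.", which(acgt == 0L)[1L]
    ))
  }
  gc / acgt
}

#' Per-contig GC content of an assembly
#'
#' @param assembly Record tibble from [read_fasta()] or the simulators.
#' @return A tibble with columns `contig`, `length`, `gc`, one row per record.
#' @export
per_contig_gc <- function(assembly) {
  if (!is.data.frame(assembly) || nrow(assembly) == 0L) {
    abort_argument("`assembly` must be a non-empty record tibble.")
  }
  tibble::tibble(
    contig = assembly$id,
    length = nchar(assembly$seq),
    gc = gc_content(assembly$seq)
  )
}

#' Binned histogram of per-contig GC values
#'
#' Bins are half-open `[low, high)` of width `binwidth` starting at 0; the
#' top bin is closed so gc = 1 is included. Fractions are of contigs, not bp.
#'
#' @param contig_gc Output of [per_contig_gc()].
#' @param binwidth Bin width as a GC fraction (default 0.02, i.e. 2
#'   percentage points).
#' @return A tibble with columns `bin_low`, `bin_high`, `n`, `fraction`.
#' @export
gc_histogram <- function(contig_gc, binwidth = 0.02) {
  check_scalar_number(binwidth, "binwidth", lower = 0, upper = 1, lower_open = TRUE)
  n_bins <- ceiling(1 / binwidth)
  idx <- pmin(floor(contig_gc$gc / binwidth), n_bins - 1L)
  tab <- tabulate(idx + 1L, nbins = n_bins)
  tibble::tibble(
    bin_low = (seq_len(n_bins) - 1L) * binwidth,
    bin_high = pmin(seq_len(n_bins) * binwidth, 1),
    n = tab,
    fraction = tab / nrow(contig_gc)
  )
}

#' Pooled genome GC content
#'
#' GC over all unambiguous bases of every contig pooled together; equal to
#' the length-weighted mean of per-contig GC (weights = unambiguous base
#' counts).
#'
#' @param assembly Record tibble.
#' @return A single GC fraction.
#' @export
genome_gc <- function(assembly) {
  gc <- sum(stringi::stri_count_regex(assembly$seq, "[GCgc]"))
  acgt <- sum(stringi::stri_count_regex(assembly$seq, "[ACGTacgt]"))
  if (acgt == 0L) abort_degenerate("assembly has no unambiguous base.")
  gc / acgt
}

#' Coding-sequence GC and third-codon-position GC3
#'
#' Trailing partial codons (length not a multiple of 3) are trimmed with a
#' warning and counted; records shorter than one codon after trimming are
#' skipped with a warning. `cds_gc` is the pooled GC over all retained codon
#' bases; `gc3` is the pooled fraction of G/C among third-codon positions
#' across all sequences (pooled over codons, as codon-usage tools report it,
#' not averaged per gene). Stop codons are not excluded. With
#' `per_gene = TRUE` a per-record table is attached.
#'
#' @param cds Record tibble of in-frame coding sequences.
#' @param per_gene Also return per-record GC/GC3?
#' @return A list with `cds_gc`, `gc3`, `n_cds`, `n_partial_codons_trimmed`,
#'   and (if requested) `per_gene` (tibble `id`, `gc`, `gc3`).
#' @examples
#' cds_gc_and_gc3(tibble::tibble(id = "g1", seq = "ATGGCC"))
#' @export
cds_gc_and_gc3 <- function(cds, per_gene = FALSE) {
  if (!is.data.frame(cds) || nrow(cds) == 0L) {
    abort_argument("`cds` must be a non-empty record tibble.")
  }
  seqs <- toupper(cds$seq)
  len <- nchar(seqs)
  keep_len <- len - (len %% 3L)
  n_partial <- sum(len %% 3L != 0L)
  if (n_partial > 0L) {
    warning(sprintf("%d sequence(s) had a trailing partial codon trimmed.", n_partial),
            call. = FALSE)
  }
  usable <- keep_len >= 3L
  if (any(!usable)) {
    warning(sprintf("%d sequence(s) shorter than one codon were skipped.", sum(!usable)),
            call. = FALSE)
  }
  if (!any(usable)) {
    abort_degenerate("no coding sequence of at least one codon remains.")
  }
  trimmed <- substr(seqs[usable], 1L, keep_len[usable])

  third_of <- function(s) {
    n <- nchar(s)
    pos <- seq.int(3L, n, by = 3L)
    paste(substring(s, pos, pos), collapse = "")
  }
  thirds <- vapply(trimmed, third_of, character(1), USE.NAMES = FALSE)

  pooled_gc <- function(x) {
    gc <- sum(stringi::stri_count_regex(x, "[GC]"))
    acgt <- sum(stringi::stri_count_regex(x, "[ACGT]"))
    if (acgt == 0L) abort_degenerate("no unambiguous base in coding sequences.")
    gc / acgt
  }
  out <- list(
    cds_gc = pooled_gc(trimmed),
    gc3 = pooled_gc(thirds),
    n_cds = sum(usable),
    n_partial_codons_trimmed = n_partial
  )
  if (per_gene) {
    out$per_gene <- tibble::tibble(
      id = cds$id[usable],
      gc = vapply(trimmed, pooled_gc, numeric(1), USE.NAMES = FALSE),
      gc3 = vapply(thirds, pooled_gc, numeric(1), USE.NAMES = FALSE)
    )
  }
  out
}

#' Full composition report for one species
#'
#' @param assembly Record tibble of the genome assembly.
#' @param cds Optional record tibble of coding sequences.
#' @param species_id Label carried into the report.
#' @return A `composition_report` list: `species_id`, `genome_gc`,
#'   `contig_gc` (tibble), and, when `cds` is given, `cds_gc`, `gc3`,
#'   `n_cds`, `n_partial_codons_trimmed`.
#' @export
composition_report <- function(assembly, cds = NULL, species_id = "species") {
  rep <- list(
    species_id = species_id,
    genome_gc = genome_gc(assembly),
    contig_gc = per_contig_gc(assembly),
    cds_gc = NA_real_, gc3 = NA_real_,
    n_cds = 0L, n_partial_codons_trimmed = 0L
  )
  if (!is.null(cds)) {
    cg <- cds_gc_and_gc3(cds)
    rep[c("cds_gc", "gc3", "n_cds", "n_partial_codons_trimmed")] <-
      cg[c("cds_gc", "gc3", "n_cds", "n_partial_codons_trimmed")]
  }
  structure(rep, class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("<composition_report> %s\n", x$species_id))
  cat(sprintf("  genome GC: %.4f over %d contig(s)\n",
              x$genome_gc, nrow(x$contig_gc)))
  if (!is.na(x$cds_gc)) {
    cat(sprintf("  CDS GC: %.4f  GC3: %.4f  (%d CDS, %d partial codon(s) trimmed)\n",
                x$cds_gc, x$gc3, x$n_cds, x$n_partial_codons_trimmed))
  }
  invisible(x)
}

# Shared scaffolding for the one-way layout: returns per-group values plus
# the classical sums of squares.
oneway_layout <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  if (anyNA(v) || anyNA(g)) abort_argument("missing values in `value` or `group`.")
  sizes <- table(g)
  if (length(sizes) < 2L) abort_argument("need at least 2 groups.")
  if (any(sizes < 2L)) {
    abort_argument(sprintf("group '%s' has fewer than 2 values.",
                           names(sizes)[which(sizes < 2L)[1L]]))
  }
  df <- data.frame(value = v, group = factor(g))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  list(
    fit = fit,
    df = df,
    means = tapply(v, g, mean),
    sizes = as.integer(sizes),
    group_names = names(sizes),
    ss_between = tab[["Sum Sq"]][1L],
    ss_within = tab[["Sum Sq"]][2L],
    df_between = tab[["Df"]][1L],
    df_within = tab[["Df"]][2L]
  )
}

#' One-way ANOVA of a per-species metric across groups
#'
#' Classical one-way ANOVA, F = MS_between / MS_within, with p from the F
#' distribution. A within-group mean square of exactly zero with non-zero
#' between-group spread yields `F = Inf`, `p = 0`; all-identical data yield
#' `F = 0`, `p = 1`.
#'
#' @param data Data frame with one row per species.
#' @param value,group Columns (tidy-eval) holding the metric and the group
#'   label.
#' @return A `group_comparison` object; see [tidy()]/[glance()] methods.
#' @examples
#' d <- tibble::tibble(gc = c(1, 2, 3, 2, 3, 4, 10, 11, 12),
#'                     grp = rep(c("a", "b", "c"), each = 3))
#' glance(anova_oneway(d, gc, grp))
#' @export
anova_oneway <- function(data, value, group) {
  lay <- oneway_layout(data, {{ value }}, {{ group }})
  ms_b <- lay$ss_between / lay$df_between
  ms_w <- lay$ss_within / lay$df_within
  # guard against pure floating-point residue in an exactly degenerate layout
  if (ms_w <= 1e-12 * max(ms_b, 1)) ms_w <- 0
  if (ms_w > 0) {
    F_stat <- ms_b / ms_w
    p <- stats::pf(F_stat, lay$df_between, lay$df_within, lower.tail = FALSE)
  } else if (ms_b > 0) {
    F_stat <- Inf
    p <- 0
  } else {
    F_stat <- 0
    p <- 1
  }
  structure(
    list(
      metric = rlang::as_name(rlang::enquo(value)),
      group_means = tibble::tibble(group = lay$group_names,
                                   mean = as.numeric(lay$means[lay$group_names]),
                                   n = lay$sizes),
      F = F_stat, df_between = lay$df_between, df_within = lay$df_within,
      p = p, tukey = NULL
    ),
    class = "group_comparison"
  )
}

#' Tukey HSD all-pairs comparison of group means
#'
#' Tukey-Kramer honest significant differences via [stats::TukeyHSD()] on the
#' one-way fit: adjusted p-values come from the studentized-range
#' distribution with (k groups, within-group df). When the within-group mean
#' square is exactly zero the studentized range degenerates; pairs with equal
#' means then get adjusted p = 1 and unequal means p = 0.
#'
#' @inheritParams anova_oneway
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `group_comparison` object whose `tukey` element is a tibble
#'   (`group_a`, `group_b`, `mean_diff`, `adjusted_p`, `significant`);
#'   `mean_diff` is mean(group_b) - mean(group_a).
#' @export
tukey_hsd <- function(data, value, group, alpha = 0.05) {
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      lower_open = TRUE, upper_open = TRUE)
  cmp <- anova_oneway(data, {{ value }}, {{ group }})
  lay <- oneway_layout(data, {{ value }}, {{ group }})
  ms_w <- lay$ss_within / lay$df_within
  ms_b <- lay$ss_between / lay$df_between
  if (ms_w <= 1e-12 * max(ms_b, 1)) ms_w <- 0
  pairs <- utils::combn(lay$group_names, 2L)
  if (ms_w > 0) {
    th <- stats::TukeyHSD(lay$fit)$group
    key <- rownames(th)
    tuk <- tibble::tibble(
      group_b = sub("-.*$", "", key),
      group_a = sub("^[^-]*-", "", key),
      mean_diff = unname(th[, "diff"]),
      adjusted_p = unname(th[, "p adj"])
    )
  } else {
    means <- lay$means
    tuk <- tibble::tibble(
      group_a = pairs[1L, ],
      group_b = pairs[2L, ],
      mean_diff = as.numeric(means[pairs[2L, ]] - means[pairs[1L, ]]),
      adjusted_p = ifelse(means[pairs[2L, ]] == means[pairs[1L, ]], 1, 0)
    )
  }
  tuk <- dplyr::select(tuk, "group_a", "group_b", "mean_diff", "adjusted_p")
  tuk$significant <- tuk$adjusted_p < alpha
  cmp$tukey <- tuk
  cmp$alpha <- alpha
  cmp
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> metric: %s\n", x$metric))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  if (!is.null(x$tukey)) {
    sig <- sum(x$tukey$significant)
    cat(sprintf("  Tukey HSD: %d of %d pairs significant at alpha = %g\n",
                sig, nrow(x$tukey), x$alpha))
  }
  invisible(x)
}
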
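# Sliding-window RIP (repeat-induced point mutation) analysis. RIP converts
# C to T preferentially at CpA, leaving a dinucleotide signature read off
# three indices per window:
#   product   = TpA / ApT                  (raised: RIP creates TpA)
#   substrate = (CpA + TpG) / (ApC + GpT)  (lowered: RIP consumes CpA/TpG)
#   composite = product - substrate        (positive under RIP)

RIP_DINUCS <- c("TpA", "ApT", "CpA", "TpG", "ApC", "GpT")

#' Count the six RIP-relevant dinucleotides
#'
#' Overlapping forward-strand dinucleotides; any pair containing a
#' non-A/C/G/T character is skipped.
#'
#' @param seq A single sequence string of length >= 2.
#' @return Named integer vector with elements TpA, ApT, CpA, TpG, ApC, GpT.
#' @examples
#' dinucleotide_counts("TACATG")
#' @export
dinucleotide_counts <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L) {
    abort_argument("`seq` must be a single string.")
  }
  if (nchar(seq) < 2L) {
    abort_degenerate("sequence shorter than 2 bp has no dinucleotides.")
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  a <- chars[-length(chars)]
  b <- chars[-1L]
  c(
    TpA = sum(a == "T" & b == "A"),
    ApT = sum(a == "A" & b == "T"),
    CpA = sum(a == "C" & b == "A"),
    TpG = sum(a == "T" & b == "G"),
    ApC = sum(a == "A" & b == "C"),
    GpT = sum(a == "G" & b == "T")
  )
}

#' RIP indices from dinucleotide counts
#'
#' A zero denominator sets that index to 0 and flags the window, which forces
#' it RIP-negative downstream (a conservative convention for degenerate
#' windows).
#'
#' @param counts Named vector or one-row data frame with the six counts of
#'   [dinucleotide_counts()].
#' @return A one-row tibble: `product`, `substrate`, `composite`,
#'   `denom_zero`.
#' @export
rip_indices <- function(counts) {
  counts <- unlist(counts)[RIP_DINUCS]
  if (anyNA(counts) || any(counts < 0)) {
    abort_argument("`counts` must contain non-negative TpA, ApT, CpA, TpG, ApC, GpT.")
  }
  prod_denom <- counts[["ApT"]]
  sub_denom <- counts[["ApC"]] + counts[["GpT"]]
  product <- if (prod_denom > 0) counts[["TpA"]] / prod_denom else 0
  substrate <- if (sub_denom > 0) (counts[["CpA"]] + counts[["TpG"]]) / sub_denom else 0
  tibble::tibble(
    product = product,
    substrate = substrate,
    composite = product - substrate,
    denom_zero = prod_denom == 0 || sub_denom == 0
  )
}

#' Sliding-window RIP scan of an assembly
#'
#' Full windows of `window` bp at starts 0, `step`, 2*`step`, ... while
#' `start + window <= contig length`; contigs shorter than one window yield a
#' single whole-contig window flagged `short`. A window is RIP-positive iff
#' all three indices indicate RIP: `product > product_min`,
#' `substrate < substrate_max` and `composite > composite_min` (all strict),
#' and no index denominator was zero.
#'
#' @param assembly Record tibble (`id`, `seq`).
#' @param window,step Window and step sizes in bp (defaults 1000/500).
#' @param product_min,substrate_max,composite_min RIP-positive thresholds
#'   (defaults 1.15, 0.75, 0).
#' @return A tibble of windows: `contig`, `start`, `end` (0-based,
#'   half-open), the six dinucleotide counts, `product`, `substrate`,
#'   `composite`, `gc`, `short`, `rip_positive`.
#' @export
scan_rip_windows <- function(assembly, window = 1000L, step = 500L,
                             product_min = 1.15, substrate_max = 0.75,
                             composite_min = 0) {
  if (!is.data.frame(assembly) || nrow(assembly) == 0L) {
    abort_argument("`assembly` must be a non-empty record tibble.")
  }
  check_scalar_number(window, "window", lower = 2)
  check_scalar_number(step, "step", lower = 1, upper = window)

  scan_contig <- function(id, seq) {
    len <- nchar(seq)
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    a <- chars[-len]
    b <- chars[-1L]
    # zero-prefixed cumulative counts; pair i covers bases i, i+1 (1-based)
    cums <- list(
      TpA = c(0L, cumsum(a == "T" & b == "A")),
      ApT = c(0L, cumsum(a == "A" & b == "T")),
      CpA = c(0L, cumsum(a == "C" & b == "A")),
      TpG = c(0L, cumsum(a == "T" & b == "G")),
      ApC = c(0L, cumsum(a == "A" & b == "C")),
      GpT = c(0L, cumsum(a == "G" & b == "T"))
    )
    cum_gc <- c(0L, cumsum(chars %in% c("G", "C")))
    cum_acgt <- c(0L, cumsum(chars %in% c("A", "C", "G", "T")))

    if (len >= window) {
      starts <- seq.int(0L, len - window, by = step)
      ends <- starts + window
      short <- FALSE
    } else {
      starts <- 0L
      ends <- len
      short <- TRUE
    }
    # pairs fully inside [s, e) are pair indices s+1 .. e-1
    pair_count <- function(cum, s, e) cum[e] - cum[s + 1L]
    counts <- lapply(cums, pair_count, s = starts, e = ends)
    gc_n <- cum_gc[ends + 1L] - cum_gc[starts + 1L]
    acgt_n <- cum_acgt[ends + 1L] - cum_acgt[starts + 1L]

    prod_denom <- counts$ApT
    sub_denom <- counts$ApC + counts$GpT
    product <- ifelse(prod_denom > 0, counts$TpA / prod_denom, 0)
    substrate <- ifelse(sub_denom > 0, (counts$CpA + counts$TpG) / sub_denom, 0)
    composite <- product - substrate
    denom_zero <- prod_denom == 0 | sub_denom == 0

    tibble::tibble(
      contig = id, start = starts, end = ends,
      TpA = counts$TpA, ApT = counts$ApT, CpA = counts$CpA,
      TpG = counts$TpG, ApC = counts$ApC, GpT = counts$GpT,
      product = product, substrate = substrate, composite = composite,
      gc = ifelse(acgt_n > 0, gc_n / acgt_n, NA_real_),
      short = short,
      rip_positive = !denom_zero &
        product > product_min &
        substrate < substrate_max &
        composite > composite_min
    )
  }

  purrr::map2(assembly$id, assembly$seq, scan_contig) |>
    dplyr::bind_rows()
}

#' Merge RIP-positive windows into regions and call LRARs
#'
#' On each contig, maximal runs of consecutive RIP-positive windows are
#' merged by union into one region `[first.start, last.end)`. Regions longer
#' than `lrar_min_len` bp (strict) are large RIP-affected regions (LRARs);
#' each region's `mean_composite` is the unweighted mean of its member
#' windows' composite index.
#'
#' @param windows Output of [scan_rip_windows()], sorted by (contig, start).
#' @param lrar_min_len Minimum LRAR length bound in bp (default 4000,
#'   exclusive).
#' @return A list with `regions` and `lrars` tibbles (`contig`, `start`,
#'   `end`, `length`, `n_windows`, `mean_composite`).
#' @export
call_rip_regions <- function(windows, lrar_min_len = 4000L) {
  check_scalar_number(lrar_min_len, "lrar_min_len", lower = 0)
  if (nrow(windows) > 0L) {
    ord <- order(windows$contig, windows$start)
    if (!identical(ord, seq_len(nrow(windows)))) {
      abort_argument("`windows` must be sorted by (contig, start).")
    }
  }
  empty <- tibble::tibble(contig = character(), start = integer(),
                          end = integer(), length = integer(),
                          n_windows = integer(), mean_composite = double())
  if (nrow(windows) == 0L || !any(windows$rip_positive)) {
    return(list(regions = empty, lrars = empty))
  }
  regions <- windows |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(.run = cumsum(!.data$rip_positive)) |>
    dplyr::filter(.data$rip_positive) |>
    dplyr::group_by(.data$contig, .data$.run) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_windows = dplyr::n(),
      mean_composite = mean(.data$composite),
      .groups = "drop"
    ) |>
    dplyr::mutate(length = .data$end - .data$start) |>
    dplyr::select("contig", "start", "end", "length", "n_windows", "mean_composite") |>
    dplyr::arrange(.data$contig, .data$start)
  lrars <- dplyr::filter(regions, .data$length > lrar_min_len)
  list(regions = regions, lrars = lrars)
}

# Union length of possibly overlapping [start, end) intervals on one contig.
interval_union_bp <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  total <- 0L
  cur_s <- start[1L]
  cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]
      cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Genome-wide RIP summary
#'
#' RIP-affected bases are the union of RIP-positive window regions (no
#' double counting of overlap), so `genome_rip_percent` can never exceed
#' 100.
#'
#' @param assembly Record tibble the windows were scanned from.
#' @param regions,lrars Output of [call_rip_regions()].
#' @return A `rip_summary` object: `genome_rip_percent`, `total_rip_bp`,
#'   `genome_bp`, `n_regions`, `lrars`, `lrar_mean_composite` (NA when there
#'   is no LRAR).
#' @export
summarize_rip <- function(assembly, regions, lrars) {
  genome_bp <- sum(nchar(assembly$seq))
  total_rip_bp <- if (nrow(regions) == 0L) 0L else {
    sum(vapply(split(regions, regions$contig), function(r) {
      interval_union_bp(r$start, r$end)
    }, numeric(1)))
  }
  structure(
    list(
      genome_rip_percent = 100 * total_rip_bp / genome_bp,
      total_rip_bp = as.integer(total_rip_bp),
      genome_bp = as.integer(genome_bp),
      n_regions = nrow(regions),
      lrars = lrars,
      lrar_mean_composite = if (nrow(lrars) > 0L) mean(lrars$mean_composite) else NA_real_
    ),
    class = "rip_summary"
  )
}

#' @export
print.rip_summary <- function(x, ...) {
  cat("<rip_summary>\n")
  cat(sprintf("  genome-wide RIP: %.2f%% (%d of %d bp in %d region(s))\n",
              x$genome_rip_percent, x$total_rip_bp, x$genome_bp, x$n_regions))
  if (nrow(x$lrars) > 0L) {
    cat(sprintf("  LRARs: %d, mean composite %.3f\n",
                nrow(x$lrars), x$lrar_mean_composite))
  } else {
    cat("  LRARs: none\n")
  }
  invisible(x)
}

#' Write RIP regions as a BED file
#'
#' 0-based, half-open intervals with the region's mean composite index as
#' the score column.
#'
#' @param regions Region tibble from [call_rip_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rip_bed <- function(regions, path) {
  bed <- tibble::tibble(
    chrom = regions$contig,
    chromStart = regions$start,
    chromEnd = regions$end,
    mean_composite = signif(regions$mean_composite, 6)
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
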
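# Canonical k-mer spectra and ploidy diagnostics. A diploid (or dikaryotic)
# genome shows a bimodal depth spectrum: homozygous k-mers peak at the full
# coverage c, heterozygous (haplotype-unique) k-mers at c/2.

#' Count canonical k-mers
#'
#' Every length-k window over A/C/G/T is counted under its canonical form,
#' the lexicographic minimum of the k-mer and its reverse complement, making
#' counts strand-independent. Windows containing any non-A/C/G/T character
#' are skipped. Odd k only: canonical form would be ill-defined for
#' reverse-complement-palindromic even-length k-mers.
#'
#' @param seqs Character vector of sequences, or a record tibble with a
#'   `seq` column.
#' @param k Odd k-mer size, 3..63 (default 31).
#' @return A tibble with columns `kmer`, `count`, sorted by `kmer`;
#'   attribute `k`.
#' @examples
#' count_canonical_kmers("ACGTA", k = 3) # ACG x2 (CGT canonicalises to ACG), GTA x1
#' @export
count_canonical_kmers <- function(seqs, k = 31L) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (!is.character(seqs) || length(seqs) == 0L) {
    abort_argument("`seqs` must be sequences or a record tibble.")
  }
  if (k %% 2 == 0) {
    abort_argument("`k` must be odd (canonical form is ill-defined for even k).")
  }
  check_scalar_number(k, "k", lower = 3, upper = 63)
  seqs <- toupper(seqs)

  window_kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    starts <- seq_len(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    km[!stringi::stri_detect_regex(km, "[^ACGT]")]
  }
  fwd <- unlist(lapply(seqs, window_kmers), use.names = FALSE)
  if (length(fwd) == 0L) {
    out <- tibble::tibble(kmer = character(), count = integer())
    attr(out, "k") <- as.integer(k)
    return(out)
  }
  canon <- pmin(fwd, reverse_complement(fwd))
  tab <- table(canon)
  out <- tibble::tibble(kmer = names(tab), count = as.integer(tab))
  attr(out, "k") <- as.integer(k)
  out
}

#' Build a k-mer multiplicity/depth histogram
#'
#' @param x Either the count tibble from [count_canonical_kmers()] (bins over
#'   multiplicity) or a numeric vector of per-k-mer depths (bins over depth).
#' @param k Optional k recorded as an attribute (taken from `x` if present).
#' @return A tibble with columns `depth` and `count` (number of distinct
#'   k-mers at that multiplicity/depth), positive depths only, sorted.
#' @export
build_histogram <- function(x, k = NULL) {
  if (is.data.frame(x)) {
    if (is.null(k)) k <- attr(x, "k")
    x <- x$count
  }
  if (!is.numeric(x) || length(x) == 0L) {
    abort_argument("`x` must be non-empty k-mer counts or depths.")
  }
  x <- x[x > 0]
  if (length(x) == 0L) abort_argument("no k-mer with positive multiplicity.")
  tab <- table(x)
  out <- tibble::tibble(depth = as.integer(names(tab)), count = as.integer(tab))
  out <- dplyr::arrange(out, .data$depth)
  attr(out, "k") <- if (is.null(k)) NA_integer_ else as.integer(k)
  out
}

#' Detect peaks in a k-mer spectrum
#'
#' The histogram is placed on a dense depth grid, smoothed with a moving
#' average of halfwidth `smoothing_halfwidth`, and the low-depth noise
#' region — the initial descending flank typical of sequencing-error k-mers —
#' is excluded by truncating below the first local minimum of the smoothed
#' curve (no truncation when the curve starts by rising). Remaining strict
#' local maxima are returned; peaks whose depths differ by less than 25% of
#' their mean depth are merged, keeping the taller.
#'
#' @param hist Histogram tibble (`depth`, `count`) from [build_histogram()].
#' @param smoothing_halfwidth Moving-average halfwidth in depth units
#'   (default 2).
#' @return A tibble with columns `depth`, `height` (smoothed height), sorted
#'   by depth; zero rows when no peak survives (the spectrum is then
#'   ambiguous).
#' @export
detect_peaks <- function(hist, smoothing_halfwidth = 2L) {
  if (!is.data.frame(hist) || nrow(hist) == 0L) {
    abort_argument("`hist` must be a non-empty histogram tibble.")
  }
  check_scalar_number(smoothing_halfwidth, "smoothing_halfwidth", lower = 0)
  h <- as.integer(smoothing_halfwidth)
  max_d <- max(hist$depth)
  y <- numeric(max_d)
  y[hist$depth] <- hist$count
  n <- length(y)
  s <- vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - h):min(n, i + h)])
  }, numeric(1))

  # truncate the initial descending (noise) flank, if any
  lo <- 1L
  if (n >= 2L && s[2L] < s[1L]) {
    j <- 2L
    while (j < n && s[j + 1L] <= s[j]) j <- j + 1L
    lo <- j  # first local minimum of the smoothed curve
  }
  if (n - lo < 2L) {
    return(tibble::tibble(depth = integer(), height = double()))
  }
  idx <- seq.int(max(lo + 1L, 2L), n - 1L)
  is_peak <- s[idx] > s[idx - 1L] & s[idx] > s[idx + 1L]
  peaks <- tibble::tibble(depth = idx[is_peak], height = s[idx[is_peak]])
  if (nrow(peaks) == 0L) return(peaks)

  # merge peaks closer than 25% of their mean depth, keeping the taller
  repeat {
    if (nrow(peaks) < 2L) break
    gaps <- diff(peaks$depth)
    means <- (head(peaks$depth, -1L) + tail(peaks$depth, -1L)) / 2
    close <- which(gaps < 0.25 * means)
    if (length(close) == 0L) break
    i <- close[1L]
    drop <- if (peaks$height[i] >= peaks$height[i + 1L]) i + 1L else i
    peaks <- peaks[-drop, , drop = FALSE]
  }
  dplyr::arrange(peaks, .data$depth)
}

#' Classify spectrum modality and estimate heterozygosity
#'
#' The spectrum is *bimodal* when the two tallest peaks have a depth ratio
#' within `ratio_window` (default \[1.6, 2.4\], bracketing the 2x expected
#' between the heterozygous c/2 peak and the homozygous c peak); *unimodal*
#' with exactly one peak; *ambiguous* otherwise. Under bimodality, each
#' histogram bin is attributed to the nearest of the two peaks, giving the
#' fraction f of distinct k-mers in the heterozygous peak, and per-base
#' heterozygosity is inverted from the k-mer spanning model as
#' `1 - (1 - f/2)^(1/k)`: a k-mer is heterozygous when it overlaps at least
#' one heterozygous site, and the factor 2 accounts for each such locus
#' contributing one unique k-mer set per haplotype. This is a deliberately
#' simple spectrum-reading surrogate (no mixture-model fit), validated
#' against [simulate_diploid_spectrum()]'s generative model only.
#'
#' @param hist Histogram tibble from [build_histogram()].
#' @param k K-mer size; defaults to the histogram's `k` attribute.
#' @param peaks Optional pre-computed peaks from [detect_peaks()].
#' @param ratio_window Depth-ratio window for calling the het/hom peak pair.
#' @return A `ploidy_report` object: `peaks`, `modality` (`"unimodal"`,
#'   `"bimodal"` or `"ambiguous"`), `het_estimate` (NA unless bimodal),
#'   `het_kmer_fraction`, `k`.
#' @export
classify_ploidy <- function(hist, k = attr(hist, "k"), peaks = NULL,
                            ratio_window = c(1.6, 2.4)) {
  if (is.null(k) || is.na(k)) {
    abort_argument("`k` must be supplied (or carried by the histogram).")
  }
  if (is.null(peaks)) peaks <- detect_peaks(hist)
  report <- list(peaks = peaks, modality = "ambiguous",
                 het_estimate = NA_real_, het_kmer_fraction = NA_real_,
                 k = as.integer(k))
  if (nrow(peaks) == 1L) {
    report$modality <- "unimodal"
  } else if (nrow(peaks) >= 2L) {
    two <- peaks |> dplyr::arrange(dplyr::desc(.data$height)) |> head(2L)
    lo <- min(two$depth)
    hi <- max(two$depth)
    ratio <- hi / lo
    if (ratio >= ratio_window[1L] && ratio <= ratio_window[2L]) {
      report$modality <- "bimodal"
      nearest_het <- abs(hist$depth - lo) < abs(hist$depth - hi)
      n_het <- sum(hist$count[nearest_het])
      n_tot <- sum(hist$count)
      f <- n_het / n_tot
      report$het_kmer_fraction <- f
      report$het_estimate <- 1 - (1 - f / 2)^(1 / k)
    }
  }
  structure(report, class = "ploidy_report")
}

#' @export
print.ploidy_report <- function(x, ...) {
  cat(sprintf("<ploidy_report> modality: %s (k = %d)\n", x$modality, x$k))
  if (nrow(x$peaks) > 0L) {
    cat(sprintf("  peaks at depth %s\n",
                paste(x$peaks$depth, collapse = ", ")))
  } else {
    cat("  no peaks detected\n")
  }
  if (!is.na(x$het_estimate)) {
    cat(sprintf("  heterozygous k-mer fraction: %.4f -> per-base heterozygosity: %.4f%%\n",
                x$het_kmer_fraction, 100 * x$het_estimate))
  }
  invisible(x)
}

#' Read/write a depth histogram as two-column TSV
#'
#' @param path File with two tab-separated columns (depth, count), with or
#'   without a header line.
#' @param k K-mer size to record on the returned histogram.
#' @return [read_histogram()]: a histogram tibble; [write_histogram()]:
#'   `path`, invisibly.
#' @export
read_histogram <- function(path, k = NULL) {
  tbl <- readr::read_tsv(path, col_names = c("depth", "count"),
                         col_types = "cc", progress = FALSE)
  if (nrow(tbl) > 0L && !stringr::str_detect(tbl$depth[1L], "^[0-9]+$")) {
    tbl <- tbl[-1L, , drop = FALSE]  # header line
  }
  if (nrow(tbl) == 0L) abort_format("histogram file is empty.")
  out <- tibble::tibble(depth = as.integer(tbl$depth), count = as.integer(tbl$count))
  if (anyNA(out$depth) || anyNA(out$count)) {
    abort_format("histogram file must contain two integer columns (depth, count).")
  }
  out <- dplyr::arrange(out, .data$depth)
  attr(out, "k") <- if (is.null(k)) NA_integer_ else as.integer(k)
  out
}

#' @rdname read_histogram
#' @param hist Histogram tibble.
#' @export
write_histogram <- function(hist, path) {
  readr::write_tsv(hist[, c("depth", "count")], path, progress = FALSE)
  invisible(path)
}
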
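# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Dinucleotide recount by explicit position-by-position loop.
brute_dinucs <- function(seq) {
  n <- nchar(seq)
  out <- c(TpA = 0L, ApT = 0L, CpA = 0L, TpG = 0L, ApC = 0L, GpT = 0L)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    pair <- substr(seq, i, i + 1L)
    key <- switch(pair,
      TA = "TpA", AT = "ApT", CA = "CpA", TG = "TpG", AC = "ApC", GT = "GpT",
      NULL
    )
    if (!is.null(key)) out[key] <- out[key] + 1L
  }
  out
}

# Pearson correlation from the definition.
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# One-way ANOVA F from explicit sums of squares.
brute_anova_F <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1L
  df_w <- length(all_v) - length(groups)
  (ss_b / df_b) / (ss_w / df_w)
}

# Random A/C/G/T sequence outside the package's generators.
random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

# Sequence with exact RIP-relevant dinucleotide counts
# (TpA = a, ApT = b, CpA = cc, TpG = d, ApC = e, GpT = f) and nothing else:
# unit blocks contribute exactly one counted dinucleotide each, and the
# block order plus a CC spacer keeps junctions free of counted pairs.
dinuc_fixture <- function(a, b, cc, d, e, f) {
  paste0(
    strrep("ATCG", b), strrep("ACCG", e), "CC",
    strrep("TAGC", a), strrep("CAGC", cc), strrep("TGCC", d), strrep("GTCC", f)
  )
}

# Minimal hand-built window table for region/LRAR calling tests.
make_windows <- function(contig, starts, window, positive, composite = 1) {
  tibble::tibble(
    contig = contig, start = starts, end = starts + window,
    composite = rep_len(composite, length(starts)),
    rip_positive = positive
  )
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
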
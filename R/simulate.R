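# Seeded generators that plant known signal: the recovery target of the
# package's validation tests. All are pure functions of (arguments, seed).

#' Simulate an orthogroup gene-count matrix with planted shifts
#'
#' Baseline counts are drawn i.i.d. from a negative binomial with mean
#' `baseline_mean` and dispersion `dispersion` (variance = mu + mu^2 /
#' dispersion, the overdispersed regime typical of gene-family counts). For
#' planted-expanded orthogroups the focal group's mean is multiplied by
#' `effect_multiplier` before sampling; for planted-contracted orthogroups it
#' is divided by it.
#'
#' Defaults mirror the validation study design used throughout the package:
#' an 11-species focal (psychrophile) group against a 41-species background,
#' 2000 orthogroups, 50 planted expansions and 50 contractions with a
#' four-fold effect.
#'
#' @param n_orthogroups Number of orthogroups.
#' @param group_sizes Named integer vector of species counts per group; the
#'   first name is the focal group unless `focal_group` says otherwise.
#' @param baseline_mean,dispersion Negative-binomial mean and dispersion.
#' @param n_expanded,n_contracted Numbers of planted expanded/contracted
#'   orthogroups (disjoint, chosen at random).
#' @param effect_multiplier Multiplicative effect size (> 1).
#' @param focal_group Group receiving the planted effects.
#' @param seed Integer seed; identical arguments and seed give identical output.
#' @return A list with `counts` (tibble: `orthogroup` + one integer column per
#'   species), `groups` (tibble: `species`, `group`) and `truth` (a
#'   `synthetic_truth` list recording `planted_expanded`, `planted_contracted`,
#'   `effect_multiplier` and `seed`).
#' @examples
#' sim <- simulate_count_matrix(n_orthogroups = 200, seed = 1)
#' sim$counts
#' @export
simulate_count_matrix <- function(n_orthogroups = 2000,
                                  group_sizes = c(psychrophile = 11, non_psychrophile = 41),
                                  baseline_mean = 3,
                                  dispersion = 2,
                                  n_expanded = 50,
                                  n_contracted = 50,
                                  effect_multiplier = 4,
                                  focal_group = names(group_sizes)[1L],
                                  seed = 1) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    abort_argument("`group_sizes` must be a named vector of species counts.")
  }
  if (any(group_sizes < 2)) {
    abort_argument("every group needs at least 2 species.")
  }
  if (!focal_group %in% names(group_sizes)) {
    abort_argument(sprintf("focal group '%s' is not in `group_sizes`.", focal_group))
  }
  check_scalar_number(n_orthogroups, "n_orthogroups", lower = 1)
  check_scalar_number(baseline_mean, "baseline_mean", lower = 0, lower_open = TRUE)
  check_scalar_number(dispersion, "dispersion", lower = 0, lower_open = TRUE)
  check_scalar_number(effect_multiplier, "effect_multiplier", lower = 1, lower_open = TRUE)
  if (n_expanded + n_contracted > n_orthogroups) {
    abort_argument("n_expanded + n_contracted exceeds n_orthogroups.")
  }

  groups_tbl <- tibble::tibble(
    species = unlist(lapply(names(group_sizes), function(g) {
      sprintf("%s_%02d", g, seq_len(group_sizes[[g]]))
    }), use.names = FALSE),
    group = rep(names(group_sizes), times = group_sizes)
  )
  og_ids <- sprintf("OG%07d", seq_len(n_orthogroups))

  with_seed_or_inherit(seed, {
    planted <- sample(og_ids, n_expanded + n_contracted)
    expanded <- sort(planted[seq_len(n_expanded)])
    contracted <- sort(planted[n_expanded + seq_len(n_contracted)])

    mu <- matrix(baseline_mean, nrow = n_orthogroups, ncol = nrow(groups_tbl),
                 dimnames = list(og_ids, groups_tbl$species))
    focal_cols <- groups_tbl$group == focal_group
    mu[expanded, focal_cols] <- baseline_mean * effect_multiplier
    mu[contracted, focal_cols] <- baseline_mean / effect_multiplier

    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = dispersion),
      nrow = n_orthogroups, dimnames = dimnames(mu)
    )

    truth <- structure(
      list(planted_expanded = expanded, planted_contracted = contracted,
           effect_multiplier = effect_multiplier, seed = seed),
      class = "synthetic_truth"
    )
    list(
      counts = dplyr::bind_cols(tibble::tibble(orthogroup = og_ids),
                                as_tibble(counts)),
      groups = groups_tbl,
      truth = truth
    )
  })
}

#' Simulate a random genome sequence with a target GC content
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param length Sequence length in bp.
#' @param gc Target GC fraction in \[0, 1\].
#' @param seed Integer seed, or `NULL` to draw from the RNG stream in scope.
#' @param id Record id for the returned contig.
#' @return A one-row tibble with columns `id`, `description`, `seq`.
#' @export
simulate_genome <- function(length, gc = 0.5, seed = NULL, id = "contig_1") {
  check_scalar_number(length, "length", lower = 1)
  check_scalar_number(gc, "gc", lower = 0, upper = 1)
  with_seed_or_inherit(seed, {
    bases <- sample(c("A", "T", "G", "C"), size = length, replace = TRUE,
                    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
    tibble::tibble(id = id,
                   description = sprintf("synthetic length=%d gc=%g", as.integer(length), gc),
                   seq = paste(bases, collapse = ""))
  })
}

#' Apply RIP-style C-to-T mutation to a sequence
#'
#' Repeat-induced point mutation introduces C-to-T transitions preferentially
#' at CpA dinucleotides (the canonical Neurospora context). In a single
#' left-to-right pass over the *original* sequence, the C of every
#' forward-strand CpA is replaced by T with probability `rate`, and the G of
#' every forward-strand TpG (the reverse-strand CpA) is replaced by A with the
#' same probability. Contexts are determined once on the input, so mutations
#' never cascade into newly created contexts and the result is
#' order-independent.
#'
#' @param seq A single A/C/G/T string (no ambiguity codes).
#' @param rate Per-site mutation probability in \[0, 1\].
#' @param seed Integer seed, or `NULL` to use the RNG stream in scope.
#' @return The mutated sequence (same length).
#' @examples
#' rip_mutate("CACA", rate = 1, seed = 1) # "TATA"
#' @export
rip_mutate <- function(seq, rate, seed = NULL) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort_argument("`seq` must be a single character string.")
  }
  check_dna(seq)
  check_scalar_number(rate, "rate", lower = 0, upper = 1)
  n <- nchar(seq)
  if (n < 2L || rate == 0) {
    return(seq)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  a <- chars[-n]
  b <- chars[-1L]
  cpa_c <- which(a == "C" & b == "A")          # mutate the C (position i)
  tpg_g <- which(a == "T" & b == "G") + 1L     # mutate the G (position i + 1)
  with_seed_or_inherit(seed, {
    hit_c <- cpa_c[stats::runif(length(cpa_c)) < rate]
    hit_g <- tpg_g[stats::runif(length(tpg_g)) < rate]
    chars[hit_c] <- "T"
    chars[hit_g] <- "A"
    paste(chars, collapse = "")
  })
}

#' Simulate a genome carrying RIP-mutated repeat regions
#'
#' Generates a background genome with [simulate_genome()], places
#' `n_regions` non-overlapping intervals of `region_length` bp uniformly at
#' random, and passes each through [rip_mutate()] at the given rate. The
#' planted intervals are recorded in the returned truth object (0-based,
#' half-open), giving the recovery target for the RIP scanner.
#'
#' Defaults match the package's planted-RIP validation design: two 8-kb
#' regions mutated at rate 0.9 inside a 200-kb genome of 55% GC.
#'
#' @param length Genome length in bp.
#' @param gc Background GC fraction.
#' @param n_regions,region_length Number and size of planted repeat regions.
#' @param rate RIP mutation rate within regions.
#' @param seed Integer seed.
#' @return A list with `genome` (one-row record tibble) and `truth`
#'   (`synthetic_truth` with `rip_intervals`, `rip_rate`, `seed`).
#' @export
simulate_ripped_genome <- function(length = 2e5, gc = 0.55, n_regions = 2,
                                   region_length = 8000, rate = 0.9, seed = 1) {
  check_scalar_number(n_regions, "n_regions", lower = 0)
  if (n_regions > 0) check_scalar_number(region_length, "region_length", lower = 1)
  check_scalar_number(rate, "rate", lower = 0, upper = 1)
  if (n_regions * region_length > length / 2) {
    abort_argument("planted regions exceed half the genome; infeasible packing.")
  }
  with_seed_or_inherit(seed, {
    genome <- simulate_genome(length, gc = gc, seed = NULL)
    seq <- genome$seq
    if (n_regions > 0) {
      free <- length - n_regions * region_length
      gaps <- sort(sample.int(free + 1L, n_regions, replace = TRUE) - 1L)
      starts0 <- gaps + (seq_len(n_regions) - 1L) * region_length  # 0-based
      for (s0 in starts0) {
        piece <- substr(seq, s0 + 1L, s0 + region_length)
        mut <- rip_mutate(piece, rate = rate, seed = NULL)
        substr(seq, s0 + 1L, s0 + region_length) <- mut
      }
      intervals <- tibble::tibble(contig = genome$id, start = starts0,
                                  end = starts0 + region_length)
    } else {
      intervals <- tibble::tibble(contig = character(), start = integer(),
                                  end = integer())
    }
    genome$seq <- seq
    truth <- structure(
      list(rip_intervals = intervals, rip_rate = rate, seed = seed),
      class = "synthetic_truth"
    )
    list(genome = genome, truth = truth)
  })
}

#' Simulate coding sequences with a target third-position GC (GC3)
#'
#' Each record is `n_codons` codons long. First and second codon positions
#' are uniform over A/C/G/T; third positions are G or C with total
#' probability `gc3_target` (split evenly) and A or T otherwise. These are
#' composition fixtures, not genes: no stop-codon avoidance is attempted.
#'
#' @param n Number of sequences.
#' @param n_codons Codons per sequence.
#' @param gc3_target Target third-position GC fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return A tibble of records (`id`, `description`, `seq`).
#' @export
simulate_cds <- function(n = 100, n_codons = 300, gc3_target = 0.6, seed = 1) {
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(n_codons, "n_codons", lower = 1)
  check_scalar_number(gc3_target, "gc3_target", lower = 0, upper = 1)
  with_seed_or_inherit(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      p12 <- sample(c("A", "C", "G", "T"), size = 2L * n_codons, replace = TRUE)
      p3 <- sample(c("G", "C", "A", "T"), size = n_codons, replace = TRUE,
                   prob = c(gc3_target / 2, gc3_target / 2,
                            (1 - gc3_target) / 2, (1 - gc3_target) / 2))
      codons <- paste0(p12[c(TRUE, FALSE)], p12[c(FALSE, TRUE)], p3)
      paste(codons, collapse = "")
    }, character(1))
    tibble::tibble(
      id = sprintf("cds_%04d", seq_len(n)),
      description = sprintf("synthetic gc3=%g", gc3_target),
      seq = seqs
    )
  })
}

#' Simulate a diploid canonical k-mer depth spectrum
#'
#' Haplotype A is simulated with [simulate_genome()]; haplotype B is A with
#' i.i.d. substitutions at rate `het_rate` (to a uniformly chosen different
#' base). Canonical k-mers are counted over both haplotypes, so a k-mer is
#' shared (multiplicity 2) unless a window overlaps a heterozygous site.
#' Each distinct k-mer with multiplicity m receives an observed depth drawn
#' from Poisson(m * coverage / 2); depth-0 k-mers are dropped. The model is
#' k-mer-level only — no reads, no sequencing error — which is sufficient to
#' exercise peak detection and heterozygosity inversion.
#'
#' @param genome_length Haplotype length in bp.
#' @param het_rate Per-base heterozygosity in \[0, 0.1).
#' @param coverage Total (diploid) depth of the homozygous peak.
#' @param k Odd k-mer size, 11..63.
#' @param gc Background GC of haplotype A.
#' @param seed Integer seed.
#' @return A list with `histogram` (tibble `depth`, `count`, attribute `k`),
#'   `hap_a`/`hap_b` (strings) and `truth` (`synthetic_truth` with
#'   `het_rate`, `het_positions`, `coverage`, `k`, `seed`).
#' @export
simulate_diploid_spectrum <- function(genome_length = 2e5, het_rate = 0.01,
                                      coverage = 40, k = 21, gc = 0.5,
                                      seed = 1) {
  check_scalar_number(genome_length, "genome_length", lower = 1)
  if (!is.numeric(het_rate) || het_rate < 0 || het_rate >= 0.1) {
    abort_argument("`het_rate` must be in [0, 0.1); the two-peak model breaks above that.")
  }
  check_scalar_number(coverage, "coverage", lower = 0, lower_open = TRUE)
  if (k %% 2 == 0 || k < 11 || k > 63) {
    abort_argument("`k` must be odd and in 11..63.")
  }
  with_seed_or_inherit(seed, {
    hap_a <- simulate_genome(genome_length, gc = gc, seed = NULL)$seq
    chars <- strsplit(hap_a, "", fixed = TRUE)[[1L]]
    het_pos <- which(stats::runif(genome_length) < het_rate)
    if (length(het_pos) > 0L) {
      alt <- vapply(chars[het_pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1), USE.NAMES = FALSE)
      chars_b <- chars
      chars_b[het_pos] <- alt
      hap_b <- paste(chars_b, collapse = "")
    } else {
      hap_b <- hap_a
    }
    mult <- count_canonical_kmers(c(hap_a, hap_b), k = k)
    depth <- stats::rpois(nrow(mult), lambda = mult$count * coverage / 2)
    hist <- build_histogram(depth[depth > 0L], k = k)
    truth <- structure(
      list(het_rate = het_rate, het_positions = het_pos, coverage = coverage,
           k = k, seed = seed),
      class = "synthetic_truth"
    )
    list(histogram = hist, hap_a = hap_a, hap_b = hap_b,
         multiplicities = mult, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.data.frame(v)) {
      cat(sprintf("  %s: %d rows\n", nm, nrow(v)))
    } else if (length(v) > 6L) {
      cat(sprintf("  %s: %s, ... (%d values)\n", nm,
                  paste(utils::head(v, 3L), collapse = ", "), length(v)))
    } else {
      cat(sprintf("  %s: %s\n", nm, paste(v, collapse = ", ")))
    }
  }
  invisible(x)
}
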
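test_that("count-matrix simulation is deterministic and validates arguments", {
  a <- simulate_count_matrix(n_orthogroups = 50, n_expanded = 5,
                             n_contracted = 5, seed = 11)
  b <- simulate_count_matrix(n_orthogroups = 50, n_expanded = 5,
                             n_contracted = 5, seed = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$planted_expanded, b$truth$planted_expanded)
  expect_length(intersect(a$truth$planted_expanded, a$truth$planted_contracted), 0)

  expect_error(simulate_count_matrix(effect_multiplier = 1),
               class = "cryocomp_argument_error")
  expect_error(simulate_count_matrix(n_orthogroups = 5, n_expanded = 4,
                                     n_contracted = 4),
               class = "cryocomp_argument_error")
  expect_error(
    simulate_count_matrix(group_sizes = c(psychrophile = 1, other = 5)),
    class = "cryocomp_argument_error"
  )
})

test_that("count simulation approaches the Poisson limit at huge dispersion", {
  sim <- simulate_count_matrix(
    n_orthogroups = 200, group_sizes = c(a = 25, b = 25),
    baseline_mean = 3, dispersion = 1e6, n_expanded = 0, n_contracted = 0,
    seed = 5
  )
  x <- as.vector(as.matrix(sim$counts[, -1]))  # 10^4 draws
  expect_equal(var(x) / mean(x), 1, tolerance = 0.1)
})

test_that("genome simulation respects the GC target", {
  expect_false(grepl("[GC]", simulate_genome(500, gc = 0, seed = 1)$seq))
  expect_false(grepl("[AT]", simulate_genome(500, gc = 1, seed = 1)$seq))
  g <- simulate_genome(1e5, gc = 0.5, seed = 3)
  expect_equal(gc_content(g$seq), 0.5, tolerance = 0.01)  # 0.5 +/- 0.005
  expect_error(simulate_genome(100, gc = 1.2), class = "cryocomp_argument_error")
})

test_that("rip_mutate hits exactly the CpA / TpG contexts of the original", {
  expect_equal(rip_mutate("CACA", rate = 1, seed = 1), "TATA")
  expect_equal(rip_mutate("CATG", rate = 1, seed = 1), "TATA")
  s <- random_seq(300, 9)
  expect_equal(rip_mutate(s, rate = 0, seed = 1), s)
  expect_error(rip_mutate("ACGN", rate = 0.5, seed = 1),
               class = "cryocomp_argument_error")
})

test_that("rip_mutate at rate 1 removes covered contexts and never creates C/G", {
  for (seed in 1:5) {
    s <- random_seq(2000, seed)
    m <- rip_mutate(s, rate = 1, seed = seed + 100)
    expect_equal(nchar(m), nchar(s))
    # no mutation may introduce a C or G
    sc <- strsplit(s, "")[[1]]
    mc <- strsplit(m, "")[[1]]
    changed <- which(sc != mc)
    expect_true(all(mc[changed] %in% c("T", "A")))
    expect_true(all(sc[changed] %in% c("C", "G")))
    # every original CpA lost its C; every original TpG lost its G
    n <- nchar(s)
    a <- sc[-n]; b <- sc[-1]
    expect_true(all(mc[which(a == "C" & b == "A")] == "T"))
    expect_true(all(mc[which(a == "T" & b == "G") + 1L] == "A"))
  }
})

test_that("planted RIP intervals are in bounds, non-overlapping, recorded", {
  for (seed in 1:5) {
    sim <- simulate_ripped_genome(length = 3e4, n_regions = 3,
                                  region_length = 2000, seed = seed)
    iv <- sim$truth$rip_intervals
    expect_equal(nrow(iv), 3L)
    expect_true(all(iv$start >= 0 & iv$end <= 3e4))
    iv <- iv[order(iv$start), ]
    expect_true(all(head(iv$end, -1) <= tail(iv$start, -1)))
  }
  expect_equal(nrow(simulate_ripped_genome(length = 1e4, n_regions = 0,
                                           seed = 1)$truth$rip_intervals), 0L)
  expect_error(simulate_ripped_genome(length = 1e4, n_regions = 3,
                                      region_length = 2000, seed = 1),
               class = "cryocomp_argument_error")
})

test_that("CDS simulation pins third-position composition", {
  expect_equal(cds_gc_and_gc3(simulate_cds(5, 50, gc3_target = 1, seed = 1))$gc3, 1)
  expect_equal(cds_gc_and_gc3(simulate_cds(5, 50, gc3_target = 0, seed = 1))$gc3, 0)
  cds <- simulate_cds(100, 300, gc3_target = 0.6, seed = 2)
  expect_equal(cds_gc_and_gc3(cds)$gc3, 0.6, tolerance = 0.02)  # +/- 0.01 abs
  expect_error(simulate_cds(gc3_target = 1.5), class = "cryocomp_argument_error")
})

test_that("diploid spectrum simulation is deterministic and validates het_rate", {
  a <- simulate_diploid_spectrum(genome_length = 2e4, seed = 13)
  b <- simulate_diploid_spectrum(genome_length = 2e4, seed = 13)
  expect_identical(a$histogram, b$histogram)
  expect_error(simulate_diploid_spectrum(het_rate = 0.2),
               class = "cryocomp_argument_error")
  expect_error(simulate_diploid_spectrum(k = 20), class = "cryocomp_argument_error")
})

test_that("heterozygous k-mer content matches the direct substitution-overlap oracle", {
  sim <- simulate_diploid_spectrum(genome_length = 1e5, het_rate = 0.01,
                                   k = 21, seed = 42)
  k <- 21
  n <- nchar(sim$hap_a)
  # oracle: windows of haplotype A overlapping at least one planted substitution
  overlaps <- logical(n - k + 1)
  for (p in sim$truth$het_positions) {
    lo <- max(1L, p - k + 1L)
    hi <- min(n - k + 1L, p)
    if (lo <= hi) overlaps[lo:hi] <- TRUE
  }
  frac_windows <- mean(overlaps)
  expect_equal(frac_windows, 1 - (1 - 0.01)^k, tolerance = 0.1)
  # each het-overlapping window contributes one unique k-mer per haplotype
  m1 <- sum(sim$multiplicities$count == 1)
  expect_equal(m1, 2 * sum(overlaps), tolerance = 0.05)
})
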
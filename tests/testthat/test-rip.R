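test_that("dinucleotide counting matches manual enumeration and skips ambiguity", {
  expect_equal(dinucleotide_counts("TACATG"),
               c(TpA = 1L, ApT = 1L, CpA = 1L, TpG = 1L, ApC = 1L, GpT = 0L))
  expect_equal(unname(dinucleotide_counts("AAAA")), rep(0L, 6))
  expect_equal(dinucleotide_counts("TANAT"),
               c(TpA = 1L, ApT = 1L, CpA = 0L, TpG = 0L, ApC = 0L, GpT = 0L))
  expect_error(dinucleotide_counts("A"), class = "cryocomp_degenerate_error")
})

test_that("RIP indices follow their definitions with the zero-denominator policy", {
  idx <- rip_indices(dinucleotide_counts("TACATG"))
  expect_equal(idx$product, 1)
  expect_equal(idx$substrate, 2)
  expect_equal(idx$composite, -1)

  zero <- rip_indices(c(TpA = 0, ApT = 0, CpA = 0, TpG = 0, ApC = 0, GpT = 0))
  expect_equal(zero$product, 0)
  expect_equal(zero$substrate, 0)
  expect_equal(zero$composite, 0)
  expect_true(zero$denom_zero)

  idx <- rip_indices(c(TpA = 3, ApT = 2, CpA = 1, TpG = 0, ApC = 2, GpT = 2))
  expect_equal(idx$product, 1.5)
  expect_equal(idx$substrate, 0.25)
  expect_equal(idx$composite, 1.25)
})

test_that("window tiling follows start/step arithmetic with the short-contig rule", {
  asm <- tibble::tibble(id = "c", description = "", seq = random_seq(2500, 1))
  w <- scan_rip_windows(asm, window = 1000, step = 500)
  expect_equal(w$start, c(0, 500, 1000, 1500))
  expect_equal(w$end, c(1000, 1500, 2000, 2500))
  expect_false(any(w$short))

  short <- tibble::tibble(id = "s", description = "", seq = random_seq(999, 2))
  ws <- scan_rip_windows(short, window = 1000, step = 500)
  expect_equal(nrow(ws), 1L)
  expect_equal(c(ws$start, ws$end), c(0, 999))
  expect_true(ws$short)
})

test_that("window indices equal brute-force recounts on random genomes", {
  for (seed in 1:4) {
    asm <- tibble::tibble(id = "c", description = "", seq = random_seq(5000, seed + 10))
    w <- scan_rip_windows(asm, window = 1000, step = 500)
    for (i in seq_len(nrow(w))) {
      sub <- substr(asm$seq, w$start[i] + 1L, w$end[i])
      bd <- brute_dinucs(sub)
      expect_equal(unlist(w[i, names(bd)]), bd)
      ref <- rip_indices(bd)
      expect_equal(w$product[i], ref$product)
      expect_equal(w$substrate[i], ref$substrate)
      expect_equal(w$composite[i], ref$composite)
      expect_equal(w$gc[i], gc_content(sub))
    }
  }
})

test_that("RIP-positive calls are strict at all three thresholds", {
  # product exactly 1.15 (23/20) and substrate exactly 0.75 (3/4): negative
  at_bound <- dinuc_fixture(a = 23, b = 20, cc = 3, d = 0, e = 2, f = 2)
  len <- nchar(at_bound)
  asm <- function(s) tibble::tibble(id = "c", description = "", seq = s)
  w <- scan_rip_windows(asm(at_bound), window = len, step = len)
  expect_equal(w$product, 1.15)
  expect_equal(w$substrate, 0.75)
  expect_false(w$rip_positive)

  # product above the bound but substrate still at it: negative
  above <- dinuc_fixture(24, 20, 3, 0, 2, 2)
  w <- scan_rip_windows(asm(above), window = nchar(above), step = nchar(above))
  expect_gt(w$product, 1.15)
  expect_false(w$rip_positive)

  # product above, substrate below, composite positive: positive
  pos <- dinuc_fixture(a = 24, b = 20, cc = 7, d = 0, e = 8, f = 2)
  w <- scan_rip_windows(asm(pos), window = nchar(pos), step = nchar(pos))
  expect_equal(w$substrate, 0.7)
  expect_true(w$rip_positive)

  # composite bound is strict too: the same window fails when composite_min
  # sits exactly at its composite of 0.5, and passes just below
  w <- scan_rip_windows(asm(pos), window = nchar(pos), step = nchar(pos),
                        composite_min = 0.5)
  expect_equal(w$composite, 0.5)
  expect_false(w$rip_positive)
  w <- scan_rip_windows(asm(pos), window = nchar(pos), step = nchar(pos),
                        composite_min = 0.49)
  expect_true(w$rip_positive)
})

test_that("regions merge consecutive positive windows by union; LRAR bound is strict", {
  # two overlapping positives -> one 1500-bp region, not an LRAR
  w <- make_windows("c", c(0, 500), 1000, positive = c(TRUE, TRUE))
  rg <- call_rip_regions(w)
  expect_equal(nrow(rg$regions), 1L)
  expect_equal(rg$regions$length, 1500)
  expect_equal(nrow(rg$lrars), 0L)

  # 7 consecutive positives -> 4000 bp exactly: still not an LRAR (strict)
  w <- make_windows("c", seq(0, 3000, 500), 1000, positive = rep(TRUE, 7))
  rg <- call_rip_regions(w)
  expect_equal(rg$regions$length, 4000)
  expect_equal(nrow(rg$lrars), 0L)

  # 9 consecutive positives -> 5000 bp: LRAR
  w <- make_windows("c", seq(0, 4000, 500), 1000, positive = rep(TRUE, 9),
                    composite = seq(0.1, 0.9, 0.1))
  rg <- call_rip_regions(w)
  expect_equal(rg$lrars$length, 5000)
  expect_equal(rg$lrars$mean_composite, 0.5)

  # a negative window splits runs
  w <- make_windows("c", seq(0, 2000, 500), 1000,
                    positive = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  rg <- call_rip_regions(w)
  expect_equal(nrow(rg$regions), 2L)

  expect_error(call_rip_regions(w[c(2, 1, 3, 4, 5), ]),
               class = "cryocomp_argument_error")
  none <- make_windows("c", c(0, 500), 1000, positive = c(FALSE, FALSE))
  rg <- call_rip_regions(none)
  expect_equal(nrow(rg$regions), 0L)
  expect_equal(nrow(rg$lrars), 0L)
})

test_that("the genome-wide RIP summary uses union base accounting", {
  asm <- tibble::tibble(id = "c", description = "", seq = random_seq(1e5, 3))
  regions <- tibble::tibble(contig = "c", start = 0L, end = 5000L,
                            length = 5000L, n_windows = 9L, mean_composite = 0.5)
  sm <- summarize_rip(asm, regions, regions)
  expect_equal(sm$genome_rip_percent, 5)
  expect_equal(sm$lrar_mean_composite, 0.5)

  sm0 <- summarize_rip(asm, regions[0, ], regions[0, ])
  expect_equal(sm0$genome_rip_percent, 0)
  expect_true(is.na(sm0$lrar_mean_composite))

  # overlapping regions are not double-counted
  two <- tibble::tibble(contig = "c", start = c(0L, 2000L), end = c(3000L, 6000L),
                        length = c(3000L, 4000L), n_windows = c(5L, 7L),
                        mean_composite = c(0.4, 0.6))
  expect_equal(summarize_rip(asm, two, two[0, ])$total_rip_bp, 6000L)
})

test_that("the product index is strand-symmetric on reverse complements", {
  for (seed in 1:5) {
    s <- random_seq(3000, seed + 30)
    rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", s))
    a <- rip_indices(dinucleotide_counts(s))
    b <- rip_indices(dinucleotide_counts(rc))
    expect_equal(a$product, b$product, tolerance = 1e-12)
    expect_equal(a$substrate, b$substrate, tolerance = 1e-12)
  }
})

test_that("RIP mutation monotonically shifts the indices in affected windows", {
  g <- simulate_genome(3e4, gc = 0.55, seed = 77)$seq
  med_prod <- c(); med_sub <- c()
  for (rate in c(0, 0.3, 0.6, 0.9)) {
    m <- rip_mutate(g, rate = rate, seed = 101)
    w <- scan_rip_windows(tibble::tibble(id = "c", description = "", seq = m))
    med_prod <- c(med_prod, median(w$product))
    med_sub <- c(med_sub, median(w$substrate))
  }
  expect_true(all(diff(med_prod) >= 0))
  expect_true(all(diff(med_sub) <= 0))
})

test_that("a rate-zero mutation leaves essentially no RIP-positive windows", {
  # false positives on unmutated 100-kb GC-0.5 genomes are rare single windows
  npos <- vapply(1:20, function(s) {
    sim <- simulate_ripped_genome(length = 1e5, gc = 0.5, n_regions = 2,
                                  region_length = 4000, rate = 0, seed = s)
    sum(scan_rip_windows(sim$genome)$rip_positive)
  }, numeric(1))
  expect_gte(sum(npos == 0), 17)   # most seeds perfectly clean
  expect_lte(sum(npos), 4)         # and never more than isolated windows
  # isolated false positives can never form an LRAR
  expect_true(all(npos * 1000 < 4000))
})
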
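test_that("trimmed statistics match hand-computed examples", {
  ts <- trimmed_stats(c(1, 2, 3, 4, 100), 0.25)  # k = 1, kept 2,3,4
  expect_equal(ts$mean, 3)
  expect_equal(ts$sd, 1)
  ts <- trimmed_stats(c(5, 5, 5, 5), 0.25)
  expect_equal(ts$mean, 5)
  expect_equal(ts$sd, 0)
  ts <- trimmed_stats(c(1, 2), 0.25)  # k = 0
  expect_equal(ts$mean, 1.5)
  expect_equal(ts$sd, sqrt(0.5))
  expect_error(trimmed_stats(c(1, 2, 3), 0.4), class = "cryocomp_degenerate_error")
})

test_that("normalization converts counts to trimmed standard deviates", {
  counts <- tibble::tibble(orthogroup = "OG1", a = 2, b = 4, c = 6, d = 8)
  nm <- normalize_counts(counts)  # kept 4,6: mean 5, sd sqrt(2)
  expect_equal(unlist(nm[1, -1]),
               c(a = -3, b = -1, c = 1, d = 3) / sqrt(2),
               tolerance = 1e-12)
  # constant orthogroup under each zero-SD policy
  const <- tibble::tibble(orthogroup = "OG1", a = 3, b = 3, c = 3, d = 3)
  expect_equal(unname(unlist(normalize_counts(const)[1, -1])), rep(0, 4))
  dropped <- normalize_counts(const, zero_sd_policy = "drop")
  expect_equal(nrow(dropped), 0L)
  expect_equal(attr(dropped, "dropped_orthogroups"), "OG1")
})

test_that("normalization is scale-invariant and shift-equivariant", {
  base <- simulate_count_matrix(n_orthogroups = 40, n_expanded = 4,
                                n_contracted = 4, seed = 21)$counts
  nm <- normalize_counts(base)
  scaled <- base
  scaled[, -1] <- scaled[, -1] * 10
  expect_equal(as.data.frame(normalize_counts(scaled)), as.data.frame(nm),
               tolerance = 1e-12)
  shifted <- base
  shifted[, -1] <- shifted[, -1] + 7
  expect_equal(as.data.frame(normalize_counts(shifted)), as.data.frame(nm),
               tolerance = 1e-12)
})

test_that("Welch-type t matches hand computations in both formulas", {
  nm <- tibble::tibble(orthogroup = "OG1", a = 2, b = 0, c = 0, d = -2)
  gr <- c(a = "p", b = "p", c = "n", d = "n")
  expect_equal(welch_t_scores(nm, gr, "p")$t, sqrt(2), tolerance = 1e-12)
  expect_equal(welch_t_scores(nm, gr, "p", t_formula = "paper_literal")$t, 1,
               tolerance = 1e-12)
  expect_error(welch_t_scores(nm, gr, "nosuch"), class = "cryocomp_argument_error")
})

test_that("t is exactly antisymmetric under swapping focal and background", {
  sim <- simulate_count_matrix(n_orthogroups = 100,
                               group_sizes = c(p = 4, n = 6),
                               n_expanded = 10, n_contracted = 10, seed = 31)
  nm <- normalize_counts(sim$counts)
  tp <- welch_t_scores(nm, sim$groups, "p")$t
  tn <- welch_t_scores(nm, sim$groups, "n")$t
  expect_identical(tp, -tn)
})

test_that("degenerate zero-variance orthogroups get the documented t sentinels", {
  nm <- tibble::tibble(orthogroup = c("OG1", "OG2"),
                       a = c(1, 1), b = c(1, 1), c = c(1, 0), d = c(1, 0))
  gr <- c(a = "p", b = "p", c = "n", d = "n")
  t <- welch_t_scores(nm, gr, "p")$t
  expect_equal(t[1], 0)      # both SDs 0, means equal
  expect_equal(t[2], Inf)    # both SDs 0, focal mean higher
})

test_that("rank_shifts selects disjoint extremes with deterministic ties", {
  sc <- tibble::tibble(orthogroup = c("OG1", "OG2", "OG3", "OG4"),
                       t = c(2, -1, 0.5, -3))
  top <- rank_shifts(sc, top_n = 1)
  expect_equal(top$orthogroup[top$direction == "expanded"], "OG1")
  expect_equal(top$orthogroup[top$direction == "contracted"], "OG4")

  tied <- tibble::tibble(orthogroup = sprintf("OG%d", 1:6), t = rep(1, 6))
  top <- rank_shifts(tied, top_n = 2)
  expect_equal(sort(top$orthogroup[top$direction == "expanded"]), c("OG1", "OG2"))
  expect_length(intersect(top$orthogroup[top$direction == "expanded"],
                          top$orthogroup[top$direction == "contracted"]), 0)
  expect_error(rank_shifts(sc, top_n = 3), class = "cryocomp_argument_error")
})

test_that("per-species shift counts use strict thresholds", {
  nm <- tibble::tibble(orthogroup = c("OG1", "OG2", "OG3"),
                       s1 = c(0.8, -0.9, 0.5),
                       s2 = c(0.75, -0.75, 0),
                       s3 = c(0, 0, 0))
  pc <- per_species_shift_counts(nm, threshold = 0.75)
  expect_equal(pc$n_expanded, c(1L, 0L, 0L))
  expect_equal(pc$n_contracted, c(1L, 0L, 0L))
})

test_that("species correlation matches a brute-force Pearson oracle", {
  sim <- simulate_count_matrix(n_orthogroups = 30,
                               group_sizes = c(p = 2, n = 3),
                               n_expanded = 3, n_contracted = 3, seed = 41)
  nm <- normalize_counts(sim$counts)
  r <- species_correlation(nm)
  mat <- as.matrix(nm[, -1])
  for (i in 1:5) for (j in 1:5) {
    expect_equal(r[i, j], brute_pearson(mat[, i], mat[, j]), tolerance = 1e-10)
  }
  expect_true(isSymmetric(unname(r)))
  expect_equal(unname(diag(r)), rep(1, 5))
})

test_that("correlation handles collinear and zero-variance species", {
  nm <- tibble::tibble(orthogroup = c("OG1", "OG2"),
                       s1 = c(1, 2), s2 = c(2, 4), s3 = c(-1, -2), s4 = c(5, 5))
  r <- species_correlation(nm)
  expect_equal(r["s1", "s2"], 1)
  expect_equal(r["s1", "s3"], -1)
  expect_equal(r["s1", "s4"], 0)  # flat species
  expect_equal(attr(r, "zero_variance_species"), "s4")
  expect_error(species_correlation(nm, orthogroups = "OG9"),
               class = "cryocomp_argument_error")
})

test_that("Ward clustering on correlation distance recovers planted blocks", {
  n <- 8
  r <- matrix(-0.5, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  block <- list(1:4, 5:8)
  for (b in block) r[b, b] <- 0.95
  diag(r) <- 1
  cl <- ward_cluster(r, 2)
  expect_equal(length(unique(cl$clusters$cluster[1:4])), 1L)
  expect_equal(length(unique(cl$clusters$cluster[5:8])), 1L)
  expect_false(cl$clusters$cluster[1] == cl$clusters$cluster[5])
  expect_true(all(diff(cl$hclust$height) >= -1e-12))

  # permuting species relabels but does not change the partition
  perm <- c(3, 7, 1, 5, 2, 8, 4, 6)
  cl2 <- ward_cluster(r[perm, perm], 2)
  m <- cl2$clusters$cluster[match(cl$clusters$species, cl2$clusters$species)]
  expect_equal(length(unique(paste(cl$clusters$cluster, m))), 2L)

  expect_equal(dplyr::n_distinct(ward_cluster(r, n)$clusters$cluster), n)
  r_bad <- r; r_bad[1, 2] <- 0
  expect_error(ward_cluster(r_bad, 2), class = "cryocomp_argument_error")
})

test_that("PCA of the correlation matrix behaves on canonical spectra", {
  n <- 6
  id <- diag(n); dimnames(id) <- list(paste0("s", 1:n), paste0("s", 1:n))
  p <- pca_scores(id, n_components = n)
  # centered identity: n-1 equal nonzero eigenvalues plus the centering null
  expect_equal(p$explained_variance[1:(n - 1)],
               rep(1 / (n - 1), n - 1), tolerance = 1e-10)
  expect_equal(p$explained_variance[n], 0, tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance) <= 1e-12))

  ones <- matrix(1, n, n, dimnames = dimnames(id))
  # rank-1 structure carries no variance at all after centering a constant
  # matrix; perturb one species to make a single informative direction
  ones[, 1] <- c(1, rep(0.5, n - 1)); ones[1, ] <- ones[, 1]
  p1 <- pca_scores(ones, n_components = 2)
  expect_gt(p1$explained_variance[1], 0.99)
})
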
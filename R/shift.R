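# Orthogroup expansion/contraction scoring: trimmed-mean standardisation of
# gene counts, a Welch-type t statistic contrasting a focal species group
# against the background, ranking, per-species shift counts, and species
# clustering on correlation distance.

#' Trimmed mean and standard deviation
#'
#' Sorts the values, removes `floor(trim_fraction_per_tail * n)` from each
#' end, and returns the mean and sample SD (denominator n - 1) of the kept
#' values. The default 0.25 per tail removes 50% of the data in total (the
#' "midmean"), the trimming used to standardise orthogroup gene counts.
#'
#' @param values Numeric vector.
#' @param trim_fraction_per_tail Fraction removed from each tail, in \[0, 0.5).
#' @return A list with elements `mean` and `sd`.
#' @examples
#' trimmed_stats(c(1, 2, 3, 4, 100), 0.25) # mean 3, sd 1
#' @export
trimmed_stats <- function(values, trim_fraction_per_tail = 0.25) {
  if (!is.numeric(values)) abort_argument("`values` must be numeric.")
  check_scalar_number(trim_fraction_per_tail, "trim_fraction_per_tail",
                      lower = 0, upper = 0.5, upper_open = TRUE)
  n <- length(values)
  k <- floor(trim_fraction_per_tail * n)
  if (n - 2L * k < 2L) {
    abort_degenerate(sprintf(
      "trimming %d values per tail from %d leaves fewer than 2.", k, n
    ))
  }
  kept <- sort(values)[(k + 1L):(n - k)]
  list(mean = mean(kept), sd = stats::sd(kept))
}

#' Standardise a gene-count matrix per orthogroup
#'
#' Each orthogroup's counts across species are converted to standard normal
#' deviates using that orthogroup's trimmed mean and trimmed (sample) SD:
#' `score = (count - trimmed_mean) / trimmed_sd`. Orthogroups whose trimmed
#' SD is zero are handled per `zero_sd_policy`: `"zeros"` (default) sets all
#' their scores to 0, keeping the matrix shape stable for clustering;
#' `"drop"` removes them and records their ids in the
#' `dropped_orthogroups` attribute.
#'
#' @param counts Tibble: `orthogroup` column plus one numeric column per
#'   species (see [read_genecounts()], [simulate_count_matrix()]).
#' @param trim_fraction_per_tail Passed to [trimmed_stats()].
#' @param zero_sd_policy `"zeros"` or `"drop"`.
#' @return A tibble of the same shape holding normalized scores, with
#'   attribute `dropped_orthogroups` (character vector).
#' @export
normalize_counts <- function(counts, trim_fraction_per_tail = 0.25,
                             zero_sd_policy = c("zeros", "drop")) {
  zero_sd_policy <- match.arg(zero_sd_policy)
  mat <- scores_as_matrix(counts)
  n_sp <- ncol(mat)
  k <- floor(trim_fraction_per_tail * n_sp)
  if (n_sp - 2L * k < 2L) {
    abort_degenerate("trimming leaves fewer than 2 species per orthogroup.")
  }
  sorted <- t(apply(mat, 1L, sort))
  kept <- sorted[, (k + 1L):(n_sp - k), drop = FALSE]
  m <- rowMeans(kept)
  n_kept <- ncol(kept)
  s <- sqrt(pmax(rowSums((kept - m)^2), 0) / (n_kept - 1L))

  scores <- (mat - m) / s
  zero_sd <- s == 0
  dropped <- character()
  if (any(zero_sd)) {
    if (zero_sd_policy == "zeros") {
      scores[zero_sd, ] <- 0
    } else {
      dropped <- rownames(mat)[zero_sd]
      scores <- scores[!zero_sd, , drop = FALSE]
    }
  }
  out <- dplyr::bind_cols(
    tibble::tibble(orthogroup = rownames(scores)),
    as_tibble(scores)
  )
  attr(out, "dropped_orthogroups") <- dropped
  out
}

#' Welch-type t statistic per orthogroup, focal group vs background
#'
#' For each orthogroup, the mean (c) and sample SD (s) of the normalized
#' scores are computed for the focal group and for the background (every
#' non-focal species). `t_formula = "welch"` (default) uses the standard
#' Welch denominator `sqrt(s_p^2/n_p + s_n^2/n_n)`; `"paper_literal"` uses
#' `sqrt(s_p^2 + s_n^2)`, i.e. without the group sizes under the radical.
#' Positive t means the focal group is expanded relative to background.
#' When both SDs are zero, t is 0 for equal means and +/-Inf otherwise.
#'
#' @param normalized Output of [normalize_counts()].
#' @param groups Species/group tibble or named character vector.
#' @param focal_group Label of the focal group (e.g. `"psychrophile"`).
#' @param t_formula `"welch"` or `"paper_literal"`.
#' @return A tibble with columns `orthogroup`, `c_p`, `c_n`, `s_p`, `s_n`,
#'   `n_p`, `n_n`, `t`; attribute `t_formula` records the variant used.
#' @export
welch_t_scores <- function(normalized, groups, focal_group,
                           t_formula = c("welch", "paper_literal")) {
  t_formula <- match.arg(t_formula)
  mat <- scores_as_matrix(normalized)
  map <- as_group_map(groups)
  species <- colnames(mat)
  missing <- setdiff(species, names(map))
  if (length(missing) > 0L) {
    abort_argument(sprintf("species with no group assignment: %s",
                           paste(missing, collapse = ", ")))
  }
  if (!focal_group %in% map[species]) {
    abort_argument(sprintf("focal group '%s' matches no species.", focal_group))
  }
  focal <- species[map[species] == focal_group]
  backg <- setdiff(species, focal)
  n_p <- length(focal)
  n_n <- length(backg)
  if (n_p < 2L || n_n < 2L) {
    abort_argument("need at least 2 species in the focal group and 2 in the background.")
  }

  group_stats <- function(m) {
    mu <- rowMeans(m)
    ss <- rowSums((m - mu)^2)
    list(mean = mu, sd = sqrt(pmax(ss, 0) / (ncol(m) - 1L)))
  }
  p <- group_stats(mat[, focal, drop = FALSE])
  n <- group_stats(mat[, backg, drop = FALSE])

  num <- p$mean - n$mean
  den <- switch(t_formula,
    welch = sqrt(p$sd^2 / n_p + n$sd^2 / n_n),
    paper_literal = sqrt(p$sd^2 + n$sd^2)
  )
  t <- ifelse(den > 0, num / den, ifelse(num == 0, 0, sign(num) * Inf))

  out <- tibble::tibble(
    orthogroup = rownames(mat),
    c_p = unname(p$mean), c_n = unname(n$mean),
    s_p = unname(p$sd), s_n = unname(n$sd),
    n_p = n_p, n_n = n_n,
    t = unname(t)
  )
  attr(out, "t_formula") <- t_formula
  out
}

#' Select the most expanded and most contracted orthogroups
#'
#' Returns the `top_n` orthogroups with the largest t (expanded) and the
#' `top_n` with the smallest t (contracted). Ties are broken by orthogroup id
#' (lexicographic) for determinism, and the contracted list is drawn from the
#' orthogroups not already selected as expanded, so the two lists are always
#' disjoint.
#'
#' @param scores Output of [welch_t_scores()].
#' @param top_n Number of orthogroups per direction (default 50).
#' @return A tibble with columns `orthogroup`, `t`, `direction`
#'   (`"expanded"`/`"contracted"`) and `rank` (1 = most extreme).
#' @export
rank_shifts <- function(scores, top_n = 50) {
  check_scalar_number(top_n, "top_n", lower = 1)
  if (nrow(scores) < 2L * top_n) {
    abort_argument(sprintf(
      "need at least %d orthogroups to select %d per direction.", 2L * top_n, top_n
    ))
  }
  expanded <- scores |>
    dplyr::arrange(dplyr::desc(t), .data$orthogroup) |>
    dplyr::slice_head(n = top_n)
  contracted <- scores |>
    dplyr::filter(!.data$orthogroup %in% expanded$orthogroup) |>
    dplyr::arrange(t, .data$orthogroup) |>
    dplyr::slice_head(n = top_n)
  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(expanded, "orthogroup", "t"),
                  direction = "expanded", rank = dplyr::row_number()),
    dplyr::mutate(dplyr::select(contracted, "orthogroup", "t"),
                  direction = "contracted", rank = dplyr::row_number())
  )
}

#' Count expanded/contracted orthogroups per species
#'
#' A species' orthogroup is called expanded when its normalized score exceeds
#' `threshold` and contracted when it is below `-threshold` (strict
#' inequalities; scores exactly at the threshold count as neither). This is
#' the per-species reading of the group-level shift statistic: it asks, for
#' each species, how many orthogroups deviate strongly from that
#' orthogroup's trimmed centre.
#'
#' @param normalized Output of [normalize_counts()].
#' @param threshold Score threshold (default 0.75).
#' @return A tibble with columns `species`, `n_expanded`, `n_contracted`.
#' @export
per_species_shift_counts <- function(normalized, threshold = 0.75) {
  check_scalar_number(threshold, "threshold", lower = 0, lower_open = TRUE)
  mat <- scores_as_matrix(normalized)
  tibble::tibble(
    species = colnames(mat),
    n_expanded = as.integer(colSums(mat > threshold)),
    n_contracted = as.integer(colSums(mat < -threshold))
  )
}

#' Pearson correlation between species over normalized scores
#'
#' @param normalized Output of [normalize_counts()].
#' @param orthogroups Optional character vector of orthogroup ids restricting
#'   the computation (e.g. the top shifted set); default uses all rows.
#' @return A species x species correlation matrix (diagonal 1, symmetric).
#'   Species with zero variance over the subset get correlation 0 with every
#'   other species and are listed in the `zero_variance_species` attribute.
#' @export
species_correlation <- function(normalized, orthogroups = NULL) {
  mat <- scores_as_matrix(normalized)
  if (!is.null(orthogroups)) {
    unknown <- setdiff(orthogroups, rownames(mat))
    if (length(unknown) > 0L) {
      abort_argument(sprintf("unknown orthogroup ids: %s",
                             paste(head(unknown, 3L), collapse = ", ")))
    }
    mat <- mat[orthogroups, , drop = FALSE]
  }
  if (nrow(mat) < 2L) {
    abort_argument("need at least 2 orthogroups to correlate species.")
  }
  flat <- colnames(mat)[apply(mat, 2L, function(v) stats::sd(v) == 0)]
  r <- suppressWarnings(stats::cor(mat))
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "zero_variance_species") <- flat
  r
}

#' Ward clustering of species on correlation distance
#'
#' Agglomerative clustering with Ward linkage (`hclust` method `"ward.D2"`)
#' on the distance d = 1 - r. Deterministic given its input.
#'
#' @param corr Species correlation matrix from [species_correlation()].
#' @param n_clusters Number of clusters to cut the tree into.
#' @return A list with `hclust` (the linkage object) and `clusters` (tibble
#'   `species`, `cluster`).
#' @export
ward_cluster <- function(corr, n_clusters) {
  if (!is.matrix(corr) || !isSymmetric(unname(corr), tol = 1e-8)) {
    abort_argument("`corr` must be a symmetric correlation matrix.")
  }
  n <- nrow(corr)
  check_scalar_number(n_clusters, "n_clusters", lower = 2, upper = n)
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "ward.D2")
  cl <- stats::cutree(hc, k = n_clusters)
  list(
    hclust = hc,
    clusters = tibble::tibble(species = names(cl), cluster = unname(cl))
  )
}

#' Principal components of the species correlation matrix
#'
#' Eigendecomposition (via [stats::prcomp()]) of the column-centered
#' correlation matrix. Component signs are fixed by making each component's
#' largest-magnitude loading positive, so results are reproducible across
#' platforms.
#'
#' @param corr Species correlation matrix.
#' @param n_components Number of components to return.
#' @return A list with `scores` (tibble: `species`, `PC1`, ...) and
#'   `explained_variance` (fractions, non-increasing, summing to <= 1 over
#'   the returned components).
#' @export
pca_scores <- function(corr, n_components = 2) {
  if (!is.matrix(corr)) abort_argument("`corr` must be a matrix.")
  n <- nrow(corr)
  check_scalar_number(n_components, "n_components", lower = 1, upper = n)
  p <- stats::prcomp(corr, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  frac <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  n_components <- min(n_components, ncol(p$x))
  x <- p$x[, seq_len(n_components), drop = FALSE]
  rot <- p$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      x[, j] <- -x[, j]
    }
  }
  scores <- dplyr::bind_cols(
    tibble::tibble(species = rownames(corr)),
    as_tibble(x)
  )
  list(scores = scores, explained_variance = frac[seq_len(n_components)])
}
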
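# Internal helpers: error classes, seed scoping, small validators.

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "cryocomp_format_error", ...)
}

abort_argument <- function(msg, ...) {
  rlang::abort(msg, class = "cryocomp_argument_error", ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = "cryocomp_degenerate_error", ...)
}

# Run `code` under `seed` without disturbing the caller's RNG state.
# seed = NULL means "use the RNG stream already in scope" so that composite
# generators can drive their sub-generators from one root seed.
with_seed_or_inherit <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort_argument("`seed` must be a single integer or NULL.")
    }
    withr::with_seed(as.integer(seed), code)
  }
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_argument(sprintf("`%s` must be a single number.", name))
  }
  ok_low <- if (lower_open) x > lower else x >= lower
  ok_up <- if (upper_open) x < upper else x <= upper
  if (!ok_low || !ok_up) {
    abort_argument(sprintf(
      "`%s` = %s is outside the allowed range %s%s, %s%s.",
      name, format(x),
      if (lower_open) "(" else "[", format(lower),
      format(upper), if (upper_open) ")" else "]"
    ))
  }
  invisible(x)
}

check_dna <- function(seq, name = "seq") {
  bad <- stringr::str_extract(seq, "[^ACGT]")
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    abort_argument(sprintf(
      "`%s` must contain only A/C/G/T; found '%s' in element %d.",
      name, bad[i], i
    ))
  }
  invisible(seq)
}

# Accept either a two-column tibble/data.frame (species, group) or a named
# character vector; return a named character vector species -> group.
as_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    if (ncol(groups) < 2L) {
      abort_argument("`groups` data frame needs columns species and group.")
    }
    nm <- names(groups)
    sp_col <- if ("species" %in% nm) "species" else nm[1L]
    gr_col <- if ("group" %in% nm) "group" else nm[2L]
    map <- stats::setNames(as.character(groups[[gr_col]]),
                           as.character(groups[[sp_col]]))
  } else if (is.character(groups) && !is.null(names(groups))) {
    map <- groups
  } else {
    abort_argument("`groups` must be a species/group data frame or a named character vector.")
  }
  if (anyDuplicated(names(map))) {
    dup <- unique(names(map)[duplicated(names(map))])
    conflicting <- vapply(dup, function(s) length(unique(map[names(map) == s])) > 1L, logical(1))
    if (any(conflicting)) {
      abort_format(sprintf(
        "species assigned to conflicting groups: %s",
        paste(dup[conflicting], collapse = ", ")
      ))
    }
    map <- map[!duplicated(names(map))]
  }
  map
}

# Matrix of the numeric columns of a score/count tibble whose first column
# is the orthogroup id; rownames are orthogroup ids, colnames species.
scores_as_matrix <- function(x) {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort_argument("expected a data frame with an orthogroup column plus one column per species.")
  }
  mat <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    abort_argument("species columns must all be numeric.")
  }
  rownames(mat) <- as.character(x[[1L]])
  mat
}

reverse_complement <- function(seq) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", seq))
}
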
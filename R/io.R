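#' Read a FASTA file into a tibble of sequence records
#'
#' Wraps [Biostrings::readBStringSet()] (so wrapped sequence lines and
#' gzip-compressed files are handled transparently) and adds strict
#' validation: sequences are upper-cased and every character must be an IUPAC
#' nucleotide code. The record id is the first whitespace-delimited token of
#' the header; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file (plain or `.gz`).
#' @return A tibble with columns `id`, `description`, `seq`, one row per
#'   record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">ctg1 first contig", "ACGT", "GGCC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort_argument(sprintf("FASTA file '%s' does not exist.", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort_format(sprintf("could not parse '%s' as FASTA: %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) {
    abort_format(sprintf("FASTA file '%s' contains no records.", path))
  }
  headers <- names(set)
  id <- stringr::str_extract(headers, "^\\S+")
  description <- stringr::str_trim(stringr::str_remove(headers, "^\\S+\\s*"))
  description[is.na(description)] <- ""
  if (any(is.na(id) | id == "")) {
    abort_format(sprintf("record %d of '%s' has an empty id.", which(is.na(id) | id == "")[1L], path))
  }
  seq <- toupper(as.character(set))
  if (any(nchar(seq) == 0L)) {
    abort_format(sprintf("record '%s' has an empty sequence.", id[which(nchar(seq) == 0L)[1L]]))
  }
  bad <- stringr::str_extract(seq, "[^ACGTRYSWKMBDHVN]")
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    abort_format(sprintf(
      "record '%s' contains non-IUPAC character '%s'.", id[i], bad[i]
    ))
  }
  tibble::tibble(id = id, description = description, seq = unname(seq))
}

#' Write sequence records to a FASTA file
#'
#' @param records A tibble with columns `id`, `description` (optional) and
#'   `seq`, as returned by [read_fasta()].
#' @param path Output path; a `.gz` suffix writes gzip-compressed output.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (!is.data.frame(records) || !all(c("id", "seq") %in% names(records))) {
    abort_argument("`records` must be a data frame with columns id and seq.")
  }
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- ifelse(is.na(desc) | desc == "", records$id,
                   paste(records$id, desc))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- header
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read an OrthoFinder-style gene-count table
#'
#' Parses the `Orthogroups.GeneCount.tsv` dialect: a tab-separated table whose
#' first column holds orthogroup ids, one column of non-negative integer gene
#' counts per species, and an optional trailing `Total` column. When `Total`
#' is present each row's value is checked against the row sum and the column
#' is then dropped.
#'
#' @param path Path to a tab-separated gene-count file.
#' @return A tibble with an `orthogroup` column followed by one integer column
#'   per species.
#' @export
read_genecounts <- function(path) {
  if (!file.exists(path)) {
    abort_argument(sprintf("gene-count file '%s' does not exist.", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         name_repair = "minimal", progress = FALSE)
  if (ncol(raw) < 2L) {
    abort_format("gene-count table needs an orthogroup column plus at least one species column.")
  }
  species <- names(raw)[-1L]
  has_total <- identical(tail(species, 1L), "Total")
  if (has_total) species <- head(species, -1L)
  if (length(species) == 0L) {
    abort_format("gene-count table has no species columns.")
  }
  if (anyDuplicated(species)) {
    abort_format(sprintf(
      "duplicate species in header: %s",
      paste(unique(species[duplicated(species)]), collapse = ", ")
    ))
  }
  og <- raw[[1L]]
  if (anyDuplicated(og)) {
    abort_format(sprintf(
      "duplicate orthogroup ids: %s",
      paste(unique(og[duplicated(og)])[1:min(3, sum(duplicated(og)))], collapse = ", ")
    ))
  }
  cols <- if (has_total) c(species, "Total") else species
  for (cn in cols) {
    v <- raw[[cn]]
    bad <- !stringr::str_detect(v, "^[0-9]+$")
    if (any(bad)) {
      i <- which(bad)[1L]
      abort_format(sprintf(
        "non-integer or negative count '%s' at row %d (orthogroup '%s'), column '%s'.",
        v[i], i, og[i], cn
      ))
    }
  }
  counts <- as_tibble(lapply(raw[species], function(v) as.integer(v)))
  if (has_total) {
    total <- as.integer(raw[["Total"]])
    rs <- rowSums(counts)
    off <- which(total != rs)
    if (length(off) > 0L) {
      i <- off[1L]
      abort_format(sprintf(
        "Total column mismatch at row %d (orthogroup '%s'): Total = %d but row sum = %d.",
        i, og[i], total[i], rs[i]
      ))
    }
  }
  dplyr::bind_cols(tibble::tibble(orthogroup = og), counts)
}

#' Write a gene-count table in the OrthoFinder dialect
#'
#' The output always carries a trailing `Total` column equal to the row sums,
#' and an `Orthogroup` header for the id column.
#'
#' @param counts A tibble as returned by [read_genecounts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genecounts <- function(counts, path) {
  mat <- scores_as_matrix(counts)
  out <- dplyr::bind_cols(
    tibble::tibble(Orthogroup = as.character(counts[[1L]])),
    as_tibble(counts[, -1L, drop = FALSE]),
    tibble::tibble(Total = as.integer(rowSums(mat)))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a species-to-group assignment table
#'
#' Two tab-separated columns (species, group), either headerless or with the
#' header `species<TAB>group`. Duplicated consistent rows are de-duplicated;
#' a species listed with two different groups is an error.
#'
#' @param path Path to the assignment file.
#' @return A tibble with columns `species` and `group`.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) {
    abort_argument(sprintf("group file '%s' does not exist.", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) == 0L) {
    abort_format(sprintf("group file '%s' is empty.", path))
  }
  if (identical(tolower(lines[1L]), "species\tgroup")) {
    lines <- lines[-1L]
  }
  parts <- stringr::str_split(lines, "\t")
  if (any(lengths(parts) != 2L)) {
    abort_format("each line of the group file must have exactly two tab-separated fields.")
  }
  species <- vapply(parts, `[[`, character(1), 1L)
  group <- vapply(parts, `[[`, character(1), 2L)
  tbl <- tibble::tibble(species = species, group = group)
  tbl <- dplyr::distinct(tbl)
  if (anyDuplicated(tbl$species)) {
    dup <- unique(tbl$species[duplicated(tbl$species)])
    abort_format(sprintf(
      "species assigned to conflicting groups: %s", paste(dup, collapse = ", ")
    ))
  }
  tbl
}

#' @importFrom dplyr distinct bind_cols
NULL
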
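#' PSL column names
#'
#' Canonical names for the 21 columns of BLAT's PSL alignment format, in file
#' order. `read_psl()` returns tibbles with these columns; the three
#' per-block columns (`block_sizes`, `q_starts`, `t_starts`) are list-columns
#' of integer vectors.
#'
#' @format A character vector of length 21.
#' @export
psl_columns <- c(
  "matches", "mismatches", "rep_matches", "n_count",
  "q_num_insert", "q_base_insert", "t_num_insert", "t_base_insert",
  "strand", "q_name", "q_size", "q_start", "q_end",
  "t_name", "t_size", "t_start", "t_end",
  "block_count", "block_sizes", "q_starts", "t_starts"
)

.psl_int_cols <- psl_columns[c(1:8, 11:13, 15:18)]
.psl_list_cols <- c("block_sizes", "q_starts", "t_starts")

psl_empty <- function() {
  out <- tibble(
    matches = integer(), mismatches = integer(), rep_matches = integer(),
    n_count = integer(), q_num_insert = integer(), q_base_insert = integer(),
    t_num_insert = integer(), t_base_insert = integer(),
    strand = character(), q_name = character(), q_size = integer(),
    q_start = integer(), q_end = integer(), t_name = character(),
    t_size = integer(), t_start = integer(), t_end = integer(),
    block_count = integer(),
    block_sizes = list(), q_starts = list(), t_starts = list()
  )
  out
}

#' Read a PSL alignment file
#'
#' Parses BLAT PSL output (21 tab-delimited columns) into a tibble, one row
#' per alignment, in file order. Both the headered dialect (five `psLayout`
#' banner lines) and the headless `-noHead` dialect are accepted. Coordinates
#' follow the PSL convention: 0-based, half-open; `q_start`/`q_end` are
#' always plus-strand query coordinates regardless of the `strand` field.
#'
#' @param path Path to a PSL file. An empty file yields a zero-row tibble.
#' @return A tibble with columns [psl_columns]; `block_sizes`, `q_starts`
#'   and `t_starts` are list-columns of integer vectors.
#' @seealso [write_psl()], [percent_identity()], [length_coverage()]
#' @export
read_psl <- function(path) {
  if (!file.exists(path)) abort(paste0("PSL file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  if (length(lines) > 0 && startsWith(lines[1], "psLayout")) {
    offset <- min(5L, length(lines))
    lines <- lines[-seq_len(offset)]
  }
  keep <- nzchar(trimws(lines))
  lineno <- which(keep) + offset
  lines <- lines[keep]
  if (length(lines) == 0) return(psl_empty())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L)) {
    bad <- which(nf != 21L)[1]
    abort(sprintf("malformed PSL line %d: expected 21 tab-separated fields, found %d",
                  lineno[bad], nf[bad]))
  }
  mat <- matrix(unlist(fields), ncol = 21L, byrow = TRUE)
  colnames(mat) <- psl_columns
  out <- as_tibble(mat)
  for (col in .psl_int_cols) {
    v <- suppressWarnings(as.integer(out[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(sprintf("malformed PSL line %d: non-numeric value '%s' in column %s",
                    lineno[bad], out[[col]][bad], col))
    }
    out[[col]] <- v
  }
  if (!all(out$strand %in% c("+", "-"))) {
    bad <- which(!out$strand %in% c("+", "-"))[1]
    abort(sprintf("malformed PSL line %d: strand must be '+' or '-', found '%s'",
                  lineno[bad], out$strand[bad]))
  }
  for (col in .psl_list_cols) {
    parsed <- lapply(strsplit(out[[col]], ",", fixed = TRUE), as.integer)
    if (any(vapply(parsed, anyNA, logical(1)))) {
      bad <- which(vapply(parsed, anyNA, logical(1)))[1]
      abort(sprintf("malformed PSL line %d: non-numeric entry in column %s",
                    lineno[bad], col))
    }
    out[[col]] <- parsed
  }
  out
}

#' Write alignments to a PSL file
#'
#' Serialises a PSL tibble (as returned by [read_psl()] or
#' [emit_truth_psl()]) back to headless 21-column PSL text. Round-trips
#' losslessly with [read_psl()].
#'
#' @param psl A PSL tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psl <- function(psl, path) {
  stopifnot(all(psl_columns %in% names(psl)))
  fmt_list <- function(v) vapply(v, function(x) paste0(paste(x, collapse = ","), ","), character(1))
  cols <- lapply(psl_columns, function(col) {
    if (col %in% .psl_list_cols) fmt_list(psl[[col]]) else as.character(psl[[col]])
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Per-alignment percent identity
#'
#' Computes the web-BLAT percent identity (the "milliBad" formula in its
#' mRNA-vs-DNA form) for each alignment: with
#' `qAli = q_end - q_start`, `tAli = t_end - t_start`,
#' `sizeDif = max(qAli - tAli, 0)` and
#' `total = matches + rep_matches + mismatches`,
#' \deqn{milliBad = 1000 (mismatches + qNumInsert +
#'   round(3 \ln(1 + sizeDif))) / total}
#' and the identity is `100 - milliBad / 10`. Only query-side gap openings
#' are penalised and `sizeDif` is floored at zero, as appropriate for
#' spliced transcript alignments whose target-side gaps are introns.
#' Rounding is half-away-from-zero.
#'
#' @param aln A PSL tibble (any number of rows).
#' @return Numeric vector of identities in `[0, 100]`. Degenerate alignments
#'   with `total = 0` return 0 with a warning.
#' @export
percent_identity <- function(aln) {
  if (nrow(aln) == 0) return(numeric())
  total <- aln$matches + aln$rep_matches + aln$mismatches
  q_ali <- aln$q_end - aln$q_start
  t_ali <- aln$t_end - aln$t_start
  size_dif <- pmax(q_ali - t_ali, 0)
  milli_bad <- ifelse(
    total > 0,
    1000 * (aln$mismatches + aln$q_num_insert + round_half_up(3 * log(1 + size_dif))) / total,
    1000
  )
  out <- ifelse(total > 0, 100 - milli_bad / 10, 0)
  if (any(total == 0)) {
    warn(sprintf("%d degenerate alignment(s) with zero aligned bases; identity set to 0",
                 sum(total == 0)))
  }
  out
}

#' Per-alignment query length coverage
#'
#' Fraction of the read that is actually paired in the alignment:
#' `(matches + rep_matches + mismatches) / q_size`. Bases of the query,
#' not the span `q_end - q_start`, so internal query gaps do not inflate
#' coverage.
#'
#' @param aln A PSL tibble.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
length_coverage <- function(aln) {
  if (nrow(aln) == 0) return(numeric())
  if (any(aln$q_size <= 0)) abort("length_coverage: q_size must be positive")
  (aln$matches + aln$rep_matches + aln$mismatches) / aln$q_size
}
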
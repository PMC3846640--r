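#' Build a reference layout table
#'
#' A reference layout places each contig on a reference sequence:
#' `contig`, `ref`, `start`, `end` (0-based half-open), `strand`. A `rank`
#' column (order of the contig along its reference sequence) is computed
#' from the starts. Contigs on one reference sequence must not overlap.
#'
#' @param df Data frame with at least `contig`, `ref`, `start`, `end`,
#'   `strand`.
#' @return Tibble with the five columns plus `rank`.
#' @export
as_reference_layout <- function(df) {
  need <- c("contig", "ref", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    abort(paste0("reference layout needs columns: ", paste(need, collapse = ", ")))
  }
  out <- as_tibble(df)[need]
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (any(out$end <= out$start)) abort("reference layout: end must exceed start")
  if (anyDuplicated(out$contig)) abort("reference layout: duplicate contig ids")
  out <- out |>
    group_by(.data$ref) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  overlap <- out |>
    group_by(.data$ref) |>
    summarise(bad = any(head(.data$end, -1) > tail(.data$start, -1)), .groups = "drop")
  if (any(overlap$bad)) abort("reference layout: overlapping contig spans on one reference")
  out
}

#' Read a reference layout from AGP or TSV
#'
#' Accepts either an AGP file (component `W` lines define contig placements;
#' object coordinates are converted from 1-based closed to 0-based
#' half-open) or a 5-column TSV `contig ref start end strand`, with or
#' without a header line.
#'
#' @param path File path.
#' @return A reference layout tibble (see [as_reference_layout()]).
#' @export
read_reference_layout <- function(path) {
  if (!file.exists(path)) abort(paste0("reference layout not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) abort("reference layout: no records")
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf == 9L)) {
    mat <- do.call(rbind, fields)
    w <- mat[, 5] == "W"
    df <- tibble(
      contig = mat[w, 6], ref = mat[w, 1],
      start = as.integer(mat[w, 2]) - 1L, end = as.integer(mat[w, 3]),
      strand = mat[w, 9]
    )
  } else if (all(nf == 5L)) {
    mat <- do.call(rbind, fields)
    if (mat[1, 1] == "contig") mat <- mat[-1, , drop = FALSE]
    df <- tibble(
      contig = mat[, 1], ref = mat[, 2],
      start = as.integer(mat[, 3]), end = as.integer(mat[, 4]), strand = mat[, 5]
    )
  } else {
    abort("reference layout: expected 9-column AGP or 5-column TSV")
  }
  as_reference_layout(df)
}

#' Write a reference layout as 5-column TSV
#'
#' @param layout A reference layout tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_layout <- function(layout, path) {
  readr::write_tsv(layout[c("contig", "ref", "start", "end", "strand")], path)
  invisible(path)
}

misjoin_levels <- c("consistent", "inversion", "relocation_correctable",
                    "relocation_errant", "translocation", "unevaluable")

#' Classify predicted joins against a reference layout
#'
#' Each predicted join (an oriented contig pair) is compared with the
#' contigs' placement in a trusted reference, using the standard misjoin
#' taxonomy:
#' * `translocation` — the contigs lie on different reference sequences;
#' * `inversion` — same reference, but the join's relative orientation
#'   disagrees with the reference strands;
#' * `consistent` — orientation agrees and the contigs are adjacent along
#'   the reference, in the order and direction the join implies;
#' * `relocation_correctable` — orientation agrees but intervening reference
#'   contigs are skipped (or the order is reversed), and the reference
#'   distance between the two contigs is below `mil`; such joins still
#'   recover the full transcript, since the skipped contigs are intronic;
#' * `relocation_errant` — as above but the distance reaches `mil`.
#'
#' A join touching a contig absent from the layout is `unevaluable` and
#' reported separately. `ref_distance` is the gap from the earlier contig's
#' reference end to the later contig's reference start (same-reference joins
#' only).
#'
#' @param conns Tibble of joins with columns `s_contig`, `s_orient`,
#'   `e_contig`, `e_orient` (e.g. junctions from [path_junctions()]).
#' @param layout A reference layout (see [as_reference_layout()]).
#' @param mil Maximal intron length in bases; the correctable/errant cutoff.
#' @return `conns` with added `category` and `ref_distance` columns.
#' @export
classify_connections <- function(conns, layout, mil = 100000) {
  layout <- as_reference_layout(layout)
  lut <- function(contig, col) layout[[col]][match(contig, layout$contig)]
  r1 <- lut(conns$s_contig, "ref");   r2 <- lut(conns$e_contig, "ref")
  s1 <- lut(conns$s_contig, "strand"); s2 <- lut(conns$e_contig, "strand")
  k1 <- lut(conns$s_contig, "rank");  k2 <- lut(conns$e_contig, "rank")
  b1 <- lut(conns$s_contig, "start"); b2 <- lut(conns$e_contig, "start")
  e1 <- lut(conns$s_contig, "end");   e2 <- lut(conns$e_contig, "end")

  agree1 <- conns$s_orient == s1
  agree2 <- conns$e_orient == s2
  dir <- ifelse(agree1, 1L, -1L)
  dist <- ifelse(b1 <= b2, b2 - e1, b1 - e2)
  same_ref <- !is.na(r1) & !is.na(r2) & r1 == r2
  category <- case_when(
    is.na(r1) | is.na(r2) ~ "unevaluable",
    !same_ref ~ "translocation",
    agree1 != agree2 ~ "inversion",
    k2 == k1 + dir ~ "consistent",
    abs(dist) < mil ~ "relocation_correctable",
    TRUE ~ "relocation_errant"
  )
  conns$category <- factor(category, levels = misjoin_levels)
  conns$ref_distance <- ifelse(same_ref, dist, NA_integer_)
  conns
}

#' Corrected accuracy rate
#'
#' `1 - (inversions + errant relocations + translocations) / total`, where
#' the total counts all evaluable joins. Consistent joins and correctable
#' relocations (which still recover full transcripts) both count as correct.
#'
#' @param x Either a classified connection tibble (from
#'   [classify_connections()]) or a named numeric vector / list of
#'   per-category counts (names among `consistent`, `inversion`,
#'   `relocation_correctable`, `relocation_errant`, `translocation`).
#' @return A fraction in `[0, 1]`.
#' @export
corrected_accuracy <- function(x) {
  if (is.data.frame(x)) {
    cat_ <- as.character(x$category)
    counts <- table(factor(cat_[cat_ != "unevaluable"], levels = setdiff(misjoin_levels, "unevaluable")))
  } else {
    counts <- setNames(numeric(5), setdiff(misjoin_levels, "unevaluable"))
    counts[names(x)] <- unlist(x)
  }
  total <- sum(counts)
  if (total == 0) abort("corrected_accuracy: no evaluable connections")
  bad <- counts[["inversion"]] + counts[["relocation_errant"]] + counts[["translocation"]]
  1 - bad / total
}

#' Extract the junctions of walked scaffold paths
#'
#' Each adjacent fragment pair inside a path is one predicted join, in
#' canonical orientation so it can be tallied against a reference.
#'
#' @param paths Path tibble from [build_paths()].
#' @return Tibble `s_contig`, `s_orient`, `e_contig`, `e_orient`,
#'   `intron_lb`.
#' @export
path_junctions <- function(paths) {
  if (nrow(paths) == 0) {
    out <- connections_empty()
    return(out[setdiff(names(out), "read_id")])
  }
  paths <- paths[order(paths$path_id, paths$position), , drop = FALSE]
  a <- paths[-nrow(paths), , drop = FALSE]
  b <- paths[-1, , drop = FALSE]
  keep <- a$path_id == b$path_id
  junc <- tibble(
    read_id = "",
    s_contig = a$t_name[keep], s_orient = a$orient[keep],
    e_contig = b$t_name[keep], e_orient = b$orient[keep],
    intron_lb = a$intron_lb_to_next[keep]
  )
  out <- canonicalize_connections(junc)
  out[setdiff(names(out), "read_id")]
}
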
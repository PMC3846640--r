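scaffold_end <- function(t_start, t_end, t_size, strand) {
  ifelse(strand == "+", t_end, t_size - t_start)
}

scaffold_start <- function(t_start, t_end, t_size, strand) {
  ifelse(strand == "+", t_start, t_size - t_end)
}

#' Lower bound on the intron between two neighbouring blocks
#'
#' For neighbouring blocks n (on fragment A) and m (on fragment B) of one
#' guide read, the intron separating them is at least
#' `Length(A) - End(n) + Start(m)`: the tail of A after the last aligned
#' base of n plus the head of B before the first aligned base of m, all in
#' scaffold orientation. A block on the minus strand has its coordinates
#' mirrored (`x -> t_size - x`) before the formula is applied.
#'
#' @param block_a,block_b One-row (or equal-length) tibbles of representative
#'   regions with columns `t_start`, `t_end`, `t_size`, `strand`; `block_a`
#'   precedes `block_b` in read order.
#' @return Integer vector of lower bounds in bases; never negative for
#'   coordinate-consistent input (a negative value raises an error).
#' @export
intron_lower_bound <- function(block_a, block_b) {
  d <- block_a$t_size -
    scaffold_end(block_a$t_start, block_a$t_end, block_a$t_size, block_a$strand) +
    scaffold_start(block_b$t_start, block_b$t_end, block_b$t_size, block_b$strand)
  if (any(d < 0)) {
    abort("intron_lower_bound: negative bound; coordinates are not orientation-normalised")
  }
  as.integer(d)
}

connections_empty <- function() {
  tibble(
    read_id = character(),
    s_contig = character(), s_orient = character(),
    e_contig = character(), e_orient = character(),
    intron_lb = integer()
  )
}

#' Emit directed contig connections from one guide read's blocks
#'
#' Walks the read's ordered blocks and, for each adjacent pair on different
#' contigs, emits one directed connection from the earlier block's contig to
#' the later one's, each oriented by its block's strand (a minus-strand block
#' enters the scaffold reverse-complemented). Pairs whose
#' [intron_lower_bound()] exceeds `thr$mil` are dropped — very large implied
#' introns are more likely misalignment or fusion transcripts than true
#' introns. Adjacent blocks on the same contig produce no connection. A
#' guide in which one contig reappears in a non-adjacent block is discarded
#' whole as a likely repeat or chimera artifact.
#'
#' @param blocks Representative blocks of one read, from
#'   [build_read_blocks()].
#' @param thr A [thresholds()] object (only `mil` is used).
#' @return Tibble of connections: `read_id`, `s_contig`, `s_orient`,
#'   `e_contig`, `e_orient`, `intron_lb`.
#' @export
emit_connections <- function(blocks, thr = thresholds()) {
  n <- nrow(blocks)
  if (n < 2) return(connections_empty())
  runs <- rle(blocks$t_name)$values
  if (anyDuplicated(runs)) return(connections_empty())
  a <- blocks[-n, , drop = FALSE]
  b <- blocks[-1, , drop = FALSE]
  keep <- a$t_name != b$t_name
  if (!any(keep)) return(connections_empty())
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  d <- intron_lower_bound(a, b)
  ok <- d <= thr$mil
  tibble(
    read_id = a$read_id[ok],
    s_contig = a$t_name[ok], s_orient = a$strand[ok],
    e_contig = b$t_name[ok], e_orient = b$strand[ok],
    intron_lb = d[ok]
  )
}

flip_orient <- function(x) ifelse(x == "+", "-", "+")

#' Canonicalise connections so mirror-image joins pool their support
#'
#' A connection and its mirror (end reversed then start reversed) describe
#' the same physical join, seen from a sense versus an antisense transcript.
#' The canonical form puts the byte-wise smaller contig identifier first;
#' the lexicographically larger side is mirrored into it.
#'
#' @param conns Connection tibble from [emit_connections()].
#' @return The same tibble with `s_contig`/`s_orient`/`e_contig`/`e_orient`
#'   replaced by their canonical form.
#' @export
canonicalize_connections <- function(conns) {
  if (nrow(conns) == 0) return(conns)
  keep <- str_lt(conns$s_contig, conns$e_contig)
  tibble(
    read_id = conns$read_id,
    s_contig = ifelse(keep, conns$s_contig, conns$e_contig),
    s_orient = ifelse(keep, conns$s_orient, flip_orient(conns$e_orient)),
    e_contig = ifelse(keep, conns$e_contig, conns$s_contig),
    e_orient = ifelse(keep, conns$e_orient, flip_orient(conns$s_orient)),
    intron_lb = conns$intron_lb
  )
}
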
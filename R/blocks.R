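#' Sort a guide read's query regions
#'
#' Orders one read's query regions by ascending start position on the read;
#' ties on the start are broken by descending length, so at equal starts the
#' enclosing region precedes the enclosed one.
#'
#' @param regions Tibble of query regions for a single read (see
#'   [partition_reads()]).
#' @return The regions, reordered.
#' @export
sort_regions <- function(regions) {
  if (nrow(regions) == 0) return(regions)
  regions[order(regions$q_start, -regions$length), , drop = FALSE]
}

#' Drop query regions enclosed by another region
#'
#' A region whose query span lies completely within another region's span
#' (strict containment: the two spans are not identical) is put aside.
#' Identical duplicate spans are both kept; they surface later as an
#' ambiguous block and are filtered there.
#'
#' @param regions Sorted query regions of one read.
#' @return The surviving regions, in order.
#' @export
remove_enclosed <- function(regions) {
  n <- nrow(regions)
  if (n <= 1) return(regions)
  qs <- regions$q_start
  qe <- regions$q_end
  enclosed <- vapply(seq_len(n), function(i) {
    any(qs <= qs[i] & qe >= qe[i] & !(qs == qs[i] & qe == qe[i]))
  }, logical(1))
  regions[!enclosed, , drop = FALSE]
}

#' Cluster query regions into blocks
#'
#' Single-linkage chaining in sort order: a region joins the current block
#' iff the absolute difference between its end position and the end position
#' of the block's last-added member is less than `thr$bound`; otherwise it
#' starts a new block. With `bound = 0` every region is its own block.
#'
#' @param regions Sorted, enclosure-filtered query regions of one read.
#' @param thr A [thresholds()] object (only `bound` is used).
#' @return `regions` with an integer `block` column (1-based, increasing in
#'   read order).
#' @export
cluster_blocks <- function(regions, thr = thresholds()) {
  n <- nrow(regions)
  if (n == 0) return(mutate(regions, block = integer()))
  block <- integer(n)
  block[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      same <- abs(regions$q_end[i] - regions$q_end[i - 1]) < thr$bound
      block[i] <- if (same) block[i - 1] else block[i - 1] + 1L
    }
  }
  mutate(regions, block = block)
}

#' Pick each block's representative region, rejecting ambiguous blocks
#'
#' The longest query region in a block represents it. A block in which two
#' or more regions tie for the maximal length is ambiguous — such co-equal
#' regions typically come from repeats or duplicated genes — and the whole
#' block is filtered out together with its regions.
#'
#' @param clustered Output of [cluster_blocks()] for one read.
#' @return Tibble of representative regions (one row per surviving block)
#'   with columns of the input plus `block` and `order_key` (the
#'   representative's `q_start`); ordered by `order_key`.
#' @export
resolve_representatives <- function(clustered) {
  if (nrow(clustered) == 0) return(mutate(clustered, order_key = integer()))
  reps <- clustered |>
    group_by(.data$block) |>
    filter(sum(.data$length == max(.data$length)) == 1,
           .data$length == max(.data$length)) |>
    ungroup()
  reps <- mutate(reps, order_key = .data$q_start)
  reps[order(reps$order_key), , drop = FALSE]
}

#' Build the ordered exon blocks of one guide read
#'
#' Convenience wrapper running [sort_regions()], [remove_enclosed()],
#' [cluster_blocks()] and [resolve_representatives()] for a single read.
#'
#' @param regions Query regions of one read.
#' @param thr A [thresholds()] object.
#' @return Representative regions in block order along the read.
#' @export
build_read_blocks <- function(regions, thr = thresholds()) {
  regions |>
    sort_regions() |>
    remove_enclosed() |>
    cluster_blocks(thr) |>
    resolve_representatives()
}
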
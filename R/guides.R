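#' Scaffolding thresholds
#'
#' Bundle of the filtering parameters that govern guide selection and
#' connection filtering:
#' * `mpi` — minimal percent identity; alignments below it are discarded.
#' * `mlc` — minimal length coverage (fraction); a read with any single
#'   alignment covering at least this fraction is "fully covered" and never
#'   used as a guide.
#' * `mil` — maximal intron length in bases; a contig pair whose implied
#'   intron lower bound exceeds it loses that read's support.
#' * `bound` — block-clustering distance bound in bases; query regions whose
#'   end positions differ by less than this are clustered into one block.
#'
#' Defaults are the published operating point `mil = 100000`, `mlc = 0.95`,
#' `mpi = 90`, with a 10 bp clustering bound that tolerates aligner
#' end-jitter while keeping adjacent exons distinct.
#'
#' @param mpi Minimal percent identity, in `[0, 100]`.
#' @param mlc Minimal length coverage, in `[0, 1]`.
#' @param mil Maximal intron length in bases, positive.
#' @param bound Block clustering bound in bases, non-negative.
#' @return A list of class `txs_thresholds`.
#' @export
thresholds <- function(mpi = 90, mlc = 0.95, mil = 100000, bound = 10) {
  stopifnot(is.numeric(mpi), length(mpi) == 1, mpi >= 0, mpi <= 100)
  stopifnot(is.numeric(mlc), length(mlc) == 1, mlc >= 0, mlc <= 1)
  stopifnot(is.numeric(mil), length(mil) == 1, mil > 0)
  stopifnot(is.numeric(bound), length(bound) == 1, bound >= 0)
  structure(list(mpi = mpi, mlc = mlc, mil = mil, bound = bound),
            class = "txs_thresholds")
}

#' @export
print.txs_thresholds <- function(x, ...) {
  cat(sprintf("txscaffold thresholds: MPI >= %g%%, MLC >= %g, MIL <= %g bp, bound %g bp\n",
              x$mpi, x$mlc, x$mil, x$bound))
  invisible(x)
}

#' Filter alignments by percent identity
#'
#' Keeps exactly the alignments whose [percent_identity()] is at least
#' `thr$mpi` (inclusive threshold). Input order is preserved.
#'
#' @param alns A PSL tibble.
#' @param thr A [thresholds()] object.
#' @return The surviving rows of `alns`.
#' @export
filter_by_identity <- function(alns, thr = thresholds()) {
  if (nrow(alns) == 0) return(alns)
  alns[percent_identity(alns) >= thr$mpi, , drop = FALSE]
}

#' Partition reads into fully covered reads and guide reads
#'
#' A read with any single alignment whose [length_coverage()] reaches
#' `thr$mlc` is considered fully covered in the genome: all of its
#' alignments are removed from scaffolding (but retained for intron-size
#' estimation). Every other read with at least one surviving alignment
#' becomes a guide; its alignments become query regions that will be
#' clustered into exon blocks.
#'
#' @param alns A PSL tibble, already identity-filtered.
#' @param thr A [thresholds()] object.
#' @return A list with elements:
#'   * `fully_covered` — PSL tibble of all alignments of fully covered reads;
#'   * `guides` — tibble of query regions with columns `read_id`, `q_start`,
#'     `q_end`, `t_name`, `t_size`, `t_start`, `t_end`, `strand`, `length`.
#' @export
partition_reads <- function(alns, thr = thresholds()) {
  if (nrow(alns) == 0) {
    return(list(fully_covered = psl_empty(), guides = guide_regions_empty()))
  }
  cov <- length_coverage(alns)
  covered_reads <- unique(alns$q_name[cov >= thr$mlc])
  fully_covered <- alns[alns$q_name %in% covered_reads, , drop = FALSE]
  rest <- alns[!alns$q_name %in% covered_reads, , drop = FALSE]
  guides <- tibble(
    read_id = rest$q_name,
    q_start = rest$q_start, q_end = rest$q_end,
    t_name = rest$t_name, t_size = rest$t_size,
    t_start = rest$t_start, t_end = rest$t_end,
    strand = rest$strand,
    length = rest$q_end - rest$q_start
  )
  list(fully_covered = fully_covered, guides = guides)
}

guide_regions_empty <- function() {
  tibble(
    read_id = character(), q_start = integer(), q_end = integer(),
    t_name = character(), t_size = integer(), t_start = integer(),
    t_end = integer(), strand = character(), length = integer()
  )
}
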
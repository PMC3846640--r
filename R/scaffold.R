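#' Median intron size from fully covered transcripts
#'
#' Intron sizes are strongly right-skewed, so the median — not the mean —
#' is used as the central tendency of the gap distribution. Every
#' inter-block target-side gap of the fully covered alignments
#' (`t_starts[i+1] - (t_starts[i] + block_sizes[i])`) is collected;
#' non-positive gaps are dropped; the lower median (for an even count, the
#' smaller of the two central values — integer-valued and reproducible) is
#' returned. When no introns are observed, a configurable fallback is
#' returned with a warning.
#'
#' @param fully_covered PSL tibble of fully covered reads' alignments (from
#'   [partition_reads()]).
#' @param fallback Median to assume when no intron is observed (bases).
#' @return Integer number of bases.
#' @export
median_intron_size <- function(fully_covered, fallback = 1000L) {
  gaps <- integer()
  if (nrow(fully_covered) > 0) {
    multi <- fully_covered[fully_covered$block_count > 1, , drop = FALSE]
    if (nrow(multi) > 0) {
      gaps <- unlist(map2(multi$t_starts, multi$block_sizes, function(ts, bs) {
        ts[-1] - (head(ts, -1) + head(bs, -1))
      }))
      gaps <- gaps[gaps > 0]
    }
  }
  if (length(gaps) == 0) {
    warn(sprintf("no introns observed in fully covered reads; using fallback median of %d bases",
                 as.integer(fallback)))
    return(as.integer(fallback))
  }
  sort(gaps)[floor((length(gaps) + 1) / 2)]
}

#' Size the gap at one scaffold junction
#'
#' The sequence between two joined contigs is mostly the unassembled part of
#' an intron. When the junction's intron lower bound is smaller than the
#' median intron size, the gap is filled with `median - lower_bound` Ns
#' (floored at 1) — the expected missing intron length after subtracting the
#' intronic sequence already inside the two contigs. Otherwise a
#' conventional 100 Ns are inserted, indicating only that a gap of unknown
#' size exists.
#'
#' @param lower_bound Intron lower bound(s) at the junction, bases.
#' @param median Median intron size, bases.
#' @return Tibble with `n_count` (integer, >= 1) and
#'   `mode` (`"median_derived"` or `"default_100"`).
#' @export
gap_size <- function(lower_bound, median) {
  stopifnot(all(lower_bound >= 0))
  derived <- lower_bound < median
  tibble(
    n_count = as.integer(ifelse(derived, pmax(median - lower_bound, 1), 100L)),
    mode = ifelse(derived, "median_derived", "default_100")
  )
}

#' N50 of a set of sequence lengths
#'
#' The smallest length L such that sequences of length at least L together
#' contain at least half of the total bases.
#'
#' @param lengths Positive integer vector of sequence lengths.
#' @return The N50 length in bases.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) abort("n50: empty length set")
  if (any(lengths <= 0)) abort("n50: lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[min(which(cumsum(s) >= sum(s) / 2))]
}

as_dna <- function(x, what = "contigs") {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
    names(x) <- sub("\\s.*$", "", names(x))
  }
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (!methods::is(x, "DNAStringSet")) {
    abort(paste0(what, " must be a DNAStringSet, a named character vector, or a FASTA path"))
  }
  x
}

#' Emit scaffold sequences and AGP layout from walked paths
#'
#' Each path becomes one scaffold: its contigs are taken in path order,
#' reverse-complemented where `orient == "-"`, and joined by runs of N sized
#' with [gap_size()] against the supplied median intron. Contigs in no path
#' are emitted unchanged as singletons under their input identifiers;
#' scaffolds are named `scaffold_<k>` in path order. The AGP (v2.0) table
#' records every component and gap line; gap lines carry
#' `scaffold`/`yes`/`align_trnscpt`.
#'
#' @param paths Path tibble from [build_paths()] (may have zero rows).
#' @param contigs Contig sequences: `DNAStringSet`, named character vector,
#'   or FASTA path. Duplicate ids are fatal, as is a path fragment missing
#'   from the set.
#' @param median_intron Median intron size from [median_intron_size()].
#' @return A list with `scaffolds` (a `DNAStringSet`: scaffolds then
#'   singletons) and `agp` (a tibble of AGP v2.0 rows).
#' @export
write_scaffolds <- function(paths, contigs, median_intron = 1000L) {
  contigs <- as_dna(contigs)
  if (anyDuplicated(names(contigs))) {
    abort(paste0("duplicate contig id(s): ",
                 paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", ")))
  }
  missing <- setdiff(paths$t_name, names(contigs))
  if (length(missing)) {
    abort(paste0("path fragment(s) absent from contig FASTA: ", paste(missing, collapse = ", ")))
  }
  seqs <- character()
  agp <- list()
  if (nrow(paths) > 0) {
    for (pid in unique(paths$path_id)) {
      rows <- paths[paths$path_id == pid, , drop = FALSE]
      rows <- rows[order(rows$position), , drop = FALSE]
      sid <- sprintf("scaffold_%d", pid)
      pieces <- character(0)
      beg <- 1L
      part <- 0L
      for (i in seq_len(nrow(rows))) {
        s <- contigs[[rows$t_name[i]]]
        if (rows$orient[i] == "-") s <- Biostrings::reverseComplement(s)
        len <- length(s)
        part <- part + 1L
        agp[[length(agp) + 1L]] <- tibble(
          object = sid, object_beg = beg, object_end = beg + len - 1L,
          part_number = part, component_type = "W",
          component_id = rows$t_name[i], component_beg = "1",
          component_end = as.character(len), orientation = rows$orient[i]
        )
        pieces <- c(pieces, as.character(s))
        beg <- beg + len
        if (i < nrow(rows)) {
          g <- gap_size(rows$intron_lb_to_next[i], median_intron)$n_count
          part <- part + 1L
          agp[[length(agp) + 1L]] <- tibble(
            object = sid, object_beg = beg, object_end = beg + g - 1L,
            part_number = part, component_type = "N",
            component_id = as.character(g), component_beg = "scaffold",
            component_end = "yes", orientation = "align_trnscpt"
          )
          pieces <- c(pieces, strrep("N", g))
          beg <- beg + g
        }
      }
      seqs[sid] <- paste(pieces, collapse = "")
    }
  }
  singles <- setdiff(names(contigs), paths$t_name)
  for (nm in singles) {
    len <- length(contigs[[nm]])
    agp[[length(agp) + 1L]] <- tibble(
      object = nm, object_beg = 1L, object_end = len, part_number = 1L,
      component_type = "W", component_id = nm, component_beg = "1",
      component_end = as.character(len), orientation = "+"
    )
    seqs[nm] <- as.character(contigs[[nm]])
  }
  list(scaffolds = Biostrings::DNAStringSet(seqs), agp = bind_rows(agp))
}

#' Write an AGP v2.0 file
#'
#' @param agp AGP tibble from [write_scaffolds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  lines <- do.call(paste, c(lapply(agp, as.character), sep = "\t"))
  writeLines(c("##agp-version\t2.0", lines), path)
  invisible(path)
}
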
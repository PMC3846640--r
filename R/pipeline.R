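#' Scaffold contigs with transcript evidence, end to end
#'
#' Runs the full scaffolding pipeline: identity filtering, guide selection,
#' block building, connection emission with the maximal-intron filter,
#' best-supported connection selection, path walking, intron-median gap
#' sizing and scaffold emission.
#'
#' @param contigs Contig sequences: `DNAStringSet`, named character vector,
#'   or FASTA path.
#' @param alignments Transcript-to-contig alignments: a PSL tibble or a PSL
#'   file path.
#' @param thr A [thresholds()] object.
#' @param gap_fallback Median intron to assume when no intron is observed in
#'   fully covered reads, bases.
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `txscaffold_run`: a list with the scaffold
#'   sequences (`scaffolds`), AGP layout (`agp`), walked `paths`, support
#'   `tallies`, `selected` connections, fragment `roles`, the
#'   `median_intron`, per-stage `counts`, and the `thresholds` used.
#'   [tidy()] returns the path table, [glance()] the one-row run summary,
#'   and [autoplot()] compares length distributions before and after.
#' @export
scaffold_genome <- function(contigs, alignments, thr = thresholds(),
                            gap_fallback = 1000L, quiet = FALSE) {
  contigs <- as_dna(contigs)
  psl <- if (is.character(alignments)) read_psl(alignments) else alignments
  say <- function(...) if (!quiet) inform(sprintf(...))

  say("alignments in: %d (%d reads)", nrow(psl), length(unique(psl$q_name)))
  kept <- filter_by_identity(psl, thr)
  say("alignments passing MPI >= %g: %d", thr$mpi, nrow(kept))
  parts <- partition_reads(kept, thr)
  n_guides <- length(unique(parts$guides$read_id))
  say("fully covered reads: %d; guide reads: %d",
      length(unique(parts$fully_covered$q_name)), n_guides)

  blocks <- parts$guides |>
    dplyr::group_split(.data$read_id) |>
    map(build_read_blocks, thr = thr)
  conns <- bind_rows(map(blocks, emit_connections, thr = thr))
  say("connections emitted: %d (from %d guide reads)",
      nrow(conns), length(unique(conns$read_id)))

  tallies <- tally_support(conns)
  selected <- select_optimal(tallies)
  say("distinct connections: %d; selected (mutual best): %d", nrow(tallies), nrow(selected))
  roles <- classify_fragments(selected, fragments = names(contigs))
  paths <- build_paths(selected)

  med <- median_intron_size(parts$fully_covered, fallback = gap_fallback)
  say("median intron size: %d bases", med)
  out <- write_scaffolds(paths, contigs, median_intron = med)

  len_in <- Biostrings::width(contigs)
  len_out <- Biostrings::width(out$scaffolds)
  counts <- tibble(
    stage = c("alignments_in", "alignments_identity_filtered", "fully_covered_reads",
              "guide_reads", "connections_emitted", "distinct_connections",
              "selected_connections", "paths", "contigs_in", "scaffold_records_out"),
    n = c(nrow(psl), nrow(kept), length(unique(parts$fully_covered$q_name)),
          n_guides, nrow(conns), nrow(tallies), nrow(selected),
          length(unique(paths$path_id)), length(contigs), length(out$scaffolds))
  )
  say("scaffolds: %d paths + %d singletons; N50 %d -> %d",
      length(unique(paths$path_id)), length(out$scaffolds) - length(unique(paths$path_id)),
      n50(len_in), n50(len_out))

  structure(list(
    scaffolds = out$scaffolds, agp = out$agp, paths = paths,
    tallies = tallies, selected = selected, roles = roles,
    fully_covered = parts$fully_covered, median_intron = med,
    n50_before = n50(len_in), n50_after = n50(len_out),
    counts = counts, thresholds = thr
  ), class = "txscaffold_run")
}

#' @export
print.txscaffold_run <- function(x, ...) {
  cat("txscaffold run\n")
  cat(sprintf("  contigs in:   %d (N50 %d bp)\n",
              x$counts$n[x$counts$stage == "contigs_in"], x$n50_before))
  cat(sprintf("  scaffolds out: %d records, %d multi-contig paths (N50 %d bp)\n",
              length(x$scaffolds), length(unique(x$paths$path_id)), x$n50_after))
  cat(sprintf("  selected connections: %d; median intron %d bp\n",
              nrow(x$selected), x$median_intron))
  invisible(x)
}

#' @rdname scaffold_genome
#' @param x A `txscaffold_run`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.txscaffold_run <- function(x, ...) x$paths

#' @rdname scaffold_genome
#' @exportS3Method generics::glance
glance.txscaffold_run <- function(x, ...) {
  tibble(
    n_contigs = x$counts$n[x$counts$stage == "contigs_in"],
    n_scaffold_records = length(x$scaffolds),
    n_paths = length(unique(x$paths$path_id)),
    n_selected_connections = nrow(x$selected),
    median_intron = x$median_intron,
    n50_before = x$n50_before,
    n50_after = x$n50_after
  )
}

#' Write a run's outputs to disk
#'
#' Writes `<prefix>.fa` (scaffolds), `<prefix>.agp`, `<prefix>.paths.tsv`,
#' `<prefix>.connections.tsv` and `<prefix>.summary.tsv`.
#'
#' @param run A `txscaffold_run`.
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_run <- function(run, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  files <- paste0(prefix, c(".fa", ".agp", ".paths.tsv", ".connections.tsv", ".summary.tsv"))
  Biostrings::writeXStringSet(run$scaffolds, files[1], width = 60)
  write_agp(run$agp, files[2])
  readr::write_tsv(run$paths, files[3])
  readr::write_tsv(run$tallies, files[4])
  readr::write_tsv(bind_rows(run$counts,
                             tibble(stage = c("n50_before", "n50_after", "median_intron"),
                                    n = c(run$n50_before, run$n50_after, run$median_intron))),
                   files[5])
  invisible(files)
}

#' Assess predicted joins against a reference layout
#'
#' Classifies every junction of a scaffolding run (or an explicit junction
#' table) with [classify_connections()] and summarises the misjoin taxonomy
#' and the corrected accuracy rate.
#'
#' @param x A `txscaffold_run` or a tibble of joins (`s_contig`, `s_orient`,
#'   `e_contig`, `e_orient`).
#' @param layout A reference layout (tibble or AGP/TSV path).
#' @param mil Maximal intron length used as the correctable/errant cutoff.
#' @return An object of class `txscaffold_assessment` with `verdicts`,
#'   per-category `summary`, and `corrected_accuracy` (a fraction; `NA`
#'   when nothing is evaluable).
#' @export
assess_scaffolds <- function(x, layout, mil = 100000) {
  junctions <- if (inherits(x, "txscaffold_run")) path_junctions(x$paths) else as_tibble(x)
  if (is.character(layout)) layout <- read_reference_layout(layout)
  verdicts <- classify_connections(junctions, layout, mil = mil)
  summary <- tibble(category = factor(misjoin_levels, levels = misjoin_levels)) |>
    left_join(dplyr::count(verdicts, .data$category), by = "category") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  evaluable <- sum(summary$n[summary$category != "unevaluable"])
  acc <- if (evaluable > 0) corrected_accuracy(verdicts) else NA_real_
  structure(list(verdicts = verdicts, summary = summary,
                 corrected_accuracy = acc, mil = mil),
            class = "txscaffold_assessment")
}

#' @export
print.txscaffold_assessment <- function(x, ...) {
  cat("txscaffold assessment (MIL =", x$mil, "bp)\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-24s %d\n", x$summary$category[i], x$summary$n[i]))
  }
  cat(sprintf("  corrected accuracy: %s\n",
              ifelse(is.na(x$corrected_accuracy), "NA",
                     sprintf("%.4f", x$corrected_accuracy))))
  invisible(x)
}

#' @rdname assess_scaffolds
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.txscaffold_assessment <- function(x, ...) x$verdicts

#' @rdname assess_scaffolds
#' @exportS3Method generics::glance
glance.txscaffold_assessment <- function(x, ...) {
  wide <- setNames(as.list(x$summary$n), as.character(x$summary$category))
  as_tibble(c(wide, list(corrected_accuracy = x$corrected_accuracy)))
}
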
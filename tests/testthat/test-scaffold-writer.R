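multi_block_psl <- function(gaps, q_name = "fc") {
  # one fully covered alignment whose target-side inter-block gaps are `gaps`
  sizes <- rep(100L, length(gaps) + 1)
  t_starts <- cumsum(c(0L, head(sizes, -1) + gaps))
  make_psl(matches = sum(sizes), q_name = q_name, t_size = 100000L,
           t_end = max(t_starts) + 100L,
           block_sizes = sizes, q_starts = cumsum(c(0L, head(sizes, -1))),
           t_starts = t_starts)
}

test_that("median intron size is the lower median of positive target gaps", {
  expect_equal(median_intron_size(multi_block_psl(c(10L, 20L, 30L))), 20L)
  expect_equal(median_intron_size(dplyr::bind_rows(
    multi_block_psl(c(10L, 20L), "a"), multi_block_psl(c(30L, 40L), "b")
  )), 20L)
  # single-block alignments contribute nothing -> fallback with warning
  expect_warning(med <- median_intron_size(make_psl()), "fallback")
  expect_equal(med, 1000L)
  expect_warning(med0 <- median_intron_size(make_psl()[0, ], fallback = 555L))
  expect_equal(med0, 555L)
})

test_that("gap sizing subtracts the lower bound from the median, defaulting to 100 Ns", {
  g <- gap_size(150, 500)
  expect_equal(g$n_count, 350L)
  expect_equal(g$mode, "median_derived")

  g2 <- gap_size(600, 500)
  expect_equal(g2$n_count, 100L)
  expect_equal(g2$mode, "default_100")

  expect_equal(gap_size(499, 500)$n_count, 1L)
  # lower bound equal to the median already falls to the default
  expect_equal(gap_size(500, 500)$mode, "default_100")
})

path_tbl <- function(names, orients, lbs) {
  tibble::tibble(path_id = 1L, position = seq_along(names), t_name = names,
                 orient = orients,
                 weight_to_next = c(rep(1L, length(names) - 1), NA),
                 intron_lb_to_next = c(lbs, NA))
}

test_that("scaffold emission reverse-complements and joins with sized gaps", {
  contigs <- Biostrings::DNAStringSet(c(A = "ACGT", B = "AAAA"))
  paths <- path_tbl(c("A", "B"), c("+", "-"), 495L)
  out <- write_scaffolds(paths, contigs, median_intron = 500L)
  expect_equal(as.character(out$scaffolds[["scaffold_1"]]), "ACGTNNNNNTTTT")
})

test_that("contigs in no path pass through unchanged", {
  contigs <- Biostrings::DNAStringSet(c(A = "ACGT", B = "AAAA"))
  no_paths <- path_tbl("A", "+", integer())[0, ]
  out <- write_scaffolds(no_paths, contigs, 500L)
  expect_equal(as.character(out$scaffolds), c(A = "ACGT", B = "AAAA"))
})

test_that("a 3-contig path produces 3 AGP component lines and 2 gap lines", {
  contigs <- Biostrings::DNAStringSet(c(A = "ACGTACGT", B = "GGGG", C = "TTTTTT"))
  paths <- path_tbl(c("A", "B", "C"), c("+", "+", "+"), c(10L, 600L))
  out <- write_scaffolds(paths, contigs, median_intron = 500L)
  agp <- out$agp[out$agp$object == "scaffold_1", ]
  expect_equal(sum(agp$component_type == "W"), 3)
  expect_equal(sum(agp$component_type == "N"), 2)
  # second junction's bound exceeds the median -> 100 N default
  expect_equal(as.integer(agp$component_id[agp$component_type == "N"]), c(490L, 100L))
})

test_that("missing or duplicated contig ids are fatal", {
  contigs <- Biostrings::DNAStringSet(c(A = "ACGT"))
  paths <- path_tbl(c("A", "Z"), c("+", "+"), 1L)
  expect_error(write_scaffolds(paths, contigs, 500L), "Z")
  dup <- Biostrings::DNAStringSet(c("ACGT", "GG"))
  names(dup) <- c("A", "A")
  expect_error(write_scaffolds(paths, dup, 500L), "duplicate")
})

test_that("N50 is the smallest length covering half the bases", {
  expect_equal(n50(5), 5)
  expect_equal(n50(c(10, 8, 6, 4, 2)), 8)
  expect_equal(n50(c(1, 1, 1, 1)), 1)
  expect_error(n50(numeric()), "empty")
  expect_error(n50(c(5, 0)), "positive")
})

test_that("scaffolding conserves every contig base and never lowers N50", {
  for (seed in c(21, 22, 23)) {
    ds <- simulate_dataset(sim_params(seed = seed, n_genes = 12))
    run <- suppressWarnings(scaffold_genome(ds$contigs, ds$psl, quiet = TRUE))
    non_n <- sum(Biostrings::letterFrequency(run$scaffolds, "ACGT"))
    expect_equal(non_n, sum(Biostrings::width(ds$contigs)))
    # every contig appears exactly once across scaffolds + singletons
    comp <- run$agp$component_id[run$agp$component_type == "W"]
    expect_setequal(comp, names(ds$contigs))
    expect_equal(anyDuplicated(comp), 0L)
    expect_gte(run$n50_after, run$n50_before)
  }
})

test_that("rebuilding scaffolds from AGP lines reproduces the FASTA byte for byte", {
  ds <- simulate_dataset(sim_params(seed = 31, n_genes = 10))
  run <- suppressWarnings(scaffold_genome(ds$contigs, ds$psl, quiet = TRUE))
  for (obj in unique(run$agp$object)) {
    rows <- run$agp[run$agp$object == obj, ]
    rows <- rows[order(rows$part_number), ]
    parts <- vapply(seq_len(nrow(rows)), function(i) {
      if (rows$component_type[i] == "N") {
        strrep("N", as.integer(rows$component_id[i]))
      } else {
        s <- ds$contigs[[rows$component_id[i]]]
        if (rows$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
        as.character(s)
      }
    }, character(1))
    expect_equal(paste(parts, collapse = ""), as.character(run$scaffolds[[obj]]))
  }
})
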
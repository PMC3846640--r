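test_that("the generator is seed-deterministic end to end", {
  p <- sim_params(seed = 42, n_genes = 10, read_error_rate = 0.01,
                  isoform_rate = 0.3, fusion_rate = 0.2)
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(as.character(d1$genome), as.character(d2$genome))
  expect_identical(as.character(d1$contigs), as.character(d2$contigs))
  expect_identical(d1$layout, d2$layout)
  expect_identical(d1$reads$seq, d2$reads$seq)
  expect_identical(d1$psl, d2$psl)
})

test_that("a gene-free genome is intergenic-only with empty annotation", {
  g <- simulate_genome(sim_params(seed = 1, n_genes = 0))
  expect_equal(nrow(g$annotations), 0)
  expect_equal(length(g$genome), 1)
  expect_gt(Biostrings::width(g$genome)[1], 0)
})

test_that("sampled intron medians track the log-normal closed form", {
  meds <- vapply(1:20, function(s) {
    g <- simulate_genome(sim_params(seed = s, n_genes = 30,
                                    intron_meanlog = 7, intron_sdlog = 1))
    ann <- g$annotations
    introns <- ann |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(g = list(utils::tail(start, -1) - utils::head(end, -1)),
                       .groups = "drop")
    stats::median(unlist(introns$g))
  }, numeric(1))
  # log-normal median is exp(meanlog)
  expect_lt(abs(median(meds) - exp(7)) / exp(7), 0.10)
})

test_that("contigs tile each chromosome without gaps or overlaps", {
  p <- sim_params(seed = 9, n_genes = 12, n_chromosomes = 2)
  g <- simulate_genome(p)
  f <- fragment_genome(g$genome, g$annotations, p)
  for (ch in names(g$genome)) {
    lay <- f$layout[f$layout$ref == ch, ]
    lay <- lay[order(lay$start), ]
    expect_equal(lay$start[1], 0L)
    expect_equal(lay$end[nrow(lay)], length(g$genome[[ch]]))
    if (nrow(lay) > 1) expect_equal(lay$start[-1], head(lay$end, -1))
  }
  expect_equal(sum(Biostrings::width(f$contigs)), sum(Biostrings::width(g$genome)))
})

test_that("zero break probability leaves one contig per chromosome", {
  p <- sim_params(seed = 2, n_genes = 5, p_intron_break = 0, p_intergenic_break = 0)
  g <- simulate_genome(p)
  f <- fragment_genome(g$genome, g$annotations, p)
  expect_equal(length(f$contigs), 1)
})

test_that("a broken intron splits its transcript across contigs", {
  p <- sim_params(seed = 3, n_genes = 1, exons_per_gene = c(2L, 2L),
                  p_intron_break = 1, antisense_rate = 0)
  ds <- simulate_dataset(p)
  rec <- ds$psl[ds$psl$q_name == "read_001", ]
  expect_equal(nrow(rec), 2)  # one record per contig
  expect_true(all(length_coverage(rec) < 0.95))
})

test_that("pristine reads equal their spliced exon concatenation", {
  p <- sim_params(seed = 4, n_genes = 6, antisense_rate = 0, tail_length = c(0L, 0L))
  g <- simulate_genome(p)
  reads <- simulate_transcripts(g$annotations, g$genome, p)
  for (i in seq_len(nrow(reads))) {
    ex <- g$annotations[g$annotations$gene_id == reads$gene_id[i], ]
    ex <- ex[order(ex$exon_rank), ]
    expected <- paste(substring(as.character(g$genome[[ex$chrom[1]]]),
                                ex$start + 1L, ex$end), collapse = "")
    expect_identical(reads$seq[i], expected)
  }
})

test_that("fusion and antisense confounders behave as constructed", {
  pf <- sim_params(seed = 6, n_genes = 2, n_chromosomes = 2, fusion_rate = 1,
                   antisense_rate = 0)
  g <- simulate_genome(pf)
  reads <- simulate_transcripts(g$annotations, g$genome, pf)
  expect_true(all(!is.na(reads$fused_to)))
  expect_true(all(vapply(reads$blocks, function(b) length(unique(b$chrom)) == 2, logical(1))))

  # an antisense read reverse-complements the sense read but leaves the
  # canonical connection set unchanged
  base <- sim_params(seed = 12, n_genes = 4, antisense_rate = 0, tail_length = c(0L, 0L))
  anti <- sim_params(seed = 12, n_genes = 4, antisense_rate = 1, tail_length = c(0L, 0L))
  ds_s <- simulate_dataset(base)
  ds_a <- simulate_dataset(anti)
  expect_identical(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(ds_a$reads$seq))),
    ds_s$reads$seq
  )
  conns_of <- function(ds) {
    run <- suppressWarnings(scaffold_genome(ds$contigs, ds$psl, quiet = TRUE))
    run$tallies[c("s_contig", "s_orient", "e_contig", "e_orient", "weight")]
  }
  expect_identical(conns_of(ds_a), conns_of(ds_s))
})

test_that("truth PSL records are exact alignments", {
  ds <- simulate_dataset(sim_params(seed = 13, n_genes = 10))
  expect_true(all(percent_identity(ds$psl) == 100))
  expect_true(all(ds$psl$mismatches == 0))
  # block bookkeeping is internally consistent
  expect_equal(ds$psl$block_count, lengths(ds$psl$block_sizes))
  expect_true(all(ds$psl$matches + ds$psl$mismatches ==
                    vapply(ds$psl$block_sizes, sum, integer(1))))
  # single-exon-in-one-contig records reach full core coverage
  cov <- length_coverage(ds$psl)
  expect_true(all(cov <= 1))

  # substitution errors surface as counted mismatches, not structure changes
  noisy <- simulate_dataset(sim_params(seed = 13, n_genes = 10, read_error_rate = 0.02))
  expect_identical(noisy$psl$block_sizes, ds$psl$block_sizes)
  expect_gt(sum(noisy$psl$mismatches), 0)
  expect_lt(mean(percent_identity(noisy$psl)), 100)
})
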
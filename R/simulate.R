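#' Simulation parameters
#'
#' Study conditions for the synthetic eukaryotic genome / transcriptome
#' generator. Defaults emulate a compact ~1 Mb genome of 100 multi-exon
#' genes with the strongly right-skewed intron-size distribution typical of
#' vertebrate genomes (log-normal, median ~1.1 kb), fragmented with
#' breaks landing in introns (each intron broken with probability 1/2) and
#' in every intergenic gap — the situation in which transcript reads carry
#' contig-linking information while fully covered reads still exist to
#' estimate the intron median.
#'
#' @param seed Integer seed; the same seed gives byte-identical output from
#'   every generator operation.
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of reference sequences the genes are spread
#'   over.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_length Integer range of exon lengths, bases.
#' @param intron_meanlog,intron_sdlog Log-normal parameters of intron
#'   lengths (bases; sampled lengths are floored at 50).
#' @param intergenic_length Integer range of intergenic gap lengths, bases.
#' @param p_intron_break Probability each intron receives one contig break.
#' @param p_intergenic_break Probability each between-gene gap receives one
#'   break.
#' @param p_exon_break Probability each exon receives one break (an
#'   assembly pathology; default 0).
#' @param read_error_rate Per-base substitution rate on reads.
#' @param isoform_rate Probability a gene's read skips one internal exon.
#' @param fusion_rate Probability a read is chimeric (its gene's transcript
#'   fused to another gene's).
#' @param antisense_rate Probability a read is reverse-complemented.
#' @param tail_length Integer range of the unaligned poly(A)-like 3' tail
#'   appended to each read, bases.
#' @return A list of class `txs_sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_genes = 100L,
                       n_chromosomes = 1L,
                       exons_per_gene = c(3L, 8L),
                       exon_length = c(80L, 400L),
                       intron_meanlog = 7,
                       intron_sdlog = 1,
                       intergenic_length = c(500L, 2000L),
                       p_intron_break = 0.5,
                       p_intergenic_break = 1,
                       p_exon_break = 0,
                       read_error_rate = 0,
                       isoform_rate = 0,
                       fusion_rate = 0,
                       antisense_rate = 0.5,
                       tail_length = c(5L, 30L)) {
  p <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
            n_chromosomes = as.integer(n_chromosomes),
            exons_per_gene = as.integer(exons_per_gene),
            exon_length = as.integer(exon_length),
            intron_meanlog = intron_meanlog, intron_sdlog = intron_sdlog,
            intergenic_length = as.integer(intergenic_length),
            p_intron_break = p_intron_break,
            p_intergenic_break = p_intergenic_break,
            p_exon_break = p_exon_break,
            read_error_rate = read_error_rate, isoform_rate = isoform_rate,
            fusion_rate = fusion_rate, antisense_rate = antisense_rate,
            tail_length = as.integer(tail_length))
  rates <- c(p$p_intron_break, p$p_intergenic_break, p$p_exon_break,
             p$read_error_rate, p$isoform_rate, p$fusion_rate, p$antisense_rate)
  if (any(rates < 0 | rates > 1)) abort("sim_params: rates must lie in [0, 1]")
  if (p$n_genes < 0 || p$n_chromosomes < 1) abort("sim_params: invalid counts")
  rngs <- list(p$exons_per_gene, p$exon_length, p$intergenic_length, p$tail_length)
  if (any(vapply(rngs, function(r) length(r) != 2 || r[1] > r[2] || r[1] < 0, logical(1))) ||
      p$exons_per_gene[1] < 1 || p$exon_length[1] < 1 || p$intergenic_length[1] < 1) {
    abort("sim_params: infeasible range")
  }
  structure(p, class = "txs_sim_params")
}

rand_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

sample_range <- function(r, n = 1) {
  if (r[1] == r[2]) rep(r[1], n) else sample(seq(r[1], r[2]), n, replace = TRUE)
}

#' Simulate a genome with annotated multi-exon genes
#'
#' Lays genes end to end along each chromosome: an intergenic gap, then
#' alternating exons and log-normal introns, then the next gap. All genes
#' are annotated on the plus strand; antisense transcription is modelled on
#' the read side (see [simulate_transcripts()]), where it is
#' indistinguishable to the scaffolder.
#'
#' @param p A [sim_params()] object.
#' @return A list with `genome` (a named `DNAStringSet` of chromosomes) and
#'   `annotations` (tibble `gene_id`, `chrom`, `exon_rank`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @export
simulate_genome <- function(p = sim_params()) {
  set.seed(p$seed)
  chrom_names <- sprintf("chr_%d", seq_len(p$n_chromosomes))
  gene_chrom <- if (p$n_genes > 0) sort(rep_len(seq_len(p$n_chromosomes), p$n_genes)) else integer()
  seqs <- setNames(character(p$n_chromosomes), chrom_names)
  ann <- list()
  gene_i <- 0L
  for (ci in seq_len(p$n_chromosomes)) {
    pos <- 0L
    pieces <- character()
    add <- function(n) {
      pieces[[length(pieces) + 1L]] <<- rand_dna(n)
      pos <<- pos + as.integer(n)
    }
    add(sample_range(p$intergenic_length))
    for (g in which(gene_chrom == ci)) {
      gene_i <- gene_i + 1L
      gid <- sprintf("gene_%03d", gene_i)
      k <- sample_range(p$exons_per_gene)
      exon_len <- sample_range(p$exon_length, k)
      intron_len <- if (k > 1) pmax(as.integer(round(rlnorm(k - 1, p$intron_meanlog, p$intron_sdlog))), 50L) else integer()
      for (e in seq_len(k)) {
        if (e > 1) add(intron_len[e - 1])
        ann[[length(ann) + 1L]] <- tibble(
          gene_id = gid, chrom = chrom_names[ci], exon_rank = e,
          start = pos, end = pos + exon_len[e], strand = "+"
        )
        add(exon_len[e])
      }
      add(sample_range(p$intergenic_length))
    }
    seqs[ci] <- paste(pieces, collapse = "")
  }
  annotations <- if (length(ann)) bind_rows(ann) else
    tibble(gene_id = character(), chrom = character(), exon_rank = integer(),
           start = integer(), end = integer(), strand = character())
  list(genome = Biostrings::DNAStringSet(seqs), annotations = annotations)
}

#' Fragment a genome into contigs with a truth layout
#'
#' Cuts each chromosome into contiguous, non-overlapping contigs that tile
#' it exactly. Break positions follow the break policy in `p`: each intron,
#' each between-gene intergenic gap and (optionally) each exon receives one
#' uniformly placed interior break with its configured probability. The
#' returned truth layout records every contig's reference span on the plus
#' strand.
#'
#' @param genome,annotations Output of [simulate_genome()].
#' @param p A [sim_params()] object.
#' @return A list with `contigs` (a `DNAStringSet`) and `layout` (a
#'   reference layout tibble, see [as_reference_layout()]).
#' @export
fragment_genome <- function(genome, annotations, p = sim_params()) {
  set.seed(p$seed + 1L)
  chrom_names <- names(genome)
  intervals <- list()
  if (nrow(annotations) > 0) {
    ann <- annotations[order(annotations$chrom, annotations$gene_id, annotations$exon_rank), ]
    by_gene <- split(ann, ann$gene_id)
    for (g in by_gene) {
      if (nrow(g) > 1) {
        intervals[[length(intervals) + 1L]] <- tibble(
          chrom = g$chrom[-1], lo = head(g$end, -1), hi = tail(g$start, -1),
          prob = p$p_intron_break
        )
      }
      intervals[[length(intervals) + 1L]] <- tibble(
        chrom = g$chrom, lo = g$start, hi = g$end, prob = p$p_exon_break
      )
    }
    gene_spans <- ann |>
      group_by(.data$chrom, .data$gene_id) |>
      summarise(lo = min(.data$start), hi = max(.data$end), .groups = "drop") |>
      arrange(.data$chrom, .data$lo)
    gaps <- gene_spans |>
      group_by(.data$chrom) |>
      filter(n() > 1) |>
      summarise(gap_lo = list(head(.data$hi, -1)), gap_hi = list(tail(.data$lo, -1)),
                .groups = "drop") |>
      tidyr::unnest(c("gap_lo", "gap_hi")) |>
      rename(lo = "gap_lo", hi = "gap_hi")
    if (nrow(gaps) > 0) {
      intervals[[length(intervals) + 1L]] <- mutate(gaps, prob = p$p_intergenic_break)
    }
  }
  breaks <- setNames(vector("list", length(chrom_names)), chrom_names)
  if (length(intervals)) {
    iv <- bind_rows(intervals)
    iv <- iv[order(iv$chrom, iv$lo), , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
      if (iv$hi[i] - iv$lo[i] >= 2 && runif(1) < iv$prob[i]) {
        b <- sample(seq(iv$lo[i] + 1L, iv$hi[i] - 1L), 1)
        breaks[[iv$chrom[i]]] <- c(breaks[[iv$chrom[i]]], b)
      }
    }
  }
  rows <- list()
  seqs <- character()
  k <- 0L
  for (ch in chrom_names) {
    len <- length(genome[[ch]])
    bs <- sort(unique(breaks[[ch]]))
    starts <- c(0L, bs)
    ends <- c(bs, len)
    for (i in seq_along(starts)) {
      k <- k + 1L
      nm <- sprintf("contig_%04d", k)
      rows[[k]] <- tibble(contig = nm, ref = ch, start = starts[i], end = ends[i], strand = "+")
      seqs[nm] <- as.character(Biostrings::subseq(genome[[ch]], starts[i] + 1L, ends[i]))
    }
  }
  list(contigs = Biostrings::DNAStringSet(seqs),
       layout = as_reference_layout(bind_rows(rows)))
}

#' Simulate long transcript reads
#'
#' One read per gene: its spliced exon concatenation, optionally perturbed
#' by the configured confounders — one skipped internal exon (alternative
#' splicing), fusion to a second gene's transcript (chimeric RNA),
#' reverse-complementation (antisense/unknown-strand reads), uniform
#' substitution errors, and a poly(A)-like unaligned 3' tail.
#'
#' @param annotations,genome Output of [simulate_genome()].
#' @param p A [sim_params()] object.
#' @return Tibble with one row per read: `read_id`, `gene_id`, `antisense`,
#'   `fused_to`, `seq` (the final read), `core` (the spliced, error-bearing
#'   sequence before reverse-complementation), `core_len`, `tail_len`,
#'   `q_size`, and a `blocks` list-column mapping transcript coordinates to
#'   genome coordinates (`chrom`, `g_start`, `g_end`, `q_start`, `q_end`).
#' @export
simulate_transcripts <- function(annotations, genome, p = sim_params()) {
  set.seed(p$seed + 2L)
  if (nrow(annotations) == 0) {
    return(tibble(read_id = character(), gene_id = character(),
                  antisense = logical(), fused_to = character(),
                  seq = character(), core = character(), core_len = integer(),
                  tail_len = integer(), q_size = integer(), blocks = list()))
  }
  gseq <- setNames(as.character(genome), names(genome))
  gene_ids <- unique(annotations$gene_id)
  exon_tbl <- function(gid) {
    g <- annotations[annotations$gene_id == gid, , drop = FALSE]
    g[order(g$exon_rank), c("chrom", "start", "end")]
  }
  reads <- list()
  for (i in seq_along(gene_ids)) {
    gid <- gene_ids[i]
    ex <- exon_tbl(gid)
    if (nrow(ex) >= 3 && runif(1) < p$isoform_rate) {
      ex <- ex[-sample(2:(nrow(ex) - 1), 1), , drop = FALSE]
    }
    fused_to <- NA_character_
    if (length(gene_ids) >= 2 && runif(1) < p$fusion_rate) {
      fused_to <- sample(setdiff(gene_ids, gid), 1)
      ex <- bind_rows(ex, exon_tbl(fused_to))
    }
    lens <- ex$end - ex$start
    q_end <- cumsum(lens)
    blocks <- tibble(chrom = ex$chrom, g_start = ex$start, g_end = ex$end,
                     q_start = c(0L, head(q_end, -1)), q_end = as.integer(q_end))
    core <- paste(substring(gseq[ex$chrom], ex$start + 1L, ex$end), collapse = "")
    core_len <- nchar(core)
    if (p$read_error_rate > 0) {
      nmut <- stats::rbinom(1, core_len, p$read_error_rate)
      if (nmut > 0) {
        at <- sample.int(core_len, nmut)
        chars <- strsplit(core, "", fixed = TRUE)[[1]]
        chars[at] <- vapply(chars[at],
                            function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                            character(1))
        core <- paste(chars, collapse = "")
      }
    }
    antisense <- runif(1) < p$antisense_rate
    tail_len <- as.integer(sample_range(p$tail_length))
    body <- if (antisense) revcomp_chr(core) else core
    reads[[i]] <- tibble(
      read_id = sprintf("read_%03d", i), gene_id = gid, antisense = antisense,
      fused_to = fused_to, seq = paste0(body, strrep("A", tail_len)),
      core = core, core_len = core_len, tail_len = tail_len,
      q_size = core_len + tail_len, blocks = list(blocks)
    )
  }
  bind_rows(reads)
}

#' Emit truth PSL alignments for simulated reads
#'
#' Maps each read's exon blocks through the truth layout onto the containing
#' contigs and writes the exact spliced alignments as valid PSL records —
#' correct block structure, strand, coordinates and match/mismatch counts
#' (mismatches are counted by direct sequence comparison, so
#' substitution-bearing reads are handled exactly). One record is emitted
#' per maximal run of blocks on one contig along the read.
#'
#' @param reads Output of [simulate_transcripts()].
#' @param layout Truth layout from [fragment_genome()].
#' @param contigs Contig sequences from [fragment_genome()].
#' @return A PSL tibble (see [psl_columns]).
#' @export
emit_truth_psl <- function(reads, layout, contigs) {
  cseq <- setNames(as.character(contigs), names(contigs))
  recs <- list()
  for (i in seq_len(nrow(reads))) {
    rd <- reads[i, ]
    blocks <- rd$blocks[[1]]
    sub <- list()
    for (j in seq_len(nrow(blocks))) {
      b <- blocks[j, ]
      hit <- layout[layout$ref == b$chrom & layout$start < b$g_end & layout$end > b$g_start, , drop = FALSE]
      if (nrow(hit) == 0) abort("emit_truth_psl: read block maps outside the layout")
      hit <- hit[order(hit$start), , drop = FALSE]
      lo <- pmax(hit$start, b$g_start)
      hi <- pmin(hit$end, b$g_end)
      sub[[j]] <- tibble(
        contig = hit$contig,
        t_start = lo - hit$start, t_end = hi - hit$start,
        q_start = b$q_start + (lo - b$g_start), q_end = b$q_start + (hi - b$g_start)
      )
    }
    sub <- bind_rows(sub)
    sub <- sub[order(sub$q_start), , drop = FALSE]
    run <- cumsum(c(TRUE, sub$contig[-1] != sub$contig[-nrow(sub)]))
    for (r in split(seq_len(nrow(sub)), run)) {
      s <- sub[r, , drop = FALSE]
      s <- s[order(s$t_start), , drop = FALSE]
      contig <- s$contig[1]
      bs <- as.integer(s$q_end - s$q_start)
      mism <- 0L
      for (j in seq_len(nrow(s))) {
        a <- charToRaw(substring(rd$core, s$q_start[j] + 1L, s$q_end[j]))
        b <- charToRaw(substring(cseq[contig], s$t_start[j] + 1L, s$t_end[j]))
        mism <- mism + sum(a != b)
      }
      qgap <- s$q_start[-1] - head(s$q_end, -1)
      tgap <- s$t_start[-1] - head(s$t_end, -1)
      strand <- if (rd$antisense) "-" else "+"
      L <- rd$core_len
      recs[[length(recs) + 1L]] <- tibble(
        matches = sum(bs) - mism, mismatches = mism, rep_matches = 0L, n_count = 0L,
        q_num_insert = sum(qgap > 0), q_base_insert = sum(qgap[qgap > 0]),
        t_num_insert = sum(tgap > 0), t_base_insert = sum(tgap[tgap > 0]),
        strand = strand, q_name = rd$read_id, q_size = rd$q_size,
        q_start = if (strand == "+") min(s$q_start) else L - max(s$q_end),
        q_end = if (strand == "+") max(s$q_end) else L - min(s$q_start),
        t_name = contig, t_size = nchar(cseq[contig]),
        t_start = min(s$t_start), t_end = max(s$t_end),
        block_count = nrow(s),
        block_sizes = list(bs),
        q_starts = list(as.integer(s$q_start + if (strand == "-") rd$tail_len else 0L)),
        t_starts = list(as.integer(s$t_start))
      )
    }
  }
  if (length(recs) == 0) return(psl_empty())
  out <- bind_rows(recs)
  for (col in .psl_int_cols) out[[col]] <- as.integer(out[[col]])
  out
}

#' Generate a complete synthetic scaffolding dataset
#'
#' Runs [simulate_genome()], [fragment_genome()], [simulate_transcripts()]
#' and [emit_truth_psl()] under one parameter set.
#'
#' @param p A [sim_params()] object.
#' @return A list `params`, `genome`, `annotations`, `contigs`, `layout`,
#'   `reads`, `psl`.
#' @export
simulate_dataset <- function(p = sim_params()) {
  g <- simulate_genome(p)
  f <- fragment_genome(g$genome, g$annotations, p)
  reads <- simulate_transcripts(g$annotations, g$genome, p)
  psl <- emit_truth_psl(reads, f$layout, f$contigs)
  list(params = p, genome = g$genome, annotations = g$annotations,
       contigs = f$contigs, layout = f$layout, reads = reads, psl = psl)
}

#' Write a synthetic dataset to disk
#'
#' Writes `genome.fa`, `contigs.fa`, `reads.fa`, `alignments.psl`,
#' `layout.tsv` and a `params.json` snapshot under `dir`.
#'
#' @param ds Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ds$genome, file.path(dir, "genome.fa"), width = 60)
  Biostrings::writeXStringSet(ds$contigs, file.path(dir, "contigs.fa"), width = 60)
  rfa <- Biostrings::DNAStringSet(setNames(ds$reads$seq, ds$reads$read_id))
  Biostrings::writeXStringSet(rfa, file.path(dir, "reads.fa"), width = 60)
  write_psl(ds$psl, file.path(dir, "alignments.psl"))
  write_reference_layout(ds$layout, file.path(dir, "layout.tsv"))
  jsonlite::write_json(unclass(ds$params), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
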
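test_that("intron lower bound follows Length(A) - End(n) + Start(m)", {
  a <- make_region(q_start = 0, q_end = 100, t_name = "A", t_size = 1000,
                   t_start = 800, t_end = 900)
  b <- make_region(q_start = 100, q_end = 200, t_name = "B", t_size = 2000,
                   t_start = 50, t_end = 150)
  expect_equal(intron_lower_bound(a, b), 150L)

  # abutting exons at the fragment boundary
  a2 <- make_region(q_start = 0, q_end = 100, t_name = "A", t_size = 1000,
                    t_start = 900, t_end = 1000)
  b2 <- make_region(q_start = 100, q_end = 200, t_name = "B", t_size = 2000,
                    t_start = 0, t_end = 100)
  expect_equal(intron_lower_bound(a2, b2), 0L)

  # a reversed fragment's coordinates are mirrored: a block at raw [0,100)
  # of a 1000 bp fragment abuts the junction after reversal, so only the
  # next fragment's head contributes
  a3 <- make_region(q_start = 0, q_end = 100, t_name = "A", t_size = 1000,
                    t_start = 0, t_end = 100, strand = "-")
  expect_equal(intron_lower_bound(a3, b2), 0L)
  # mid-fragment reversed block: raw [600,700) sits at [300,400) reversed,
  # leaving 600 bases of tail
  a4 <- make_region(q_start = 0, q_end = 100, t_name = "A", t_size = 1000,
                    t_start = 600, t_end = 700, strand = "-")
  expect_equal(intron_lower_bound(a4, b2), 600L)
})

blocks_of <- function(...) {
  b <- dplyr::bind_rows(...)
  b$block <- seq_len(nrow(b))
  b$order_key <- b$q_start
  b
}

test_that("adjacent blocks on different contigs yield oriented connections", {
  blocks <- blocks_of(
    make_region(q_start = 0, q_end = 100, t_name = "A", t_size = 1000,
                t_start = 850, t_end = 950, strand = "+"),
    make_region(q_start = 100, q_end = 200, t_name = "B", t_size = 1000,
                t_start = 100, t_end = 200, strand = "-"),
    make_region(q_start = 200, q_end = 300, t_name = "C", t_size = 1000,
                t_start = 20, t_end = 120, strand = "+")
  )
  conns <- emit_connections(blocks, thresholds())
  expect_equal(nrow(conns), 2)
  expect_equal(conns$s_contig, c("A", "B"))
  expect_equal(conns$s_orient, c("+", "-"))
  expect_equal(conns$e_contig, c("B", "C"))
  expect_equal(conns$e_orient, c("-", "+"))
})

test_that("pairs implying introns above MIL are dropped", {
  blocks <- blocks_of(
    make_region(q_start = 0, q_end = 100, t_name = "A", t_size = 100000,
                t_start = 0, t_end = 100),
    make_region(q_start = 100, q_end = 200, t_name = "B", t_size = 100000,
                t_start = 50100, t_end = 50200)
  )
  # lower bound = 100000 - 100 + 50100 = 150000
  expect_equal(nrow(emit_connections(blocks, thresholds(mil = 100000))), 0)
  expect_equal(nrow(emit_connections(blocks, thresholds(mil = 200000))), 1)
})

test_that("same-contig pairs and repeated-contig guides produce nothing", {
  same <- blocks_of(
    make_region(q_start = 0, q_end = 100, t_name = "A", t_start = 0),
    make_region(q_start = 100, q_end = 200, t_name = "A", t_start = 2000)
  )
  expect_equal(nrow(emit_connections(same, thresholds())), 0)

  repeated <- blocks_of(
    make_region(q_start = 0, q_end = 100, t_name = "A", t_start = 9000, t_end = 9100),
    make_region(q_start = 100, q_end = 200, t_name = "B", t_start = 0),
    make_region(q_start = 200, q_end = 300, t_name = "A", t_start = 0)
  )
  expect_equal(nrow(emit_connections(repeated, thresholds())), 0)
})

test_that("a guide with k blocks on k contigs yields at most k - 1 connections", {
  set.seed(7)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    blocks <- blocks_of(dplyr::bind_rows(lapply(seq_len(k), function(i) {
      make_region(q_start = (i - 1) * 100, q_end = i * 100,
                  t_name = sprintf("c%02d", i), t_size = 5000,
                  t_start = sample(0:4900, 1),
                  t_end = NULL, strand = sample(c("+", "-"), 1))
    })))
    blocks$t_end <- pmin(blocks$t_start + 100L, blocks$t_size)
    conns <- emit_connections(blocks, thresholds())
    expect_lte(nrow(conns), k - 1)
    if (nrow(conns) > 0) expect_true(all(conns$intron_lb <= 100000))
  }
})

test_that("reversing a guide read yields the mirror connections, equal under canonicalisation", {
  blocks <- blocks_of(
    make_region(q_start = 0, q_end = 100, t_name = "A", t_size = 1000,
                t_start = 850, t_end = 950, strand = "+"),
    make_region(q_start = 100, q_end = 200, t_name = "B", t_size = 1000,
                t_start = 100, t_end = 200, strand = "-"),
    make_region(q_start = 200, q_end = 300, t_name = "C", t_size = 1000,
                t_start = 20, t_end = 120, strand = "+")
  )
  # the same read sequenced from the other strand: block order mirrored,
  # strands complemented, query coordinates reflected
  L <- 300L
  rev_blocks <- blocks[nrow(blocks):1, ]
  rev_blocks$strand <- ifelse(rev_blocks$strand == "+", "-", "+")
  qs <- L - rev_blocks$q_end
  rev_blocks$q_end <- L - rev_blocks$q_start
  rev_blocks$q_start <- qs
  rev_blocks$order_key <- rev_blocks$q_start
  rev_blocks$block <- seq_len(nrow(rev_blocks))

  fwd <- canonicalize_connections(emit_connections(blocks, thresholds()))
  rev <- canonicalize_connections(emit_connections(rev_blocks, thresholds()))
  key <- function(x) sort(paste(x$s_contig, x$s_orient, x$e_contig, x$e_orient, x$intron_lb))
  expect_equal(key(rev), key(fwd))
})
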
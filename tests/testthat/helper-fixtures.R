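# Build a single PSL record with consistent derived fields unless overridden.
make_psl <- function(matches = 100L, mismatches = 0L, rep_matches = 0L,
                     n_count = 0L, q_num_insert = 0L, q_base_insert = 0L,
                     t_num_insert = 0L, t_base_insert = 0L, strand = "+",
                     q_name = "r1", q_size = NULL, q_start = 0L, q_end = NULL,
                     t_name = "c1", t_size = 10000L, t_start = 0L, t_end = NULL,
                     block_sizes = NULL, q_starts = NULL, t_starts = NULL) {
  aligned <- matches + rep_matches + mismatches
  if (is.null(q_end)) q_end <- q_start + aligned
  if (is.null(q_size)) q_size <- q_end
  if (is.null(t_end)) t_end <- t_start + aligned
  if (is.null(block_sizes)) block_sizes <- aligned
  if (is.null(q_starts)) q_starts <- q_start
  if (is.null(t_starts)) t_starts <- t_start
  tibble::tibble(
    matches = as.integer(matches), mismatches = as.integer(mismatches),
    rep_matches = as.integer(rep_matches), n_count = as.integer(n_count),
    q_num_insert = as.integer(q_num_insert), q_base_insert = as.integer(q_base_insert),
    t_num_insert = as.integer(t_num_insert), t_base_insert = as.integer(t_base_insert),
    strand = strand, q_name = q_name, q_size = as.integer(q_size),
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    t_name = t_name, t_size = as.integer(t_size),
    t_start = as.integer(t_start), t_end = as.integer(t_end),
    block_count = length(block_sizes),
    block_sizes = list(as.integer(block_sizes)),
    q_starts = list(as.integer(q_starts)), t_starts = list(as.integer(t_starts))
  )
}

# A query region row as produced by partition_reads().
make_region <- function(read_id = "r1", q_start, q_end, t_name = "c1",
                        t_size = 10000L, t_start = 0L, t_end = NULL,
                        strand = "+") {
  if (is.null(t_end)) t_end <- t_start + (q_end - q_start)
  tibble::tibble(
    read_id = read_id, q_start = as.integer(q_start), q_end = as.integer(q_end),
    t_name = t_name, t_size = as.integer(t_size),
    t_start = as.integer(t_start), t_end = as.integer(t_end),
    strand = strand, length = as.integer(q_end - q_start)
  )
}

# Directed weighted edge table in the shape select_optimal() consumes.
make_tallies <- function(from, to, weight, s_orient = "+", e_orient = "+") {
  tibble::tibble(
    s_contig = from, s_orient = rep_len(s_orient, length(from)),
    e_contig = to, e_orient = rep_len(e_orient, length(from)),
    weight = as.integer(weight), intron_lb = 0L
  )
}

# Independent brute-force implementation of the optimal-connection and
# path-walking rules, used as the oracle for graph_resolver: per node keep
# the unique max-weight outgoing and incoming edge (a tie disqualifies the
# role), retain mutually-best edges, then walk from every node that starts
# an edge but ends none, collecting node chains.
oracle_paths <- function(edges) {
  n <- nrow(edges)
  if (n == 0) return(list())
  keep_out <- logical(n)
  keep_in <- logical(n)
  for (i in seq_len(n)) {
    w_out <- edges$weight[edges$from == edges$from[i]]
    keep_out[i] <- edges$weight[i] == max(w_out) && sum(w_out == max(w_out)) == 1
    w_in <- edges$weight[edges$to == edges$to[i]]
    keep_in[i] <- edges$weight[i] == max(w_in) && sum(w_in == max(w_in)) == 1
  }
  sel <- edges[keep_out & keep_in, , drop = FALSE]
  preds <- sort(setdiff(sel$from, sel$to), method = "radix")
  lapply(preds, function(p) {
    chain <- p
    cur <- p
    while (cur %in% sel$from) {
      cur <- sel$to[sel$from == cur]
      chain <- c(chain, cur)
    }
    chain
  })
}

# Package-side counterpart: resolve a directed weighted edge table and
# return the walked paths as a list of node chains.
package_paths <- function(edges) {
  tal <- make_tallies(edges$from, edges$to, edges$weight)
  sel <- select_optimal(tal)
  paths <- suppressWarnings(build_paths(sel))
  if (nrow(paths) == 0) return(list())
  unname(lapply(split(paths, paths$path_id), function(p) p$t_name[order(p$position)]))
}
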
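#' Tally supporting reads per canonical connection
#'
#' Groups connections by their canonical oriented contig pair and counts the
#' distinct reads supporting each; one read contributes at most 1 to a given
#' edge even if several of its block pairs link the same contigs. The
#' minimum intron lower bound across supporting reads is carried along for
#' later gap sizing (the most conservative estimate of missing sequence).
#'
#' @param conns Connection tibble (canonicalised internally).
#' @return Tibble with `s_contig`, `s_orient`, `e_contig`, `e_orient`,
#'   `weight` (distinct supporting reads) and `intron_lb`, sorted by contig
#'   pair for reproducibility.
#' @export
tally_support <- function(conns) {
  conns <- canonicalize_connections(conns)
  if (nrow(conns) == 0) {
    return(tibble(s_contig = character(), s_orient = character(),
                  e_contig = character(), e_orient = character(),
                  weight = integer(), intron_lb = integer()))
  }
  out <- conns |>
    group_by(.data$s_contig, .data$s_orient, .data$e_contig, .data$e_orient) |>
    summarise(weight = n_distinct(.data$read_id),
              intron_lb = min(.data$intron_lb), .groups = "drop")
  key <- paste(out$s_contig, out$s_orient, out$e_contig, out$e_orient, sep = "\r")
  out[order(key, method = "radix"), , drop = FALSE]
}

#' Select each fragment's best-supported connection per role
#'
#' For every fragment acting as a start, only its maximum-weight outgoing
#' connection is retained; likewise, as an end, only the maximum-weight
#' incoming connection. A fragment whose maximum is tied between two or more
#' connections takes no edge in that role (ties in one role do not affect
#' the other role). An edge survives only if it is the chosen edge of both
#' its start and its end fragment, so every fragment ends up in at most two
#' selected connections — one outgoing, one incoming.
#'
#' @param tallies Output of [tally_support()].
#' @return The selected rows of `tallies`.
#' @export
select_optimal <- function(tallies) {
  n <- nrow(tallies)
  if (n == 0) return(tallies)
  chosen_role <- function(key) {
    sel <- logical(n)
    for (idx in split(seq_len(n), key)) {
      w <- tallies$weight[idx]
      mw <- max(w)
      hits <- idx[w == mw]
      if (length(hits) == 1) sel[hits] <- TRUE
    }
    sel
  }
  out_ok <- chosen_role(tallies$s_contig)
  in_ok <- chosen_role(tallies$e_contig)
  tallies[out_ok & in_ok, , drop = FALSE]
}

#' Classify fragments by their role in the selected connection set
#'
#' * crossover — the fragment is the start of one selected connection and
#'   the end of another (an internal scaffold node);
#' * predecessor — start only (a scaffold's first fragment);
#' * terminator — end only (a scaffold's last fragment);
#' * unplaced — in no selected connection.
#'
#' @param selected Selected connections from [select_optimal()].
#' @param fragments Character vector of all fragment ids to classify;
#'   defaults to the fragments appearing in `selected`.
#' @return Tibble `t_name`, `role`.
#' @export
classify_fragments <- function(selected,
                               fragments = union(selected$s_contig, selected$e_contig)) {
  if (anyDuplicated(selected$s_contig) || anyDuplicated(selected$e_contig)) {
    abort("classify_fragments: a fragment holds two selected edges in one role")
  }
  fragments <- sort(unique(fragments), method = "radix")
  has_out <- fragments %in% selected$s_contig
  has_in <- fragments %in% selected$e_contig
  tibble(
    t_name = fragments,
    role = case_when(
      has_out & has_in ~ "crossover",
      has_out ~ "predecessor",
      has_in ~ "terminator",
      TRUE ~ "unplaced"
    )
  )
}

paths_empty <- function() {
  tibble(path_id = integer(), position = integer(), t_name = character(),
         orient = character(), weight_to_next = integer(),
         intron_lb_to_next = integer())
}

#' Walk scaffold paths through the selected connections
#'
#' Starting from each predecessor, follows selected connections through
#' crossover fragments until a terminator is reached. Every selected edge is
#' used at most once; components with no predecessor (cycles) are
#' unreachable by construction and are discarded whole with a warning, their
#' fragments remaining unplaced singletons. If consecutive selected edges
#' disagree on a shared fragment's orientation, the path ends there and the
#' conflicting downstream edges are likewise discarded with a warning.
#' Predecessors are visited in byte-wise fragment-id order, so identical
#' inputs give identical path tables regardless of record order.
#'
#' @param selected Selected connections from [select_optimal()].
#' @return Tibble with one row per placed fragment: `path_id`, `position`,
#'   `t_name`, `orient`, and `weight_to_next` / `intron_lb_to_next` for the
#'   junction to the following fragment (`NA` on the last fragment).
#' @export
build_paths <- function(selected) {
  if (nrow(selected) == 0) return(paths_empty())
  roles <- classify_fragments(selected)
  preds <- roles$t_name[roles$role == "predecessor"]
  next_of <- setNames(seq_len(nrow(selected)), selected$s_contig)
  used <- logical(nrow(selected))
  rows <- list()
  path_id <- 0L
  for (p in preds) {
    e <- next_of[[p]]
    path_id <- path_id + 1L
    pos <- 1L
    rows[[length(rows) + 1L]] <- tibble(
      path_id = path_id, position = pos,
      t_name = selected$s_contig[e], orient = selected$s_orient[e],
      weight_to_next = selected$weight[e], intron_lb_to_next = selected$intron_lb[e]
    )
    used[e] <- TRUE
    repeat {
      cur <- selected$e_contig[e]
      cur_or <- selected$e_orient[e]
      nxt <- next_of[cur]
      if (is.na(nxt) || used[nxt]) {
        # terminator (or, defensively, an already-walked edge)
        rows[[length(rows) + 1L]] <- tibble(
          path_id = path_id, position = pos + 1L, t_name = cur, orient = cur_or,
          weight_to_next = NA_integer_, intron_lb_to_next = NA_integer_
        )
        break
      }
      nxt <- unname(nxt)
      if (selected$s_orient[nxt] != cur_or) {
        warn(sprintf("conflicting orientation evidence at fragment %s; ending path here", cur))
        rows[[length(rows) + 1L]] <- tibble(
          path_id = path_id, position = pos + 1L, t_name = cur, orient = cur_or,
          weight_to_next = NA_integer_, intron_lb_to_next = NA_integer_
        )
        break
      }
      pos <- pos + 1L
      rows[[length(rows) + 1L]] <- tibble(
        path_id = path_id, position = pos, t_name = cur, orient = cur_or,
        weight_to_next = selected$weight[nxt], intron_lb_to_next = selected$intron_lb[nxt]
      )
      used[nxt] <- TRUE
      e <- nxt
    }
  }
  if (!all(used)) {
    warn(sprintf("%d selected connection(s) unreachable from any predecessor (cycles or conflicts); their fragments stay unplaced",
                 sum(!used)))
  }
  if (length(rows) == 0) return(paths_empty())
  bind_rows(rows)
}
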
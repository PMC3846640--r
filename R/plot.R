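#' Plot contig versus scaffold length distributions
#'
#' Empirical cumulative base coverage by sequence length, before and after
#' scaffolding — the curve whose half-way crossing is the N50.
#'
#' @param object A `txscaffold_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.txscaffold_run <- function(object, ...) {
  # input contig lengths are recoverable from the AGP component lines
  comp <- object$agp[object$agp$component_type == "W", , drop = FALSE]
  df <- bind_rows(
    tibble(set = "contigs (before)", length = as.numeric(comp$component_end)),
    tibble(set = "scaffolds (after)",
           length = as.numeric(Biostrings::width(object$scaffolds)))
  )
  df <- df |>
    group_by(.data$set) |>
    arrange(dplyr::desc(.data$length), .by_group = TRUE) |>
    mutate(cum_frac = cumsum(.data$length) / sum(.data$length)) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$cum_frac,
                                   colour = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sequence length (bp, log scale)",
                  y = "cumulative fraction of bases (longest first)",
                  colour = NULL,
                  title = "Assembly contiguity before and after scaffolding") +
    ggplot2::theme_minimal()
}

#' Plot connection support weights
#'
#' Bar chart of the number of distinct supporting reads per distinct
#' connection, split by whether the connection survived best-support
#' selection.
#'
#' @param run A `txscaffold_run`.
#' @return A ggplot object.
#' @export
plot_connection_support <- function(run) {
  sel_key <- paste(run$selected$s_contig, run$selected$e_contig)
  df <- run$tallies |>
    mutate(selected = ifelse(paste(.data$s_contig, .data$e_contig) %in% sel_key,
                             "selected", "dropped"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$weight), fill = .data$selected)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "supporting reads per connection", y = "connections",
                  fill = NULL, title = "Connection support") +
    ggplot2::theme_minimal()
}

#' Plot the misjoin taxonomy of an assessment
#'
#' @param object A `txscaffold_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.txscaffold_assessment <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "connections",
                  title = sprintf("Misjoin classification (corrected accuracy %.3f)",
                                  object$corrected_accuracy)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
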
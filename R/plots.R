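# ggplot2 displays for the main result types.

#' Plot gains and losses per species branch
#'
#' Diverging bar chart of weighted gain (up) and loss (down) tallies along
#' nonterminal species-tree branches, faceted by organelle when several are
#' present.
#'
#' @param tallies Tibble from [tally_changes()].
#' @param include_terminal Include terminal branches (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_branch_tallies <- function(tallies, include_terminal = FALSE) {
  df <- if (include_terminal) tallies else
    tallies[!tallies$terminal, , drop = FALSE]
  long <- tidyr::pivot_longer(df, c("gains", "losses"),
                              names_to = "direction", values_to = "count")
  long$count <- ifelse(long$direction == "losses", -long$count, long$count)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$species_label, y = .data$count, fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(gains = "#2E8B57",
                                          losses = "#E0701A")) +
    ggplot2::labs(x = "species-tree branch", y = "weighted changes",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (length(unique(long$organelle)) > 1L) {
    p <- p + ggplot2::facet_wrap(~organelle)
  }
  p
}

#' Plot normalized rates for change versus no-change branches
#'
#' @param rates Tibble from [collect_normalized_rates()].
#' @return A ggplot object (log-scale boxplot).
#' @export
plot_rate_comparison <- function(rates) {
  df <- rates
  df$group <- ifelse(df$has_change, "change", "no change")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$norm_rate)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "normalized branch rate (gene / species)") +
    ggplot2::theme_minimal()
}

#' Plot change frequencies after duplication and speciation
#'
#' @param dup_test A `dup_change_test` from [duplication_change_test()].
#' @return A ggplot object.
#' @export
plot_duplication_association <- function(dup_test) {
  df <- tidy(dup_test)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = 100 * .data$frequency)) +
    ggplot2::geom_col(fill = "#4477AA", width = 0.6) +
    ggplot2::labs(x = NULL, y = "% nodes with child-branch targeting change") +
    ggplot2::theme_minimal()
}

#' Plot top enriched terms
#'
#' @param enrichment Tibble from [enrich()].
#' @param top_n Number of terms to display (default 15).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top_n = 15) {
  df <- head(enrichment[order(enrichment$q), , drop = FALSE], top_n)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q), y = .data$term,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#4477AA",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = expression(-log[10] * "(BH-corrected p)"), y = NULL,
                  fill = "q <= 0.01") +
    ggplot2::theme_minimal()
}

#' Plot per-million-year change rates across dated nodes
#'
#' @param per_myr Tibble from [per_myr_rates()].
#' @return A ggplot object.
#' @export
plot_myr_rates <- function(per_myr) {
  long <- tidyr::pivot_longer(per_myr, c("total_per_my", "net_per_my"),
                              names_to = "measure", values_to = "rate")
  long$measure <- ifelse(long$measure == "total_per_my",
                         "total (gains + losses)", "net (gains - losses)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$organelle, y = .data$rate)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, size = 0.8, alpha = 0.6) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "changes per My") +
    ggplot2::theme_minimal()
}
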
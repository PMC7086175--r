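# Molecular-rate analyses: normalized branch rates (gene-tree branch length
# divided by the corresponding species-tree branch length) compared between
# change and no-change branches with a Welch t-test and a phylogenetically
# matched Monte Carlo resampling test; and per-million-year change rates from
# dated species-tree nodes.

#' Collect normalized molecular rates for qualifying gene-tree branches
#'
#' The normalized rate of a gene-tree branch is its length (substitutions per
#' site) divided by the length of the corresponding species-tree branch. Only
#' branches uniquely placed in the species tree (span of exactly one species
#' branch) with no duplication at either endpoint qualify; branches over
#' zero-length species branches are excluded and counted.
#'
#' @param recon An [lca_reconcile()] result whose gene tree has branch lengths.
#' @param events Optional event tibble from [call_changes()] for the same
#'   orthogroup, used to flag change branches.
#' @param orthogroup Orthogroup id recorded on the rows.
#' @return A tibble with `orthogroup`, `parent`, `child`, `species_branch`,
#'   `norm_rate`, `has_change`; excluded-branch counts in attribute
#'   `excluded` (named integer vector).
#' @export
collect_normalized_rates <- function(recon, events = NULL, orthogroup = "OG") {
  stopifnot(inherits(recon, "orgflux_recon"))
  gt <- recon$gene_tree
  sp <- recon$species_tree
  assert_branch_lengths(gt, "rate analysis")
  assert_branch_lengths(sp, "rate analysis")
  sp_len <- numeric(n_nodes_total(sp))
  sp_len[sp$edge[, 2L]] <- sp$edge.length

  change_key <- character(0)
  if (!is.null(events) && nrow(events)) {
    change_key <- paste(events$parent, events$child)
  }

  p <- gt$edge[, 1L]; c_ <- gt$edge[, 2L]
  span_len <- lengths(recon$spans)
  span1 <- vapply(recon$spans, function(s) if (length(s) == 1L) s else NA_integer_,
                  integer(1))
  dup_end <- recon$event[p] == "duplication" | recon$event[c_] == "duplication"
  keep_place <- span_len == 1L & !dup_end
  sl <- ifelse(is.na(span1), NA_real_, sp_len[ifelse(is.na(span1), 1L, span1)])
  keep <- keep_place & !is.na(sl) & sl > 0
  excluded <- c(
    multi_span = sum(span_len > 1L),
    within_species = sum(span_len == 0L),
    duplication = sum(dup_end & span_len == 1L),
    zero_species_branch = sum(keep_place & sl <= 0, na.rm = TRUE)
  )
  out <- tibble::tibble(
    orthogroup = rep(orthogroup, sum(keep)),
    parent = p[keep], child = c_[keep],
    species_branch = span1[keep],
    norm_rate = gt$edge.length[keep] / sl[keep],
    has_change = paste(p[keep], c_[keep]) %in% change_key
  )
  attr(out, "excluded") <- excluded
  out
}

# Draw one matched resample of no-change rates: per species-branch stratum,
# as many values as the change group has there, with replacement. Strata
# absent from the no-change pool fall back to the topologically nearest
# available stratum (or the whole pool when no species tree is supplied).
matched_resample <- function(change_counts, nochange_values_by_stratum,
                             fallback) {
  out <- numeric(0)
  for (s in names(change_counts)) {
    pool <- nochange_values_by_stratum[[s]]
    if (is.null(pool) || !length(pool)) pool <- fallback[[s]]
    out <- c(out, pool[sample.int(length(pool), change_counts[[s]],
                                  replace = TRUE)])
  }
  out
}

#' Compare normalized rates between change and no-change branches
#'
#' Two complementary tests on the normalized branch rates of branches
#' associated with a change in organellar targeting versus those without:
#' a two-tailed Welch t-test, and a matched Monte Carlo test that repeatedly
#' draws from the no-change group a multiset matching the change group's size
#' and per-species-branch distribution and compares group means (one-sided:
#' the resampled mean at least as large as the observed change-group mean).
#' The Monte Carlo p-value uses the add-one estimator
#' (1 + hits) / (1 + n_resamples), so it lies in \[1/(n+1), 1\].
#'
#' @param rates Tibble from [collect_normalized_rates()] (rows from several
#'   orthogroups may be bound together).
#' @param n_resamples Number of matched resamples (default 1000).
#' @param species_tree Optional species `phylo`; when given, strata missing
#'   from the no-change pool are matched to the topologically nearest
#'   available stratum (with a warning), otherwise to the whole pool.
#' @param seed Optional integer seed for reproducible resampling.
#' @return An object of class `rate_comparison`: list with `mean_change`,
#'   `mean_nochange`, `t_p`, `mc_p`, `n_change`, `n_nochange`, `n_resamples`.
#' @export
compare_rates <- function(rates, n_resamples = 1000, species_tree = NULL,
                          seed = NULL) {
  ch <- rates$norm_rate[rates$has_change]
  nc <- rates$norm_rate[!rates$has_change]
  if (!length(ch) || !length(nc)) {
    abort("both the change and no-change groups must be nonempty")
  }
  if (!is.null(seed)) set.seed(seed)

  t_p <- if (length(ch) > 1L && length(nc) > 1L &&
             (stats::sd(ch) > 0 || stats::sd(nc) > 0)) {
    t.test(ch, nc, alternative = "two.sided")$p.value
  } else if (isTRUE(all.equal(mean(ch), mean(nc)))) 1 else 0

  strata_change <- table(as.character(rates$species_branch[rates$has_change]))
  by_stratum <- split(nc, as.character(rates$species_branch[!rates$has_change]))
  missing_strata <- setdiff(names(strata_change), names(by_stratum))
  fallback <- list()
  if (length(missing_strata)) {
    warn(paste0("species branch(es) present only in the change group: ",
                paste(missing_strata, collapse = ", "),
                "; matched from nearest available stratum"))
    for (s in missing_strata) {
      fallback[[s]] <- nearest_stratum_pool(s, names(by_stratum), by_stratum,
                                            species_tree, nc)
    }
  }
  obs <- mean(ch)
  counts <- as.list(strata_change)
  hits <- 0L
  for (r in seq_len(n_resamples)) {
    m <- mean(matched_resample(counts, by_stratum, fallback))
    if (m >= obs) hits <- hits + 1L
  }
  structure(
    list(mean_change = obs, mean_nochange = mean(nc),
         t_p = t_p, mc_p = (1 + hits) / (1 + n_resamples),
         n_change = length(ch), n_nochange = length(nc),
         n_resamples = n_resamples),
    class = "rate_comparison"
  )
}

nearest_stratum_pool <- function(stratum, available, by_stratum, species_tree,
                                 pooled) {
  if (is.null(species_tree) || !length(available)) return(pooled)
  par <- tree_parents(species_tree)
  dep <- tree_depths(species_tree)
  s0 <- as.integer(stratum)
  dist_to <- vapply(as.integer(available), function(s1) {
    l <- lca_pair(s0, s1, par, dep)
    (dep[s0] - dep[l]) + (dep[s1] - dep[l])
  }, numeric(1))
  by_stratum[[available[which.min(dist_to)]]]
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf(
    "<rate_comparison> mean normalized rate %.3f (change, n=%d) vs %.3f (no change, n=%d)\n  t-test p = %.3g; matched Monte Carlo p = %.3g (%d resamples)\n",
    x$mean_change, x$n_change, x$mean_nochange, x$n_nochange,
    x$t_p, x$mc_p, x$n_resamples))
  invisible(x)
}

#' @method glance rate_comparison
#' @export
glance.rate_comparison <- function(x, ...) {
  tibble::tibble(
    mean_change = x$mean_change, mean_nochange = x$mean_nochange,
    t_p = x$t_p, mc_p = x$mc_p, n_change = x$n_change,
    n_nochange = x$n_nochange, n_resamples = x$n_resamples
  )
}

#' Per-million-year change rates from dated species-tree nodes
#'
#' For each dated node, sums the (weighted) gains and losses tallied on the
#' species branches of the path from the root to that node, and divides by
#' the elapsed time (root age minus node age). The total rate is
#' (gains + losses) / time and the net rate (gains - losses) / time. Dated
#' nodes share evolutionary paths and are nonindependent, so the summary
#' across nodes is a median and range, not a confidence interval.
#'
#' @param tallies Tibble from [tally_changes()].
#' @param dated_nodes Tibble with `node` (species-tree node index) and
#'   `age_my`, e.g. a subset of [node_ages()].
#' @param species_tree The species `phylo`.
#' @param root_age Root age in millions of years (default 450).
#' @return A tibble with `node`, `label`, `age_my`, `elapsed_my`, `organelle`,
#'   `gains`, `losses`, `total_per_my`, `net_per_my`.
#' @export
per_myr_rates <- function(tallies, dated_nodes, species_tree, root_age = 450) {
  stopifnot(all(c("node", "age_my") %in% names(dated_nodes)))
  nn <- n_nodes_total(species_tree)
  if (any(dated_nodes$node < 1L | dated_nodes$node > nn)) {
    abort("dated node index outside the species tree")
  }
  par <- tree_parents(species_tree)
  rows <- list()
  for (i in seq_len(nrow(dated_nodes))) {
    v <- dated_nodes$node[i]
    elapsed <- root_age - dated_nodes$age_my[i]
    if (elapsed <= 0) abort("dated node must be younger than the root age")
    path <- integer(0)
    u <- v
    while (par[u] > 0L) { path <- c(path, u); u <- par[u] }
    sel <- tallies[tallies$species_branch %in% path, , drop = FALSE]
    agg <- dplyr::summarise(dplyr::group_by(sel, .data$organelle),
                            gains = sum(.data$gains),
                            losses = sum(.data$losses), .groups = "drop")
    if (nrow(agg) == 0L) next
    agg$node <- v
    agg$label <- node_labels(species_tree, v)
    agg$age_my <- dated_nodes$age_my[i]
    agg$elapsed_my <- elapsed
    rows[[length(rows) + 1L]] <- agg
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(node = integer(), label = character(),
                          age_my = numeric(), elapsed_my = numeric(),
                          organelle = character(), gains = numeric(),
                          losses = numeric(), total_per_my = numeric(),
                          net_per_my = numeric()))
  }
  out$total_per_my <- (out$gains + out$losses) / out$elapsed_my
  out$net_per_my <- (out$gains - out$losses) / out$elapsed_my
  dplyr::select(out, "node", "label", "age_my", "elapsed_my", "organelle",
                "gains", "losses", "total_per_my", "net_per_my")
}

#' Summarise per-million-year rates across dated nodes
#'
#' @param rates Tibble from [per_myr_rates()].
#' @return One row per organelle with the median and range of the total and
#'   net change rates across dated nodes.
#' @export
summarize_myr_rates <- function(rates) {
  dplyr::summarise(
    dplyr::group_by(rates, .data$organelle),
    n_nodes = dplyr::n(),
    total_per_my_median = stats::median(.data$total_per_my),
    total_per_my_min = min(.data$total_per_my),
    total_per_my_max = max(.data$total_per_my),
    net_per_my_median = stats::median(.data$net_per_my),
    net_per_my_min = min(.data$net_per_my),
    net_per_my_max = max(.data$net_per_my),
    .groups = "drop"
  )
}
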
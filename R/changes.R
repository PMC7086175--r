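# Turning per-node marginal probabilities into retained gain/loss events:
# winner-takes-all binarization (>= 0.5 is targeted), candidate transitions on
# consecutive branches, the >75% descendant-retention filter with the
# >=2-species rule, and mapping of retained events onto species-tree branches.

#' Winner-takes-all binarization of targeting probabilities
#'
#' State 1 (targeted) iff the probability is greater than or equal to the
#' threshold; ties go to the targeted state.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return Integer vector of 0/1 states.
#' @export
binarize <- function(p, threshold = 0.5) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  as.integer(p >= threshold)
}

# Full per-node state vector: observed states at leaves, binarized marginal
# probabilities at internal nodes.
node_state_vector <- function(tree, marginals, tip_states, threshold = 0.5) {
  s <- as_tip_states(tip_states, tree)
  st <- integer(n_nodes_total(tree))
  st[seq_len(n_tips(tree))] <- s
  internal <- marginals$node[!marginals$is_tip]
  st[internal] <- binarize(marginals$p_targeted[!marginals$is_tip], threshold)
  st
}

#' Candidate gain/loss transitions on a gene tree
#'
#' One candidate per branch whose parent and child binarized states differ:
#' a gain for a 0 to 1 transition, a loss for 1 to 0. The root has no parent,
#' so no candidate is generated above it.
#'
#' @param tree Rooted `phylo`.
#' @param states Integer 0/1 state per node (tips then internals, ape order),
#'   e.g. from internal binarization of an [fit_mk()] result.
#' @return A tibble with `parent`, `child`, `direction`.
#' @export
candidate_transitions <- function(tree, states) {
  stopifnot(length(states) == n_nodes_total(tree))
  p <- states[tree$edge[, 1L]]
  c_ <- states[tree$edge[, 2L]]
  diff <- p != c_
  tibble::tibble(
    parent = tree$edge[diff, 1L],
    child = tree$edge[diff, 2L],
    direction = ifelse(c_[diff] == 1L, "gain", "loss")
  )
}

#' Descendant-retention filter for a candidate change
#'
#' A candidate change on branch X (parent -> child) is retained iff
#' strictly more than `retention` of the extant genes descending from X carry
#' the changed state, strictly more than `retention` of the genes descending
#' from X's sister branch Y carry the ancestral state, and the genes under X
#' come from at least `min_species` distinct species. Descendant states are
#' the observed (predicted) localizations of extant genes, not ancestral
#' estimates, so every retained change is informed by at least three extant
#' genes.
#'
#' @param tree Rooted binary `phylo`.
#' @param parent,child Node indices of the candidate branch.
#' @param node_states Integer 0/1 state per node (binarized; leaves observed).
#' @param tip_states Named 0/1 vector of observed leaf states.
#' @param gene_species_map Named character vector gene -> species.
#' @param retention Retention fraction (default 0.75; the test is strict ">").
#' @param min_species Minimum number of species under X (default 2).
#' @return A logical scalar with attributes `frac_changed`, `frac_ancestral`
#'   and `n_species`.
#' @export
retention_filter <- function(tree, parent, child, node_states, tip_states,
                             gene_species_map, retention = 0.75,
                             min_species = 2L) {
  s <- as_tip_states(tip_states, tree)
  map_vec <- as_species_map(gene_species_map)
  children <- tree_children(tree)
  sibs <- setdiff(children[[parent]], child)
  if (length(sibs) != 1L) {
    warn("candidate branch has no unique sister; rejected")
    return(structure(FALSE, frac_changed = NA_real_,
                     frac_ancestral = NA_real_, n_species = NA_integer_))
  }
  tipsets <- clade_tip_sets(tree)
  x_tips <- tipsets[[child]]
  y_tips <- tipsets[[sibs]]
  changed <- node_states[child]
  ancestral <- node_states[parent]
  frac_x <- mean(s[x_tips] == changed)
  frac_y <- mean(s[y_tips] == ancestral)
  nsp <- length(unique(map_vec[tree$tip.label[x_tips]]))
  ok <- (frac_x > retention) && (frac_y > retention) && (nsp >= min_species)
  structure(ok, frac_changed = frac_x, frac_ancestral = frac_y,
            n_species = nsp)
}

#' Map a species-branch span to weighted species-branch assignments
#'
#' With `mode = "mrca"` the whole event weight goes to the most recent
#' (tipward) spanned branch; with `mode = "split"` the event is distributed
#' equally over all spanned branches. Both modes coincide for spans of
#' length 1. An empty span (within-species branch) yields no assignment.
#'
#' @param span Integer vector of spanned species branches, rootward to
#'   tipward (see [species_branch_span()]).
#' @param mode `"mrca"` (default) or `"split"`.
#' @return A tibble with `species_branch`, `weight` (weights sum to 1, or
#'   zero rows for an empty span).
#' @export
map_to_species_branches <- function(span, mode = c("mrca", "split")) {
  mode <- match.arg(mode)
  if (!length(span)) {
    return(tibble::tibble(species_branch = integer(), weight = numeric()))
  }
  if (mode == "mrca") {
    tibble::tibble(species_branch = span[length(span)], weight = 1)
  } else {
    tibble::tibble(species_branch = span, weight = 1 / length(span))
  }
}

#' Call retained gain/loss events from a fitted ancestral-state model
#'
#' Runs the full change-calling chain for one orthogroup: binarize marginal
#' probabilities (internal nodes) together with observed leaf states, list
#' candidate transitions, apply the descendant-retention filter, and map the
#' retained events onto species-tree branches through the reconciliation.
#'
#' @param fit An [fit_mk()] result for the orthogroup's trait.
#' @param recon The orthogroup's [lca_reconcile()] result.
#' @param organelle Organelle label recorded on the events.
#' @param orthogroup Orthogroup id recorded on the events.
#' @param mode Species-branch mapping mode, `"mrca"` (default) or `"split"`.
#' @param threshold Binarization threshold (default 0.5).
#' @param retention Retention fraction for the filter (default 0.75).
#' @param min_species Minimum species under the change branch (default 2).
#' @return A tibble of retained events with columns `orthogroup`, `organelle`,
#'   `direction`, `parent`, `child`, `frac_changed`, `frac_ancestral`,
#'   `n_species`, `span_length` and a list-column `assignment` of
#'   species-branch weight tibbles.
#' @export
call_changes <- function(fit, recon, organelle = "chloroplast",
                         orthogroup = "OG", mode = c("mrca", "split"),
                         threshold = 0.5, retention = 0.75, min_species = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "mk_fit"), inherits(recon, "orgflux_recon"))
  tree <- fit$tree
  states <- node_state_vector(tree, fit$marginals, fit$tip_states, threshold)
  cand <- candidate_transitions(tree, states)
  if (nrow(cand) == 0L) return(empty_events())
  keep <- logical(nrow(cand))
  frac_x <- frac_y <- numeric(nrow(cand))
  nsp <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- retention_filter(tree, cand$parent[i], cand$child[i], states,
                          fit$tip_states, recon$gene_species_map,
                          retention, min_species)
    keep[i] <- as.logical(r)
    frac_x[i] <- attr(r, "frac_changed")
    frac_y[i] <- attr(r, "frac_ancestral")
    nsp[i] <- attr(r, "n_species")
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_events())
  assignment <- vector("list", nrow(cand))
  span_length <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- species_branch_span(recon, cand$parent[i], cand$child[i])
    span_length[i] <- length(span)
    assignment[[i]] <- map_to_species_branches(span, mode)
  }
  tibble::tibble(
    orthogroup = orthogroup, organelle = organelle,
    direction = cand$direction, parent = cand$parent, child = cand$child,
    frac_changed = frac_x[keep], frac_ancestral = frac_y[keep],
    n_species = nsp[keep], span_length = span_length,
    assignment = assignment
  )
}

empty_events <- function() {
  tibble::tibble(
    orthogroup = character(), organelle = character(), direction = character(),
    parent = integer(), child = integer(), frac_changed = numeric(),
    frac_ancestral = numeric(), n_species = integer(), span_length = integer(),
    assignment = list()
  )
}

#' Tally weighted gains and losses per species branch
#'
#' Sums the weighted species-branch assignments of retained events per
#' organelle, direction and species branch. Events with empty spans
#' (within-species changes) carry no assignment and do not contribute.
#' Terminal species branches are flagged so the headline table can be
#' restricted to nonterminal branches.
#'
#' @param events Event tibble from [call_changes()] (rows from several
#'   orthogroups may be bound together).
#' @param species_tree The species `phylo`.
#' @return A tibble with `species_branch`, `species_label`, `terminal`,
#'   `organelle`, `gains`, `losses`.
#' @export
tally_changes <- function(events, species_tree) {
  base <- tibble::tibble(
    species_branch = setdiff(seq_len(n_nodes_total(species_tree)),
                             root_node(species_tree))
  )
  base$species_label <- node_labels(species_tree, base$species_branch)
  base$terminal <- base$species_branch <= n_tips(species_tree)
  organelles <- unique(events$organelle)
  if (!length(organelles)) organelles <- "chloroplast"
  grid <- tidyr::crossing(base, organelle = organelles)
  if (nrow(events) == 0L) {
    grid$gains <- 0; grid$losses <- 0
    return(grid)
  }
  long <- tidyr::unnest(
    dplyr::select(events, "organelle", "direction", "assignment"),
    "assignment"
  )
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$organelle, .data$direction, .data$species_branch),
    w = sum(.data$weight), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(agg, names_from = "direction", values_from = "w",
                             values_fill = 0)
  for (col in c("gain", "loss")) if (!col %in% names(wide)) wide[[col]] <- 0
  out <- dplyr::left_join(grid, wide, by = c("species_branch", "organelle"))
  out$gains <- dplyr::coalesce(out$gain, 0)
  out$losses <- dplyr::coalesce(out$loss, 0)
  dplyr::select(out, "species_branch", "species_label", "terminal",
                "organelle", "gains", "losses")
}
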
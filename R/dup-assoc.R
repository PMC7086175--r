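# Association between gene duplication and changes in organellar targeting:
# high-confidence duplication/speciation node selection (complete retention
# in all descendant species), the hypergeometric and matched Monte Carlo
# tests on child-branch changes, stratification by whole-genome versus
# single-gene duplication origin, and fossil duplicate branches.

#' Select high-confidence duplication and speciation nodes
#'
#' A duplication node is high-confidence when each of its two child clades
#' contains at least one gene from every extant species descending from the
#' node's mapped species node (the duplication is retained in all descendant
#' species of both child branches). A speciation node is high-confidence when
#' it has no duplication anywhere in its subtree and its clade contains at
#' least one gene from every species under its mapped species node (no
#' subsequent gene loss). `child_change` flags nodes with at least one
#' retained change event on either immediate child branch.
#'
#' @param recon An [lca_reconcile()] result.
#' @param events Optional event tibble from [call_changes()] for the same
#'   orthogroup.
#' @param orthogroup Orthogroup id recorded on the rows.
#' @param subtree_dup_free Require speciation nodes to have duplication-free
#'   subtrees (default `TRUE`, the strict reading); `FALSE` checks only the
#'   node itself.
#' @return A tibble with `orthogroup`, `gene_node`, `gene_label`, `class`,
#'   `species_node`, `species_label`, `child_change`.
#' @export
select_high_confidence_nodes <- function(recon, events = NULL,
                                         orthogroup = "OG",
                                         subtree_dup_free = TRUE) {
  stopifnot(inherits(recon, "orgflux_recon"))
  gt <- recon$gene_tree
  sp <- recon$species_tree
  nt <- n_tips(gt)
  nn <- n_nodes_total(gt)
  children <- tree_children(gt)
  tipsets <- clade_tip_sets(gt)
  sp_tipsets <- clade_tip_sets(sp)
  sp_of_tip <- recon$gene_species_map[gt$tip.label]
  sp_tip_index <- setNames(seq_along(sp$tip.label), sp$tip.label)

  # species (tip indices in the species tree) represented under each gene node
  species_under <- function(v) unique(sp_tip_index[sp_of_tip[tipsets[[v]]]])

  # duplication presence in each subtree
  has_dup <- logical(nn)
  post <- ape::reorder.phylo(gt, "postorder")$edge
  for (i in seq_len(nrow(post))) {
    p <- post[i, 1L]; c_ <- post[i, 2L]
    has_dup[p] <- has_dup[p] || has_dup[c_] || recon$event[c_] == "duplication"
  }
  internal <- (nt + 1L):nn
  has_dup[internal] <- has_dup[internal] | (recon$event[internal] == "duplication")

  change_key <- character(0)
  if (!is.null(events) && nrow(events)) {
    change_key <- paste(events$parent, events$child)
  }

  r_node <- integer(0); r_class <- character(0)
  r_sp <- integer(0); r_cc <- logical(0)
  for (v in internal) {
    sp_node <- recon$map[v]
    required <- sp_tipsets[[sp_node]]
    cls <- NA_character_
    if (recon$event[v] == "duplication") {
      ok <- all(vapply(children[[v]], function(k) {
        all(required %in% species_under(k))
      }, logical(1)))
      if (ok) cls <- "duplication"
    } else {
      dup_in_subtree <- if (subtree_dup_free) has_dup[v] else FALSE
      if (!dup_in_subtree && all(required %in% species_under(v))) {
        cls <- "speciation"
      }
    }
    if (is.na(cls)) next
    r_node <- c(r_node, v)
    r_class <- c(r_class, cls)
    r_sp <- c(r_sp, sp_node)
    r_cc <- c(r_cc, any(paste(v, children[[v]]) %in% change_key))
  }
  tibble::tibble(
    orthogroup = rep(orthogroup, length(r_node)),
    gene_node = r_node,
    gene_label = node_labels(gt, r_node),
    class = r_class,
    species_node = r_sp,
    species_label = node_labels(sp, r_sp),
    child_change = r_cc
  )
}

#' Test whether targeting changes are enriched after gene duplication
#'
#' Compares the fraction of high-confidence duplication nodes with a retained
#' change on either immediate child branch against the same fraction for
#' high-confidence speciation nodes, with (i) an upper-tail hypergeometric
#' test on the 2x2 table of class by child-change, and (ii) a matched Monte
#' Carlo test resampling speciation nodes to match the duplication set's size
#' and per-species-node distribution (add-one p-value).
#'
#' @param records Tibble from [select_high_confidence_nodes()] (rows from
#'   several orthogroups may be bound together).
#' @param n_resamples Number of matched resamples (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `dup_change_test`: list with `n_dup`, `n_spec`,
#'   `k_dup`, `k_spec`, `freq_dup`, `freq_spec` (fractions), `hypergeom_p`,
#'   `mc_p`, `n_resamples`.
#' @export
duplication_change_test <- function(records, n_resamples = 1000, seed = NULL) {
  dup <- records[records$class == "duplication", , drop = FALSE]
  spec <- records[records$class == "speciation", , drop = FALSE]
  if (!nrow(dup) || !nrow(spec)) {
    abort("both duplication and speciation records are required")
  }
  if (!is.null(seed)) set.seed(seed)
  n_dup <- nrow(dup); n_spec <- nrow(spec)
  k_dup <- sum(dup$child_change); k_spec <- sum(spec$child_change)
  k_tot <- k_dup + k_spec
  n_tot <- n_dup + n_spec

  if (k_tot == 0L || k_tot == n_tot) {
    warn("no variance in child-change status; p-values reported as 1")
    hyper_p <- 1; mc_p <- 1
  } else {
    # upper tail: P(X >= k_dup) drawing n_dup nodes from n_tot with k_tot changed
    hyper_p <- phyper(k_dup - 1L, k_tot, n_tot - k_tot, n_dup,
                      lower.tail = FALSE)
    obs <- k_dup / n_dup
    by_stratum <- split(spec$child_change, as.character(spec$species_node))
    counts <- table(as.character(dup$species_node))
    hits <- 0L
    for (r in seq_len(n_resamples)) {
      draw <- logical(0)
      for (s in names(counts)) {
        pool <- by_stratum[[s]]
        if (is.null(pool) || !length(pool)) pool <- spec$child_change
        draw <- c(draw, pool[sample.int(length(pool), counts[[s]],
                                        replace = TRUE)])
      }
      if (mean(draw) >= obs) hits <- hits + 1L
    }
    mc_p <- (1 + hits) / (1 + n_resamples)
  }

  structure(
    list(n_dup = n_dup, n_spec = n_spec, k_dup = k_dup, k_spec = k_spec,
         freq_dup = k_dup / n_dup, freq_spec = k_spec / n_spec,
         hypergeom_p = hyper_p, mc_p = mc_p, n_resamples = n_resamples),
    class = "dup_change_test"
  )
}

#' @export
print.dup_change_test <- function(x, ...) {
  cat(sprintf(
    "<dup_change_test> child-branch change in %.1f%% of %d duplication nodes vs %.1f%% of %d speciation nodes\n  hypergeometric p = %.3g; matched Monte Carlo p = %.3g\n",
    100 * x$freq_dup, x$n_dup, 100 * x$freq_spec, x$n_spec,
    x$hypergeom_p, x$mc_p))
  invisible(x)
}

#' @method glance dup_change_test
#' @export
glance.dup_change_test <- function(x, ...) {
  tibble::tibble(
    n_dup = x$n_dup, n_spec = x$n_spec, k_dup = x$k_dup, k_spec = x$k_spec,
    freq_dup = x$freq_dup, freq_spec = x$freq_spec,
    hypergeom_p = x$hypergeom_p, mc_p = x$mc_p, n_resamples = x$n_resamples
  )
}

#' @method tidy dup_change_test
#' @export
tidy.dup_change_test <- function(x, ...) {
  tibble::tibble(
    class = c("duplication", "speciation"),
    n = c(x$n_dup, x$n_spec),
    child_change = c(x$k_dup, x$k_spec),
    frequency = c(x$freq_dup, x$freq_spec)
  )
}

#' Classify duplication origin as whole-genome or single-gene
#'
#' A duplication record is classified WGD when the species branch above its
#' mapped species node carries a whole-genome duplication flag, single-gene
#' otherwise. Duplications mapped to the species root (no branch above) are
#' single-gene with a warning. Speciation records get origin `"n/a"`.
#'
#' @param records Tibble from [select_high_confidence_nodes()].
#' @param wgd_branches Integer vector of WGD-flagged species branches (each
#'   identified by its child species node).
#' @param species_tree The species `phylo`.
#' @return `records` with an added `origin` column
#'   (`"WGD"`, `"single-gene"`, `"n/a"`).
#' @export
classify_duplication_origin <- function(records, wgd_branches, species_tree) {
  at_root <- records$class == "duplication" &
    records$species_node == root_node(species_tree)
  if (any(at_root)) {
    warn("duplication(s) mapped to the species root classified single-gene")
  }
  records$origin <- dplyr::case_when(
    records$class != "duplication" ~ "n/a",
    records$species_node %in% wgd_branches & !at_root ~ "WGD",
    TRUE ~ "single-gene"
  )
  records
}

#' Find fossil duplicate gene-tree branches
#'
#' Fossil duplicates are genes that must have existed in duplicated state
#' across a whole-genome duplication before returning to single copy: their
#' gene-tree branch spans a WGD-flagged species branch without carrying a
#' duplication node mapped to that branch at either endpoint.
#'
#' @param recon An [lca_reconcile()] result.
#' @param wgd_branches Integer vector of WGD-flagged species branches.
#' @param events Optional event tibble to flag changes on fossil branches.
#' @param orthogroup Orthogroup id recorded on the rows.
#' @return A tibble with `orthogroup`, `parent`, `child`, `wgd_branch`,
#'   `has_change`.
#' @export
find_fossil_duplicate_branches <- function(recon, wgd_branches, events = NULL,
                                           orthogroup = "OG") {
  stopifnot(inherits(recon, "orgflux_recon"))
  if (!length(wgd_branches)) {
    return(tibble::tibble(orthogroup = character(), parent = integer(),
                          child = integer(), wgd_branch = integer(),
                          has_change = logical()))
  }
  gt <- recon$gene_tree
  change_key <- character(0)
  if (!is.null(events) && nrow(events)) {
    change_key <- paste(events$parent, events$child)
  }
  f_parent <- integer(0); f_child <- integer(0); f_wgd <- integer(0)
  for (i in seq_len(nrow(gt$edge))) {
    span <- recon$spans[[i]]
    hit <- intersect(span, wgd_branches)
    if (!length(hit)) next
    p <- gt$edge[i, 1L]; c_ <- gt$edge[i, 2L]
    for (w in hit) {
      endpoint_dup_on_w <-
        (recon$event[p] == "duplication" && recon$map[p] == w) ||
        (recon$event[c_] == "duplication" && recon$map[c_] == w)
      if (endpoint_dup_on_w) next
      f_parent <- c(f_parent, p); f_child <- c(f_child, c_)
      f_wgd <- c(f_wgd, w)
    }
  }
  tibble::tibble(
    orthogroup = rep(orthogroup, length(f_parent)),
    parent = f_parent, child = f_child, wgd_branch = f_wgd,
    has_change = paste(f_parent, f_child) %in% change_key
  )
}

#' Summarise change frequencies by duplication origin
#'
#' @param records Tibble from [classify_duplication_origin()].
#' @param fossil Optional tibble from [find_fossil_duplicate_branches()]
#'   (rows from several orthogroups may be bound together).
#' @return One row per group (WGD, single-gene, speciation, fossil) with `n`,
#'   `n_change` and `frequency`.
#' @export
dup_origin_summary <- function(records, fossil = NULL) {
  grp <- ifelse(records$class == "speciation", "speciation", records$origin)
  base <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = grp,
                                   child_change = records$child_change),
                    .data$group),
    n = dplyr::n(), n_change = sum(.data$child_change),
    frequency = mean(.data$child_change), .groups = "drop"
  )
  if (!is.null(fossil) && nrow(fossil)) {
    base <- dplyr::bind_rows(base, tibble::tibble(
      group = "fossil", n = nrow(fossil), n_change = sum(fossil$has_change),
      frequency = mean(fossil$has_change)
    ))
  }
  base
}
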
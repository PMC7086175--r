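# Shared rooted-tree helpers on ape "phylo" objects. All downstream stages
# address nodes by their ape integer index (tips 1..Ntip, root Ntip+1) and
# species branches by the index of the node *below* the branch.

#' Read a rooted tree from a newick string or file
#'
#' Thin, validating wrapper around [ape::read.tree()]. Trees are used as
#' rooted exactly as written; no rerooting is performed. Duplicate leaf
#' labels and malformed newick are rejected with an informative error.
#'
#' @param x A newick string (must contain "(") or a path to a newick file.
#' @return An object of class `phylo`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  is_text <- grepl("(", x, fixed = TRUE) || grepl(";", x, fixed = TRUE)
  if (!is_text && !file.exists(x)) {
    abort(paste0("`x` is neither newick text nor an existing file: ", x))
  }
  tr <- tryCatch(
    if (is_text) ape::read.tree(text = x) else ape::read.tree(file = x),
    error = function(e) abort(paste0("newick parse error: ", conditionMessage(e))),
    warning = function(w) abort(paste0("newick parse error: ", conditionMessage(w)))
  )
  if (is.null(tr)) abort("newick parse error: input could not be parsed")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) abort("expected a single tree")
    tr <- tr[[1L]]
  }
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) {
    abort(paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")))
  }
  if (any(!is.na(tr$edge.length) & tr$edge.length < 0)) {
    abort("negative branch length in newick input")
  }
  tr
}

#' Write a tree as newick
#'
#' @param tree A `phylo` object.
#' @param file Optional output path; if `NULL` the newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

n_tips <- function(tree) length(tree$tip.label)

root_node <- function(tree) n_tips(tree) + 1L

n_nodes_total <- function(tree) n_tips(tree) + tree$Nnode

#' @noRd
tree_parents <- function(tree) {
  par <- integer(n_nodes_total(tree))
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par  # 0 for the root
}

#' @noRd
tree_children <- function(tree) {
  ch <- vector("list", n_nodes_total(tree))
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2L])
  }
  ch
}

# Depth (number of edges from root) per node.
#' @noRd
tree_depths <- function(tree) {
  par <- tree_parents(tree)
  dep <- integer(length(par))
  ord <- preorder_nodes(tree)
  for (v in ord) if (par[v] > 0L) dep[v] <- dep[par[v]] + 1L
  dep
}

# Nodes in root-first order.
#' @noRd
preorder_nodes <- function(tree) {
  e <- ape::reorder.phylo(tree, "postorder")$edge
  c(root_node(tree), rev(e[, 2L]))
}

# Tip index sets per node (list over all nodes).
#' @noRd
clade_tip_sets <- function(tree) {
  nt <- n_tips(tree)
  sets <- vector("list", n_nodes_total(tree))
  for (i in seq_len(nt)) sets[[i]] <- i
  e <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; c_ <- e[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c_]])
  }
  sets
}

# Human-readable labels for arbitrary node indices.
#' @noRd
node_labels <- function(tree, nodes) {
  nt <- n_tips(tree)
  lab <- character(length(nodes))
  is_tip <- nodes <= nt
  lab[is_tip] <- tree$tip.label[nodes[is_tip]]
  internal <- nodes[!is_tip]
  if (length(internal)) {
    if (!is.null(tree$node.label) &&
        all(nzchar(tree$node.label[internal - nt]), na.rm = TRUE)) {
      lab[!is_tip] <- tree$node.label[internal - nt]
    } else {
      lab[!is_tip] <- paste0("node", internal)
    }
  }
  lab
}

#' @noRd
is_binary_rooted <- function(tree) {
  ch <- tree_children(tree)
  internal <- (n_tips(tree) + 1L):n_nodes_total(tree)
  all(lengths(ch[internal]) == 2L)
}

#' @noRd
assert_branch_lengths <- function(tree, what = "this analysis") {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort(paste0("tree has missing branch lengths; ", what, " requires them"))
  }
  invisible(TRUE)
}

# Walk-up LCA of two nodes given parent and depth vectors.
#' @noRd
lca_pair <- function(a, b, parent, depth) {
  while (a != b) {
    if (depth[a] >= depth[b]) a <- parent[a] else b <- parent[b]
  }
  a
}

#' Node ages implied by an ultrametric tree
#'
#' Returns ages (time before present) per node, scaled so the root sits at
#' `root_age`. Used to derive dated nodes for per-million-year change rates.
#'
#' @param tree Ultrametric `phylo`.
#' @param root_age Age of the root in millions of years (default 450).
#' @return A tibble with `node`, `label`, `age_my`.
#' @export
node_ages <- function(tree, root_age = 450) {
  assert_branch_lengths(tree, "node dating")
  par <- tree_parents(tree)
  elen <- numeric(n_nodes_total(tree))
  elen[tree$edge[, 2L]] <- tree$edge.length
  dist_root <- numeric(n_nodes_total(tree))
  for (v in preorder_nodes(tree)) {
    if (par[v] > 0L) dist_root[v] <- dist_root[par[v]] + elen[v]
  }
  span <- max(dist_root)
  if (span <= 0) abort("tree has zero depth; cannot assign ages")
  age <- (span - dist_root) / span * root_age
  tibble::tibble(
    node = seq_len(n_nodes_total(tree)),
    label = node_labels(tree, seq_len(n_nodes_total(tree))),
    age_my = age
  )
}
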
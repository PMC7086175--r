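# Gene-tree / species-tree reconciliation by last-common-ancestor mapping.
#
# Each gene-tree node is mapped to the species-tree LCA of its descendant
# species; a node is a duplication when its mapping equals the mapping of at
# least one child. Each gene-tree branch resolves to the ordered path of
# species branches between the mappings of its endpoints ("span"); a species
# branch is identified by the species node below it.

#' Reconcile a gene tree with a species tree
#'
#' Maps every gene-tree node to a species-tree node by last-common-ancestor
#' (LCA) reconciliation, labels duplication/speciation events, and resolves
#' every gene-tree branch to the ordered list of species-tree branches it
#' spans. Alternatively, a pre-computed reconciliation (e.g. from a joint
#' gene-tree/species-tree inference tool) can be ingested verbatim via
#' `annotations`, in which case the LCA step is skipped.
#'
#' @param gene_tree Rooted binary `phylo` gene tree.
#' @param species_tree Rooted `phylo` species tree.
#' @param gene_species_map Tibble (`gene_id`, `species_id`) or named character
#'   vector mapping every gene-tree leaf to a species-tree leaf label.
#' @param annotations Optional tibble (`gene_node_label`, `species_node_label`,
#'   `event`) giving an externally computed node mapping, keyed by gene-tree
#'   node labels; ingested verbatim.
#' @return An object of class `orgflux_recon` with elements `gene_tree`,
#'   `species_tree`, `map` (integer species node per gene node), `event`
#'   (`"leaf"`, `"speciation"` or `"duplication"` per gene node), and `spans`
#'   (per gene-tree edge, the ordered rootward-to-tipward integer vector of
#'   spanned species branches, each identified by its child node).
#' @examples
#' sp <- read_newick("((A:1,B:1)AB:1,C:2)R;")
#' gt <- read_newick("((a1:1,b1:1):1,c1:2);")
#' map <- c(a1 = "A", b1 = "B", c1 = "C")
#' rec <- lca_reconcile(gt, sp, map)
#' tidy(rec)
#' @export
lca_reconcile <- function(gene_tree, species_tree, gene_species_map,
                          annotations = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  if (!is_binary_rooted(gene_tree)) {
    abort("gene tree has nonbinary node(s); resolve polytomies upstream")
  }
  map_vec <- as_species_map(gene_species_map)
  missing <- setdiff(gene_tree$tip.label, names(map_vec))
  if (length(missing)) {
    abort(paste0("gene(s) missing from gene-species map: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  sp_of_gene <- map_vec[gene_tree$tip.label]
  bad_sp <- setdiff(unique(sp_of_gene), species_tree$tip.label)
  if (length(bad_sp)) {
    abort(paste0("species not found in species tree: ",
                 paste(bad_sp, collapse = ", ")))
  }

  ng <- n_nodes_total(gene_tree)
  sp_par <- tree_parents(species_tree)
  sp_dep <- tree_depths(species_tree)
  g_children <- tree_children(gene_tree)

  map <- integer(ng)
  event <- character(ng)

  if (is.null(annotations)) {
    sp_tip_index <- setNames(seq_along(species_tree$tip.label),
                             species_tree$tip.label)
    map[seq_len(n_tips(gene_tree))] <- sp_tip_index[sp_of_gene]
    post <- ape::reorder.phylo(gene_tree, "postorder")$edge
    internal <- unique(post[, 1L])
    for (v in internal) {
      kids <- g_children[[v]]
      m <- map[kids[1L]]
      for (k in kids[-1L]) m <- lca_pair(m, map[k], sp_par, sp_dep)
      map[v] <- m
    }
  } else {
    map <- ingest_annotations(gene_tree, species_tree, annotations, sp_of_gene)
  }

  nt <- n_tips(gene_tree)
  for (v in seq_len(ng)) {
    if (v <= nt) {
      event[v] <- "leaf"
    } else {
      kids <- g_children[[v]]
      event[v] <- if (any(map[kids] == map[v])) "duplication" else "speciation"
    }
  }

  spans <- compute_spans(gene_tree, map, sp_par)

  structure(
    list(gene_tree = gene_tree, species_tree = species_tree,
         gene_species_map = map_vec, map = map, event = event, spans = spans),
    class = "orgflux_recon"
  )
}

as_species_map <- function(gene_species_map) {
  if (is.data.frame(gene_species_map)) {
    stopifnot(all(c("gene_id", "species_id") %in% names(gene_species_map)))
    setNames(gene_species_map$species_id, gene_species_map$gene_id)
  } else if (is.character(gene_species_map) && !is.null(names(gene_species_map))) {
    gene_species_map
  } else {
    abort("`gene_species_map` must be a tibble (gene_id, species_id) or a named character vector")
  }
}

ingest_annotations <- function(gene_tree, species_tree, annotations, sp_of_gene) {
  req <- c("gene_node_label", "species_node_label")
  stopifnot(all(req %in% names(annotations)))
  ng <- n_nodes_total(gene_tree)
  glabels <- node_labels(gene_tree, seq_len(ng))
  slabels <- node_labels(species_tree, seq_len(n_nodes_total(species_tree)))
  sindex <- setNames(seq_along(slabels), slabels)
  map <- integer(ng)
  sp_tip_index <- setNames(seq_along(species_tree$tip.label),
                           species_tree$tip.label)
  map[seq_len(n_tips(gene_tree))] <- sp_tip_index[sp_of_gene]
  idx <- match(glabels, annotations$gene_node_label)
  internal <- (n_tips(gene_tree) + 1L):ng
  for (v in internal) {
    if (is.na(idx[v])) {
      abort(paste0("no external annotation for gene node ", glabels[v]))
    }
    s <- annotations$species_node_label[idx[v]]
    if (is.na(sindex[s])) abort(paste0("unknown species node label: ", s))
    map[v] <- sindex[[s]]
  }
  map
}

# Per-edge ordered species-branch paths between endpoint mappings.
compute_spans <- function(gene_tree, map, sp_par) {
  spans <- vector("list", nrow(gene_tree$edge))
  for (i in seq_len(nrow(gene_tree$edge))) {
    top <- map[gene_tree$edge[i, 1L]]
    bot <- map[gene_tree$edge[i, 2L]]
    path <- integer(0)
    v <- bot
    while (v != top) {
      path <- c(v, path)
      v <- sp_par[v]
      if (v == 0L && top != v) {
        abort("inconsistent reconciliation: child mapping not below parent mapping")
      }
    }
    spans[[i]] <- path
  }
  spans
}

#' Species branches spanned by a gene-tree branch
#'
#' @param recon An `orgflux_recon` object.
#' @param parent,child Gene-tree node indices of the branch endpoints.
#' @return Integer vector of species branches (child-node ids), ordered from
#'   rootward to tipward; length 0 for within-species (duplication) branches.
#' @export
species_branch_span <- function(recon, parent, child) {
  stopifnot(inherits(recon, "orgflux_recon"))
  i <- which(recon$gene_tree$edge[, 1L] == parent &
               recon$gene_tree$edge[, 2L] == child)
  if (length(i) != 1L) abort("no such edge in the gene tree")
  recon$spans[[i]]
}

#' @method tidy orgflux_recon
#' @export
tidy.orgflux_recon <- function(x, ...) {
  ng <- n_nodes_total(x$gene_tree)
  tibble::tibble(
    gene_node = seq_len(ng),
    gene_label = node_labels(x$gene_tree, seq_len(ng)),
    species_node = x$map,
    species_label = node_labels(x$species_tree, x$map),
    event = x$event
  )
}

#' @export
print.orgflux_recon <- function(x, ...) {
  n_dup <- sum(x$event == "duplication")
  cat("<orgflux_recon> gene tree with", n_tips(x$gene_tree), "genes over",
      n_tips(x$species_tree), "species;", n_dup, "duplication node(s)\n")
  invisible(x)
}

#' Count duplication nodes in a reconciliation
#'
#' @param recon An `orgflux_recon` object.
#' @return Integer count of duplication-labelled internal nodes.
#' @export
n_duplications <- function(recon) {
  stopifnot(inherits(recon, "orgflux_recon"))
  sum(recon$event == "duplication")
}
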
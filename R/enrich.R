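# Functional-term enrichment of orthogroup sets. Orthogroups inherit the
# union of their member genes' terms; enrichment per term is an upper-tail
# hypergeometric test with Benjamini-Hochberg correction, against a
# caller-restricted background (orthogroups with at least one
# organelle-targeted protein in the headline analysis).

#' Inherit gene-level terms up to orthogroups
#'
#' Each orthogroup is assigned the union of the terms annotated on its member
#' genes (set semantics: a term carried by several members counts once).
#' Genes without terms contribute nothing. Optionally, terms are propagated
#' to their parent terms through a supplied parent map (for hierarchical
#' vocabularies).
#'
#' @param gene_terms Tibble (`gene_id`, `term`), e.g. [read_terms_table()].
#' @param orthogroups Tibble (`orthogroup`, `gene_id`) giving membership.
#' @param parent_map Optional tibble (`term`, `parent`) for upward
#'   propagation; applied transitively.
#' @return A tibble (`orthogroup`, `term`), one row per orthogroup-term pair.
#' @export
inherit_terms <- function(gene_terms, orthogroups, parent_map = NULL) {
  stopifnot(all(c("gene_id", "term") %in% names(gene_terms)),
            all(c("orthogroup", "gene_id") %in% names(orthogroups)))
  if (!is.null(parent_map)) {
    stopifnot(all(c("term", "parent") %in% names(parent_map)))
    expanded <- gene_terms
    frontier <- gene_terms
    for (i in seq_len(50L)) {  # cap guards against cyclic parent maps
      frontier <- dplyr::inner_join(frontier, parent_map, by = "term",
                                    relationship = "many-to-many")
      if (!nrow(frontier)) break
      frontier <- dplyr::distinct(
        dplyr::transmute(frontier, gene_id = .data$gene_id,
                         term = .data$parent))
      frontier <- dplyr::anti_join(frontier, expanded,
                                   by = c("gene_id", "term"))
      if (!nrow(frontier)) break
      expanded <- dplyr::bind_rows(expanded, frontier)
    }
    gene_terms <- expanded
  }
  dplyr::distinct(
    dplyr::select(
      dplyr::inner_join(orthogroups, gene_terms, by = "gene_id",
                        relationship = "many-to-many"),
      "orthogroup", "term"
    )
  )
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' For each term, tests whether foreground orthogroups carry the term more
#' often than expected from the background: upper-tail hypergeometric
#' probability of observing at least `k` carriers among `n` foreground
#' orthogroups when `K` of the `N` background orthogroups carry the term.
#' P-values are BH-corrected; a term is significant when its corrected value
#' is at most `alpha`. Terms with fewer than `min_carriers` background
#' carriers are not tested.
#'
#' @param foreground Character vector of foreground orthogroup ids; must be a
#'   subset of `background`.
#' @param background Character vector of background orthogroup ids (restrict
#'   to orthogroups with at least one organelle-targeted protein for the
#'   headline analysis).
#' @param term_table Tibble (`orthogroup`, `term`) from [inherit_terms()].
#' @param alpha Significance level on the corrected p-value (default 0.01).
#' @param min_carriers Minimum background carriers per testable term
#'   (default 2).
#' @return A tibble with `term`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`,
#'   ordered by `p`.
#' @export
enrich <- function(foreground, background, term_table, alpha = 0.01,
                   min_carriers = 2L) {
  foreground <- unique(foreground)
  background <- unique(background)
  extra <- setdiff(foreground, background)
  if (length(extra)) {
    abort(paste0("foreground orthogroup(s) not in background: ",
                 paste(head(extra, 5L), collapse = ", ")))
  }
  tt <- term_table[term_table$orthogroup %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(foreground)
  carriers <- dplyr::summarise(
    dplyr::group_by(tt, .data$term),
    K = dplyr::n_distinct(.data$orthogroup),
    k = dplyr::n_distinct(.data$orthogroup[.data$orthogroup %in% foreground]),
    .groups = "drop"
  )
  carriers <- carriers[carriers$K >= min_carriers, , drop = FALSE]
  if (nrow(carriers) == 0L) {
    return(tibble::tibble(term = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p = numeric(),
                          q = numeric(), significant = logical()))
  }
  p <- phyper(carriers$k - 1L, carriers$K, N - carriers$K, n,
              lower.tail = FALSE)
  out <- tibble::tibble(
    term = carriers$term, k = carriers$k, K = carriers$K,
    n = n, N = N, p = p, q = p.adjust(p, method = "BH")
  )
  out$significant <- out$q <= alpha
  dplyr::arrange(out, .data$p, .data$term)
}
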
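# Ground-truthed simulator: species trees (Yule), duplication-loss gene
# families evolved along the species tree (with optional whole-genome
# duplication branches), binary targeting states under a two-rate Markov
# process with an elevated change rate on post-duplication branches (kappa),
# molecular-rate jitter with an elevated rate on true change branches (rho),
# protein sequences with planted PTS motifs, and term annotations with
# planted enrichment.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic study conditions. Defaults encode
#' a desk-scale plant-like data set: 20 species, 50 duplication-rich gene
#' families, a species tree of unit root-to-tip depth (substitutions/site)
#' spanning 450 My, gene duplication/loss rates 0.8/0.05 per unit branch
#' length, targeting gain/loss rates 0.15/0.4, no whole-genome duplication
#' branches (WGD flags are user-supplied annotations; set `n_wgd` to plant
#' them), and the null effect sizes kappa = 1 (no post-duplication elevation
#' of targeting change) and rho = 1 (no molecular-rate elevation on change
#' branches).
#'
#' @param n_species Number of species (>= 2).
#' @param n_orthogroups Number of gene families to simulate.
#' @param birth Species-tree birth rate (Yule).
#' @param tree_depth Root-to-tip depth of the species tree in
#'   substitutions/site.
#' @param root_age Root age in My (default 450).
#' @param lambda_dup,lambda_loss Gene duplication and loss rates per unit
#'   branch length.
#' @param alpha,beta Targeting gain (0 to 1) and loss (1 to 0) rates per unit
#'   branch length.
#' @param kappa Multiplier (>= 1) applied to both trait rates on the two
#'   immediate child branches of each gene duplication.
#' @param rho Multiplier (>= 1) applied to the molecular branch length of
#'   branches on which the targeting state truly changed.
#' @param rate_jitter_sd Standard deviation of the lognormal molecular-rate
#'   jitter applied per gene-tree branch.
#' @param n_wgd Number of internal species branches flagged as whole-genome
#'   duplications.
#' @param wgd_prob Per-lineage duplication probability on a WGD branch.
#' @param organelle Organelle label attached to the simulated trait.
#' @param min_genes,max_genes Family-size limits (families outside the range
#'   are resampled).
#' @param max_tries Resampling attempts before giving up.
#' @param p_changed,p_background Planted-term carrier probability among
#'   changed and unchanged orthogroups.
#' @param n_noise_terms,noise_prob Number of unplanted terms and their
#'   uniform carrier probability.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 20, n_orthogroups = 50, birth = 1,
                       tree_depth = 1, root_age = 450,
                       lambda_dup = 0.8, lambda_loss = 0.05,
                       alpha = 0.15, beta = 0.4, kappa = 1, rho = 1,
                       rate_jitter_sd = 0.3, n_wgd = 0, wgd_prob = 1,
                       organelle = "chloroplast",
                       min_genes = 4, max_genes = 400, max_tries = 100,
                       p_changed = 0.4, p_background = 0.05,
                       n_noise_terms = 20, noise_prob = 0.1) {
  stopifnot(n_species >= 2, n_orthogroups >= 1,
            lambda_dup >= 0, lambda_loss >= 0, alpha >= 0, beta >= 0,
            kappa >= 1, rho >= 1, rate_jitter_sd >= 0,
            wgd_prob >= 0, wgd_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a dated species tree
#'
#' Yule (pure-birth) ultrametric species tree, rescaled to `tree_depth`
#' root-to-tip substitutions/site; node ages are the same depths rescaled to
#' `root_age` My. `n_wgd` internal nonroot branches are flagged as
#' whole-genome duplications.
#'
#' @inheritParams sim_config
#' @param seed Optional integer seed.
#' @return A list with `tree` (`phylo`), `ages` (tibble from [node_ages()])
#'   and `wgd_branches` (integer vector of flagged branches).
#' @export
simulate_species_tree <- function(n_species, birth = 1, tree_depth = 1,
                                  root_age = 450, n_wgd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_species >= 2)
  tree <- if (n_species == 2L) {
    t0 <- rexp(1, birth)
    read_newick(sprintf("(t1:%.10f,t2:%.10f);", t0, t0))
  } else {
    ape::rphylo(n_species, birth = birth, death = 0)
  }
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth * tree_depth
  tree$node.label <- paste0("s", (n_species + 1L):(n_species + tree$Nnode))
  internal_branches <- setdiff((n_species + 1L):n_nodes_total(tree),
                               root_node(tree))
  wgd <- integer(0)
  if (n_wgd > 0 && length(internal_branches)) {
    wgd <- sort(sample(internal_branches, min(n_wgd, length(internal_branches))))
  }
  list(tree = tree, ages = node_ages(tree, root_age), wgd_branches = wgd)
}

#' Simulate a duplication-loss gene family along a species tree
#'
#' One root lineage descends through the species tree; duplications split it
#' (Poisson rate `lambda_dup` per unit branch length, plus a Bernoulli
#' whole-genome duplication at the midpoint of flagged branches), losses
#' prune it (rate `lambda_loss`). Lost lineages and the unifurcations they
#' leave behind are removed, so gene-tree branches may span several
#' consecutive species branches. Families smaller than `min_genes` genes or
#' covering fewer than two species are resampled. Branch lengths are
#' chronological (species-tree units); see [simulate_orthogroup()] for the
#' molecular-rate jitter.
#'
#' @param species_tree Species `phylo`.
#' @param lambda_dup,lambda_loss Duplication and loss rates per unit branch
#'   length.
#' @param wgd_branches Integer vector of WGD-flagged species branches.
#' @param wgd_prob Per-lineage duplication probability at a WGD midpoint.
#' @param min_genes,max_genes,max_tries Family-size limits and retry cap.
#' @param seed Optional integer seed.
#' @return A list with `tree` (`phylo`, node labels `g1`, `g2`, ...),
#'   `gene_species_map` (tibble), and `truth`: a tibble of true internal-node
#'   events (`node`, `label`, `event`, `species_node`, `wgd`).
#' @export
simulate_gene_tree <- function(species_tree, lambda_dup = 0.2,
                               lambda_loss = 0.1, wgd_branches = integer(0),
                               wgd_prob = 1, min_genes = 4, max_genes = 400,
                               max_tries = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp_children <- tree_children(species_tree)
  sp_elen <- numeric(n_nodes_total(species_tree))
  sp_elen[species_tree$edge[, 2L]] <- species_tree$edge.length
  nt_sp <- n_tips(species_tree)

  for (try in seq_len(max_tries)) {
    env <- new.env(parent = emptyenv())
    env$n_leaves <- 0L

    descend <- function(s_node, start, wgd_done) {
      Tlen <- sp_elen[s_node]
      wgd_here <- (s_node %in% wgd_branches) && !wgd_done
      repeat {
        t_dup <- if (lambda_dup > 0) rexp(1, lambda_dup) else Inf
        t_loss <- if (lambda_loss > 0) rexp(1, lambda_loss) else Inf
        t_ev <- min(t_dup, t_loss)
        stop_at <- min(start + t_ev, Tlen)
        wgd_pos <- Tlen / 2
        if (wgd_here && start < wgd_pos && stop_at >= wgd_pos) {
          if (runif(1) < wgd_prob) {
            kids <- list(descend(s_node, wgd_pos, TRUE),
                         descend(s_node, wgd_pos, TRUE))
            return(join_kids(kids, wgd_pos - start, "duplication",
                             s_node, TRUE))
          }
          wgd_here <- FALSE
          next  # memoryless: redraw waiting times from the same position
        }
        if (start + t_ev >= Tlen) {
          if (s_node <= nt_sp) {
            env$n_leaves <- env$n_leaves + 1L
            if (env$n_leaves > max_genes) stop("family too large")
            return(list(type = "leaf", species = s_node,
                        elen = Tlen - start, children = NULL))
          }
          kids <- lapply(sp_children[[s_node]], descend, start = 0,
                         wgd_done = FALSE)
          return(join_kids(kids, Tlen - start, "speciation", s_node, FALSE))
        }
        if (t_loss <= t_dup) return(NULL)
        pos <- start + t_ev
        kids <- list(descend(s_node, pos, wgd_done || !wgd_here ||
                               pos >= wgd_pos),
                     descend(s_node, pos, wgd_done || !wgd_here ||
                               pos >= wgd_pos))
        return(join_kids(kids, pos - start, "duplication", s_node, FALSE))
      }
    }

    root_try <- tryCatch({
      sp_root <- root_node(species_tree)
      kids <- lapply(sp_children[[sp_root]], descend, start = 0,
                     wgd_done = FALSE)
      join_kids(kids, 0, "speciation", sp_root, FALSE)
    }, error = function(e) {
      if (conditionMessage(e) == "family too large") NULL else stop(e)
    })
    if (is.null(root_try) || root_try$type == "leaf") next

    built <- build_phylo_from_sim(root_try, species_tree)
    n_sp_seen <- length(unique(built$gene_species_map$species_id))
    if (nrow(built$gene_species_map) >= min_genes && n_sp_seen >= 2L) {
      return(built)
    }
  }
  abort(paste0("failed to simulate a surviving gene family in ", max_tries,
               " attempts"))
}

join_kids <- function(kids, elen, type, species, wgd) {
  alive <- kids[!vapply(kids, is.null, logical(1))]
  if (length(alive) == 0L) return(NULL)
  if (length(alive) == 1L) {
    survivor <- alive[[1L]]
    survivor$elen <- survivor$elen + elen
    return(survivor)
  }
  list(type = type, species = species, elen = elen, wgd = wgd,
       children = alive)
}

# Convert the simulated node structure to an ape phylo plus truth tables.
build_phylo_from_sim <- function(root, species_tree) {
  env <- new.env(parent = emptyenv())
  env$leaf_count <- integer(n_tips(species_tree))
  env$node_id <- 0L
  env$t_label <- character(0); env$t_event <- character(0)
  env$t_species <- integer(0); env$t_wgd <- logical(0)
  env$m_gene <- character(0); env$m_species <- character(0)

  to_newick <- function(node, is_root = FALSE) {
    if (node$type == "leaf") {
      sp_lab <- species_tree$tip.label[node$species]
      env$leaf_count[node$species] <- env$leaf_count[node$species] + 1L
      gid <- paste0(sp_lab, "_g", env$leaf_count[node$species])
      env$m_gene <- c(env$m_gene, gid)
      env$m_species <- c(env$m_species, sp_lab)
      return(sprintf("%s:%.12f", gid, node$elen))
    }
    env$node_id <- env$node_id + 1L
    lab <- paste0("g", env$node_id)
    env$t_label <- c(env$t_label, lab)
    env$t_event <- c(env$t_event, node$type)
    env$t_species <- c(env$t_species, node$species)
    env$t_wgd <- c(env$t_wgd, isTRUE(node$wgd))
    inner <- paste(vapply(node$children, to_newick, character(1)),
                   collapse = ",")
    if (is_root) sprintf("(%s)%s;", inner, lab)
    else sprintf("(%s)%s:%.12f", inner, lab, node$elen)
  }

  nwk <- to_newick(root, is_root = TRUE)
  tree <- read_newick(nwk)
  truth <- tibble::tibble(
    node = match(env$t_label, tree$node.label) + n_tips(tree),
    label = env$t_label, event = env$t_event,
    species_node = env$t_species, wgd = env$t_wgd
  )
  list(tree = tree,
       gene_species_map = tibble::tibble(gene_id = env$m_gene,
                                         species_id = env$m_species),
       truth = truth)
}

#' Simulate a binary targeting trait on a gene tree
#'
#' Evolves a two-state Markov trait from a root state drawn from the
#' stationary distribution (or fixed via `root_state`). On the two immediate
#' child branches of each node in `dup_nodes`, both rates are multiplied by
#' `kappa`. Every realized flip is recorded.
#'
#' @param gene_tree Gene `phylo` with chronological branch lengths.
#' @param dup_nodes Integer node indices of true duplication nodes.
#' @param alpha,beta Gain and loss rates per unit branch length.
#' @param kappa Post-duplication rate multiplier (>= 1).
#' @param root_state Optional fixed root state (0 or 1).
#' @param seed Optional integer seed.
#' @return A list with `node_states` (integer per node), `tip_states` (named
#'   0/1 vector), `flips` (tibble `parent`, `child`, `direction`), and
#'   `change_branches` (tibble `parent`, `child`, `changed`,
#'   `post_duplication`).
#' @export
simulate_trait <- function(gene_tree, dup_nodes = integer(0), alpha = 0.1,
                           beta = 0.4, kappa = 1, root_state = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(alpha >= 0, beta >= 0, kappa >= 1)
  nn <- n_nodes_total(gene_tree)
  elen <- numeric(nn)
  elen[gene_tree$edge[, 2L]] <- gene_tree$edge.length
  par <- tree_parents(gene_tree)
  states <- integer(nn)
  root <- root_node(gene_tree)
  if (is.null(root_state)) {
    p1 <- if (alpha + beta > 0) alpha / (alpha + beta) else 0.5
    states[root] <- rbinom(1, 1, p1)
  } else {
    states[root] <- as.integer(root_state)
  }
  flip_parent <- integer(0); flip_child <- integer(0); flip_dir <- character(0)
  ord <- preorder_nodes(gene_tree)
  ord <- ord[par[ord] != 0L]
  eb_parent <- par[ord]; eb_child <- ord
  eb_changed <- logical(length(ord))
  eb_post <- eb_parent %in% dup_nodes
  for (j in seq_along(ord)) {
    v <- ord[j]
    mult <- if (eb_post[j]) kappa else 1
    s <- states[par[v]]
    t_left <- elen[v]
    repeat {
      rate <- mult * (if (s == 0L) alpha else beta)
      if (rate <= 0) break
      w <- rexp(1, rate)
      if (w >= t_left) break
      t_left <- t_left - w
      s <- 1L - s
      flip_parent <- c(flip_parent, par[v])
      flip_child <- c(flip_child, v)
      flip_dir <- c(flip_dir, if (s == 1L) "gain" else "loss")
    }
    eb_changed[j] <- states[par[v]] != s
    states[v] <- s
  }
  tip_states <- setNames(states[seq_len(n_tips(gene_tree))],
                         gene_tree$tip.label)
  list(
    node_states = states,
    tip_states = tip_states,
    flips = tibble::tibble(parent = flip_parent, child = flip_child,
                           direction = flip_dir),
    change_branches = tibble::tibble(parent = eb_parent, child = eb_child,
                                     changed = eb_changed,
                                     post_duplication = eb_post)
  )
}

#' Simulate one fully ground-truthed orthogroup
#'
#' Chains [simulate_gene_tree()] and [simulate_trait()] for one family, then
#' converts chronological branch lengths to molecular ones by applying a
#' per-branch lognormal rate jitter and the `rho` multiplier on branches with
#' a true targeting change.
#'
#' @param species_tree Species `phylo`.
#' @param config A [sim_config()].
#' @param wgd_branches Integer vector of WGD-flagged species branches.
#' @param orthogroup Orthogroup id.
#' @return A list with `orthogroup`, `gene_tree` (molecular branch lengths),
#'   `chrono_tree`, `gene_species_map`, `tip_states`, and `truth` (node
#'   events, trait flips, change branches).
#' @export
simulate_orthogroup <- function(species_tree, config = sim_config(),
                                wgd_branches = integer(0),
                                orthogroup = "OG0001") {
  fam <- simulate_gene_tree(
    species_tree, lambda_dup = config$lambda_dup,
    lambda_loss = config$lambda_loss, wgd_branches = wgd_branches,
    wgd_prob = config$wgd_prob, min_genes = config$min_genes,
    max_genes = config$max_genes, max_tries = config$max_tries
  )
  # gene ids must be unique across orthogroups, so carry the family id
  prefix <- paste0(orthogroup, "_")
  fam$tree$tip.label <- paste0(prefix, fam$tree$tip.label)
  fam$gene_species_map$gene_id <- paste0(prefix, fam$gene_species_map$gene_id)
  dup_nodes <- fam$truth$node[fam$truth$event == "duplication"]
  trait <- simulate_trait(fam$tree, dup_nodes, alpha = config$alpha,
                          beta = config$beta, kappa = config$kappa)
  mol <- fam$tree
  jitter <- exp(rnorm(nrow(mol$edge), 0, config$rate_jitter_sd))
  changed_edge <- trait$change_branches$changed[
    match(paste(mol$edge[, 1L], mol$edge[, 2L]),
          paste(trait$change_branches$parent, trait$change_branches$child))]
  mult <- ifelse(changed_edge, config$rho, 1)
  mol$edge.length <- mol$edge.length * jitter * mult
  list(
    orthogroup = orthogroup,
    gene_tree = mol,
    chrono_tree = fam$tree,
    gene_species_map = fam$gene_species_map,
    tip_states = trait$tip_states,
    truth = list(nodes = fam$truth, flips = trait$flips,
                 change_branches = trait$change_branches)
  )
}

#' Simulate protein sequences with planted PTS motifs
#'
#' Peroxisome-state genes receive either a valid PTS1 C-terminal tripeptide
#' or an in-window PTS2 nonapeptide; all other genes are scrubbed so that
#' neither motif matches.
#'
#' @param perox_states Named 0/1 vector (gene id to peroxisomal state).
#' @param length_range Sequence length range (residues).
#' @param seed Optional integer seed.
#' @return Named character vector of amino-acid sequences.
#' @export
simulate_sequences <- function(perox_states, length_range = c(80, 150),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rand_seq <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")
  out <- character(length(perox_states))
  names(out) <- names(perox_states)
  for (i in seq_along(perox_states)) {
    len <- sample(seq(length_range[1], length_range[2]), 1)
    s <- rand_seq(len)
    if (perox_states[i] == 1L) {
      if (runif(1) < 0.5) {
        s <- paste0(substr(s, 1, len - 3), sample(PTS1_TRIPEPTIDES, 1))
      } else {
        motif <- paste0("R", sample(c("L", "I"), 1), rand_seq(5), "HL")
        at <- sample(1:22, 1)
        s <- paste0(substr(s, 1, at - 1), motif, substr(s, at + 9, len))
      }
    } else {
      # scrub accidental motifs
      while (classify_pts1(s)$pts1) {
        s <- paste0(substr(s, 1, nchar(s) - 3), rand_seq(3))
      }
      while (classify_pts2(s, anchor = "start")$pts2) {
        at <- classify_pts2(s, anchor = "start")$start
        substr(s, at, at) <- sample(setdiff(aa20, "R"), 1)
      }
    }
    out[i] <- s
  }
  out
}

#' Simulate orthogroup term annotations with a planted enrichment
#'
#' The planted term is carried by changed orthogroups with probability
#' `p_changed` and by the rest with probability `p_background`; unplanted
#' noise terms are carried uniformly at `noise_prob`.
#'
#' @param orthogroups Character vector of orthogroup ids.
#' @param changed Character vector of changed orthogroup ids.
#' @param planted_term Name of the planted term.
#' @param p_changed,p_background,n_noise_terms,noise_prob See [sim_config()].
#' @param seed Optional integer seed.
#' @return A tibble (`orthogroup`, `term`) usable as a term table.
#' @export
simulate_term_annotations <- function(orthogroups, changed,
                                      planted_term = "PLANTED",
                                      p_changed = 0.4, p_background = 0.05,
                                      n_noise_terms = 20, noise_prob = 0.1,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  p_carry <- ifelse(orthogroups %in% changed, p_changed, p_background)
  carry <- runif(length(orthogroups)) < p_carry
  if (any(carry)) {
    rows[[1]] <- tibble::tibble(orthogroup = orthogroups[carry],
                                term = planted_term)
  }
  for (j in seq_len(n_noise_terms)) {
    hit <- runif(length(orthogroups)) < noise_prob
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        orthogroup = orthogroups[hit], term = sprintf("NOISE%03d", j))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(orthogroup = character(), term = character()))
  }
  dplyr::bind_rows(rows)
}

#' Simulate a complete ground-truthed data set
#'
#' Species tree plus `n_orthogroups` orthogroups, a localization-call table
#' derived from the simulated trait (state 1 maps to the configured
#' organelle, state 0 to "none"), and planted term annotations keyed to the
#' orthogroups that truly changed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole data set is reproducible from it.
#' @return A list of class `sim_dataset` with `config`, `seed`,
#'   `species_tree`, `ages`, `wgd_branches`, `orthogroups` (list from
#'   [simulate_orthogroup()]), `localization`, `term_table`,
#'   `changed_orthogroups`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  sp <- simulate_species_tree(config$n_species, birth = config$birth,
                              tree_depth = config$tree_depth,
                              root_age = config$root_age,
                              n_wgd = config$n_wgd)
  ogs <- vector("list", config$n_orthogroups)
  for (i in seq_len(config$n_orthogroups)) {
    ogs[[i]] <- simulate_orthogroup(sp$tree, config, sp$wgd_branches,
                                    orthogroup = sprintf("OG%04d", i))
  }
  loc <- dplyr::bind_rows(lapply(ogs, function(og) {
    tibble::tibble(
      gene_id = names(og$tip_states),
      compartment = ifelse(og$tip_states == 1L, config$organelle, "none"),
      dual_peroxisomal = FALSE
    )
  }))
  changed <- vapply(ogs, function(og) any(og$truth$change_branches$changed),
                    logical(1))
  og_ids <- vapply(ogs, `[[`, character(1), "orthogroup")
  terms <- simulate_term_annotations(
    og_ids, og_ids[changed], p_changed = config$p_changed,
    p_background = config$p_background,
    n_noise_terms = config$n_noise_terms, noise_prob = config$noise_prob
  )
  structure(
    list(config = config, seed = seed, species_tree = sp$tree,
         ages = sp$ages, wgd_branches = sp$wgd_branches, orthogroups = ogs,
         localization = loc, term_table = terms,
         changed_orthogroups = og_ids[changed]),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", length(x$orthogroups), "orthogroups over",
      n_tips(x$species_tree), "species (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}
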
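test_that("binarization uses winner-takes-all with ties to targeted", {
  expect_equal(binarize(c(0.5, 0.4999, 1, 0)), c(1L, 0L, 1L, 0L))
  expect_equal(binarize(0.6, threshold = 0.7), 0L)
})

test_that("candidate transitions appear exactly on state-discordant branches", {
  tr <- read_newick("((A:1,B:1)x:1,C:1)r;")
  # nodes: A=1 B=2 C=3 r=4 x=5
  states <- c(1L, 1L, 0L, 0L, 1L)
  cand <- candidate_transitions(tr, states)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$parent, 4L)
  expect_equal(cand$child, 5L)
  expect_equal(cand$direction, "gain")
  # all targeted: no candidates anywhere (and nothing above the root)
  expect_equal(nrow(candidate_transitions(tr, rep(1L, 5))), 0L)
})

make_filter_case <- function(nx, ny, nx_changed, nspx, ny_anc) {
  x_labs <- paste0("x", seq_len(nx))
  y_labs <- paste0("y", seq_len(ny))
  nwk <- paste0("(", caterpillar(x_labs), ":1,", caterpillar(y_labs), ":1);")
  tr <- read_newick(nwk)
  nt <- nx + ny
  root <- nt + 1L
  x_node <- if (nx == 1L) which(tr$tip.label == "x1") else
    tr$edge[tr$edge[, 1] == root, 2][1]
  # observed leaf states: gain scenario, ancestral 0 -> changed 1
  st <- setNames(integer(nt), tr$tip.label)
  st[x_labs[seq_len(nx_changed)]] <- 1L
  st[y_labs] <- 0L
  if (ny_anc < ny) st[y_labs[seq_len(ny - ny_anc)]] <- 1L
  species <- setNames(c(paste0("S", pmin(seq_len(nx), nspx)),
                        rep("SY", ny)), c(x_labs, y_labs))
  node_states <- integer(nt + tr$Nnode)
  node_states[seq_len(nt)] <- st
  node_states[root] <- 0L
  node_states[x_node] <- 1L
  list(tree = tr, root = root, x_node = x_node, st = st,
       node_states = node_states, species = species)
}

test_that("the retention filter applies the strict >75% and >=2 species rules", {
  # X: 4/5 changed (80%), Y: 3/3 ancestral, X spans 2 species -> retained
  cs <- make_filter_case(5, 3, 4, 2, 3)
  r <- retention_filter(cs$tree, cs$root, cs$x_node, cs$node_states, cs$st,
                        cs$species)
  expect_true(as.logical(r))
  expect_equal(attr(r, "frac_changed"), 0.8)

  # exactly 75% fails the strict inequality
  cs <- make_filter_case(4, 3, 3, 2, 3)
  r <- retention_filter(cs$tree, cs$root, cs$x_node, cs$node_states, cs$st,
                        cs$species)
  expect_false(as.logical(r))
  expect_equal(attr(r, "frac_changed"), 0.75)

  # both changed leaves from one species fails the species rule
  cs <- make_filter_case(2, 3, 2, 1, 3)
  r <- retention_filter(cs$tree, cs$root, cs$x_node, cs$node_states, cs$st,
                        cs$species)
  expect_false(as.logical(r))
  expect_equal(attr(r, "n_species"), 1L)

  # sister side failing its 75% criterion also rejects
  cs <- make_filter_case(5, 4, 5, 2, 3)
  r <- retention_filter(cs$tree, cs$root, cs$x_node, cs$node_states, cs$st,
                        cs$species)
  expect_false(as.logical(r))
  expect_equal(attr(r, "frac_ancestral"), 0.75)
})

test_that("species-branch mapping distributes weight per mode", {
  span <- c(5L, 1L)
  mrca <- map_to_species_branches(span, "mrca")
  expect_equal(mrca$species_branch, 1L)
  expect_equal(mrca$weight, 1)
  split <- map_to_species_branches(span, "split")
  expect_equal(split$species_branch, c(5L, 1L))
  expect_equal(split$weight, c(0.5, 0.5))
  one <- map_to_species_branches(7L, "mrca")
  expect_identical(one, map_to_species_branches(7L, "split"))
  empty <- map_to_species_branches(integer(0))
  expect_equal(nrow(empty), 0L)
})

test_that("tallies conserve total event weight across mapping modes", {
  set.seed(21)
  cfg <- sim_config(n_species = 10, n_orthogroups = 6, kappa = 3,
                    lambda_loss = 0.25)
  ds <- simulate_dataset(cfg, seed = 21)
  states_all <- trait_states(ds$localization, "chloroplast")
  ev_mrca <- list(); ev_split <- list()
  for (og in ds$orthogroups) {
    rec <- lca_reconcile(og$gene_tree, ds$species_tree, og$gene_species_map)
    fit <- fit_mk(og$gene_tree, states_all[og$gene_tree$tip.label])
    ev_mrca[[og$orthogroup]] <- call_changes(fit, rec, orthogroup = og$orthogroup,
                                             mode = "mrca")
    ev_split[[og$orthogroup]] <- call_changes(fit, rec, orthogroup = og$orthogroup,
                                              mode = "split")
  }
  ev_mrca <- dplyr::bind_rows(ev_mrca)
  ev_split <- dplyr::bind_rows(ev_split)
  t_mrca <- tally_changes(ev_mrca, ds$species_tree)
  t_split <- tally_changes(ev_split, ds$species_tree)
  expect_equal(sum(t_mrca$gains) + sum(t_mrca$losses),
               sum(t_split$gains) + sum(t_split$losses), tolerance = 1e-9)
  # every tallied event has full weight 1 distributed
  n_mapped <- sum(ev_mrca$span_length >= 1L)
  expect_equal(sum(t_mrca$gains) + sum(t_mrca$losses), n_mapped,
               tolerance = 1e-9)
})

test_that("an empty event set tallies to all zeros", {
  sp <- read_newick("((A:1,B:1)AB:1,C:2)R;")
  no_events <- tibble::tibble(orthogroup = character(), organelle = character(),
                              direction = character(), parent = integer(),
                              child = integer(), assignment = list())
  tal <- tally_changes(no_events, sp)
  expect_true(all(tal$gains == 0) && all(tal$losses == 0))
  expect_equal(sum(!tal$terminal), 1L)  # only the AB branch is internal
})

test_that("recall is nonincreasing in the retention threshold", {
  set.seed(22)
  cfg <- sim_config(n_species = 12, n_orthogroups = 8, alpha = 0.3,
                    beta = 0.6)
  ds <- simulate_dataset(cfg, seed = 22)
  states_all <- trait_states(ds$localization, "chloroplast")
  counts <- sapply(c(0.5, 0.75, 0.9), function(th) {
    tot <- 0L
    for (og in ds$orthogroups) {
      rec <- lca_reconcile(og$gene_tree, ds$species_tree, og$gene_species_map)
      fit <- fit_mk(og$gene_tree, states_all[og$gene_tree$tip.label])
      tot <- tot + nrow(call_changes(fit, rec, retention = th))
    }
    tot
  })
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})
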
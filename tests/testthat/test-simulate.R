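test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_species = 6, n_orthogroups = 3)
  d1 <- simulate_dataset(cfg, seed = 99)
  d2 <- simulate_dataset(cfg, seed = 99)
  expect_identical(write_newick(d1$species_tree), write_newick(d2$species_tree))
  expect_identical(lapply(d1$orthogroups, function(o) write_newick(o$gene_tree)),
                   lapply(d2$orthogroups, function(o) write_newick(o$gene_tree)))
  expect_identical(d1$localization, d2$localization)
  expect_identical(d1$term_table, d2$term_table)
})

test_that("gene ids are unique across orthogroups and states align", {
  cfg <- sim_config(n_species = 6, n_orthogroups = 5)
  ds <- simulate_dataset(cfg, seed = 17)
  all_ids <- unlist(lapply(ds$orthogroups, function(o) o$gene_tree$tip.label))
  expect_false(any(duplicated(all_ids)))
  expect_setequal(ds$localization$gene_id, all_ids)
  # the dataset-level localization table reproduces each family's tip states
  states_all <- trait_states(ds$localization, "chloroplast")
  for (og in ds$orthogroups) {
    expect_identical(unname(states_all[names(og$tip_states)]),
                     unname(og$tip_states))
  }
})

test_that("species trees have the requested size, depth and ages", {
  sim <- simulate_species_tree(42, seed = 1)
  expect_equal(sim$tree$Nnode, 41L)
  expect_equal(max(ape::node.depth.edgelength(sim$tree)), 1, tolerance = 1e-12)
  expect_equal(max(sim$ages$age_my), 450)
  expect_true(all(diff(sim$ages$age_my[order(sim$ages$node)]) <= 450))
  # parent older than child throughout
  par <- sim$tree$edge[, 1]; ch <- sim$tree$edge[, 2]
  expect_true(all(sim$ages$age_my[par] > sim$ages$age_my[ch] - 1e-9))
  cherry <- simulate_species_tree(2, seed = 2)
  expect_equal(length(cherry$tree$tip.label), 2L)
})

test_that("null duplication/loss rates give congruent single-copy families", {
  set.seed(61)
  sim <- simulate_species_tree(7, n_wgd = 0)
  fam <- simulate_gene_tree(sim$tree, lambda_dup = 0, lambda_loss = 0)
  expect_equal(length(fam$tree$tip.label), 7L)
  expect_equal(sum(fam$truth$event == "duplication"), 0L)
  expect_equal(sort(fam$gene_species_map$species_id), sort(sim$tree$tip.label))
})

test_that("a certain WGD duplicates every crossing lineage and is recoverable", {
  set.seed(62)
  sim <- simulate_species_tree(8, n_wgd = 0)
  # flag the oldest internal non-root branch so several lineages cross it
  internal <- setdiff(9:15, 9L)
  wgd <- internal[which.max(sim$ages$age_my[internal])]
  fam <- simulate_gene_tree(sim$tree, lambda_dup = 0, lambda_loss = 0,
                            wgd_branches = wgd, wgd_prob = 1)
  wgd_dups <- fam$truth[fam$truth$event == "duplication", ]
  expect_equal(nrow(wgd_dups), 1L)  # one lineage crosses, duplicates once
  expect_true(all(wgd_dups$wgd))
  expect_equal(wgd_dups$species_node, wgd)
  rec <- lca_reconcile(fam$tree, sim$tree, fam$gene_species_map)
  expect_equal(n_duplications(rec), 1L)
})

test_that("losses create branches spanning several species branches", {
  set.seed(63)
  sim <- simulate_species_tree(10, n_wgd = 0)
  found <- FALSE
  for (i in 1:20) {
    fam <- simulate_gene_tree(sim$tree, lambda_dup = 0, lambda_loss = 0.4)
    rec <- lca_reconcile(fam$tree, sim$tree, fam$gene_species_map)
    if (any(lengths(rec$spans) > 1L)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("an absorbing trait stays absorbed", {
  set.seed(64)
  sim <- simulate_species_tree(6, n_wgd = 0)
  fam <- simulate_gene_tree(sim$tree, lambda_dup = 0.2, lambda_loss = 0)
  tr <- simulate_trait(fam$tree, alpha = 0, beta = 0.5, root_state = 0)
  expect_true(all(tr$tip_states == 0L))
  expect_equal(nrow(tr$flips), 0L)
  expect_false(any(tr$change_branches$changed))
})

test_that("kappa elevates the post-duplication flip rate by the right factor", {
  set.seed(65)
  sim <- simulate_species_tree(12, n_wgd = 0)
  tally <- function(kappa) {
    flips <- c(post = 0, other = 0); len <- c(post = 0, other = 0)
    for (i in 1:60) {
      fam <- simulate_gene_tree(sim$tree, lambda_dup = 0.4, lambda_loss = 0)
      dup_nodes <- fam$truth$node[fam$truth$event == "duplication"]
      tr <- simulate_trait(fam$tree, dup_nodes, alpha = 0.15, beta = 0.25,
                           kappa = kappa)
      elen <- numeric(length(fam$tree$tip.label) + fam$tree$Nnode)
      elen[fam$tree$edge[, 2]] <- fam$tree$edge.length
      cb <- tr$change_branches
      nf <- table(factor(paste(tr$flips$parent, tr$flips$child),
                         levels = paste(cb$parent, cb$child)))
      post <- cb$post_duplication
      flips["post"] <- flips["post"] + sum(nf[post])
      flips["other"] <- flips["other"] + sum(nf[!post])
      len["post"] <- len["post"] + sum(elen[cb$child[post]])
      len["other"] <- len["other"] + sum(elen[cb$child[!post]])
    }
    list(flips = flips, len = len)
  }
  null <- tally(1)
  # under kappa = 1 flips split between classes in proportion to length
  expect_gt(stats::chisq.test(
    null$flips, p = null$len / sum(null$len))$p.value, 0.01)
  planted <- tally(5)
  ratio <- (planted$flips["post"] / planted$len["post"]) /
    (planted$flips["other"] / planted$len["other"])
  expect_gt(ratio, 3)
  expect_lt(ratio, 7.5)
})

test_that("planted sequences carry PTS motifs exactly where intended", {
  set.seed(66)
  states <- setNames(rep(c(1L, 0L), each = 40), sprintf("g%02d", 1:80))
  seqs <- simulate_sequences(states)
  res <- scan_pts(seqs)
  pos <- res$pts1 | res$pts2
  expect_true(all(pos[match(names(states)[states == 1L], res$gene_id)]))
  expect_false(any(pos[match(names(states)[states == 0L], res$gene_id)]))
})

test_that("planted term frequencies match their configuration", {
  set.seed(67)
  ogs <- sprintf("og%04d", 1:2000)
  changed <- ogs[1:500]
  tt <- simulate_term_annotations(ogs, changed, p_changed = 0.4,
                                  p_background = 0.05, n_noise_terms = 3)
  carriers <- tt$orthogroup[tt$term == "PLANTED"]
  f_changed <- mean(changed %in% carriers)
  f_back <- mean(setdiff(ogs, changed) %in% carriers)
  expect_lt(abs(f_changed - 0.4), 4 * sqrt(0.4 * 0.6 / 500))
  expect_lt(abs(f_back - 0.05), 4 * sqrt(0.05 * 0.95 / 1500))
})

test_that("rho inflates molecular lengths on true change branches", {
  set.seed(68)
  cfg <- sim_config(n_species = 10, n_orthogroups = 15, rho = 3,
                    alpha = 0.3, beta = 0.5, rate_jitter_sd = 0.2)
  ds <- simulate_dataset(cfg, seed = 68)
  ratios <- unlist(lapply(ds$orthogroups, function(og) {
    key <- paste(og$gene_tree$edge[, 1], og$gene_tree$edge[, 2])
    cb <- og$truth$change_branches
    changed <- key %in% paste(cb$parent, cb$child)[cb$changed]
    mol <- og$gene_tree$edge.length
    chrono <- og$chrono_tree$edge.length
    (mol / chrono)[changed]
  }))
  base <- unlist(lapply(ds$orthogroups, function(og) {
    key <- paste(og$gene_tree$edge[, 1], og$gene_tree$edge[, 2])
    cb <- og$truth$change_branches
    changed <- key %in% paste(cb$parent, cb$child)[cb$changed]
    mol <- og$gene_tree$edge.length
    chrono <- og$chrono_tree$edge.length
    (mol / chrono)[!changed]
  }))
  expect_gt(median(ratios) / median(base), 2)
})
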
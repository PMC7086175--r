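sp3 <- read_newick("((A:1,B:1)AB:1,C:2)R;")

test_that("high-confidence duplication nodes require retention in both children", {
  gt <- read_newick("((a1:1,b1:1):1,(a2:1,b2:1):1);")
  rec <- lca_reconcile(gt, sp3, c(a1 = "A", b1 = "B", a2 = "A", b2 = "B"))
  recs <- select_high_confidence_nodes(rec)
  dup <- recs[recs$class == "duplication", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$species_label, "AB")

  # dropping one species from one child clade disqualifies the duplication
  gt2 <- read_newick("((a1:1,b1:1):1,a2:2);")
  rec2 <- lca_reconcile(gt2, sp3, c(a1 = "A", b1 = "B", a2 = "A"))
  recs2 <- select_high_confidence_nodes(rec2)
  expect_equal(sum(recs2$class == "duplication"), 0L)
})

test_that("a within-species duplication qualifies via its single species", {
  gt <- read_newick("((a1:1,a2:1):1,b1:2);")
  rec <- lca_reconcile(gt, sp3, c(a1 = "A", a2 = "A", b1 = "B"))
  recs <- select_high_confidence_nodes(rec)
  dup <- recs[recs$class == "duplication", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$species_label, "A")
  # terminal child branches can never carry a retained change, so the node
  # cannot score a child change
  expect_false(dup$child_change)
})

test_that("speciation nodes demand complete species coverage and dup-free subtrees", {
  # full coverage: both internal nodes qualify
  gt <- read_newick("((a1:1,b1:1):1,c1:2);")
  rec <- lca_reconcile(gt, sp3, c(a1 = "A", b1 = "B", c1 = "C"))
  recs <- select_high_confidence_nodes(rec)
  expect_equal(sum(recs$class == "speciation"), 2L)

  # gene loss below the mapped node disqualifies: root maps to R but B absent
  gt2 <- read_newick("(a1:1,c1:1);")
  rec2 <- lca_reconcile(gt2, sp3, c(a1 = "A", c1 = "C"))
  recs2 <- select_high_confidence_nodes(rec2)
  expect_equal(nrow(recs2), 0L)

  # a duplication anywhere in the subtree disqualifies the strict variant
  gt3 <- read_newick("(((a1:1,a2:1):1,b1:1):1,c1:2);")
  rec3 <- lca_reconcile(gt3, sp3, c(a1 = "A", a2 = "A", b1 = "B", c1 = "C"))
  strict <- select_high_confidence_nodes(rec3)
  expect_equal(sum(strict$class == "speciation"), 0L)
  lax <- select_high_confidence_nodes(rec3, subtree_dup_free = FALSE)
  expect_gt(sum(lax$class == "speciation"), 0L)
})

test_that("high-confidence child branches are unambiguously placed", {
  set.seed(41)
  sim <- simulate_species_tree(10, n_wgd = 0)
  for (i in 1:6) {
    fam <- simulate_gene_tree(sim$tree, lambda_dup = 0.3, lambda_loss = 0.2)
    rec <- lca_reconcile(fam$tree, sim$tree, fam$gene_species_map)
    recs <- select_high_confidence_nodes(rec)
    for (v in recs$gene_node) {
      kids <- rec$gene_tree$edge[rec$gene_tree$edge[, 1] == v, 2]
      for (k in kids) {
        expect_lte(length(species_branch_span(rec, v, k)), 1L)
      }
    }
  }
})

test_that("the hypergeometric test matches an exact enumeration oracle", {
  fake_records <- function(n_dup, k_dup, n_spec, k_spec) {
    tibble::tibble(
      orthogroup = "OG",
      gene_node = seq_len(n_dup + n_spec),
      gene_label = "g",
      class = rep(c("duplication", "speciation"), c(n_dup, n_spec)),
      species_node = 1L, species_label = "s",
      child_change = c(rep(c(TRUE, FALSE), c(k_dup, n_dup - k_dup)),
                       rep(c(TRUE, FALSE), c(k_spec, n_spec - k_spec)))
    )
  }
  res <- duplication_change_test(fake_records(10, 5, 100, 50),
                                 n_resamples = 0)
  # oracle: sum of hypergeometric point masses over the upper tail
  oracle <- sum(stats::dhyper(5:10, 55, 55, 10))
  expect_equal(res$hypergeom_p, oracle, tolerance = 1e-12)
  expect_lt(abs(oracle - 0.62), 0.02)  # clearly no enrichment

  extreme <- duplication_change_test(fake_records(10, 10, 100, 0),
                                     n_resamples = 0)
  expect_equal(extreme$hypergeom_p, 1 / choose(110, 10), tolerance = 1e-12)

  expect_warning(flat <- duplication_change_test(fake_records(5, 0, 20, 0),
                                                 n_resamples = 0),
                 "no variance")
  expect_equal(flat$hypergeom_p, 1)
})

test_that("origin classification partitions duplications by WGD flags", {
  gt <- read_newick("((a1:1,b1:1):1,(a2:1,b2:1):1);")
  rec <- lca_reconcile(gt, sp3, c(a1 = "A", b1 = "B", a2 = "A", b2 = "B"))
  recs <- select_high_confidence_nodes(rec)
  with_wgd <- classify_duplication_origin(recs, wgd_branches = 5L, sp3)
  expect_equal(with_wgd$origin[with_wgd$class == "duplication"], "WGD")
  without <- classify_duplication_origin(recs, wgd_branches = integer(0), sp3)
  expect_equal(without$origin[without$class == "duplication"], "single-gene")
  expect_true(all(without$origin[without$class == "speciation"] == "n/a"))
  is_dup <- with_wgd$class == "duplication"
  expect_true(all(with_wgd$origin[is_dup] %in% c("WGD", "single-gene")))

  # duplication mapped to the species root -> single-gene with warning
  gtr <- read_newick("((a1:1,c1:1):1,(a2:1,c2:1):1);")
  recr <- lca_reconcile(gtr, sp3, c(a1 = "A", c1 = "C", a2 = "A", c2 = "C"))
  tdr <- tidy(recr)
  rootdup <- tibble::tibble(
    orthogroup = "OG", gene_node = 5L, gene_label = "r",
    class = "duplication", species_node = 4L, species_label = "R",
    child_change = FALSE
  )
  expect_warning(out <- classify_duplication_origin(rootdup, 5L, sp3), "root")
  expect_equal(out$origin, "single-gene")
})

test_that("fossil duplicate branches span a WGD branch without a duplication there", {
  # single-copy lineage crossing the WGD-flagged AB branch (node 5)
  gt <- read_newick("((a1:1,b1:1)x:1,c1:1);")
  rec <- lca_reconcile(gt, sp3, c(a1 = "A", b1 = "B", c1 = "C"))
  # remove B to force the span: use (a1, c1) instead
  gt2 <- read_newick("(a1:1,c1:1);")
  rec2 <- lca_reconcile(gt2, sp3, c(a1 = "A", c1 = "C"))
  fossil <- find_fossil_duplicate_branches(rec2, wgd_branches = 5L)
  expect_equal(nrow(fossil), 1L)
  expect_equal(fossil$wgd_branch, 5L)

  # a retained duplication mapped to the WGD branch is not a fossil
  gt3 <- read_newick("(((a1:1,b1:1):1,(a2:1,b2:1):1)d:1,c1:1);")
  rec3 <- lca_reconcile(gt3, sp3, c(a1 = "A", b1 = "B", a2 = "A",
                                    b2 = "B", c1 = "C"))
  fossil3 <- find_fossil_duplicate_branches(rec3, wgd_branches = 5L)
  expect_equal(nrow(fossil3), 0L)

  # no WGD flags, no fossils
  expect_equal(nrow(find_fossil_duplicate_branches(rec, integer(0))), 0L)
})

test_that("origin and fossil groups summarise coherently", {
  recs <- tibble::tibble(
    orthogroup = "OG", gene_node = 1:6, gene_label = "g",
    class = rep(c("duplication", "speciation"), each = 3),
    species_node = 1L, species_label = "s",
    child_change = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    origin = c("WGD", "WGD", "single-gene", "n/a", "n/a", "n/a")
  )
  fossil <- tibble::tibble(orthogroup = "OG", parent = 1L, child = 2L,
                           wgd_branch = 5L, has_change = c(TRUE, FALSE))
  s <- dup_origin_summary(recs, fossil)
  expect_setequal(s$group, c("WGD", "single-gene", "speciation", "fossil"))
  expect_equal(s$frequency[s$group == "WGD"], 0.5)
  expect_equal(s$frequency[s$group == "fossil"], 0.5)
  expect_equal(sum(s$n[s$group %in% c("WGD", "single-gene")]), 3L)
})
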
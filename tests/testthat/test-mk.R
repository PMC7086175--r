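test_that("transition matrices match the matrix-exponential oracle", {
  expect_equal(transition_matrix(0.3, 0.8, 0), diag(2), ignore_attr = TRUE)
  P <- transition_matrix(1, 1, 1e6)
  expect_equal(as.numeric(P), rep(0.5, 4), tolerance = 1e-12)
  expect_equal(unname(transition_matrix(0.2, 0.6, 1)),
               expm_transition(0.2, 0.6, 1), tolerance = 1e-10)
  set.seed(3)
  for (i in 1:25) {
    a <- runif(1, 0.01, 5); b <- runif(1, 0.01, 5); t <- runif(1, 0, 4)
    P <- transition_matrix(a, b, t)
    expect_equal(unname(P), expm_transition(a, b, t), tolerance = 1e-10)
    expect_equal(rowSums(P), c(`0` = 1, `1` = 1))
  }
  expect_error(transition_matrix(1, 1, -0.1), ">= 0")
})

test_that("pruning log-likelihood matches exhaustive enumeration", {
  tr <- read_newick("(A:1,B:1);")
  st <- c(A = 0, B = 1)
  expect_equal(mk_loglik(tr, st, 1, 1), enum_loglik(tr, st, 1, 1),
               tolerance = 1e-8)
  tr4 <- read_newick("((A:0.4,B:1.2):0.7,(C:0.2,D:2):0.3);")
  st4 <- c(A = 1, B = 1, C = 0, D = 1)
  expect_equal(mk_loglik(tr4, st4, 0.3, 0.9), enum_loglik(tr4, st4, 0.3, 0.9),
               tolerance = 1e-8)
})

test_that("a no-event limit gives the root prior mass", {
  tr <- read_newick("((A:1,B:1):1,C:1);")
  st <- c(A = 0, B = 0, C = 0)
  expect_equal(mk_loglik(tr, st, 1e-8, 1e-8), log(0.5), tolerance = 1e-5)
})

test_that("likelihood is symmetric under state flip with rate swap", {
  set.seed(5)
  for (i in 1:10) {
    tr <- random_tree(6)
    st <- random_states(tr)
    flipped <- setNames(1L - st, names(st))
    expect_equal(mk_loglik(tr, st, 0.3, 0.7),
                 mk_loglik(tr, flipped, 0.7, 0.3), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to leaf ordering", {
  st <- c(A = 1, B = 0, C = 1)
  t1 <- read_newick("(A:1,(B:0.5,C:0.5):1);")
  t2 <- read_newick("((C:0.5,B:0.5):1,A:1);")
  expect_equal(mk_loglik(t1, st, 0.4, 0.2), mk_loglik(t2, st, 0.4, 0.2),
               tolerance = 1e-12)
})

test_that("missing branch lengths or tip states are errors", {
  tr <- read_newick("((A,B),C);")
  expect_error(mk_loglik(tr, c(A = 1, B = 0, C = 0), 1, 1), "branch length")
  tr2 <- read_newick("((A:1,B:1):1,C:1);")
  expect_error(mk_loglik(tr2, c(A = 1, B = 0), 1, 1), "C")
})

test_that("marginal probabilities match exhaustive enumeration", {
  set.seed(6)
  tr4 <- read_newick("((A:0.4,B:1.2):0.7,(C:0.2,D:2):0.3);")
  st4 <- c(A = 1, B = 1, C = 0, D = 1)
  got <- marginal_probabilities(tr4, st4, 0.25, 0.8)
  want <- enum_marginals(tr4, st4, 0.25, 0.8)
  expect_equal(got$p_targeted, unname(want), tolerance = 1e-8)
  # leaves reproduce their observed states exactly
  expect_equal(got$p_targeted[got$is_tip], unname(st4[got$label[got$is_tip]]))
})

test_that("a symmetric cherry with opposite states has root probability 1/2", {
  tr <- read_newick("(A:1,B:1);")
  m <- marginal_probabilities(tr, c(A = 0, B = 1), 0.7, 0.7)
  expect_equal(m$p_targeted[!m$is_tip], 0.5, tolerance = 1e-12)
})

test_that("marginals are invariant to branch-length/rate rescaling", {
  set.seed(7)
  tr <- random_tree(8)
  st <- random_states(tr)
  m1 <- marginal_probabilities(tr, st, 0.2, 0.5)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 10
  m2 <- marginal_probabilities(tr2, st, 0.02, 0.05)
  expect_equal(m1$p_targeted, m2$p_targeted, tolerance = 1e-9)
})

test_that("fitting recovers a boundary result on monomorphic data", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  fit <- fit_mk(tr, c(A = 1, B = 1, C = 1, D = 1))
  expect_true(fit$boundary)
  expect_lt(fit$beta, 1e-6)  # the loss rate collapses to its lower bound
})

test_that("ARD log-likelihood dominates ER on the same data", {
  set.seed(8)
  for (i in 1:5) {
    tr <- random_tree(10)
    st <- random_states(tr, 0.3)
    if (length(unique(st)) < 2L) next
    f_er <- fit_mk(tr, st, model = "ER")
    f_ard <- fit_mk(tr, st, model = "ARD")
    expect_gte(f_ard$logL, f_er$logL - 1e-6)
  }
})

test_that("fits are deterministic", {
  set.seed(9)
  tr <- random_tree(12)
  st <- random_states(tr)
  f1 <- fit_mk(tr, st)
  f2 <- fit_mk(tr, st)
  expect_identical(glance(f1), glance(f2))
})

test_that("the ER/ARD likelihood-ratio test follows the chi-squared law", {
  mk_stub <- function(model, logL) {
    structure(list(model = model, logL = logL), class = "mk_fit")
  }
  eq <- lrt_er_vs_ard(mk_stub("ER", -10), mk_stub("ARD", -10))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  crit <- lrt_er_vs_ard(mk_stub("ER", -10), mk_stub("ARD", -10 + 3.841459 / 2))
  expect_equal(crit$p_value, 0.05, tolerance = 1e-4)
  expect_error(lrt_er_vs_ard(mk_stub("ER", -9), mk_stub("ARD", -10)),
               "optimizer failure")
  expect_error(lrt_er_vs_ard(mk_stub("ARD", -9), mk_stub("ARD", -10)),
               "ER fit")
})

test_that("the stationary root prior option changes the likelihood as expected", {
  tr <- read_newick("(A:1,B:1);")
  st <- c(A = 1, B = 1)
  ll_u <- mk_loglik(tr, st, 0.6, 0.2, root_prior = "uniform")
  ll_s <- mk_loglik(tr, st, 0.6, 0.2, root_prior = "stationary")
  # stationary prior puts 0.75 mass on state 1 here: likelihood must rise
  expect_gt(ll_s, ll_u)
  ll_fix <- mk_loglik(tr, st, 0.6, 0.2, root_prior = c(0.25, 0.75))
  expect_equal(ll_s, ll_fix, tolerance = 1e-12)
})
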
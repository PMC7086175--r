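# Independent oracles: numerical matrix exponential for transition
# probabilities, and exhaustive enumeration over internal-state assignments
# for likelihoods and marginals. These never share code with the package's
# pruning implementation.

expm_transition <- function(alpha, beta, t) {
  Q <- matrix(c(-alpha, alpha, beta, -beta), 2, 2, byrow = TRUE)
  as.matrix(Matrix::expm(Q * t))
}

# Per-edge transition matrices via the expm oracle (lengths floored like the
# implementation so the comparison is apples to apples).
edge_p_list <- function(tree, alpha, beta) {
  lapply(seq_len(nrow(tree$edge)), function(i) {
    expm_transition(alpha, beta, max(tree$edge.length[i], 1e-9))
  })
}

enum_likelihood_terms <- function(tree, tip_states, alpha, beta,
                                  prior = c(0.5, 0.5)) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  internal <- (nt + 1L):nn
  Ps <- edge_p_list(tree, alpha, beta)
  s_tips <- as.integer(tip_states[tree$tip.label])
  terms <- numeric(2^length(internal))
  state1_mass <- numeric(nn)  # per-node likelihood mass with that node in state 1
  for (code in seq_len(2^length(internal)) - 1L) {
    st <- integer(nn)
    st[seq_len(nt)] <- s_tips
    st[internal] <- as.integer(intToBits(code))[seq_along(internal)]
    lik <- prior[st[root] + 1L]
    for (i in seq_len(nrow(tree$edge))) {
      lik <- lik * Ps[[i]][st[tree$edge[i, 1L]] + 1L, st[tree$edge[i, 2L]] + 1L]
    }
    terms[code + 1L] <- lik
    state1_mass[st == 1L] <- state1_mass[st == 1L] + lik
  }
  list(total = sum(terms), state1_mass = state1_mass)
}

enum_loglik <- function(tree, tip_states, alpha, beta, prior = c(0.5, 0.5)) {
  log(enum_likelihood_terms(tree, tip_states, alpha, beta, prior)$total)
}

enum_marginals <- function(tree, tip_states, alpha, beta, prior = c(0.5, 0.5)) {
  e <- enum_likelihood_terms(tree, tip_states, alpha, beta, prior)
  e$state1_mass / e$total
}

# Random rooted binary tree with uniform branch lengths.
random_tree <- function(n, min_len = 0.05, max_len = 2) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

random_states <- function(tree, p = 0.5) {
  stats::setNames(stats::rbinom(length(tree$tip.label), 1, p), tree$tip.label)
}

# A caterpillar newick over the given labels (binary, unit branch lengths).
caterpillar <- function(labels) {
  if (length(labels) == 1L) return(paste0(labels, ":1"))
  paste0("(", labels[1L], ":1,", caterpillar(labels[-1L]), ":1)")
}

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
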
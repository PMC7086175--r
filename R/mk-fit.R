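# Maximum-likelihood ancestral character estimation for a binary targeting
# trait under two-state continuous-time Markov models:
#   ER  — equal rates (alpha == beta, 1 free parameter)
#   ARD — all rates different (alpha = gain 0->1, beta = loss 1->0)
# Likelihoods via Felsenstein pruning (C++ kernel); marginal (empirical
# Bayes) node probabilities via combined downward/upward conditional
# likelihoods at the fitted rates.

RATE_LOWER <- 1e-8
RATE_UPPER <- 1e3
MIN_BLEN <- 1e-9

#' Transition probability matrix of the two-state Markov model
#'
#' Closed-form 2x2 row-stochastic transition matrix for a binary trait
#' evolving for duration `t` (branch-length units) with gain rate `alpha`
#' (0 to 1) and loss rate `beta` (1 to 0).
#'
#' @param alpha Gain rate (per branch-length unit), >= 0.
#' @param beta Loss rate, >= 0.
#' @param t Branch length, >= 0.
#' @return A 2x2 matrix with rows/columns named "0" and "1".
#' @examples
#' transition_matrix(0.2, 0.6, 1)
#' @export
transition_matrix <- function(alpha, beta, t) {
  stopifnot(alpha >= 0, beta >= 0)
  if (t < 0) abort("branch length `t` must be >= 0")
  sigma <- alpha + beta
  if (sigma <= 0 || t == 0) {
    P <- diag(2)
  } else {
    e <- exp(-sigma * t)
    pi1 <- alpha / sigma
    pi0 <- beta / sigma
    p01 <- pi1 * (1 - e)
    p10 <- pi0 * (1 - e)
    P <- matrix(c(1 - p01, p01, p10, 1 - p10), 2, 2, byrow = TRUE)
  }
  dimnames(P) <- list(c("0", "1"), c("0", "1"))
  P
}

# Coerce tip states (named vector or tibble gene_id/state) into an integer
# vector aligned with tree$tip.label.
as_tip_states <- function(tip_states, tree) {
  if (is.data.frame(tip_states)) {
    stopifnot(all(c("gene_id", "state") %in% names(tip_states)))
    tip_states <- setNames(tip_states$state, tip_states$gene_id)
  }
  if (is.null(names(tip_states))) {
    abort("`tip_states` must be named by gene id")
  }
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing)) {
    abort(paste0("missing tip state(s) for: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  s <- as.integer(tip_states[tree$tip.label])
  if (anyNA(s) || !all(s %in% c(0L, 1L))) {
    abort("tip states must be 0 or 1 for every leaf")
  }
  setNames(s, tree$tip.label)
}

root_prior_vec <- function(root_prior, alpha, beta) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == 2L, all(root_prior >= 0), sum(root_prior) > 0)
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("uniform", "stationary")),
         uniform = c(0.5, 0.5),
         stationary = {
           s <- alpha + beta
           if (s <= 0) c(0.5, 0.5) else c(beta / s, alpha / s)
         })
}

#' Log-likelihood of a binary trait on a tree under a two-state Markov model
#'
#' Computed by the pruning algorithm with per-node rescaling for underflow
#' protection; the root state is integrated against `root_prior`
#' (uniform by default). Zero-length branches are floored at 1e-9.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param tip_states Named 0/1 vector (or tibble `gene_id`, `state`) covering
#'   every leaf.
#' @param alpha,beta Gain and loss rates (per branch-length unit).
#' @param root_prior `"uniform"` (default), `"stationary"`, or a numeric
#'   length-2 prior over states (0, 1).
#' @return The log-likelihood (natural log).
#' @export
mk_loglik <- function(tree, tip_states, alpha, beta, root_prior = "uniform") {
  assert_branch_lengths(tree, "likelihood computation")
  s <- as_tip_states(tip_states, tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  .mk_loglik_cpp(tr$edge, tr$edge.length, n_tips(tree), n_nodes_total(tree),
                 s, alpha, beta, root_prior_vec(root_prior, alpha, beta),
                 MIN_BLEN)
}

#' Marginal ancestral state probabilities under fixed rates
#'
#' Empirical-Bayes marginal probability that each node is in the targeted
#' state (state 1), combining downward conditional likelihoods (data below a
#' node) with upward partial likelihoods (data elsewhere plus the root
#' prior) at the supplied rates. Leaf marginals equal the observed states.
#'
#' @inheritParams mk_loglik
#' @return A tibble with `node`, `label`, `is_tip`, `p_targeted`.
#' @export
marginal_probabilities <- function(tree, tip_states, alpha, beta,
                                   root_prior = "uniform") {
  assert_branch_lengths(tree, "ancestral state estimation")
  s <- as_tip_states(tip_states, tree)
  nn <- n_nodes_total(tree)
  nt <- n_tips(tree)
  prior <- root_prior_vec(root_prior, alpha, beta)
  tr <- ape::reorder.phylo(tree, "postorder")
  D <- .mk_down_cpp(tr$edge, tr$edge.length, nt, nn, s, alpha, beta, MIN_BLEN)

  # Upward pass (preorder). U[v, ] is proportional to the likelihood of all
  # data outside the clade of v, as a function of the state at v.
  elen <- numeric(nn)
  elen[tr$edge[, 2L]] <- pmax(tr$edge.length, MIN_BLEN)
  children <- tree_children(tree)
  par <- tree_parents(tree)
  U <- matrix(0, nn, 2L)
  U[root_node(tree), ] <- prior
  for (v in preorder_nodes(tree)) {
    kids <- children[[v]]
    if (!length(kids)) next
    # message to child c: sum over parent state of U[v] times sibling
    # contributions, propagated through c's branch.
    sib_contrib <- vapply(kids, function(k) {
      P <- transition_matrix(alpha, beta, elen[k])
      as.numeric(P %*% D[k, ])
    }, numeric(2))  # 2 x nkids; column k = contribution of child k per parent state
    for (j in seq_along(kids)) {
      k <- kids[j]
      above <- U[v, ]
      for (jj in seq_along(kids)) {
        if (jj != j) above <- above * sib_contrib[, jj]
      }
      P <- transition_matrix(alpha, beta, elen[k])
      u <- as.numeric(above %*% P)
      m <- max(u)
      U[k, ] <- if (m > 0) u / m else c(0.5, 0.5)
    }
  }
  joint <- U * D
  tot <- rowSums(joint)
  p1 <- ifelse(tot > 0, joint[, 2L] / tot, NA_real_)
  tibble::tibble(
    node = seq_len(nn),
    label = node_labels(tree, seq_len(nn)),
    is_tip = seq_len(nn) <= nt,
    p_targeted = p1
  )
}

mk_negloglik_factory <- function(tree, s, root_prior, constraint) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge; elen <- tr$edge.length
  nt <- n_tips(tree); nn <- n_nodes_total(tree)
  function(logrates) {
    r <- exp(logrates)
    a <- r[1L]
    b <- if (constraint == "ER") r[1L] else r[2L]
    ll <- .mk_loglik_cpp(edge, elen, nt, nn, s, a, b,
                         root_prior_vec(root_prior, a, b), MIN_BLEN)
    if (!is.finite(ll)) 1e10 else -ll
  }
}

#' Fit a two-state Markov model of trait evolution by maximum likelihood
#'
#' Fits the gain rate `alpha` and loss rate `beta` of a binary targeting
#' trait on a rooted gene tree, under the equal-rates (`"ER"`) or
#' all-rates-different (`"ARD"`) constraint, by bounded quasi-Newton
#' optimisation from multiple fixed starting points (the ER estimate, then
#' 0.1/0.1 and 1/1). Rates are bounded in \[1e-8, 1e3\]. Monomorphic tip data
#' yield a boundary fit (flagged, not an error). The fit carries the marginal
#' ancestral state probabilities at the optimum.
#'
#' @inheritParams mk_loglik
#' @param model `"ARD"` (default) or `"ER"`.
#' @return An object of class `mk_fit`: list with `alpha`, `beta`, `logL`,
#'   `model`, `converged`, `boundary`, `root_prior`, `marginals` (tibble from
#'   [marginal_probabilities()]), `tree` and `tip_states`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' fit <- fit_mk(tr, c(A = 1, B = 1, C = 0, D = 0), model = "ARD")
#' glance(fit)
#' @export
fit_mk <- function(tree, tip_states, model = c("ARD", "ER"),
                   root_prior = "uniform") {
  model <- match.arg(model)
  assert_branch_lengths(tree, "model fitting")
  s <- as_tip_states(tip_states, tree)

  lb <- log(RATE_LOWER); ub <- log(RATE_UPPER)
  opt1 <- function(fn, par) {
    tryCatch(
      optim(par, fn, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) list(par = par, value = fn(par), convergence = 99L)
    )
  }

  # ER fit (always computed: it seeds the ARD starts)
  fn_er <- mk_negloglik_factory(tree, s, root_prior, "ER")
  er_starts <- list(log(0.1), log(1))
  er_best <- NULL
  for (p0 in er_starts) {
    o <- opt1(fn_er, p0)
    if (is.null(er_best) || o$value < er_best$value) er_best <- o
  }

  if (model == "ER") {
    best <- er_best
    a <- exp(best$par[1L]); b <- a
  } else {
    fn <- mk_negloglik_factory(tree, s, root_prior, "ARD")
    starts <- list(rep(er_best$par[1L], 2L), log(c(0.1, 0.1)), log(c(1, 1)))
    best <- NULL
    for (p0 in starts) {
      o <- opt1(fn, p0)
      if (is.null(best) || o$value < best$value) best <- o
    }
    a <- exp(best$par[1L]); b <- exp(best$par[2L])
  }

  boundary <- any(abs(best$par - lb) < 1e-6) || any(abs(best$par - ub) < 1e-6)
  marg <- marginal_probabilities(tree, s, a, b, root_prior)
  structure(
    list(alpha = a, beta = b, logL = -best$value, model = model,
         converged = identical(best$convergence, 0L), boundary = boundary,
         root_prior = root_prior, marginals = marg,
         tree = tree, tip_states = s),
    class = "mk_fit"
  )
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("<mk_fit> %s model: alpha (gain) = %.4g, beta (loss) = %.4g, logL = %.4f%s\n",
              x$model, x$alpha, x$beta, x$logL,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' @method tidy mk_fit
#' @export
tidy.mk_fit <- function(x, ...) x$marginals

#' @method glance mk_fit
#' @export
glance.mk_fit <- function(x, ...) {
  k <- if (x$model == "ER") 1L else 2L
  tibble::tibble(
    model = x$model, alpha = x$alpha, beta = x$beta, logL = x$logL,
    AIC = 2 * k - 2 * x$logL, converged = x$converged, boundary = x$boundary,
    n_tips = n_tips(x$tree)
  )
}

#' Likelihood-ratio test of ARD against ER
#'
#' Chi-squared test with one degree of freedom on twice the log-likelihood
#' difference between the all-rates-different and equal-rates fits of the
#' same data. The statistic is clamped at zero; an ARD log-likelihood
#' below the ER one beyond tolerance indicates optimiser failure and is an
#' error.
#'
#' @param fit_er An `mk_fit` with `model == "ER"`.
#' @param fit_ard An `mk_fit` with `model == "ARD"`.
#' @param tol Tolerance for the nesting check (default 1e-6).
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
lrt_er_vs_ard <- function(fit_er, fit_ard, tol = 1e-6) {
  stopifnot(inherits(fit_er, "mk_fit"), inherits(fit_ard, "mk_fit"))
  if (fit_er$model != "ER" || fit_ard$model != "ARD") {
    abort("`fit_er` must be an ER fit and `fit_ard` an ARD fit")
  }
  stat <- 2 * (fit_ard$logL - fit_er$logL)
  if (stat < -tol) {
    abort(sprintf("logL(ARD) < logL(ER) by %.3g: optimizer failure", -stat))
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1L, lower.tail = FALSE))
}
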
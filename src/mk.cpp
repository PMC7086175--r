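#include <Rcpp.h>
using namespace Rcpp;

// Two-state continuous-time Markov chain transition probabilities in closed
// form: with sigma = alpha + beta, pi1 = alpha/sigma,
//   P(0->1; t) = pi1 * (1 - exp(-sigma t)),  P(1->0; t) = pi0 * (1 - exp(-sigma t)).
static inline void p_matrix(double alpha, double beta, double t,
                            double &p00, double &p01, double &p10, double &p11) {
  double sigma = alpha + beta;
  if (sigma <= 0.0 || t <= 0.0) {
    p00 = 1.0; p01 = 0.0; p10 = 0.0; p11 = 1.0;
    return;
  }
  double e = std::exp(-sigma * t);
  double pi1 = alpha / sigma;
  double pi0 = beta / sigma;
  p01 = pi1 * (1.0 - e);
  p00 = 1.0 - p01;
  p10 = pi0 * (1.0 - e);
  p11 = 1.0 - p10;
}

// Felsenstein pruning log-likelihood for a binary trait on a rooted tree.
// edge: postorder-ordered edge matrix (1-based node ids, children before
// parents); elen: matching branch lengths; tip_states: 0/1 per tip
// (tips are nodes 1..n_tip, root is n_tip + 1); root_prior: length-2.
// Branch lengths below min_blen are floored at min_blen.
// [[Rcpp::export(name = ".mk_loglik_cpp")]]
double mk_loglik_cpp(IntegerMatrix edge, NumericVector elen, int n_tip,
                     int n_node_total, IntegerVector tip_states,
                     double alpha, double beta, NumericVector root_prior,
                     double min_blen = 1e-9) {
  std::vector<double> L0(n_node_total, 1.0), L1(n_node_total, 1.0);
  for (int i = 0; i < n_tip; ++i) {
    if (tip_states[i] == 0) { L0[i] = 1.0; L1[i] = 0.0; }
    else                    { L0[i] = 0.0; L1[i] = 1.0; }
  }
  double logscale = 0.0;
  int ne = edge.nrow();
  for (int e = 0; e < ne; ++e) {
    int p = edge(e, 0) - 1;
    int c = edge(e, 1) - 1;
    double t = elen[e] < min_blen ? min_blen : elen[e];
    double p00, p01, p10, p11;
    p_matrix(alpha, beta, t, p00, p01, p10, p11);
    double c0 = p00 * L0[c] + p01 * L1[c];
    double c1 = p10 * L0[c] + p11 * L1[c];
    L0[p] *= c0;
    L1[p] *= c1;
    double m = L0[p] > L1[p] ? L0[p] : L1[p];
    if (m <= 0.0) return R_NegInf;
    L0[p] /= m;
    L1[p] /= m;
    logscale += std::log(m);
  }
  int root = n_tip; // 0-based index of node n_tip + 1
  double lik = root_prior[0] * L0[root] + root_prior[1] * L1[root];
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}

// Downward (conditional) partial likelihoods per node, rescaled per node.
// Returns an (n_node_total x 2) matrix proportional to the conditional
// likelihood of the data below each node given its state.
// [[Rcpp::export(name = ".mk_down_cpp")]]
NumericMatrix mk_down_cpp(IntegerMatrix edge, NumericVector elen, int n_tip,
                          int n_node_total, IntegerVector tip_states,
                          double alpha, double beta, double min_blen = 1e-9) {
  NumericMatrix D(n_node_total, 2);
  std::fill(D.begin(), D.end(), 1.0);
  for (int i = 0; i < n_tip; ++i) {
    D(i, 0) = tip_states[i] == 0 ? 1.0 : 0.0;
    D(i, 1) = tip_states[i] == 1 ? 1.0 : 0.0;
  }
  int ne = edge.nrow();
  for (int e = 0; e < ne; ++e) {
    int p = edge(e, 0) - 1;
    int c = edge(e, 1) - 1;
    double t = elen[e] < min_blen ? min_blen : elen[e];
    double p00, p01, p10, p11;
    p_matrix(alpha, beta, t, p00, p01, p10, p11);
    double c0 = p00 * D(c, 0) + p01 * D(c, 1);
    double c1 = p10 * D(c, 0) + p11 * D(c, 1);
    D(p, 0) *= c0;
    D(p, 1) *= c1;
    double m = D(p, 0) > D(p, 1) ? D(p, 0) : D(p, 1);
    if (m > 0.0) { D(p, 0) /= m; D(p, 1) /= m; }
  }
  return D;
}
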
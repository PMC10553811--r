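// Exponentiated-gradient inner loop for the non-parametric reconstruction.
// The R front end prepares the aggregated pair statistics and the sparse
// penalty operator; this loop only iterates the multiplicative update.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// data term and its gradient w.r.t. the value matrix P (M x K)
static double data_loss(const mat& P, const uvec& ia, const uvec& ib,
                        const vec& k, const vec& n_same, const vec& n_obs,
                        bool use_bce, double delta) {
  const uword T = ia.n_elem;
  double loss = 0.0;
  for (uword t = 0; t < T; ++t) {
    double pij = dot(P.row(ia[t]), P.row(ib[t]));
    if (use_bce) {
      double pc = std::min(std::max(pij, delta), 1.0 - delta);
      loss += -n_same[t] * std::log(pc)
              - (n_obs[t] - n_same[t]) * std::log1p(-pc);
    } else {
      double r = k[t] - pij;
      loss += r * r;
    }
  }
  return loss;
}

static void data_grad(const mat& P, const uvec& ia, const uvec& ib,
                      const vec& k, const vec& n_same, const vec& n_obs,
                      bool use_bce, double delta, mat& G) {
  G.zeros();
  const uword T = ia.n_elem;
  for (uword t = 0; t < T; ++t) {
    const uword i = ia[t], j = ib[t];
    double pij = dot(P.row(i), P.row(j));
    double coef;
    if (use_bce) {
      double pc = std::min(std::max(pij, delta), 1.0 - delta);
      coef = -n_same[t] / pc + (n_obs[t] - n_same[t]) / (1.0 - pc);
    } else {
      coef = -2.0 * (k[t] - pij);
    }
    G.row(i) += coef * P.row(j);
    G.row(j) += coef * P.row(i);
  }
}

// [[Rcpp::export(name = ".eg_descent_cpp")]]
Rcpp::List eg_descent_cpp(const arma::mat& P0,
                          const arma::uvec& ia, const arma::uvec& ib,
                          const arma::vec& k, const arma::vec& n_same,
                          const arma::vec& n_obs,
                          bool use_bce, double lambda,
                          const arma::sp_mat& Lop,
                          double lr, double eps, int max_iter) {
  mat P = P0;
  const double delta = 1e-12;
  const bool use_reg = lambda > 0.0;
  mat G(P.n_rows, P.n_cols);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);

  auto total_loss = [&](const mat& P) {
    double v = data_loss(P, ia, ib, k, n_same, n_obs, use_bce, delta);
    if (use_reg) v += lambda * accu(P % (Lop * P));
    return v;
  };

  double prev = total_loss(P);
  trace.push_back(prev);
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    data_grad(P, ia, ib, k, n_same, n_obs, use_bce, delta, G);
    if (use_reg) G += 2.0 * lambda * (Lop * P);
    if (!G.is_finite())
      Rcpp::stop("non-finite gradient encountered during optimization");
    // centring each row at its minimum leaves the normalized update
    // unchanged (per-row constants cancel) and makes every multiplier
    // <= 1, so exp() cannot overflow even for the near-singular BCE
    // gradients that arise when a pair probability hits the clip bound
    G.each_col() -= min(G, 1);
    P %= exp(-lr * G);
    // strict positivity: keep iterates in the simplex interior so the
    // multiplicative update can always recover a channel
    P = clamp(P, 1e-15, datum::inf);
    P.each_col() /= sum(P, 1);
    double cur = total_loss(P);
    trace.push_back(cur);
    if (std::abs(cur - prev) <= eps) { converged = true; break; }
    prev = cur;
  }
  return Rcpp::List::create(
    Rcpp::Named("P") = P,
    Rcpp::Named("loss_trace") = trace,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}
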
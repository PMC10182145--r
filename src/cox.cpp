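// Newton-Raphson maximisation of the Cox partial likelihood with Efron or
// Breslow handling of tied event times. Subjects are processed in order of
// decreasing follow-up time so the risk-set sums accumulate in one pass.
// The inner pass uses raw loops over a transposed (p x n) copy of the design
// so each subject's covariates are contiguous; only the lower triangle of
// the information matrix is accumulated.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct LikResult {
  double loglik;
  arma::vec grad;
  arma::mat info;
  bool finite;
};

LikResult cox_loglik(const arma::mat& Xt, const arma::vec& time,
                     const arma::ivec& status, const arma::uvec& ord,
                     const arma::vec& beta, bool efron) {
  const arma::uword n = Xt.n_cols, p = Xt.n_rows;
  LikResult out{0.0, arma::zeros<arma::vec>(p), arma::zeros<arma::mat>(p, p), true};

  double s0 = 0.0;
  std::vector<double> s1(p, 0.0), s2(p * p, 0.0);
  std::vector<double> d1(p), d2(p * p), xsum(p);
  double* g = out.grad.memptr();
  double* I = out.info.memptr();

  arma::uword i = 0;
  while (i < n) {
    double t = time[ord[i]];
    double d0 = 0.0, sum_eta_d = 0.0;
    int d = 0;
    std::fill(d1.begin(), d1.end(), 0.0);
    std::fill(d2.begin(), d2.end(), 0.0);
    std::fill(xsum.begin(), xsum.end(), 0.0);

    while (i < n && time[ord[i]] == t) {
      arma::uword k = ord[i];
      const double* x = Xt.colptr(k);
      double eta = 0.0;
      for (arma::uword a = 0; a < p; ++a) eta += beta[a] * x[a];
      if (eta > 500.0) { out.finite = false; return out; }
      double w = std::exp(eta);
      s0 += w;
      for (arma::uword a = 0; a < p; ++a) {
        double wxa = w * x[a];
        s1[a] += wxa;
        double* col = &s2[a * p];
        for (arma::uword b = a; b < p; ++b) col[b] += wxa * x[b];
      }
      if (status[k] == 1) {
        ++d;
        d0 += w;
        sum_eta_d += eta;
        for (arma::uword a = 0; a < p; ++a) {
          double wxa = w * x[a];
          d1[a] += wxa;
          xsum[a] += x[a];
          double* col = &d2[a * p];
          for (arma::uword b = a; b < p; ++b) col[b] += wxa * x[b];
        }
      }
      ++i;
    }

    if (d > 0) {
      out.loglik += sum_eta_d;
      for (arma::uword a = 0; a < p; ++a) g[a] += xsum[a];
      std::vector<double> m1(p);
      for (int j = 0; j < d; ++j) {
        double r = efron ? static_cast<double>(j) / d : 0.0;
        double denom = s0 - r * d0;
        if (!(denom > 0.0) || !std::isfinite(denom)) {
          out.finite = false;
          return out;
        }
        out.loglik -= std::log(denom);
        for (arma::uword a = 0; a < p; ++a) {
          m1[a] = (s1[a] - r * d1[a]) / denom;
          g[a] -= m1[a];
        }
        for (arma::uword a = 0; a < p; ++a) {
          double* Icol = &I[a * p];
          const double* s2col = &s2[a * p];
          const double* d2col = &d2[a * p];
          for (arma::uword b = a; b < p; ++b)
            Icol[b] += (s2col[b] - r * d2col[b]) / denom - m1[a] * m1[b];
        }
      }
    }
  }
  for (arma::uword a = 0; a < p; ++a)
    for (arma::uword b = a + 1; b < p; ++b)
      out.info(a, b) = out.info(b, a);
  if (!std::isfinite(out.loglik)) out.finite = false;
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cox_fit_cpp(const arma::mat& X, const arma::vec& time,
                 const arma::ivec& status, const bool efron,
                 const double eps, const int maxiter,
                 const arma::vec& init) {
  const arma::uword p = X.n_cols;
  arma::uvec ord = arma::stable_sort_index(time, "descend");
  arma::mat Xt = X.t();

  arma::vec beta = init;
  LikResult cur = cox_loglik(Xt, time, status, ord, beta, efron);
  if (!cur.finite)
    stop("partial likelihood not finite at the initial value");

  // score test of H0: beta = 0 (for a lone binary covariate without ties
  // this is the log-rank chi-square)
  double score_stat = NA_REAL;
  double loglik0;
  {
    LikResult at0 = arma::any(init != 0.0)
                        ? cox_loglik(Xt, time, status, ord,
                                     arma::zeros<arma::vec>(p), efron)
                        : cur;
    loglik0 = at0.loglik;
    arma::vec u;
    if (at0.finite &&
        arma::solve(u, at0.info, at0.grad, arma::solve_opts::no_approx))
      score_stat = arma::dot(at0.grad, u);
  }

  bool converged = false, singular = false;
  int iter = 0;
  for (; iter < maxiter; ++iter) {
    arma::vec step;
    if (!arma::solve(step, cur.info, cur.grad, arma::solve_opts::no_approx)) {
      singular = true;
      break;
    }
    arma::vec beta_new = beta + step;
    LikResult nxt = cox_loglik(Xt, time, status, ord, beta_new, efron);
    int halves = 0;
    while ((!nxt.finite || nxt.loglik < cur.loglik) && halves < 30) {
      step *= 0.5;
      beta_new = beta + step;
      nxt = cox_loglik(Xt, time, status, ord, beta_new, efron);
      ++halves;
    }
    if (!nxt.finite) { singular = true; break; }
    double delta = arma::abs(beta_new - beta).max();
    beta = beta_new;
    cur = nxt;
    if (delta < eps) { converged = true; ++iter; break; }
  }

  arma::mat var(p, p);
  arma::vec se(p);
  bool have_var = !singular && arma::inv_sympd(var, cur.info);
  if (!have_var) { var.fill(NA_REAL); se.fill(NA_REAL); }
  else se = arma::sqrt(var.diag());
  if (arma::abs(beta).max() > 20.0) converged = false;  // separation drift

  return List::create(
      _["beta"] = beta, _["se"] = se, _["var"] = var,
      _["loglik"] = NumericVector::create(loglik0, cur.loglik),
      _["score"] = score_stat, _["iter"] = iter,
      _["converged"] = converged && have_var);
}
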
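// Full-information maximum likelihood objective for RAM-parameterized
// structural equation models under arbitrary missingness patterns.
//
// Rows sharing a missingness pattern are collapsed to sufficient statistics
// (count n, observed-part mean xbar, centered scatter W); the objective sums
//   n*k*log(2*pi) + n*log|Sigma_p| + tr(Sigma_p^-1 W) + n*(xbar-mu_p)' Sigma_p^-1 (xbar-mu_p)
// over patterns (this is -2 * loglik). Saturated means are profiled out in
// closed form (a GLS step) unless the model carries an explicit mean
// structure. Infeasible parameter values (non-positive-definite pattern
// covariance) return a large penalty value instead of an error so that
// quasi-Newton line searches can back off.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double PENALTY = 1e10;
static const double LOG2PI = 1.8378770664093454836;

struct Pattern {
  arma::uvec oidx;   // 0-based indices into the group's observed vector
  double n;
  arma::vec xbar;
  arma::mat W;
};

struct Group {
  arma::mat A0, S0;
  arma::vec M0;
  arma::uvec obs;            // 0-based indices into full variable vector
  arma::imat free_cells;     // cols: theta index, mat id (0 A,1 S,2 M), i, j
  int mean_mode;             // 0 = profile saturated means, 1 = explicit
  std::vector<Pattern> patterns;
};

static std::vector<Group> build_groups(const List& ctx) {
  List gl = ctx["groups"];
  std::vector<Group> out(gl.size());
  for (int g = 0; g < gl.size(); ++g) {
    List G = gl[g];
    Group& gr = out[g];
    gr.A0 = as<arma::mat>(G["A0"]);
    gr.S0 = as<arma::mat>(G["S0"]);
    gr.M0 = as<arma::vec>(G["M0"]);
    gr.obs = as<arma::uvec>(G["obs"]);
    gr.free_cells = as<arma::imat>(G["free_cells"]);
    gr.mean_mode = as<int>(G["mean_mode"]);
    List pl = G["patterns"];
    gr.patterns.resize(pl.size());
    for (int p = 0; p < pl.size(); ++p) {
      List P = pl[p];
      gr.patterns[p].oidx = as<arma::uvec>(P["oidx"]);
      gr.patterns[p].n = as<double>(P["n"]);
      gr.patterns[p].xbar = as<arma::vec>(P["xbar"]);
      gr.patterns[p].W = as<arma::mat>(P["W"]);
    }
  }
  return out;
}

// -2 loglik for one group; returns penalty on infeasibility
static double group_neg2ll(const Group& gr, const arma::vec& theta) {
  arma::mat A = gr.A0, S = gr.S0;
  arma::vec M = gr.M0;
  const arma::imat& fc = gr.free_cells;
  for (arma::uword r = 0; r < fc.n_rows; ++r) {
    double v = theta(fc(r, 0));
    int i = fc(r, 2), j = fc(r, 3);
    switch (fc(r, 1)) {
      case 0: A(i, j) = v; break;
      case 1: S(i, j) = v; S(j, i) = v; break;
      default: M(i) = v;
    }
  }
  arma::uword nv = A.n_rows;
  arma::mat B;
  if (!arma::inv(B, arma::eye(nv, nv) - A)) return PENALTY;
  arma::mat BF = B.rows(gr.obs);
  arma::mat Sigma = BF * S * BF.t();
  Sigma = 0.5 * (Sigma + Sigma.t());

  const size_t np = gr.patterns.size();
  std::vector<arma::mat> SigInv(np);
  std::vector<double> logdet(np);
  arma::uword p = gr.obs.n_elem;

  arma::mat Amat(p, p, arma::fill::zeros);
  arma::vec bvec(p, arma::fill::zeros);

  for (size_t ip = 0; ip < np; ++ip) {
    const Pattern& pat = gr.patterns[ip];
    arma::mat Sp = Sigma.submat(pat.oidx, pat.oidx);
    arma::mat L;
    if (!arma::chol(L, Sp, "lower")) return PENALTY;
    logdet[ip] = 2.0 * arma::sum(arma::log(L.diag()));
    arma::mat Linv = arma::inv(arma::trimatl(L));
    SigInv[ip] = Linv.t() * Linv;
    if (gr.mean_mode == 0) {
      Amat.submat(pat.oidx, pat.oidx) += pat.n * SigInv[ip];
      bvec.elem(pat.oidx) += pat.n * (SigInv[ip] * pat.xbar);
    }
  }

  arma::vec mu(p);
  if (gr.mean_mode == 0) {
    if (!arma::solve(mu, Amat, bvec, arma::solve_opts::no_approx))
      return PENALTY;
  } else {
    arma::vec mu_all = B * M;
    mu = mu_all.elem(gr.obs);
  }

  double val = 0.0;
  for (size_t ip = 0; ip < np; ++ip) {
    const Pattern& pat = gr.patterns[ip];
    arma::vec d = pat.xbar - mu.elem(pat.oidx);
    val += pat.n * pat.oidx.n_elem * LOG2PI + pat.n * logdet[ip] +
      arma::trace(SigInv[ip] * pat.W) +
      pat.n * arma::as_scalar(d.t() * SigInv[ip] * d);
  }
  return val;
}

// -2 loglik and its analytic gradient for one group. The derivative of the
// pattern sum with respect to the implied covariance is
//   G_p = n*Sigma_p^-1 - Sigma_p^-1 W Sigma_p^-1 - n*Sigma_p^-1 r r' Sigma_p^-1
// (r = xbar - mu_p); chain rule through the RAM algebra gives the A/S/M
// cells. With profiled saturated means the inner mean problem is solved
// exactly, so by the envelope theorem the partial derivative holding mu
// fixed equals the total derivative.
static double group_neg2ll_grad(const Group& gr, const arma::vec& theta,
                                arma::vec& grad) {
  arma::mat A = gr.A0, S = gr.S0;
  arma::vec M = gr.M0;
  const arma::imat& fc = gr.free_cells;
  for (arma::uword r = 0; r < fc.n_rows; ++r) {
    double v = theta(fc(r, 0));
    int i = fc(r, 2), j = fc(r, 3);
    switch (fc(r, 1)) {
      case 0: A(i, j) = v; break;
      case 1: S(i, j) = v; S(j, i) = v; break;
      default: M(i) = v;
    }
  }
  arma::uword nv = A.n_rows;
  arma::mat B;
  if (!arma::inv(B, arma::eye(nv, nv) - A)) return PENALTY;
  arma::mat BF = B.rows(gr.obs);
  arma::mat Sigma = BF * S * BF.t();
  Sigma = 0.5 * (Sigma + Sigma.t());

  const size_t np = gr.patterns.size();
  std::vector<arma::mat> SigInv(np);
  std::vector<double> logdet(np);
  arma::uword p = gr.obs.n_elem;
  arma::mat Amat(p, p, arma::fill::zeros);
  arma::vec bvec(p, arma::fill::zeros);

  for (size_t ip = 0; ip < np; ++ip) {
    const Pattern& pat = gr.patterns[ip];
    arma::mat Sp = Sigma.submat(pat.oidx, pat.oidx);
    arma::mat L;
    if (!arma::chol(L, Sp, "lower")) return PENALTY;
    logdet[ip] = 2.0 * arma::sum(arma::log(L.diag()));
    arma::mat Linv = arma::inv(arma::trimatl(L));
    SigInv[ip] = Linv.t() * Linv;
    if (gr.mean_mode == 0) {
      Amat.submat(pat.oidx, pat.oidx) += pat.n * SigInv[ip];
      bvec.elem(pat.oidx) += pat.n * (SigInv[ip] * pat.xbar);
    }
  }
  arma::vec mu(p);
  if (gr.mean_mode == 0) {
    if (!arma::solve(mu, Amat, bvec, arma::solve_opts::no_approx))
      return PENALTY;
  } else {
    arma::vec mu_all = B * M;
    mu = mu_all.elem(gr.obs);
  }

  double val = 0.0;
  arma::mat Omega(p, p, arma::fill::zeros);  // d val / d Sigma (full obs)
  arma::vec vmu(p, arma::fill::zeros);       // d val / d mu
  for (size_t ip = 0; ip < np; ++ip) {
    const Pattern& pat = gr.patterns[ip];
    arma::vec d = pat.xbar - mu.elem(pat.oidx);
    const arma::mat& E = SigInv[ip];
    arma::vec Ed = E * d;
    val += pat.n * pat.oidx.n_elem * LOG2PI + pat.n * logdet[ip] +
      arma::trace(E * pat.W) + pat.n * arma::dot(d, Ed);
    arma::mat Gp = pat.n * E - E * pat.W * E - pat.n * (Ed * Ed.t());
    Omega.submat(pat.oidx, pat.oidx) += Gp;
    if (gr.mean_mode == 1) vmu.elem(pat.oidx) += -2.0 * pat.n * Ed;
  }

  // chain rule through Sigma = (B S B')[obs,obs]
  arma::mat OmegaFull(nv, nv, arma::fill::zeros);
  OmegaFull.submat(gr.obs, gr.obs) = Omega;
  arma::mat C = B * S * B.t();
  arma::mat GA = 2.0 * (C * OmegaFull * B).t();   // d val / d A_(i,j)
  arma::mat GS = B.t() * OmegaFull * B;           // d val / d S (symmetric use)
  arma::vec GM;
  if (gr.mean_mode == 1) {
    arma::vec vmu_full(nv, arma::fill::zeros);
    vmu_full.elem(gr.obs) = vmu;
    GM = B.t() * vmu_full;
  }
  for (arma::uword r = 0; r < fc.n_rows; ++r) {
    int par = fc(r, 0), i = fc(r, 2), j = fc(r, 3);
    switch (fc(r, 1)) {
      case 0: grad(par) += GA(i, j); break;
      case 1: grad(par) += (i == j) ? GS(i, i) : 2.0 * GS(i, j); break;
      default: if (gr.mean_mode == 1) grad(par) += GM(i);
    }
  }
  return val;
}

// Parse the context once and hold it behind an external pointer so that
// repeated objective/gradient evaluations skip R-to-C++ deserialization.
// [[Rcpp::export(name = ".fiml_make_ctx_cpp")]]
SEXP fiml_make_ctx_cpp(const List& ctx) {
  Rcpp::XPtr<std::vector<Group>> ptr(new std::vector<Group>(build_groups(ctx)),
                                     true);
  return ptr;
}

static double neg2ll_all(const std::vector<Group>& groups,
                         const arma::vec& theta) {
  double total = 0.0;
  for (const Group& gr : groups) {
    double v = group_neg2ll(gr, theta);
    if (v >= PENALTY) return PENALTY;
    total += v;
  }
  return total;
}

// [[Rcpp::export(name = ".fiml_neg2ll_ptr_cpp")]]
double fiml_neg2ll_ptr_cpp(const arma::vec& theta, SEXP ctx_ptr) {
  Rcpp::XPtr<std::vector<Group>> ptr(ctx_ptr);
  return neg2ll_all(*ptr, theta);
}

// analytic gradient of the -2 loglik (exact up to floating point)
// [[Rcpp::export(name = ".fiml_grad_ptr_cpp")]]
arma::vec fiml_grad_ptr_cpp(const arma::vec& theta, SEXP ctx_ptr,
                            double eps = 1e-6) {
  (void)eps;
  Rcpp::XPtr<std::vector<Group>> ptr(ctx_ptr);
  const std::vector<Group>& groups = *ptr;
  arma::vec g(theta.n_elem, arma::fill::zeros);
  for (const Group& gr : groups) {
    double v = group_neg2ll_grad(gr, theta, g);
    if (v >= PENALTY) { g.zeros(); return g; }
  }
  return g;
}

// central-difference gradient, retained as an independent check on the
// analytic one
// [[Rcpp::export(name = ".fiml_grad_fd_ptr_cpp")]]
arma::vec fiml_grad_fd_ptr_cpp(const arma::vec& theta, SEXP ctx_ptr,
                               double eps = 1e-6) {
  Rcpp::XPtr<std::vector<Group>> ptr(ctx_ptr);
  const std::vector<Group>& groups = *ptr;
  arma::vec g(theta.n_elem);
  arma::vec th = theta;
  for (arma::uword i = 0; i < theta.n_elem; ++i) {
    double h = eps * (1.0 + std::abs(theta(i)));
    th(i) = theta(i) + h; double fp = neg2ll_all(groups, th);
    th(i) = theta(i) - h; double fm = neg2ll_all(groups, th);
    th(i) = theta(i);
    g(i) = (fp - fm) / (2.0 * h);
  }
  return g;
}

// [[Rcpp::export(name = ".fiml_neg2ll_cpp")]]
double fiml_neg2ll_cpp(const arma::vec& theta, const List& ctx) {
  std::vector<Group> groups = build_groups(ctx);
  return neg2ll_all(groups, theta);
}

// central-difference gradient of the -2 loglik
// [[Rcpp::export(name = ".fiml_grad_cpp")]]
arma::vec fiml_grad_cpp(const arma::vec& theta, const List& ctx,
                        double eps = 1e-6) {
  std::vector<Group> groups = build_groups(ctx);
  auto f = [&](const arma::vec& th) {
    double total = 0.0;
    for (const Group& gr : groups) {
      double v = group_neg2ll(gr, th);
      if (v >= PENALTY) return PENALTY;
      total += v;
    }
    return total;
  };
  arma::vec g(theta.n_elem);
  arma::vec th = theta;
  for (arma::uword i = 0; i < theta.n_elem; ++i) {
    double h = eps * (1.0 + std::abs(theta(i)));
    th(i) = theta(i) + h; double fp = f(th);
    th(i) = theta(i) - h; double fm = f(th);
    th(i) = theta(i);
    g(i) = (fp - fm) / (2.0 * h);
  }
  return g;
}

// Profiled means and implied moments at theta, for reporting
// [[Rcpp::export(name = ".fiml_details_cpp")]]
List fiml_details_cpp(const arma::vec& theta, const List& ctx) {
  std::vector<Group> groups = build_groups(ctx);
  List out(groups.size());
  for (size_t g = 0; g < groups.size(); ++g) {
    const Group& gr = groups[g];
    arma::mat A = gr.A0, S = gr.S0;
    arma::vec M = gr.M0;
    const arma::imat& fc = gr.free_cells;
    for (arma::uword r = 0; r < fc.n_rows; ++r) {
      double v = theta(fc(r, 0));
      int i = fc(r, 2), j = fc(r, 3);
      switch (fc(r, 1)) {
        case 0: A(i, j) = v; break;
        case 1: S(i, j) = v; S(j, i) = v; break;
        default: M(i) = v;
      }
    }
    arma::uword nv = A.n_rows;
    arma::mat B = arma::inv(arma::eye(nv, nv) - A);
    arma::mat BF = B.rows(gr.obs);
    arma::mat Sigma = BF * S * BF.t();
    Sigma = 0.5 * (Sigma + Sigma.t());
    arma::uword p = gr.obs.n_elem;
    arma::vec mu(p, arma::fill::zeros);
    if (gr.mean_mode == 0) {
      arma::mat Amat(p, p, arma::fill::zeros);
      arma::vec bvec(p, arma::fill::zeros);
      for (const Pattern& pat : gr.patterns) {
        arma::mat Sp = Sigma.submat(pat.oidx, pat.oidx);
        arma::mat SpInv = arma::inv_sympd(Sp);
        Amat.submat(pat.oidx, pat.oidx) += pat.n * SpInv;
        bvec.elem(pat.oidx) += pat.n * (SpInv * pat.xbar);
      }
      mu = arma::solve(Amat, bvec);
    } else {
      arma::vec mu_all = B * M;
      mu = mu_all.elem(gr.obs);
    }
    out[g] = List::create(_["Sigma"] = Sigma, _["mu"] = mu,
                          _["neg2ll"] = group_neg2ll(gr, theta));
  }
  return out;
}

// -2 loglik of an unstructured multivariate normal (mu, Sigma) over the
// observed patterns; used by the EM saturated fit and the baseline model
// [[Rcpp::export(name = ".mvn_pattern_neg2ll_cpp")]]
double mvn_pattern_neg2ll_cpp(const arma::vec& mu, const arma::mat& Sigma,
                              const List& patterns) {
  double val = 0.0;
  for (int ip = 0; ip < patterns.size(); ++ip) {
    List P = patterns[ip];
    arma::uvec oidx = as<arma::uvec>(P["oidx"]);
    double n = as<double>(P["n"]);
    arma::vec xbar = as<arma::vec>(P["xbar"]);
    arma::mat W = as<arma::mat>(P["W"]);
    arma::mat Sp = Sigma.submat(oidx, oidx);
    arma::mat L;
    if (!arma::chol(L, Sp, "lower")) return PENALTY;
    double logdet = 2.0 * arma::sum(arma::log(L.diag()));
    arma::mat Linv = arma::inv(arma::trimatl(L));
    arma::mat SpInv = Linv.t() * Linv;
    arma::vec d = xbar - mu.elem(oidx);
    val += n * oidx.n_elem * LOG2PI + n * logdet + arma::trace(SpInv * W) +
      n * arma::as_scalar(d.t() * SpInv * d);
  }
  return val;
}
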
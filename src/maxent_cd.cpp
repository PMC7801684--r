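#include <Rcpp.h>
using namespace Rcpp;

// log-sum-exp of a vector
static double lse(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

static double soft(double z, double l) {
  if (z > l) return z - l;
  if (z < -l) return z + l;
  return 0.0;
}

// Lasso-penalized maximum-entropy (Gibbs) fit by cyclic coordinate descent.
// Minimizes  -mean_presence(eta) + log sum_background exp(eta) + sum_j lambda_j |beta_j|
// where eta = F beta. Each coordinate takes a soft-thresholded Newton step with
// backtracking halving, so the objective is non-increasing across sweeps.
// [[Rcpp::export]]
List maxent_cd(NumericMatrix Fp, NumericMatrix Fb, NumericVector lambda,
               double tol, int maxit) {
  const int np = Fp.nrow(), nb = Fb.nrow(), p = Fb.ncol();
  std::vector<double> pbar(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < np; ++i) s += Fp(i, j);
    pbar[j] = s / np;
  }
  std::vector<double> beta(p, 0.0), eta(nb, 0.0), w(nb), eta_try(nb);
  double lseB = std::log((double) nb);
  double pen = 0.0, lin = 0.0;
  double obj = lin + lseB + pen;  // = log nb at beta = 0
  int it = 0;
  bool converged = false;
  bool full_sweep = true;  // glmnet-style: full sweeps bracket active-set sweeps
  for (it = 1; it <= maxit; ++it) {
    double max_d = 0.0;
    for (int j = 0; j < p; ++j) {
      if (!full_sweep && beta[j] == 0.0) continue;
      // Gibbs weights at the current beta
      double q = 0.0, q2 = 0.0;
      for (int i = 0; i < nb; ++i) {
        w[i] = std::exp(eta[i] - lseB);
        double f = Fb(i, j);
        q += w[i] * f;
        q2 += w[i] * f * f;
      }
      double g = q - pbar[j];
      double h = q2 - q * q;
      if (h < 1e-9) h = 1e-9;
      double bnew = soft(h * beta[j] - g, lambda[j]) / h;
      double d = bnew - beta[j];
      if (std::fabs(d) < 1e-12) continue;
      // backtrack until the exact objective does not increase
      bool accepted = false;
      for (int bt = 0; bt < 30; ++bt) {
        double cand = beta[j] + d;
        for (int i = 0; i < nb; ++i) eta_try[i] = eta[i] + d * Fb(i, j);
        double lse_try = lse(eta_try);
        double lin_try = lin - pbar[j] * d;  // lin = -sum pbar*beta
        double pen_try = pen - lambda[j] * std::fabs(beta[j])
          + lambda[j] * std::fabs(cand);
        double obj_try = lin_try + lse_try + pen_try;
        if (obj_try <= obj + 1e-12) {
          beta[j] = cand;
          std::swap(eta, eta_try);
          lseB = lse_try;
          lin = lin_try;
          pen = pen_try;
          obj = obj_try;
          accepted = true;
          break;
        }
        d *= 0.5;
      }
      if (accepted && std::fabs(d) > max_d) max_d = std::fabs(d);
    }
    if (max_d < tol) {
      if (full_sweep) { converged = true; break; }
      full_sweep = true;   // active set stable: verify with a full sweep
    } else {
      full_sweep = false;  // iterate the current active set
    }
  }
  double alpha = -lseB;
  return List::create(
    _["beta"] = NumericVector(beta.begin(), beta.end()),
    _["alpha"] = alpha,
    _["objective"] = obj,
    _["iterations"] = it,
    _["converged"] = converged
  );
}
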
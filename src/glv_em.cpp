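#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama stepping of the bipartite GLV-mutualism Langevin equation.
// Noise: independent per-species streams; white (rho = 0) or AR(1) colored
// innovations with lag-1 autocorrelation rho, variance-matched to the white
// case. States are clipped at zero after every step (reflecting boundary by
// truncation, matching the Fokker-Planck reflecting-barrier condition).
// Uses the R RNG so that set.seed() on the R side controls reproducibility.

static inline void glv_drift_inner(
    const NumericVector& x, NumericVector& dx,
    const NumericVector& aP, const NumericVector& aA,
    const NumericVector& bP, const NumericVector& bA,
    const NumericVector& beP, const NumericVector& beA,
    const NumericVector& kap, double h,
    const NumericVector& muP, const NumericVector& muA,
    const NumericMatrix& gPA, const NumericMatrix& gAP,
    int np, int na, double kappa_shift) {
  double sumP = 0.0, sumA = 0.0;
  for (int i = 0; i < np; ++i) sumP += x[i];
  for (int j = 0; j < na; ++j) sumA += x[np + j];
  for (int i = 0; i < np; ++i) {
    double M = 0.0;
    for (int l = 0; l < na; ++l) M += gPA(i, l) * x[np + l];
    double P = x[i];
    dx[i] = aP[i] * P - bP[i] * P * P - beP[i] * P * (sumP - P) +
            P * M / (1.0 + h * M) + muP[i];
  }
  for (int j = 0; j < na; ++j) {
    double M = 0.0;
    for (int n = 0; n < np; ++n) M += gAP(j, n) * x[n];
    double A = x[np + j];
    dx[np + j] = aA[j] * A - (kap[j] + kappa_shift) * A - bA[j] * A * A -
                 beA[j] * A * (sumA - A) + A * M / (1.0 + h * M) + muA[j];
  }
}

// [[Rcpp::export]]
List glv_em_cpp(NumericVector x0, List rp, NumericMatrix gPA,
                NumericMatrix gAP, double dt, int n_steps,
                int record_every, double d, double rho,
                NumericVector kappa_shift) {
  int np = gPA.nrow(), na = gPA.ncol(), N = np + na;
  NumericVector aP = rp["alpha_P"], aA = rp["alpha_A"];
  NumericVector bP = rp["beta_intra_P"], bA = rp["beta_intra_A"];
  NumericVector beP = rp["beta_inter_P"], beA = rp["beta_inter_A"];
  NumericVector kap = rp["kappa"], muP = rp["mu_P"], muA = rp["mu_A"];
  double h = as<double>(rp["h"]);
  bool ramp = kappa_shift.size() > 1;

  int n_rec = n_steps / record_every + 1;
  NumericMatrix rec(n_rec, N);
  NumericVector rec_t(n_rec);
  NumericVector x = clone(x0), dx(N), eta(N);
  double amp = std::sqrt(2.0 * d * dt);
  double cfac = std::sqrt(1.0 - rho * rho);
  for (int i = 0; i < N; ++i) eta[i] = (d > 0) ? R::norm_rand() : 0.0;
  int ri = 0;
  for (int i = 0; i < N; ++i) rec(0, i) = x[i];
  rec_t[0] = 0.0;
  ri = 1;
  for (int s = 1; s <= n_steps; ++s) {
    double ks = ramp ? kappa_shift[s - 1] : kappa_shift[0];
    glv_drift_inner(x, dx, aP, aA, bP, bA, beP, beA, kap, h, muP, muA,
                    gPA, gAP, np, na, ks);
    for (int i = 0; i < N; ++i) {
      double z = x[i] + dx[i] * dt + amp * eta[i];
      x[i] = z > 0.0 ? z : 0.0;
      if (d > 0) {
        if (rho != 0.0) eta[i] = rho * eta[i] + cfac * R::norm_rand();
        else eta[i] = R::norm_rand();
      }
      if (!R_finite(x[i]))
        stop("non-finite abundance at step %d", s);
    }
    if (s % record_every == 0 && ri < n_rec) {
      for (int i = 0; i < N; ++i) rec(ri, i) = x[i];
      rec_t[ri] = s * dt;
      ++ri;
    }
  }
  return List::create(_["states"] = rec, _["times"] = rec_t,
                      _["x_final"] = x);
}

// First passage into a ball around a target, measured either in the full
// state space or in projected coordinates (z = W^T x). Returns the first
// passage time, or -1 if censored at n_steps.
// [[Rcpp::export]]
double glv_fpt_cpp(NumericVector x0, List rp, NumericMatrix gPA,
                   NumericMatrix gAP, double dt, int n_steps, double d,
                   double rho, NumericMatrix W, NumericVector z_target,
                   double radius) {
  int np = gPA.nrow(), na = gPA.ncol(), N = np + na;
  int K = W.ncol();
  NumericVector aP = rp["alpha_P"], aA = rp["alpha_A"];
  NumericVector bP = rp["beta_intra_P"], bA = rp["beta_intra_A"];
  NumericVector beP = rp["beta_inter_P"], beA = rp["beta_inter_A"];
  NumericVector kap = rp["kappa"], muP = rp["mu_P"], muA = rp["mu_A"];
  double h = as<double>(rp["h"]);
  NumericVector x = clone(x0), dx(N), eta(N);
  double amp = std::sqrt(2.0 * d * dt);
  double cfac = std::sqrt(1.0 - rho * rho);
  for (int i = 0; i < N; ++i) eta[i] = (d > 0) ? R::norm_rand() : 0.0;
  for (int s = 1; s <= n_steps; ++s) {
    glv_drift_inner(x, dx, aP, aA, bP, bA, beP, beA, kap, h, muP, muA,
                    gPA, gAP, np, na, 0.0);
    for (int i = 0; i < N; ++i) {
      double z = x[i] + dx[i] * dt + amp * eta[i];
      x[i] = z > 0.0 ? z : 0.0;
      if (rho != 0.0) eta[i] = rho * eta[i] + cfac * R::norm_rand();
      else if (d > 0) eta[i] = R::norm_rand();
      if (!R_finite(x[i]))
        stop("non-finite abundance at step %d", s);
    }
    double dist2 = 0.0;
    for (int k = 0; k < K; ++k) {
      double zk = 0.0;
      for (int i = 0; i < N; ++i) zk += W(i, k) * x[i];
      double dk = zk - z_target[k];
      dist2 += dk * dk;
    }
    if (std::sqrt(dist2) <= radius) return s * dt;
  }
  return -1.0;
}
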
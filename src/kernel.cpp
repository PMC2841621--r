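#include <Rcpp.h>
using namespace Rcpp;

// Method-of-steps RK4 for the G0/G1 balance equation in flux form:
//   dN/dt = -alpha(t) * N(t) + b(t) * F(t - T(t)),
// where F(t) = kappa(t) * N(t) is the S-entry flux and b(t) bundles the
// doubling factor, the cohort Jacobian (1 - T'(t)) and the per-division
// survival fraction.  alpha, b and the (0-based, fractional) grid position
// of the delayed argument are precomputed per RK4 stage; the stored flux
// history is interpolated with a 4-point cubic Lagrange stencil.  The
// delay far exceeds the step size, so delayed lookups never touch the
// moving front of the grid.
//
// Grid layout: index i holds time (i - n_hist) * dt, i = 0 .. n_tot - 1;
// indices 0 .. n_hist are the (constant-state) history and initial point.

static inline double interp_flux(const double *F, double pos, int filled) {
  int i0 = (int)std::floor(pos);
  double u = pos - i0;
  if (i0 < 1 || i0 + 2 > filled)
    return NA_REAL;
  double wm1 = -u * (u - 1.0) * (u - 2.0) / 6.0;
  double w0 = (u * u - 1.0) * (u - 2.0) / 2.0;
  double w1 = -u * (u + 1.0) * (u - 2.0) / 2.0;
  double w2 = u * (u * u - 1.0) / 6.0;
  return wm1 * F[i0 - 1] + w0 * F[i0] + w1 * F[i0 + 1] + w2 * F[i0 + 2];
}

// [[Rcpp::export]]
List step_g1_kernel(double n_init, double dt, int n_hist,
                    NumericVector kappa_grid,
                    NumericVector alpha0, NumericVector alphah,
                    NumericVector alpha1,
                    NumericVector b0, NumericVector bh, NumericVector b1,
                    NumericVector pos0, NumericVector posh,
                    NumericVector pos1) {
  int n_steps = alpha0.size();
  int n_tot = n_hist + n_steps + 1;
  if (kappa_grid.size() != n_tot)
    stop("kappa_grid has wrong length");
  NumericVector NG1(n_tot), F(n_tot);
  for (int i = 0; i <= n_hist; ++i) {
    NG1[i] = n_init;
    F[i] = kappa_grid[i] * n_init;
  }
  const double *Fp = F.begin();
  double N = n_init;
  for (int j = 0; j < n_steps; ++j) {
    int filled = n_hist + j;  // last index with known flux
    double f0 = interp_flux(Fp, pos0[j], filled);
    double fh = interp_flux(Fp, posh[j], filled);
    double f1 = interp_flux(Fp, pos1[j], filled);
    if (ISNA(f0) || ISNA(fh) || ISNA(f1))
      stop("delayed lookup outside the stored flux history (dt too large "
           "for this delay?)");
    double k1 = -alpha0[j] * N + b0[j] * f0;
    double k2 = -alphah[j] * (N + 0.5 * dt * k1) + bh[j] * fh;
    double k3 = -alphah[j] * (N + 0.5 * dt * k2) + bh[j] * fh;
    double k4 = -alpha1[j] * (N + dt * k3) + b1[j] * f1;
    N += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (N < 0.0 || !R_FINITE(N))
      stop("G0/G1 cell number became negative or non-finite at step %d", j);
    int idx = n_hist + j + 1;
    NG1[idx] = N;
    F[idx] = kappa_grid[idx] * N;
  }
  return List::create(_["n_g1"] = NG1, _["flux"] = F);
}
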
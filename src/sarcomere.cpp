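// Half-sarcomere cross-bridge kinetics on a 21-bin strain grid.
//
// State layout per integration point (25 values):
//   [0] N_off  [1] N_on  [2] M_SRX  [3] M_DRX  [4..24] M_FG at x = -10..10 nm
//
// Parameter vector layout (see xb_params() on the R side):
//   [0] k_on (1/(M s))   [1] k_off (1/s)   [2] k_coop (-)
//   [3] k_1 (1/s)        [4] k_force (1/Pa)[5] k_2 (1/s)
//   [6] k_3 (1/s)        [7] k_4_0 (1/s)   [8] k_4_1 (1/(s nm^4))
//   [9] k_cb (N/m)       [10] kBT (J)      [11] x_ps (nm)
//   [12] N_0 (1/m^2)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const int NBIN = 21;
static const int NSTATE = 25;
static const double XMIN = -10.0, DX = 1.0; // nm

// Gaussian attachment weights exp(-k_cb x^2 / (2 kBT)), x in nm
static void attach_weights(const arma::vec& prm, double* w) {
  const double kcb = prm[9], kBT = prm[10];
  for (int i = 0; i < NBIN; ++i) {
    double x_m = (XMIN + DX * i) * 1e-9;
    w[i] = std::exp(-kcb * x_m * x_m / (2.0 * kBT));
  }
}

// time derivative of one state row
static void xb_deriv(const double* s, double Ca, double Nov, double Ftot,
                     const arma::vec& prm, const double* gw, double* ds) {
  const double k_on = prm[0], k_off = prm[1], k_coop = prm[2];
  const double k_1 = prm[3], k_force = prm[4], k_2 = prm[5];
  const double k_3 = prm[6], k_40 = prm[7], k_41 = prm[8];

  double Nb = 0.0;
  for (int i = 0; i < NBIN; ++i) Nb += s[4 + i];

  const double Non = s[1], Msrx = s[2], Mdrx = s[3];
  double Jon = 0.0, Joff = 0.0;
  if (Nov > 0.0) {
    Jon  = k_on * Ca * (Nov - Non) * (1.0 + k_coop * (Non / Nov));
    Joff = k_off * (Non - Nb) * (1.0 + k_coop * ((Nov - Non) / Nov));
  }
  const double Fpos = Ftot > 0.0 ? Ftot : 0.0;
  const double J1 = k_1 * (1.0 + k_force * Fpos) * Msrx;
  const double J2 = k_2 * Mdrx;

  double sumJ3 = 0.0, sumJ4 = 0.0;
  const double avail = (Non - Nb) * Mdrx;
  for (int i = 0; i < NBIN; ++i) {
    double x = XMIN + DX * i;
    double J3 = k_3 * gw[i] * avail;
    double J4 = (k_40 + k_41 * x * x * x * x) * s[4 + i];
    ds[4 + i] = J3 - J4;
    sumJ3 += J3;
    sumJ4 += J4;
  }
  ds[0] = -Jon + Joff;
  ds[1] = Jon - Joff;
  ds[2] = -J1 + J2;
  ds[3] = (J1 + sumJ4) - (J2 + sumJ3);
}

// mass-conserving linear-interpolation shift of the attached population by
// `shift` nm; mass advected past the grid ends detaches into M_DRX
static void advect(double* s, double shift) {
  if (shift == 0.0) return;
  double nf[NBIN];
  for (int i = 0; i < NBIN; ++i) nf[i] = 0.0;
  double before = 0.0, after = 0.0;
  for (int j = 0; j < NBIN; ++j) {
    double m = s[4 + j];
    if (m == 0.0) continue;
    before += m;
    double pos = j + shift / DX; // target index (fractional)
    int i0 = (int)std::floor(pos);
    double w = pos - i0;
    if (i0 >= 0 && i0 < NBIN) { nf[i0] += m * (1.0 - w); after += m * (1.0 - w); }
    if (i0 + 1 >= 0 && i0 + 1 < NBIN) { nf[i0 + 1] += m * w; after += m * w; }
  }
  for (int i = 0; i < NBIN; ++i) s[4 + i] = nf[i];
  s[3] += before - after; // forced detachment at the grid boundary
}

// [[Rcpp::export]]
arma::mat xb_step_cpp(const arma::mat& states, const arma::vec& Ca,
                      const arma::vec& Nov, const arma::vec& Ftot,
                      const arma::vec& dhsl_nm, const arma::vec& prm,
                      double dt, double dt_sub, const arma::vec& k1pt) {
  if ((int)states.n_cols != NSTATE)
    Rcpp::stop("state matrix must have 25 columns");
  arma::mat out = states;
  double gw[NBIN];
  attach_weights(prm, gw);

  const int npt = states.n_rows;
  int nsub = (int)std::ceil(dt / dt_sub - 1e-12);
  if (nsub < 1) nsub = 1;
  const double h = dt / nsub;

  double s[NSTATE], k1v[NSTATE], smid[NSTATE], k2v[NSTATE];
  vec prm_pt = prm;
  for (int pt = 0; pt < npt; ++pt) {
    prm_pt[3] = k1pt.n_elem == 1 ? k1pt[0] : k1pt[pt]; // regional k_1
    for (int j = 0; j < NSTATE; ++j) s[j] = out(pt, j);
    // strain advection from this step's filament sliding
    advect(s, -dhsl_nm[pt]);
    // midpoint (RK2) substeps of the 25-ODE system
    for (int it = 0; it < nsub; ++it) {
      xb_deriv(s, Ca[pt], Nov[pt], Ftot[pt], prm_pt, gw, k1v);
      for (int j = 0; j < NSTATE; ++j) smid[j] = s[j] + 0.5 * h * k1v[j];
      xb_deriv(smid, Ca[pt], Nov[pt], Ftot[pt], prm_pt, gw, k2v);
      for (int j = 0; j < NSTATE; ++j) s[j] += h * k2v[j];
    }
    // guard: fractions must stay non-negative to solver tolerance
    for (int j = 0; j < NSTATE; ++j) {
      if (s[j] < 0.0) {
        if (s[j] < -1e-8)
          Rcpp::stop("cross-bridge integrator produced a negative fraction "
                     "(%g) at point %d: reduce dt_sub", s[j], pt + 1);
        s[j] = 0.0;
      }
    }
    double thin = s[0] + s[1], thick = s[2] + s[3];
    for (int i = 0; i < NBIN; ++i) thick += s[4 + i];
    if (std::abs(thin - 1.0) > 1e-6 || std::abs(thick - 1.0) > 1e-6)
      Rcpp::stop("conservation drift in cross-bridge states (thin %g, thick %g)",
                 thin - 1.0, thick - 1.0);
    for (int j = 0; j < NSTATE; ++j) out(pt, j) = s[j];
  }
  return out;
}

// [[Rcpp::export]]
arma::vec xb_force_cpp(const arma::mat& states, const arma::vec& prm) {
  const double kcb = prm[9], xps = prm[11], N0 = prm[12];
  arma::vec f(states.n_rows, fill::zeros);
  for (size_t pt = 0; pt < states.n_rows; ++pt) {
    double acc = 0.0;
    for (int i = 0; i < NBIN; ++i) {
      double x = XMIN + DX * i;
      acc += states(pt, 4 + i) * (x + xps) * 1e-9; // nm -> m
    }
    f[pt] = N0 * kcb * acc;
  }
  return f;
}
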
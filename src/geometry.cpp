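// Cavity volume of the deformed endocardial surface and its displacement
// gradient.
//
// V = -1/3 * sum over endocardial P2 faces of int x . (dx/dr x dx/ds) dr ds
// with x the deformed position; faces are oriented outward of the wall
// elements, so the signed integral returns the (positive) enclosed cavity
// volume when the basal plane sits at z = 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// skew matrix W(v) with (e_l x v)_k = W_kl
static inline void skew(const vec3& v, mat33& W) {
  W(0, 0) = 0;      W(0, 1) = v[2];  W(0, 2) = -v[1];
  W(1, 0) = -v[2];  W(1, 1) = 0;     W(1, 2) = v[0];
  W(2, 0) = v[1];   W(2, 1) = -v[0]; W(2, 2) = 0;
}

// [[Rcpp::export]]
Rcpp::List cavity_volume_cpp(const arma::mat& nodes, const arma::imat& faces0,
                             const arma::vec& u, const arma::mat& qN,
                             const arma::mat& qdN1, const arma::mat& qdN2,
                             const arma::vec& qw, bool want_grad,
                             bool want_hess = false) {
  const int nq = qN.n_rows;
  const int nf = faces0.n_rows;
  double V = 0.0;
  vec grad;
  if (want_grad) grad.zeros(u.n_elem);

  std::vector<int> hi, hj;
  std::vector<double> hv;
  if (want_hess) {
    hi.reserve((size_t)nf * 18 * 18);
    hj.reserve((size_t)nf * 18 * 18);
    hv.reserve((size_t)nf * 18 * 18);
  }
  mat33 Wx, W1, W2;

  for (int f = 0; f < nf; ++f) {
    mat xe(6, 3);
    for (int a = 0; a < 6; ++a) {
      int n = faces0(f, a);
      for (int k = 0; k < 3; ++k) xe(a, k) = nodes(n, k) + u[3 * n + k];
    }
    for (int q = 0; q < nq; ++q) {
      rowvec x = qN.row(q) * xe;
      rowvec t1 = qdN1.row(q) * xe;
      rowvec t2 = qdN2.row(q) * xe;
      vec n3 = cross(t1.t(), t2.t());
      const double c = -qw[q] / 3.0;
      V += c * dot(x, n3);
      if (want_grad) {
        vec c1 = cross(t2.t(), x.t()); // coefficient of dN1 terms
        vec c2 = cross(x.t(), t1.t()); // coefficient of dN2 terms
        for (int a = 0; a < 6; ++a) {
          int n = faces0(f, a);
          for (int k = 0; k < 3; ++k) {
            grad[3 * n + k] += c *
              (qN(q, a) * n3[k] + qdN1(q, a) * c1[k] + qdN2(q, a) * c2[k]);
          }
        }
      }
      if (want_hess) {
        skew(x.t(), Wx); skew(t1.t(), W1); skew(t2.t(), W2);
        for (int a = 0; a < 6; ++a) {
          const double Na = qN(q, a), d1a = qdN1(q, a), d2a = qdN2(q, a);
          int na = faces0(f, a);
          for (int b = 0; b < 6; ++b) {
            const double Nb = qN(q, b), d1b = qdN1(q, b), d2b = qdN2(q, b);
            int nb = faces0(f, b);
            // coefficient matrix of the (k, l) block
            const double cW2 = Na * d1b - d1a * Nb;
            const double cW1 = d2a * Nb - Na * d2b;
            const double cWx = d1a * d2b - d2a * d1b;
            for (int k = 0; k < 3; ++k)
              for (int l = 0; l < 3; ++l) {
                double h = c * (cW2 * W2(k, l) + cW1 * W1(k, l) +
                                cWx * Wx(k, l));
                if (h != 0.0) {
                  hi.push_back(3 * na + k);
                  hj.push_back(3 * nb + l);
                  hv.push_back(h);
                }
              }
          }
        }
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("V") = V);
  if (want_grad) out["grad"] = grad;
  if (want_hess) {
    out["hi"] = hi; out["hj"] = hj; out["hv"] = hv;
  }
  return out;
}
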
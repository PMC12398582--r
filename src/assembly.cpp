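// Total-Lagrangian assembly of the incompressible mixed (P2 displacement /
// P1 pressure) momentum residual and consistent tangent for the LV wall.
//
// Stress model per quadrature point (2nd Piola-Kirchhoff):
//   S = S_active + S_vol + S_bulk (Guccione) + S_myofiber
// with S_active = Sact * f0 f0^T frozen within a Newton solve (staggered
// coupling to the sarcomere model), S_vol = -p J C^{-1}.
//
// Voigt order (11, 22, 33, 23, 13, 12); stress vectors carry single shear
// entries, strain increments engineering shears, and the 6x6 tangent D maps
// between them.  Fiber-frame quantities are rotated with the Bond matrix of
// the frame rotation.
//
// Global dof numbering: u dof = 3*node + k (k = 0,1,2); pressure dof =
// 3*n_nodes + vertex id (vertices are the first n_vert nodes).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const int VI[6] = {0, 1, 2, 1, 0, 0};
static const int VJ[6] = {0, 1, 2, 2, 2, 1};

// reference-configuration geometry: global shape gradients, weighted
// jacobians and positions at every quadrature point (element-major)
// [[Rcpp::export]]
Rcpp::List fe_precompute_cpp(const arma::mat& nodes, const arma::imat& elems0,
                             const arma::mat& qN, const arma::cube& qdN,
                             const arma::vec& qw) {
  const int ne = elems0.n_rows, nq = qN.n_rows;
  cube dNg(10, 3, ne * nq);
  vec wdet(ne * nq);
  mat pos(ne * nq, 3);
  for (int e = 0; e < ne; ++e) {
    mat xe(10, 3);
    for (int a = 0; a < 10; ++a) xe.row(a) = nodes.row(elems0(e, a));
    for (int q = 0; q < nq; ++q) {
      mat dNl(10, 3);
      for (int a = 0; a < 10; ++a)
        for (int j = 0; j < 3; ++j) dNl(a, j) = qdN(q, a, j);
      mat Jm = xe.t() * dNl; // dx/dxi
      double dj = det(Jm);
      if (dj <= 0) Rcpp::stop("inverted element %d at qpt %d", e + 1, q + 1);
      dNg.slice(e * nq + q) = dNl * inv(Jm); // dN/dX
      wdet[e * nq + q] = qw[q] * dj;
      pos.row(e * nq + q) = qN.row(q) * xe;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dNg") = dNg,
                            Rcpp::Named("wdet") = wdet,
                            Rcpp::Named("pos") = pos);
}

// Bond (Voigt rotation) matrix of Q for stress vectors: s_glob = Ms s_loc
static void bond_matrix(const mat33& Q, mat::fixed<6, 6>& Ms) {
  for (int I = 0; I < 6; ++I) {
    int i = VI[I], j = VJ[I];
    for (int J = 0; J < 6; ++J) {
      int k = VJ[J], l = VI[J]; // (l,k) pair; l==k for normals
      if (k == l) Ms(I, J) = Q(i, k) * Q(j, k);
      else Ms(I, J) = Q(i, l) * Q(j, k) + Q(i, k) * Q(j, l);
    }
  }
}

// [[Rcpp::export]]
Rcpp::List assemble_cpp(const arma::imat& elems0, int n_nodes, int n_vert,
                        const arma::cube& dNg, const arma::vec& wdet,
                        const arma::mat& pN, const arma::vec& u,
                        const arma::vec& pv,
                        const arma::mat& f0m, const arma::mat& s0m,
                        const arma::mat& n0m,
                        const arma::vec& Cb, const arma::vec& bff,
                        const arma::vec& bxx, const arma::vec& bfs,
                        const arma::vec& C1, const arma::vec& C2,
                        const arma::vec& Sact, double kpen,
                        bool want_matrix, bool want_fields) {
  const int ne = elems0.n_rows, nq = pN.n_rows;
  const int nqp = ne * nq;
  vec Ru(3 * n_nodes, fill::zeros);
  vec Rp(n_vert, fill::zeros);

  std::vector<int> ti, tj;
  std::vector<double> tvv;
  if (want_matrix) {
    ti.reserve((size_t)ne * 34 * 34);
    tj.reserve((size_t)ne * 34 * 34);
    tvv.reserve((size_t)ne * 34 * 34);
  }

  vec Jout, alphaOut, SffMyo;
  mat Svoigt, Fout, Evoigt;
  if (want_fields) {
    Jout.set_size(nqp); alphaOut.set_size(nqp); SffMyo.set_size(nqp);
    Svoigt.set_size(nqp, 6); Fout.set_size(nqp, 9); Evoigt.set_size(nqp, 6);
  }

  mat33 I3(fill::eye);
  mat::fixed<10, 3> ue, Reu, GS;
  mat::fixed<34, 34> Ke;
  mat::fixed<6, 30> Bm;
  mat::fixed<6, 6> Ms, D, Dg;
  mat33 F, C, E, Cinv, Q, Gf, B3, S;
  vec::fixed<6> gf6, mv6, sv6;
  mat::fixed<10, 10> H;
  mat::fixed<10, 3> Vn;

  for (int e = 0; e < ne; ++e) {
    vec::fixed<4> pe;
    for (int a = 0; a < 10; ++a) {
      int n = elems0(e, a);
      for (int k = 0; k < 3; ++k) ue(a, k) = u[3 * n + k];
    }
    for (int b = 0; b < 4; ++b) pe[b] = pv[elems0(e, b)];

    if (want_matrix) Ke.zeros();
    Reu.zeros();
    vec::fixed<4> Rep;
    Rep.zeros();

    for (int q = 0; q < nq; ++q) {
      const int iq = e * nq + q;
      const mat& G = dNg.slice(iq); // 10 x 3, dN/dX
      const double w = wdet[iq];

      F = I3 + (ue.t() * G).eval();
      double J = det(F);
      if (J <= 0) Rcpp::stop("negative Jacobian at element %d", e + 1);
      C = F.t() * F;
      E = 0.5 * (C - I3);
      Cinv = inv(C);
      Cinv = 0.5 * (Cinv + Cinv.t());

      for (int k = 0; k < 3; ++k) {
        Q(k, 0) = f0m(iq, k); Q(k, 1) = s0m(iq, k); Q(k, 2) = n0m(iq, k);
      }

      // Guccione bulk in fiber coordinates
      mat33 Ef = Q.t() * E * Q;
      B3(0, 0) = bff[iq];
      B3(1, 1) = B3(2, 2) = B3(1, 2) = B3(2, 1) = bxx[iq];
      B3(0, 1) = B3(1, 0) = B3(0, 2) = B3(2, 0) = bfs[iq];
      Gf = B3 % Ef;
      double Qexp = accu(B3 % (Ef % Ef));
      if (Qexp > 500.0)
        Rcpp::stop("strain energy exponent overflow at element %d", e + 1);
      double CeQ = Cb[iq] * std::exp(Qexp);

      // myofiber spring
      vec3 f0 = Q.col(0);
      double alpha = std::sqrt(as_scalar(f0.t() * C * f0));
      double smyo = 0.0, dsmyo = 0.0;
      if (alpha > 1.0 && C1[iq] > 0.0) {
        double am1 = alpha - 1.0;
        double E2 = std::exp(C2[iq] * am1 * am1);
        double psi1 = 2.0 * C1[iq] * C2[iq] * am1 * E2;
        double psi2 = 2.0 * C1[iq] * C2[iq] * E2 *
          (1.0 + 2.0 * C2[iq] * am1 * am1);
        smyo = psi1 / alpha;
        dsmyo = (psi2 * alpha - psi1) / (alpha * alpha * alpha);
      }
      mat33 M = f0 * f0.t();
      // effective pressure: multiplier plus augmented-Lagrangian penalty
      double pq = dot(pN.row(q), pe) - kpen * (J - 1.0);
      S = Q * (CeQ * Gf) * Q.t() + (smyo + Sact[iq]) * M - pq * J * Cinv;

      // residuals
      GS = G * (F * S).t(); // (a,k): [F S] grad N_a
      Reu += w * GS;
      for (int b = 0; b < 4; ++b) Rep[b] -= w * (J - 1.0) * pN(q, b);

      if (want_fields) {
        Jout[iq] = J; alphaOut[iq] = alpha; SffMyo[iq] = smyo;
        // physical stress: exclude the augmented-Lagrangian penalty part
        // (discretization stabilization, not material stress) so the
        // remodeling driver sees only multiplier + constitutive stress
        mat33 Sphys = S - kpen * (J - 1.0) * J * Cinv;
        for (int v = 0; v < 6; ++v) {
          Svoigt(iq, v) = Sphys(VI[v], VJ[v]);
          Evoigt(iq, v) = E(VI[v], VJ[v]);
        }
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c) Fout(iq, 3 * r + c) = F(r, c);
      }

      if (!want_matrix) continue;

      // ---- material tangent D = dS/dE (Voigt, engineering shear) ----
      // bulk in fiber coordinates: D_f = CeQ (diag(d) + 2 gf gf^T)
      for (int v = 0; v < 6; ++v) gf6[v] = Gf(VI[v], VJ[v]);
      D.zeros();
      D(0, 0) = B3(0, 0); D(1, 1) = B3(1, 1); D(2, 2) = B3(2, 2);
      D(3, 3) = 0.5 * B3(1, 2); D(4, 4) = 0.5 * B3(0, 2);
      D(5, 5) = 0.5 * B3(0, 1);
      D += 2.0 * (gf6 * gf6.t());
      D *= CeQ;
      bond_matrix(Q, Ms);
      Dg = Ms * D * Ms.t();
      // myofiber
      if (dsmyo != 0.0) {
        for (int v = 0; v < 6; ++v) mv6[v] = M(VI[v], VJ[v]);
        Dg += dsmyo * (mv6 * mv6.t());
      }
      // volumetric: -pJ [Ci x Ci - 2 sym(Ci . Ci)] plus the penalty
      // contribution kpen J^2 Ci x Ci from dp_eff/dE
      for (int I = 0; I < 6; ++I) {
        int i = VI[I], j = VJ[I];
        for (int Jc = 0; Jc < 6; ++Jc) {
          int k = VI[Jc], l = VJ[Jc];
          Dg(I, Jc) += -pq * J *
            (Cinv(i, j) * Cinv(k, l) - Cinv(i, k) * Cinv(j, l) -
             Cinv(i, l) * Cinv(j, k)) +
            kpen * J * J * Cinv(i, j) * Cinv(k, l);
        }
      }

      // strain-displacement matrix (6 x 30)
      for (int a = 0; a < 10; ++a) {
        double g0 = G(a, 0), g1 = G(a, 1), g2 = G(a, 2);
        for (int l = 0; l < 3; ++l) {
          int col = 3 * a + l;
          Bm(0, col) = F(l, 0) * g0;
          Bm(1, col) = F(l, 1) * g1;
          Bm(2, col) = F(l, 2) * g2;
          Bm(3, col) = F(l, 1) * g2 + F(l, 2) * g1;
          Bm(4, col) = F(l, 0) * g2 + F(l, 2) * g0;
          Bm(5, col) = F(l, 0) * g1 + F(l, 1) * g0;
        }
      }
      Ke.submat(0, 0, 29, 29) += w * (Bm.t() * (Dg * Bm));
      H = (w * G) * S * G.t(); // geometric stiffness
      for (int a = 0; a < 10; ++a)
        for (int b = 0; b < 10; ++b) {
          double h = H(a, b);
          Ke(3 * a, 3 * b) += h;
          Ke(3 * a + 1, 3 * b + 1) += h;
          Ke(3 * a + 2, 3 * b + 2) += h;
        }

      // displacement-pressure coupling: dS/dp = -J C^{-1};
      // G C^{-1} F^T = G F^{-1} gives rows F^{-T} grad N_a
      Vn = (-J * w) * (G * Cinv * F.t());
      for (int a = 0; a < 10; ++a)
        for (int k = 0; k < 3; ++k) {
          double vk = Vn(a, k);
          for (int b = 0; b < 4; ++b) {
            double v = vk * pN(q, b);
            Ke(3 * a + k, 30 + b) += v;
            Ke(30 + b, 3 * a + k) += v;
          }
        }
    }

    // scatter
    for (int a = 0; a < 10; ++a) {
      int n = elems0(e, a);
      for (int k = 0; k < 3; ++k) Ru[3 * n + k] += Reu(a, k);
    }
    for (int b = 0; b < 4; ++b) Rp[elems0(e, b)] += Rep[b];
    if (want_matrix) {
      int gdof[34];
      for (int a = 0; a < 10; ++a)
        for (int k = 0; k < 3; ++k) gdof[3 * a + k] = 3 * elems0(e, a) + k;
      for (int b = 0; b < 4; ++b) gdof[30 + b] = 3 * n_nodes + elems0(e, b);
      for (int i = 0; i < 34; ++i)
        for (int j = 0; j < 34; ++j) {
          ti.push_back(gdof[i]);
          tj.push_back(gdof[j]);
          tvv.push_back(Ke(i, j));
        }
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("Ru") = Ru, Rcpp::Named("Rp") = Rp,
    Rcpp::Named("ti") = ti, Rcpp::Named("tj") = tj,
    Rcpp::Named("tv") = tvv);
  if (want_fields) {
    out["J"] = Jout; out["alpha"] = alphaOut; out["Sff_myo"] = SffMyo;
    out["S"] = Svoigt; out["E"] = Evoigt; out["F"] = Fout;
  }
  return out;
}
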
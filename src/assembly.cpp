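// Total-Lagrangian finite-element kernels for the corneal tissue model:
// 8-node hexahedra, 2x2x2 Gauss quadrature, mean-dilatation treatment of the
// volumetric penalty (element-constant pressure from the volume-averaged J,
// preventing volumetric locking), neo-Hookean matrix, two tension-only
// Markert fiber families integrated over an in-plane angular grid, and
// follower (deformed-configuration) pressure faces with their exact
// nonsymmetric load stiffness.
//
// Units: mm - N - MPa. Stress output MPa.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct GaussHex {
  // shape-function derivatives wrt (xi,eta,zeta) at the 8 Gauss points
  mat dN[8];      // each 8 x 3
  double w[8];
  GaussHex() {
    const double g = 1.0 / std::sqrt(3.0);
    const double sg[8][3] = {{-1,-1,-1},{1,-1,-1},{1,1,-1},{-1,1,-1},
                             {-1,-1,1},{1,-1,1},{1,1,1},{-1,1,1}};
    int q = 0;
    for (int c = 0; c < 8; ++c) {
      double xi = g * sg[c][0], eta = g * sg[c][1], ze = g * sg[c][2];
      mat d(8, 3);
      for (int a = 0; a < 8; ++a) {
        double sx = sg[a][0], sy = sg[a][1], sz = sg[a][2];
        d(a, 0) = sx * (1 + sy * eta) * (1 + sz * ze) / 8.0;
        d(a, 1) = sy * (1 + sx * xi) * (1 + sz * ze) / 8.0;
        d(a, 2) = sz * (1 + sx * xi) * (1 + sy * eta) / 8.0;
      }
      dN[q] = d; w[q] = 1.0; ++q;
    }
  }
};
const GaussHex GH;

// Voigt index pairs: 11 22 33 12 13 23
const int VI[6] = {0, 1, 2, 0, 0, 1};
const int VJ[6] = {0, 1, 2, 1, 2, 2};

inline vec voigt(const mat33& A) {
  vec v(6);
  for (int p = 0; p < 6; ++p) v(p) = A(VI[p], VJ[p]);
  return v;
}

// D[p][q] += coef * (Ci_IK Ci_JL + Ci_IL Ci_JK)  (the symmetrized product)
inline void add_odot(mat& D, const mat33& A, double coef) {
  for (int p = 0; p < 6; ++p) {
    int I = VI[p], J = VJ[p];
    for (int q = 0; q < 6; ++q) {
      int K = VI[q], L = VJ[q];
      D(p, q) += coef * 0.5 * (A(I, K) * A(J, L) + A(I, L) * A(J, K));
    }
  }
}

inline void add_oxo(mat& D, const mat33& A, const mat33& B, double coef) {
  for (int p = 0; p < 6; ++p)
    for (int q = 0; q < 6; ++q)
      D(p, q) += coef * A(VI[p], VJ[p]) * B(VI[q], VJ[q]);
}

struct MatPar {
  double C10, gm, mum, gk, muk, kappa;
};

// deviatoric-part PK2 stress and Voigt tangent at one Gauss point
// (matrix + fibers; the volumetric penalty is handled at element level)
void point_material(const mat33& C, const MatPar& mp,
                    const mat& A /* ntheta x 3 fiber dirs */,
                    const rowvec& phi, vec& Sv, mat& D, double& W) {
  mat33 Ci = inv_sympd(C);
  double J2 = det(C);
  double J = std::sqrt(J2);
  double I1 = trace(C);
  mat33 I3; I3.eye();

  mat33 S = 2.0 * mp.C10 * (I3 - Ci);
  D.zeros(6, 6);
  add_odot(D, Ci, 4.0 * mp.C10);
  W = mp.C10 * (I1 - 3.0 - std::log(J2));

  const int nt = A.n_rows;
  for (int k = 0; k < nt; ++k) {
    rowvec a = A.row(k);
    double I4 = as_scalar(a * C * a.t());
    double lam = std::sqrt(I4);
    if (lam <= 1.0) continue;
    double g = mp.mum * (std::pow(lam, mp.gm - 2.0) - 1.0 / (lam * lam)) +
               mp.muk * (std::pow(lam, mp.gk - 2.0) - 1.0 / (lam * lam));
    double gp = mp.mum * ((mp.gm - 2.0) * std::pow(lam, mp.gm - 3.0) +
                          2.0 / (lam * lam * lam)) +
                mp.muk * ((mp.gk - 2.0) * std::pow(lam, mp.gk - 3.0) +
                          2.0 / (lam * lam * lam));
    double wgt = phi(k) / nt;
    mat33 aa = a.t() * a;
    S += wgt * g * aa;
    add_oxo(D, aa, aa, wgt * gp / lam);
    W += wgt * (mp.mum / mp.gm * (std::pow(lam, mp.gm) - 1.0) -
                mp.mum * std::log(lam) +
                mp.muk / mp.gk * (std::pow(lam, mp.gk) - 1.0) -
                mp.muk * std::log(lam));
  }
  Sv = voigt(S);
}

}  // namespace

// Assemble internal force and tangent stiffness.
//   nodes: N x 3 reference coordinates;  hex: ne x 8 (1-based);  u: length 3N
//   matpar: C10, gamma_m, mu_m, gamma_k, mu_k, kappa
//   e1, e2: ne x 3 in-plane fiber basis (reference);  phi: ne x ntheta weights
//   thetas: angular grid
// Returns f_int, sparse triplets of K, per-element Jbar, min/max gp J, energy.
// [[Rcpp::export]]
Rcpp::List fem_assemble(const arma::mat& nodes, const arma::imat& hex,
                        const arma::vec& u, const arma::vec& matpar,
                        const arma::mat& e1, const arma::mat& e2,
                        const arma::mat& phi, const arma::vec& thetas) {
  const int ne = hex.n_rows;
  const int N = nodes.n_rows;
  const int nt = thetas.n_elem;
  MatPar mp{matpar(0), matpar(1), matpar(2), matpar(3), matpar(4), matpar(5)};

  vec f(3 * N, fill::zeros);
  std::vector<double> tv; tv.reserve((size_t)ne * 576);
  std::vector<int> ti, tj; ti.reserve((size_t)ne * 576); tj.reserve((size_t)ne * 576);
  vec Jbar_out(ne);
  double Jmin = datum::inf, Jmax = -datum::inf, Wtot = 0.0;

  mat Ag(nt, 3);
  for (int el = 0; el < ne; ++el) {
    // fiber directions for this element
    for (int k = 0; k < nt; ++k)
      Ag.row(k) = std::cos(thetas(k)) * e1.row(el) +
                  std::sin(thetas(k)) * e2.row(el);
    rowvec phie = phi.row(el);

    mat Xe(8, 3), Ue(8, 3);
    ivec cn = hex.row(el).t();
    for (int a = 0; a < 8; ++a) {
      int n0 = cn(a) - 1;
      Xe.row(a) = nodes.row(n0);
      for (int d = 0; d < 3; ++d) Ue(a, d) = u(3 * n0 + d);
    }

    // pass 1: kinematics per gp, element volume and Jbar
    mat dNX[8]; mat33 Fg[8]; double wg[8]; double Jg[8];
    double V0 = 0.0, JV = 0.0;
    bool bad = false;
    for (int q = 0; q < 8; ++q) {
      mat33 J0 = (Xe.t() * GH.dN[q]).t();     // dX/dxi (rows: xi index)
      double dj = det(J0);
      if (dj <= 0) bad = true;
      mat dNdX = GH.dN[q] * inv(J0).t();      // 8 x 3, dN/dX
      mat33 F = eye(3, 3) + Ue.t() * dNdX;    // F_iI = delta_iI + u_ia dN_a/dX_I
      dNX[q] = dNdX; Fg[q] = F; wg[q] = GH.w[q] * dj;
      Jg[q] = det(F);
      if (Jg[q] <= 0) bad = true;
      V0 += wg[q];
      JV += wg[q] * Jg[q];
    }
    if (bad) {
      Rcpp::List out;
      out["ok"] = false; out["bad_element"] = el + 1;
      return out;
    }
    double Jbar = JV / V0;
    Jbar_out(el) = Jbar;
    double pbar = mp.kappa * (Jbar - 1.0);
    Wtot += V0 * 0.5 * mp.kappa * (Jbar - 1.0) * (Jbar - 1.0);

    mat Ke(24, 24, fill::zeros);
    vec fe(24, fill::zeros);
    vec h(24, fill::zeros);                   // d(V0 Jbar)/du

    for (int q = 0; q < 8; ++q) {
      mat33 F = Fg[q];
      mat33 C = F.t() * F;
      mat33 Ci = inv_sympd(C);
      double J = Jg[q];
      Jmin = std::min(Jmin, J); Jmax = std::max(Jmax, J);

      vec Sv; mat D; double Wp;
      point_material(C, mp, Ag, phie, Sv, D, Wp);
      Wtot += wg[q] * Wp;

      // add element-level pressure contribution to S and D
      vec Stv = Sv + voigt(mat33(pbar * J * Ci));
      add_oxo(D, Ci, Ci, pbar * J);
      add_odot(D, Ci, -2.0 * pbar * J);

      // B matrix (6 x 24), dE_v = B du
      mat B(6, 24, fill::zeros);
      const mat& dN = dNX[q];
      for (int a = 0; a < 8; ++a) {
        for (int i = 0; i < 3; ++i) {
          int col = 3 * a + i;
          B(0, col) = F(i, 0) * dN(a, 0);
          B(1, col) = F(i, 1) * dN(a, 1);
          B(2, col) = F(i, 2) * dN(a, 2);
          B(3, col) = F(i, 0) * dN(a, 1) + F(i, 1) * dN(a, 0);
          B(4, col) = F(i, 0) * dN(a, 2) + F(i, 2) * dN(a, 0);
          B(5, col) = F(i, 1) * dN(a, 2) + F(i, 2) * dN(a, 1);
        }
      }

      fe += wg[q] * (B.t() * Stv);
      Ke += wg[q] * (B.t() * D * B);

      // geometric stiffness: delta_ij dN_a . Stot dN_b
      mat33 St;
      for (int p = 0; p < 6; ++p) {
        St(VI[p], VJ[p]) = Stv(p);
        St(VJ[p], VI[p]) = Stv(p);
      }
      mat G = dN * St * dN.t();               // 8 x 8
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b < 8; ++b)
          for (int i = 0; i < 3; ++i)
            Ke(3 * a + i, 3 * b + i) += wg[q] * G(a, b);

      // h accumulates B^T (J Ci)_v  (for the mean-dilatation rank-one term)
      h += wg[q] * (B.t() * voigt(mat33(J * Ci)));
    }
    // rank-one coupling of the element-constant pressure
    Ke += (mp.kappa / V0) * (h * h.t());

    // scatter
    for (int a = 0; a < 8; ++a) {
      int ga = cn(a) - 1;
      for (int i = 0; i < 3; ++i) f(3 * ga + i) += fe(3 * a + i);
    }
    for (int a = 0; a < 8; ++a) for (int i = 0; i < 3; ++i) {
      int ra = 3 * (cn(a) - 1) + i;
      for (int b = 0; b < 8; ++b) for (int j = 0; j < 3; ++j) {
        ti.push_back(ra + 1);
        tj.push_back(3 * (cn(b) - 1) + j + 1);
        tv.push_back(Ke(3 * a + i, 3 * b + j));
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("f_int") = f,
      Rcpp::Named("i") = ti, Rcpp::Named("j") = tj, Rcpp::Named("v") = tv,
      Rcpp::Named("Jbar") = Jbar_out, Rcpp::Named("Jmin") = Jmin,
      Rcpp::Named("Jmax") = Jmax, Rcpp::Named("energy") = Wtot);
}

// Follower pressure on bilinear quad faces of the deformed configuration.
//   faces: nf x 4 (1-based), ordered so that x_,xi x x_,eta is the outward
//   normal of the solid; pressure p (MPa) loads the solid with -p * n da.
// Returns f_ext and triplets of d f_ext / d u.
// [[Rcpp::export]]
Rcpp::List fem_pressure(const arma::mat& nodes, const arma::imat& faces,
                        const arma::vec& u, double p) {
  const int N = nodes.n_rows;
  const int nf = faces.n_rows;
  vec f(3 * N, fill::zeros);
  std::vector<double> tv; std::vector<int> ti, tj;
  tv.reserve((size_t)nf * 144);
  ti.reserve((size_t)nf * 144); tj.reserve((size_t)nf * 144);

  const double g = 1.0 / std::sqrt(3.0);
  const double gx[4] = {-g, g, g, -g}, ge[4] = {-g, -g, g, g};
  const double sx[4] = {-1, 1, 1, -1}, se[4] = {-1, -1, 1, 1};

  for (int fc = 0; fc < nf; ++fc) {
    mat xe(4, 3);
    ivec cn = faces.row(fc).t();
    for (int a = 0; a < 4; ++a) {
      int n0 = cn(a) - 1;
      for (int d = 0; d < 3; ++d) xe(a, d) = nodes(n0, d) + u(3 * n0 + d);
    }
    mat fe(4, 3, fill::zeros);
    mat Kf(12, 12, fill::zeros);
    for (int q = 0; q < 4; ++q) {
      double xi = gx[q], eta = ge[q];
      vec Nq(4), Nxi(4), Neta(4);
      for (int a = 0; a < 4; ++a) {
        Nq(a) = (1 + sx[a] * xi) * (1 + se[a] * eta) / 4.0;
        Nxi(a) = sx[a] * (1 + se[a] * eta) / 4.0;
        Neta(a) = se[a] * (1 + sx[a] * xi) / 4.0;
      }
      vec3 xxi = xe.t() * Nxi, xeta = xe.t() * Neta;
      vec3 nda = cross(xxi, xeta);
      for (int a = 0; a < 4; ++a)
        fe.row(a) += (-p * Nq(a)) * nda.t();
      // load stiffness: d(nda)/du_b = -N_b,xi [xeta]x + N_b,eta [xxi]x
      mat33 Xeta = {{0, -xeta(2), xeta(1)}, {xeta(2), 0, -xeta(0)},
                    {-xeta(1), xeta(0), 0}};
      mat33 Xxi = {{0, -xxi(2), xxi(1)}, {xxi(2), 0, -xxi(0)},
                   {-xxi(1), xxi(0), 0}};
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          mat33 blk = (-p * Nq(a)) * (-Nxi(b) * Xeta + Neta(b) * Xxi);
          Kf.submat(3 * a, 3 * b, 3 * a + 2, 3 * b + 2) += blk;
        }
    }
    for (int a = 0; a < 4; ++a) {
      int ga = cn(a) - 1;
      for (int d = 0; d < 3; ++d) f(3 * ga + d) += fe(a, d);
    }
    for (int a = 0; a < 4; ++a) for (int i = 0; i < 3; ++i)
      for (int b = 0; b < 4; ++b) for (int j = 0; j < 3; ++j) {
        ti.push_back(3 * (cn(a) - 1) + i + 1);
        tj.push_back(3 * (cn(b) - 1) + j + 1);
        tv.push_back(Kf(3 * a + i, 3 * b + j));
      }
  }
  return Rcpp::List::create(Rcpp::Named("f_ext") = f, Rcpp::Named("i") = ti,
                            Rcpp::Named("j") = tj, Rcpp::Named("v") = tv);
}

// Per-Gauss-point stress/strain recovery at a converged state.
// Returns Cauchy stress (Voigt, MPa), von Mises, principal Green strains,
// J, reference-volume weights, gp positions (reference), element ids.
// [[Rcpp::export]]
Rcpp::List fem_stress(const arma::mat& nodes, const arma::imat& hex,
                      const arma::vec& u, const arma::vec& matpar,
                      const arma::mat& e1, const arma::mat& e2,
                      const arma::mat& phi, const arma::vec& thetas) {
  const int ne = hex.n_rows;
  const int nt = thetas.n_elem;
  MatPar mp{matpar(0), matpar(1), matpar(2), matpar(3), matpar(4), matpar(5)};
  const int ng = ne * 8;
  mat cauchy(ng, 6), gpX(ng, 3);
  vec vm(ng), Jout(ng), wout(ng), emax(ng), emid(ng), emin(ng);
  ivec elem(ng);

  mat Ag(nt, 3);
  // gp shape values for positions
  mat Nq(8, 8);
  {
    const double g = 1.0 / std::sqrt(3.0);
    const double sg[8][3] = {{-1,-1,-1},{1,-1,-1},{1,1,-1},{-1,1,-1},
                             {-1,-1,1},{1,-1,1},{1,1,1},{-1,1,1}};
    for (int q = 0; q < 8; ++q)
      for (int a = 0; a < 8; ++a)
        Nq(q, a) = (1 + sg[a][0] * g * sg[q][0]) *
                   (1 + sg[a][1] * g * sg[q][1]) *
                   (1 + sg[a][2] * g * sg[q][2]) / 8.0;
  }

  for (int el = 0; el < ne; ++el) {
    for (int k = 0; k < nt; ++k)
      Ag.row(k) = std::cos(thetas(k)) * e1.row(el) +
                  std::sin(thetas(k)) * e2.row(el);
    rowvec phie = phi.row(el);
    mat Xe(8, 3), Ue(8, 3);
    ivec cn = hex.row(el).t();
    for (int a = 0; a < 8; ++a) {
      int n0 = cn(a) - 1;
      Xe.row(a) = nodes.row(n0);
      for (int d = 0; d < 3; ++d) Ue(a, d) = u(3 * n0 + d);
    }
    // Jbar first
    double V0 = 0, JV = 0;
    mat33 Fg[8]; double wg[8];
    for (int q = 0; q < 8; ++q) {
      mat33 J0 = (Xe.t() * GH.dN[q]).t();
      mat dNdX = GH.dN[q] * inv(J0).t();
      mat33 F = eye(3, 3) + Ue.t() * dNdX;
      Fg[q] = F; wg[q] = det(J0);
      V0 += wg[q]; JV += wg[q] * det(F);
    }
    double pbar = mp.kappa * (JV / V0 - 1.0);

    for (int q = 0; q < 8; ++q) {
      mat33 F = Fg[q];
      mat33 C = F.t() * F;
      mat33 Ci = inv_sympd(C);
      double J = det(F);
      vec Sv; mat D; double Wp;
      point_material(C, mp, Ag, phie, Sv, D, Wp);
      mat33 S;
      for (int p = 0; p < 6; ++p) {
        S(VI[p], VJ[p]) = Sv(p); S(VJ[p], VI[p]) = Sv(p);
      }
      S += pbar * J * Ci;
      mat33 sig = F * S * F.t() / J;
      int gidx = el * 8 + q;
      cauchy.row(gidx) = voigt(sig).t();
      mat33 sdev = sig - eye(3, 3) * (trace(sig) / 3.0);
      vm(gidx) = std::sqrt(1.5 * accu(sdev % sdev));
      mat33 E = 0.5 * (C - eye(3, 3));
      vec ev = eig_sym(E);
      emin(gidx) = ev(0); emid(gidx) = ev(1); emax(gidx) = ev(2);
      Jout(gidx) = J;
      wout(gidx) = wg[q];
      gpX.row(gidx) = Nq.row(q) * Xe;
      elem(gidx) = el + 1;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("cauchy") = cauchy, Rcpp::Named("von_mises") = vm,
      Rcpp::Named("strain_max") = emax, Rcpp::Named("strain_min") = emin,
      Rcpp::Named("J") = Jout, Rcpp::Named("weight") = wout,
      Rcpp::Named("gp_x") = gpX, Rcpp::Named("elem") = elem);
}
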
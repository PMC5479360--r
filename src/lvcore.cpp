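#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Quadratic (10-node) tetrahedron shape functions in barycentric coordinates.
// Node order: 4 vertices, then edge midpoints (1,2),(1,3),(1,4),(2,3),(2,4),(3,4).
// ---------------------------------------------------------------------------
static const int TET_EDGE[6][2] = {{0,1},{0,2},{0,3},{1,2},{1,3},{2,3}};

static void tet10_shape(const double l[4], arma::vec &N, arma::mat &dNdL) {
  for (int i = 0; i < 4; i++) {
    N(i) = l[i] * (2.0 * l[i] - 1.0);
    for (int j = 0; j < 4; j++) dNdL(i, j) = 0.0;
    dNdL(i, i) = 4.0 * l[i] - 1.0;
  }
  for (int e = 0; e < 6; e++) {
    int i = TET_EDGE[e][0], j = TET_EDGE[e][1];
    N(4 + e) = 4.0 * l[i] * l[j];
    for (int k = 0; k < 4; k++) dNdL(4 + e, k) = 0.0;
    dNdL(4 + e, i) = 4.0 * l[j];
    dNdL(4 + e, j) = 4.0 * l[i];
  }
}

// 14-point degree-5 rule on the tetrahedron; barycentric points, weights sum 1.
static const int NQT = 14;
static void tet_quadrature(double QL[NQT][4], double QW[NQT]) {
  const double a1 = 0.0673422422100983, b1 = 0.3108859192633005,
               a2 = 0.7217942490673264, b2 = 0.0927352503108912,
               aa = 0.0455037041256497, bb = 0.4544962958743504,
               w1 = 0.1126879257180162, w2 = 0.0734930431163619,
               w3 = 0.0425460207770812;
  int k = 0;
  for (int i = 0; i < 4; i++, k++) {
    for (int j = 0; j < 4; j++) QL[k][j] = (j == i) ? a1 : b1;
    QW[k] = w1;
  }
  for (int i = 0; i < 4; i++, k++) {
    for (int j = 0; j < 4; j++) QL[k][j] = (j == i) ? a2 : b2;
    QW[k] = w2;
  }
  for (int e = 0; e < 6; e++, k++) {
    for (int j = 0; j < 4; j++) QL[k][j] = bb;
    QL[k][TET_EDGE[e][0]] = aa;
    QL[k][TET_EDGE[e][1]] = aa;
    QW[k] = w3;
  }
}

// 6-point degree-4 rule on the triangle (barycentric, weights sum 1).
static const int NQS = 6;
static void tri_quadrature(double QL[NQS][3], double QW[NQS]) {
  const double a1 = 0.108103018168070, b1 = 0.445948490915965,
               a2 = 0.816847572980459, b2 = 0.091576213509771,
               w1 = 0.223381589678011, w2 = 0.109951743655322;
  int k = 0;
  for (int i = 0; i < 3; i++, k++) {
    for (int j = 0; j < 3; j++) QL[k][j] = (j == i) ? a1 : b1;
    QW[k] = w1;
  }
  for (int i = 0; i < 3; i++, k++) {
    for (int j = 0; j < 3; j++) QL[k][j] = (j == i) ? a2 : b2;
    QW[k] = w2;
  }
}

// Quadratic (6-node) triangle: vertices then midpoints (1,2),(1,3),(2,3).
static void tri6_shape(const double l[3], arma::vec &N) {
  N(0) = l[0] * (2 * l[0] - 1);
  N(1) = l[1] * (2 * l[1] - 1);
  N(2) = l[2] * (2 * l[2] - 1);
  N(3) = 4 * l[0] * l[1];
  N(4) = 4 * l[0] * l[2];
  N(5) = 4 * l[1] * l[2];
}

// ---------------------------------------------------------------------------
// Mechanics assembly: residual and tangent of the internal energy
//   Pi_int = int Psi(F) + p (J - 1) dV
// with the reduced Holzapfel-Ogden energy
//   Psi = a/(2b) (exp(b (II_F - 3)) - 1) + af/(2bf) (exp(bf (II_Ff - 1)^2) - 1).
// Displacement quadratic, pressure linear, straight-edged elements.
// Returns residual blocks, stiffness triplets (0-based dof numbering:
// u dof = 3*node + comp, p dof = vertex id), and kinematic diagnostics.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List asm_mech(const arma::mat &coords, const arma::imat &tet10,
              const arma::vec &u, const arma::vec &p, const arma::mat &f0n,
              double a, double b, double af, double bf, double kappa,
              bool want_matrix = true) {
  const int ne = tet10.n_cols, nq = coords.n_cols, nv = p.n_elem;
  double QL[NQT][4], QW[NQT];
  tet_quadrature(QL, QW);

  arma::vec fu(3 * nq, arma::fill::zeros);
  arma::vec fp(nv, arma::fill::zeros);

  std::vector<int> kuu_i, kuu_j, kup_i, kup_j;
  std::vector<double> kuu_x, kup_x;
  if (want_matrix) {
    kuu_i.reserve((size_t)ne * 900); kuu_j.reserve((size_t)ne * 900);
    kuu_x.reserve((size_t)ne * 900);
    kup_i.reserve((size_t)ne * 120); kup_j.reserve((size_t)ne * 120);
    kup_x.reserve((size_t)ne * 120);
  }

  double jmin = arma::datum::inf, jmax = -arma::datum::inf;
  double energy = 0.0, wallvol = 0.0;
  bool ok = true;

  arma::vec N(10);
  arma::mat dNdL(10, 4), dNdx(10, 3), G(4, 3);
  arma::mat Xe(3, 10), Ue(3, 10), F0e(3, 10);
  arma::mat F(3, 3), P(3, 3), A(9, 9), B(9, 30), Ke(30, 30), Kup_e(30, 4);
  arma::mat fue(3, 10);
  arma::vec fpe(4);
  const arma::mat I3 = arma::eye(3, 3);
  const arma::mat I9 = arma::eye(9, 9);

  for (int e = 0; e < ne && ok; e++) {
    arma::ivec ids = tet10.col(e);
    for (int anode = 0; anode < 10; anode++) {
      int n = ids(anode);
      Xe.col(anode) = coords.col(n);
      for (int c = 0; c < 3; c++) Ue(c, anode) = u(3 * n + c);
      F0e.col(anode) = f0n.col(n);
    }
    arma::mat Jg(3, 3);
    for (int c = 0; c < 3; c++) Jg.col(c) = Xe.col(c + 1) - Xe.col(0);
    double detJ = arma::det(Jg);
    if (detJ <= 0) stop("inverted element %d (det = %g)", e + 1, detJ);
    arma::mat Ji = arma::inv(Jg);
    // gradients of barycentric coordinates: lambda_{2..4} = Ji rows, lambda_1 = -sum
    for (int r = 0; r < 3; r++) G.row(r + 1) = Ji.row(r);
    G.row(0) = -(G.row(1) + G.row(2) + G.row(3));

    Ke.zeros(); Kup_e.zeros(); fue.zeros(); fpe.zeros();

    for (int q = 0; q < NQT; q++) {
      tet10_shape(QL[q], N, dNdL);
      dNdx = dNdL * G;  // 10 x 3
      F = Ue * dNdx + I3;
      double J = arma::det(F);
      if (J < jmin) jmin = J;
      if (J > jmax) jmax = J;
      if (J <= 0 || !std::isfinite(J)) { ok = false; break; }
      double w = QW[q] * detJ / 6.0;
      wallvol += w * J;

      arma::vec f0q = F0e * N;
      double f0nrm = arma::norm(f0q);
      if (f0nrm > 1e-12) f0q /= f0nrm; else f0q = {0, 0, 1};

      double pq = 0.0;
      for (int vtx = 0; vtx < 4; vtx++) pq += p(ids(vtx)) * QL[q][vtx];

      double IIF = arma::accu(F % F);
      arma::vec h = F * f0q;
      double kap = arma::dot(h, h);
      double e1 = a * std::exp(b * (IIF - 3.0));
      double g = kap - 1.0;
      double wf = std::exp(bf * g * g);
      double c1 = 2.0 * af * g * wf;
      arma::mat Finv = arma::inv(F);
      arma::mat FinvT = Finv.t();

      // augmented-Lagrangian quasi-incompressibility penalty kappa/2 (J-1)^2
      double peff = pq + kappa * (J - 1.0);
      P = e1 * F + c1 * (h * f0q.t()) + peff * J * FinvT;
      energy += w * (a / (2 * b) * (std::exp(b * (IIF - 3.0)) - 1.0) +
                     af / (2 * bf) * (wf - 1.0) + pq * (J - 1.0) +
                     0.5 * kappa * (J - 1.0) * (J - 1.0));

      fue += w * (P * dNdx.t());
      for (int vtx = 0; vtx < 4; vtx++) fpe(vtx) += w * (J - 1.0) * QL[q][vtx];

      if (want_matrix) {
        arma::vec vF = arma::vectorise(F);
        arma::vec vh = arma::vectorise(h * f0q.t());
        arma::vec bvec = J * arma::vectorise(FinvT);
        double c2 = 2.0 * af * wf * (1.0 + 2.0 * bf * g * g);
        A = e1 * I9 + (2.0 * b * e1) * (vF * vF.t()) +
            c1 * arma::kron(f0q * f0q.t(), I3) + (2.0 * c2) * (vh * vh.t());
        // pressure + penalty terms: (pq + kappa (J-1)) d(J F^-T)/dF
        //                            + kappa (J F^-T) x (J F^-T)
        A += ((peff / J) + kappa) * (bvec * bvec.t());
        for (int i = 0; i < 3; i++)
          for (int Jj = 0; Jj < 3; Jj++)
            for (int k = 0; k < 3; k++)
              for (int L = 0; L < 3; L++)
                A(i + 3 * Jj, k + 3 * L) -= peff * J * FinvT(i, L) * FinvT(k, Jj);

        B.zeros();
        for (int anode = 0; anode < 10; anode++)
          for (int i = 0; i < 3; i++)
            for (int Jj = 0; Jj < 3; Jj++)
              B(i + 3 * Jj, 3 * anode + i) = dNdx(anode, Jj);

        Ke += w * (B.t() * (A * B));
        arma::vec Bb = B.t() * bvec;  // 30
        for (int vtx = 0; vtx < 4; vtx++)
          Kup_e.col(vtx) += (w * QL[q][vtx]) * Bb;
      }
    }
    if (!ok) break;

    for (int anode = 0; anode < 10; anode++) {
      int gn = ids(anode);
      for (int c = 0; c < 3; c++) fu(3 * gn + c) += fue(c, anode);
    }
    for (int vtx = 0; vtx < 4; vtx++) fp(ids(vtx)) += fpe(vtx);

    if (want_matrix) {
      for (int aa = 0; aa < 30; aa++) {
        int ga = 3 * ids(aa / 3) + aa % 3;
        for (int bb = 0; bb < 30; bb++) {
          double v = Ke(aa, bb);
          if (v != 0.0) {
            kuu_i.push_back(ga);
            kuu_j.push_back(3 * ids(bb / 3) + bb % 3);
            kuu_x.push_back(v);
          }
        }
        for (int vtx = 0; vtx < 4; vtx++) {
          double v = Kup_e(aa, vtx);
          if (v != 0.0) {
            kup_i.push_back(ga);
            kup_j.push_back(ids(vtx));
            kup_x.push_back(v);
          }
        }
      }
    }
  }

  return List::create(
      _["ok"] = ok, _["fu"] = fu, _["fp"] = fp,
      _["kuu_i"] = wrap(kuu_i), _["kuu_j"] = wrap(kuu_j), _["kuu_x"] = wrap(kuu_x),
      _["kup_i"] = wrap(kup_i), _["kup_j"] = wrap(kup_j), _["kup_x"] = wrap(kup_x),
      _["jmin"] = jmin, _["jmax"] = jmax, _["energy"] = energy,
      _["wall_volume"] = wallvol);
}

// Deformed wall volume int J dV only (no material needed).
// [[Rcpp::export]]
double wall_volume_p2(const arma::mat &coords, const arma::imat &tet10,
                      const arma::vec &u) {
  const int ne = tet10.n_cols;
  double QL[NQT][4], QW[NQT];
  tet_quadrature(QL, QW);
  arma::vec N(10);
  arma::mat dNdL(10, 4), G(4, 3);
  arma::mat Xe(3, 10), Ue(3, 10);
  const arma::mat I3 = arma::eye(3, 3);
  double vol = 0.0;
  for (int e = 0; e < ne; e++) {
    arma::ivec ids = tet10.col(e);
    for (int anode = 0; anode < 10; anode++) {
      int n = ids(anode);
      Xe.col(anode) = coords.col(n);
      for (int c = 0; c < 3; c++) Ue(c, anode) = u(3 * n + c);
    }
    arma::mat Jg(3, 3);
    for (int c = 0; c < 3; c++) Jg.col(c) = Xe.col(c + 1) - Xe.col(0);
    double detJ = arma::det(Jg);
    arma::mat Ji = arma::inv(Jg);
    for (int r = 0; r < 3; r++) G.row(r + 1) = Ji.row(r);
    G.row(0) = -(G.row(1) + G.row(2) + G.row(3));
    for (int q = 0; q < NQT; q++) {
      tet10_shape(QL[q], N, dNdL);
      arma::mat F = Ue * (dNdL * G) + I3;
      vol += QW[q] * detJ / 6.0 * arma::det(F);
    }
  }
  return vol;
}

// Per-element range of det F over quadrature points.
// [[Rcpp::export]]
arma::mat detF_range(const arma::mat &coords, const arma::imat &tet10,
                     const arma::vec &u) {
  const int ne = tet10.n_cols;
  double QL[NQT][4], QW[NQT];
  tet_quadrature(QL, QW);
  arma::vec N(10);
  arma::mat dNdL(10, 4), G(4, 3);
  arma::mat Xe(3, 10), Ue(3, 10);
  const arma::mat I3 = arma::eye(3, 3);
  arma::mat out(2, ne);
  for (int e = 0; e < ne; e++) {
    arma::ivec ids = tet10.col(e);
    for (int anode = 0; anode < 10; anode++) {
      int n = ids(anode);
      Xe.col(anode) = coords.col(n);
      for (int c = 0; c < 3; c++) Ue(c, anode) = u(3 * n + c);
    }
    arma::mat Jg(3, 3);
    for (int c = 0; c < 3; c++) Jg.col(c) = Xe.col(c + 1) - Xe.col(0);
    arma::mat Ji = arma::inv(Jg);
    for (int r = 0; r < 3; r++) G.row(r + 1) = Ji.row(r);
    G.row(0) = -(G.row(1) + G.row(2) + G.row(3));
    double jlo = arma::datum::inf, jhi = -arma::datum::inf;
    for (int q = 0; q < NQT; q++) {
      tet10_shape(QL[q], N, dNdL);
      double J = arma::det(Ue * (dNdL * G) + I3);
      if (J < jlo) jlo = J;
      if (J > jhi) jhi = J;
    }
    out(0, e) = jlo; out(1, e) = jhi;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cavity volume, gradient and Hessian. The cavity boundary is a list of
// straight triangles over mesh nodes (endocardial sub-triangles, oriented
// outward from the cavity) closed by a fan from the centroid of the basal
// endocardial ring. V = sum det(xa, xb, xc) / 6 over oriented triangles.
// ---------------------------------------------------------------------------
static inline arma::mat skew(const arma::vec &v) {
  arma::mat S(3, 3, arma::fill::zeros);
  S(0, 1) = -v(2); S(0, 2) = v(1);
  S(1, 0) = v(2);  S(1, 2) = -v(0);
  S(2, 0) = -v(1); S(2, 1) = v(0);
  return S;
}

// [[Rcpp::export]]
List cavity_terms(const arma::mat &coords, const arma::vec &u,
                  const arma::imat &tris, const arma::ivec &ring,
                  bool want_hessian = true) {
  const int nq = coords.n_cols, nt = tris.n_cols, m = ring.n_elem;
  arma::mat x(3, nq);
  for (int n = 0; n < nq; n++)
    for (int c = 0; c < 3; c++) x(c, n) = coords(c, n) + u(3 * n + c);

  arma::vec cen(3, arma::fill::zeros);
  for (int k = 0; k < m; k++) cen += x.col(ring(k));
  cen /= m;

  double V = 0.0;
  arma::vec grad(3 * nq, arma::fill::zeros);
  std::vector<int> hi, hj;
  std::vector<double> hx;

  auto push_block = [&](int na, int nb, const arma::mat &M) {
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++)
        if (M(i, j) != 0.0) {
          hi.push_back(3 * na + i);
          hj.push_back(3 * nb + j);
          hx.push_back(M(i, j));
        }
  };

  // plain node triangles
  for (int t = 0; t < nt; t++) {
    int na = tris(0, t), nb = tris(1, t), nc = tris(2, t);
    arma::vec xa = x.col(na), xb = x.col(nb), xc = x.col(nc);
    V += arma::dot(xa, arma::cross(xb, xc)) / 6.0;
    grad.subvec(3 * na, 3 * na + 2) += arma::cross(xb, xc) / 6.0;
    grad.subvec(3 * nb, 3 * nb + 2) += arma::cross(xc, xa) / 6.0;
    grad.subvec(3 * nc, 3 * nc + 2) += arma::cross(xa, xb) / 6.0;
    if (want_hessian) {
      arma::mat Sa = skew(xa) / 6.0, Sb = skew(xb) / 6.0, Sc = skew(xc) / 6.0;
      push_block(na, nb, -Sc); push_block(nb, na, Sc);
      push_block(na, nc, Sb);  push_block(nc, na, -Sb);
      push_block(nb, nc, -Sa); push_block(nc, nb, Sa);
    }
  }

  // cap fan: (centroid, ring_k, ring_{k+1}); centroid = mean of ring nodes
  for (int k = 0; k < m; k++) {
    int n1 = ring(k), n2 = ring((k + 1) % m);
    arma::vec x1 = x.col(n1), x2 = x.col(n2);
    V += arma::dot(cen, arma::cross(x1, x2)) / 6.0;
    arma::vec gc = arma::cross(x1, x2) / 6.0;
    for (int r = 0; r < m; r++)
      grad.subvec(3 * ring(r), 3 * ring(r) + 2) += gc / m;
    grad.subvec(3 * n1, 3 * n1 + 2) += arma::cross(x2, cen) / 6.0;
    grad.subvec(3 * n2, 3 * n2 + 2) += arma::cross(cen, x1) / 6.0;
    if (want_hessian) {
      arma::mat Sc0 = skew(cen) / 6.0, S1 = skew(x1) / 6.0, S2 = skew(x2) / 6.0;
      // blocks of det(cen, x1, x2)/6 with (a,b,c) = (cen, x1, x2)
      // d2/dcen dx1 = -S2 ; d2/dcen dx2 = S1 ; d2/dx1 dx2 = -Sc0
      for (int r = 0; r < m; r++) {
        push_block(ring(r), n1, -S2 / m); push_block(n1, ring(r), S2 / m);
        push_block(ring(r), n2, S1 / m);  push_block(n2, ring(r), -S1 / m);
      }
      push_block(n1, n2, -Sc0); push_block(n2, n1, Sc0);
    }
  }

  return List::create(_["V"] = V, _["grad"] = grad,
                      _["hi"] = wrap(hi), _["hj"] = wrap(hj), _["hx"] = wrap(hx));
}

// ---------------------------------------------------------------------------
// Surface mass matrix on quadratic boundary triangles (scalar, straight
// facets), optionally weighted by a nodal field w: M_ab = int w N_a N_b dA.
// Triplets in global node numbering.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List surf_mass(const arma::mat &coords, const arma::imat &tri6,
               const arma::vec &wnode) {
  const int nt = tri6.n_cols;
  double QL[NQS][3], QW[NQS];
  tri_quadrature(QL, QW);
  std::vector<int> mi, mj;
  std::vector<double> mx;
  mi.reserve((size_t)nt * 36); mj.reserve((size_t)nt * 36);
  mx.reserve((size_t)nt * 36);
  arma::vec N(6);
  for (int t = 0; t < nt; t++) {
    arma::ivec ids = tri6.col(t);
    arma::vec v1 = coords.col(ids(0)), v2 = coords.col(ids(1)),
              v3 = coords.col(ids(2));
    double area = arma::norm(arma::cross(v2 - v1, v3 - v1)) / 2.0;
    arma::mat Me(6, 6, arma::fill::zeros);
    for (int q = 0; q < NQS; q++) {
      tri6_shape(QL[q], N);
      double wq = 0.0;
      for (int c = 0; c < 6; c++) wq += wnode(ids(c)) * N(c);
      Me += (QW[q] * area * wq) * (N * N.t());
    }
    for (int aa = 0; aa < 6; aa++)
      for (int bb = 0; bb < 6; bb++)
        if (Me(aa, bb) != 0.0) {
          mi.push_back(ids(aa)); mj.push_back(ids(bb)); mx.push_back(Me(aa, bb));
        }
  }
  return List::create(_["i"] = wrap(mi), _["j"] = wrap(mj), _["x"] = wrap(mx));
}

// Scalar quadratic mass matrix over the volume (for L2 norms of fields).
// [[Rcpp::export]]
List mass_p2(const arma::mat &coords, const arma::imat &tet10) {
  const int ne = tet10.n_cols;
  double QL[NQT][4], QW[NQT];
  tet_quadrature(QL, QW);
  std::vector<int> mi, mj;
  std::vector<double> mx;
  mi.reserve((size_t)ne * 100); mj.reserve((size_t)ne * 100);
  mx.reserve((size_t)ne * 100);
  arma::vec N(10);
  arma::mat dNdL(10, 4);
  for (int e = 0; e < ne; e++) {
    arma::ivec ids = tet10.col(e);
    arma::mat Jg(3, 3);
    for (int c = 0; c < 3; c++)
      Jg.col(c) = coords.col(ids(c + 1)) - coords.col(ids(0));
    double detJ = arma::det(Jg);
    arma::mat Me(10, 10, arma::fill::zeros);
    for (int q = 0; q < NQT; q++) {
      tet10_shape(QL[q], N, dNdL);
      Me += (QW[q] * detJ / 6.0) * (N * N.t());
    }
    for (int aa = 0; aa < 10; aa++)
      for (int bb = 0; bb < 10; bb++) {
        mi.push_back(ids(aa)); mj.push_back(ids(bb)); mx.push_back(Me(aa, bb));
      }
  }
  return List::create(_["i"] = wrap(mi), _["j"] = wrap(mj), _["x"] = wrap(mx));
}

// ---------------------------------------------------------------------------
// Distance from points to a triangulated surface; returns distances and
// closest points (used for the transmural coordinate).
// ---------------------------------------------------------------------------
static arma::vec closest_on_triangle(const arma::vec &pp, const arma::vec &a,
                                     const arma::vec &b, const arma::vec &c) {
  // Ericson's real-time collision detection algorithm
  arma::vec ab = b - a, ac = c - a, ap = pp - a;
  double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  arma::vec bp = pp - b;
  double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return a + (d1 / (d1 - d3)) * ab;
  arma::vec cp = pp - c;
  double d5 = arma::dot(ab, cp), d6 = arma::dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return a + (d2 / (d2 - d6)) * ac;
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b);
  double denom = 1.0 / (va + vb + vc);
  return a + ab * (vb * denom) + ac * (vc * denom);
}

// [[Rcpp::export]]
List dist_to_surface(const arma::mat &pts, const arma::mat &tv) {
  const int np = pts.n_cols, nt = tv.n_cols;
  arma::vec d(np);
  arma::mat cp(3, np);
  for (int ip = 0; ip < np; ip++) {
    arma::vec pp = pts.col(ip);
    double best = arma::datum::inf;
    arma::vec bestp(3, arma::fill::zeros);
    for (int t = 0; t < nt; t++) {
      arma::vec q = closest_on_triangle(pp, tv.col(t).subvec(0, 2),
                                        tv.col(t).subvec(3, 5),
                                        tv.col(t).subvec(6, 8));
      double dd = arma::norm(pp - q);
      if (dd < best) { best = dd; bestp = q; }
    }
    d(ip) = best;
    cp.col(ip) = bestp;
  }
  return List::create(_["dist"] = d, _["closest"] = cp);
}

// Ray / triangle-soup intersection (Moller-Trumbore); returns smallest
// positive ray parameter per ray or Inf. Used for wall-thickness rays.
// [[Rcpp::export]]
arma::vec ray_surface_hits(const arma::mat &orig, const arma::mat &dir,
                           const arma::mat &tv) {
  const int nr = orig.n_cols, nt = tv.n_cols;
  arma::vec out(nr);
  for (int r = 0; r < nr; r++) {
    arma::vec o = orig.col(r), d = dir.col(r);
    double best = arma::datum::inf;
    for (int t = 0; t < nt; t++) {
      arma::vec v0 = tv.col(t).subvec(0, 2);
      arma::vec e1 = tv.col(t).subvec(3, 5) - v0;
      arma::vec e2 = tv.col(t).subvec(6, 8) - v0;
      arma::vec pv = arma::cross(d, e2);
      double det = arma::dot(e1, pv);
      if (std::fabs(det) < 1e-14) continue;
      arma::vec tvv = o - v0;
      double uu = arma::dot(tvv, pv) / det;
      if (uu < -1e-9 || uu > 1 + 1e-9) continue;
      arma::vec qv = arma::cross(tvv, e1);
      double vv = arma::dot(d, qv) / det;
      if (vv < -1e-9 || uu + vv > 1 + 1e-9) continue;
      double tt = arma::dot(e2, qv) / det;
      if (tt > 1e-9 && tt < best) best = tt;
    }
    out(r) = best;
  }
  return out;
}
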
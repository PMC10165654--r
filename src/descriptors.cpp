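// Atomic fingerprints for the neural-network potential: 5 two-body radial
// descriptors and 5 three-body angular descriptors with smooth cosine cutoffs,
// plus their analytic position derivatives in the three contraction patterns
// the package needs (forces/virial, training residual contraction, and a dense
// Jacobian for small systems).
#include "icenuc.h"
using namespace Rcpp;

static inline double fcut(double r, double rc) {
  if (r >= rc) return 0.0;
  return 0.5 * (1.0 + std::cos(M_PI * r / rc));
}
static inline double dfcut(double r, double rc) {
  if (r >= rc) return 0.0;
  return -0.5 * M_PI / rc * std::sin(M_PI * r / rc);
}

// mode: 0 values only; 1 force contraction (A in); 2 residual contraction
// (Rm in); 3 dense jacobian
static List afs_core(NumericMatrix pos, NumericVector box,
                     NumericMatrix af2, NumericMatrix af3,
                     int mode, NumericMatrix A, NumericMatrix Rm) {
  int N = pos.nrow();
  int n2 = af2.nrow(), n3 = af3.nrow(), nd = n2 + n3;
  double bx[3] = {box[0], box[1], box[2]};
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);

  double rmax = 0.0;
  for (int k = 0; k < n2; ++k) rmax = std::max(rmax, af2(k, 2));
  for (int k = 0; k < n3; ++k) rmax = std::max(rmax, af3(k, 3));
  NeighVec nl;
  build_neigh(x, N, bx, rmax, nl);

  NumericMatrix G(N, nd);
  NumericMatrix F(mode == 1 ? N : 1, 3);
  double W = 0.0;
  NumericMatrix V(mode == 2 ? N : 1, mode == 2 ? nd : 1);
  NumericVector J(mode == 3 ? (R_xlen_t)N * nd * 3 * N : 1);
  // J index helper: dG[i,k]/dx[a,al] at i + N*k + N*nd*(a + N*al)
  #define JIDX(i, k, a, al) ((R_xlen_t)(i) + (R_xlen_t)N * (k) + \
                             (R_xlen_t)N * nd * ((a) + (R_xlen_t)N * (al)))

  double d1[3], d2[3];
  // ---- two-body ----
  for (int i = 0; i < N; ++i) {
    for (size_t u = 0; u < nl[i].size(); ++u) {
      int j = nl[i][u];
      if (j < i) continue;
      min_image(d1, &x[3 * i], &x[3 * j], bx);
      double r = std::sqrt(d1[0] * d1[0] + d1[1] * d1[1] + d1[2] * d1[2]);
      for (int k = 0; k < n2; ++k) {
        double Rs = af2(k, 0), w = af2(k, 1), rc = af2(k, 2);
        if (r >= rc) continue;
        double E = std::exp(-(r - Rs) * (r - Rs) / (w * w));
        double fc = fcut(r, rc);
        double g = E * fc;
        G(i, k) += g; G(j, k) += g;
        if (mode == 0) continue;
        double gp = E * (-2.0 * (r - Rs) / (w * w) * fc + dfcut(r, rc));
        if (mode == 1) {
          double coef = (A(i, k) + A(j, k)) * gp;
          for (int m = 0; m < 3; ++m) {
            double f = -coef * d1[m] / r;  // force on j
            F(j, m) += f; F(i, m) -= f;
            W += d1[m] * f;
          }
        } else if (mode == 2) {
          double dot = 0.0;
          for (int m = 0; m < 3; ++m)
            dot += gp * d1[m] / r * (Rm(j, m) - Rm(i, m));
          V(i, k) += dot; V(j, k) += dot;
        } else {
          for (int m = 0; m < 3; ++m) {
            double der = gp * d1[m] / r;  // dG_i[k]/dx_j[m]
            J[JIDX(i, k, j, m)] += der; J[JIDX(i, k, i, m)] -= der;
            J[JIDX(j, k, j, m)] += der; J[JIDX(j, k, i, m)] -= der;
          }
        }
      }
    }
  }
  // ---- three-body ----
  for (int i = 0; i < N; ++i) {
    int nn = nl[i].size();
    for (int u = 0; u < nn; ++u) {
      int j = nl[i][u];
      min_image(d1, &x[3 * i], &x[3 * j], bx);
      double r1 = std::sqrt(d1[0] * d1[0] + d1[1] * d1[1] + d1[2] * d1[2]);
      for (int v = u + 1; v < nn; ++v) {
        int kk = nl[i][v];
        min_image(d2, &x[3 * i], &x[3 * kk], bx);
        double r2 = std::sqrt(d2[0] * d2[0] + d2[1] * d2[1] + d2[2] * d2[2]);
        double c = (d1[0] * d2[0] + d1[1] * d2[1] + d1[2] * d2[2]) / (r1 * r2);
        for (int k = 0; k < n3; ++k) {
          double zeta = af3(k, 0), lam = af3(k, 1), w3 = af3(k, 2),
                 rc = af3(k, 3);
          if (r1 >= rc || r2 >= rc) continue;
          double base = 1.0 + lam * c;
          if (base < 1e-12) base = 1e-12;
          double P = std::pow(2.0, 1.0 - zeta) * std::pow(base, zeta);
          double E1 = std::exp(-r1 * r1 / (w3 * w3));
          double E2 = std::exp(-r2 * r2 / (w3 * w3));
          double f1 = fcut(r1, rc), f2 = fcut(r2, rc);
          double t = P * E1 * E2 * f1 * f2;
          int col = n2 + k;
          G(i, col) += t;
          if (mode == 0) continue;
          double dtdc = std::pow(2.0, 1.0 - zeta) * zeta * lam *
                        std::pow(base, zeta - 1.0) * E1 * E2 * f1 * f2;
          double dtdr1 = P * E2 * f2 *
                         (E1 * (-2.0 * r1 / (w3 * w3)) * f1 + E1 * dfcut(r1, rc));
          double dtdr2 = P * E1 * f1 *
                         (E2 * (-2.0 * r2 / (w3 * w3)) * f2 + E2 * dfcut(r2, rc));
          double gj[3], gk[3];  // dt/dx_j, dt/dx_k
          for (int m = 0; m < 3; ++m) {
            double gcj = d2[m] / (r1 * r2) - c * d1[m] / (r1 * r1);
            double gck = d1[m] / (r1 * r2) - c * d2[m] / (r2 * r2);
            gj[m] = dtdc * gcj + dtdr1 * d1[m] / r1;
            gk[m] = dtdc * gck + dtdr2 * d2[m] / r2;
          }
          if (mode == 1) {
            double a = A(i, col);
            for (int m = 0; m < 3; ++m) {
              double fj = -a * gj[m], fk = -a * gk[m];
              F(j, m) += fj; F(kk, m) += fk; F(i, m) -= fj + fk;
              W += d1[m] * fj + d2[m] * fk;
            }
          } else if (mode == 2) {
            double dot = 0.0;
            for (int m = 0; m < 3; ++m)
              dot += gj[m] * (Rm(j, m) - Rm(i, m)) +
                     gk[m] * (Rm(kk, m) - Rm(i, m));
            V(i, col) += dot;
          } else {
            for (int m = 0; m < 3; ++m) {
              J[JIDX(i, col, j, m)] += gj[m];
              J[JIDX(i, col, kk, m)] += gk[m];
              J[JIDX(i, col, i, m)] -= gj[m] + gk[m];
            }
          }
        }
      }
    }
  }
  #undef JIDX
  if (mode == 1) return List::create(_["forces"] = F, _["virial"] = W,
                                     _["G"] = G);
  if (mode == 2) return List::create(_["V"] = V, _["G"] = G);
  if (mode == 3) {
    J.attr("dim") = IntegerVector::create(N, nd, N, 3);
    return List::create(_["J"] = J, _["G"] = G);
  }
  return List::create(_["G"] = G);
}

// [[Rcpp::export]]
NumericMatrix afs_cpp(NumericMatrix pos, NumericVector box,
                      NumericMatrix af2, NumericMatrix af3) {
  NumericMatrix dummy(1, 1);
  List out = afs_core(pos, box, af2, af3, 0, dummy, dummy);
  return out["G"];
}

// [[Rcpp::export]]
List afs_force_cpp(NumericMatrix pos, NumericVector box,
                   NumericMatrix af2, NumericMatrix af3, NumericMatrix A) {
  NumericMatrix dummy(1, 1);
  return afs_core(pos, box, af2, af3, 1, A, dummy);
}

// [[Rcpp::export]]
List afs_vcontract_cpp(NumericMatrix pos, NumericVector box,
                       NumericMatrix af2, NumericMatrix af3,
                       NumericMatrix Rm) {
  NumericMatrix dummy(1, 1);
  return afs_core(pos, box, af2, af3, 2, dummy, Rm);
}

// [[Rcpp::export]]
List afs_jacobian_cpp(NumericMatrix pos, NumericVector box,
                      NumericMatrix af2, NumericMatrix af3) {
  NumericMatrix dummy(1, 1);
  return afs_core(pos, box, af2, af3, 3, dummy, dummy);
}
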
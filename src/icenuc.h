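#ifndef ICENUC_H
#define ICENUC_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// unit system: kcal/mol, Angstrom, fs, K, bar  (g/mol masses)
#define KB_KCAL 0.0019872041
// F[kcal/mol/A] / m[g/mol] * ACC_CONV -> a[A/fs^2]
#define ACC_CONV 4.184e-4
// 1 / ACC_CONV : K[kcal/mol] = 0.5 * m v^2 * MVV2E
#define MVV2E 2390.0573613767
// kcal/mol/A^3 -> bar
#define PRESS_CONV 69476.95457

struct SWParams {
  double eps, sigma, A, B, p, q, a, gamma, lam, costheta0, mass;
  double rc;  // a*sigma
};

inline SWParams sw_from_list(const Rcpp::List& par) {
  SWParams s;
  s.eps = par["epsilon"]; s.sigma = par["sigma"];
  s.A = par["A"]; s.B = par["B"]; s.p = par["p"]; s.q = par["q"];
  s.a = par["a"]; s.gamma = par["gamma"]; s.lam = par["lam"];
  s.costheta0 = par["cos_theta0"]; s.mass = par["mass"];
  s.rc = s.a * s.sigma;
  return s;
}

// minimum-image displacement x_j - x_i for an orthorhombic box
inline void min_image(double dx[3], const double* xi, const double* xj,
                      const double* box) {
  for (int k = 0; k < 3; ++k) {
    double d = xj[k] - xi[k];
    d -= box[k] * std::round(d / box[k]);
    dx[k] = d;
  }
}

typedef std::vector< std::vector<int> > NeighVec;

// O(N^2) full (symmetric) neighbour list within cutoff
inline void build_neigh(const std::vector<double>& x, int N,
                        const double* box, double cutoff, NeighVec& nl) {
  nl.assign(N, std::vector<int>());
  double rc2 = cutoff * cutoff;
  double d[3];
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      min_image(d, &x[3 * i], &x[3 * j], box);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 < rc2) { nl[i].push_back(j); nl[j].push_back(i); }
    }
}

#endif
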
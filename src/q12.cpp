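// Rank-12 bond-orientational order parameter: per-particle q_{12,m} vectors,
// bond coherence d12, crystalline labelling, cluster decomposition, and
// cubic/hexagonal (staggered/eclipsed) polymorph discrimination.
#include "icenuc.h"
using namespace Rcpp;

static const int L = 12;

// associated Legendre P_L^m(x), m = 0..L, Condon-Shortley phase included
static void plm12(double x, double* p) {
  double somx2 = std::sqrt(std::max(0.0, 1.0 - x * x));
  // p_mm[m] = P_m^m
  std::vector<double> pmm(L + 1);
  pmm[0] = 1.0;
  for (int m = 1; m <= L; ++m) pmm[m] = -pmm[m - 1] * (2 * m - 1) * somx2;
  for (int m = 0; m <= L; ++m) {
    if (m == L) { p[m] = pmm[L]; continue; }
    double pl1 = pmm[m];                      // P_m^m
    double pl2 = x * (2 * m + 1) * pmm[m];    // P_{m+1}^m
    if (m + 1 == L) { p[m] = pl2; continue; }
    double pl = 0.0;
    for (int l = m + 2; l <= L; ++l) {
      pl = (x * (2 * l - 1) * pl2 - (l - 1 + m) * pl1) / (l - m);
      pl1 = pl2; pl2 = pl;
    }
    p[m] = pl;
  }
}

static void ylm_norms(double* nrm) {
  for (int m = 0; m <= L; ++m) {
    double lf = 1.0;
    for (int k = L - m + 1; k <= L + m; ++k) lf *= k;  // (L+m)!/(L-m)!
    nrm[m] = std::sqrt((2.0 * L + 1.0) / (4.0 * M_PI) / lf);
  }
}

// q_{12,m}(i) = mean over neighbours j of Y_{12,m}(r_ij), m = 0..12
// [[Rcpp::export]]
List qlm_cpp(NumericMatrix pos, NumericVector box, double cutoff) {
  int N = pos.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  NeighVec nl;
  build_neigh(x, N, bx, cutoff, nl);

  NumericMatrix qre(N, L + 1), qim(N, L + 1);
  IntegerVector nneigh(N);
  double p[L + 1], nrm[L + 1];
  ylm_norms(nrm);
  double d[3];
  for (int i = 0; i < N; ++i) {
    int nn = nl[i].size();
    nneigh[i] = nn;
    if (nn == 0) continue;
    for (int u = 0; u < nn; ++u) {
      int j = nl[i][u];
      min_image(d, &x[3 * i], &x[3 * j], bx);
      double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      double ct = d[2] / r;
      double phi = std::atan2(d[1], d[0]);
      plm12(ct, p);
      for (int m = 0; m <= L; ++m) {
        double v = nrm[m] * p[m];
        qre(i, m) += v * std::cos(m * phi);
        qim(i, m) += v * std::sin(m * phi);
      }
    }
    for (int m = 0; m <= L; ++m) { qre(i, m) /= nn; qim(i, m) /= nn; }
  }
  List neigh(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector v(nl[i].size());
    for (size_t u = 0; u < nl[i].size(); ++u) v[u] = nl[i][u] + 1;
    neigh[i] = v;
  }
  return List::create(_["qre"] = qre, _["qim"] = qim,
                      _["nneigh"] = nneigh, _["neighbors"] = neigh);
}

// d12(i,j) = Re< q_hat(i), q_hat(j) > summed over m = -12..12
static double d12_pair(const NumericMatrix& qre, const NumericMatrix& qim,
                       const NumericVector& norm, int i, int j) {
  if (norm[i] <= 0 || norm[j] <= 0) return 0.0;
  double s = qre(i, 0) * qre(j, 0);
  for (int m = 1; m <= L; ++m)
    s += 2.0 * (qre(i, m) * qre(j, m) + qim(i, m) * qim(j, m));
  return s / (norm[i] * norm[j]);
}

// [[Rcpp::export]]
List d12_classify_cpp(NumericMatrix qre, NumericMatrix qim, List neighbors,
                      double d_c, int xi_c) {
  int N = qre.nrow();
  NumericVector norm(N);
  for (int i = 0; i < N; ++i) {
    double s = qre(i, 0) * qre(i, 0);
    for (int m = 1; m <= L; ++m)
      s += 2.0 * (qre(i, m) * qre(i, m) + qim(i, m) * qim(i, m));
    norm[i] = std::sqrt(s);
  }
  IntegerVector ncoh(N);
  LogicalVector cryst(N);
  List d12(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector ni = neighbors[i];
    NumericVector di(ni.size());
    int c = 0;
    for (int u = 0; u < ni.size(); ++u) {
      int j = ni[u] - 1;
      di[u] = d12_pair(qre, qim, norm, i, j);
      if (di[u] > d_c) ++c;
    }
    d12[i] = di;
    ncoh[i] = c;
    cryst[i] = (c >= xi_c) && (norm[i] > 0);
  }
  return List::create(_["crystalline"] = cryst, _["n_coherent"] = ncoh,
                      _["d12"] = d12, _["qnorm"] = norm);
}

// connected components of crystalline particles over the neighbour graph
// [[Rcpp::export]]
IntegerVector cluster_components_cpp(LogicalVector crystalline,
                                     List neighbors) {
  int N = crystalline.size();
  IntegerVector comp(N, 0);
  int cid = 0;
  std::vector<int> stack;
  for (int i = 0; i < N; ++i) {
    if (!crystalline[i] || comp[i] != 0) continue;
    ++cid;
    stack.push_back(i);
    comp[i] = cid;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      IntegerVector nu = neighbors[u];
      for (int w = 0; w < nu.size(); ++w) {
        int j = nu[w] - 1;
        if (crystalline[j] && comp[j] == 0) {
          comp[j] = cid;
          stack.push_back(j);
        }
      }
    }
  }
  return comp;
}

// Per-bond staggered/eclipsed score from torsion angles: for bond i-j, the
// mean of cos(3*phi) over torsions k-i-j-l is -1 for staggered (cubic) and
// +1 for eclipsed (hexagonal) arrangements.
// [[Rcpp::export]]
List polymorph_cpp(NumericMatrix pos, NumericVector box, List neighbors,
                   LogicalVector crystalline) {
  int N = pos.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  IntegerVector n_stag(N, 0), n_ecl(N, 0);
  double b[3], d1[3], d2[3];
  for (int i = 0; i < N; ++i) {
    if (!crystalline[i]) continue;
    IntegerVector ni = neighbors[i];
    for (int u = 0; u < ni.size(); ++u) {
      int j = ni[u] - 1;
      if (j < i || !crystalline[j]) continue;
      min_image(b, &x[3 * i], &x[3 * j], bx);
      double bn = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
      IntegerVector nj = neighbors[j];
      double score = 0.0; int cnt = 0;
      for (int uk = 0; uk < ni.size(); ++uk) {
        int k = ni[uk] - 1;
        if (k == j) continue;
        min_image(d1, &x[3 * i], &x[3 * k], bx);
        // component of d1 perpendicular to bond
        double p1 = (d1[0] * b[0] + d1[1] * b[1] + d1[2] * b[2]) / (bn * bn);
        double e1[3] = {d1[0] - p1 * b[0], d1[1] - p1 * b[1], d1[2] - p1 * b[2]};
        double e1n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
        if (e1n < 1e-8) continue;
        for (int ul = 0; ul < nj.size(); ++ul) {
          int l = nj[ul] - 1;
          if (l == i) continue;
          min_image(d2, &x[3 * j], &x[3 * l], bx);
          double p2 = (d2[0] * b[0] + d2[1] * b[1] + d2[2] * b[2]) / (bn * bn);
          double e2[3] = {d2[0] - p2 * b[0], d2[1] - p2 * b[1],
                          d2[2] - p2 * b[2]};
          double e2n = std::sqrt(e2[0] * e2[0] + e2[1] * e2[1] + e2[2] * e2[2]);
          if (e2n < 1e-8) continue;
          double cphi = (e1[0] * e2[0] + e1[1] * e2[1] + e1[2] * e2[2]) /
                        (e1n * e2n);
          cphi = std::max(-1.0, std::min(1.0, cphi));
          double phi = std::acos(cphi);
          score += std::cos(3.0 * phi);
          ++cnt;
        }
      }
      if (cnt == 0) continue;
      score /= cnt;
      if (score > 0) { ++n_ecl[i]; ++n_ecl[j]; }
      else if (score < 0) { ++n_stag[i]; ++n_stag[j]; }
    }
  }
  return List::create(_["n_staggered"] = n_stag, _["n_eclipsed"] = n_ecl);
}
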
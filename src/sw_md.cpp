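// mW / Stillinger-Weber potential: energy, forces, virial, and MD integrators
// (velocity Verlet NVE, BAOAB Langevin NVT, Langevin-piston NPT).
#include "icenuc.h"
using namespace Rcpp;

// phi2(r) = A*eps*(B*(sigma/r)^p - (sigma/r)^q) * exp(sigma/(r - a sigma))
static inline void sw_pair(const SWParams& s, double r, double& e, double& de) {
  if (r >= s.rc) { e = 0.0; de = 0.0; return; }
  double sr = s.sigma / r;
  // common case of the mW/SW family: p = 4, q = 0
  double srp = (s.p == 4.0) ? (sr * sr) * (sr * sr) : std::pow(sr, s.p);
  double srq = (s.q == 0.0) ? 1.0 : std::pow(sr, s.q);
  double ex = std::exp(s.sigma / (r - s.rc));
  double poly = s.B * srp - srq;
  e = s.A * s.eps * poly * ex;
  double dpoly = (-s.B * s.p * srp + s.q * srq) / r;
  double dex = -s.sigma / ((r - s.rc) * (r - s.rc));
  de = s.A * s.eps * ex * (dpoly + poly * dex);
}

// core evaluation on an explicit neighbour list; positions may be unwrapped
static void sw_compute(const std::vector<double>& x, int N, const double* box,
                       const SWParams& s, const NeighVec& nl,
                       double& U, std::vector<double>& F, double& W) {
  U = 0.0; W = 0.0;
  F.assign(3 * N, 0.0);
  double d[3];
  std::vector<double> dj(64 * 3), rj(64), ejv(64), dejv(64);
  std::vector<int> jj(64);
  for (int i = 0; i < N; ++i) {
    const std::vector<int>& ni = nl[i];
    int nn = 0;
    jj.clear(); dj.clear(); rj.clear(); ejv.clear(); dejv.clear();
    for (size_t u = 0; u < ni.size(); ++u) {
      int j = ni[u];
      min_image(d, &x[3 * i], &x[3 * j], box);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      double r = std::sqrt(r2);
      if (r >= s.rc) continue;
      jj.push_back(j);
      dj.push_back(d[0]); dj.push_back(d[1]); dj.push_back(d[2]);
      rj.push_back(r);
      ejv.push_back(std::exp(s.gamma * s.sigma / (r - s.rc)));
      dejv.push_back(-s.gamma * s.sigma / ((r - s.rc) * (r - s.rc)));
      ++nn;
      // pair term once per pair
      if (j > i) {
        double e, de;
        sw_pair(s, r, e, de);
        U += e;
        double fmag = -de / r;  // force on j along +d
        for (int k = 0; k < 3; ++k) {
          double f = fmag * d[k];
          F[3 * j + k] += f;
          F[3 * i + k] -= f;
          W += d[k] * f;
        }
      }
    }
    // three-body: all pairs (j,k) of neighbours of i, angle at i
    for (int uj = 0; uj < nn; ++uj) {
      double r1 = rj[uj];
      double ej = ejv[uj], dej = dejv[uj];
      const double* v1 = &dj[3 * uj];
      for (int uk = uj + 1; uk < nn; ++uk) {
        double r2 = rj[uk];
        const double* v2 = &dj[3 * uk];
        double ek = ejv[uk], dek = dejv[uk];
        double c = (v1[0] * v2[0] + v1[1] * v2[1] + v1[2] * v2[2]) / (r1 * r2);
        double dc = c - s.costheta0;
        double pref = s.lam * s.eps * ej * ek;
        double h = pref * dc * dc;
        U += h;
        double dhdc = 2.0 * pref * dc;
        double dhdr1 = h * dej;
        double dhdr2 = h * dek;
        int j = jj[uj], k = jj[uk];
        for (int m = 0; m < 3; ++m) {
          // grad_c wrt x_j and x_k
          double gcj = (v2[m] / (r1 * r2)) - c * v1[m] / (r1 * r1);
          double gck = (v1[m] / (r1 * r2)) - c * v2[m] / (r2 * r2);
          double fj = -(dhdc * gcj + dhdr1 * v1[m] / r1);
          double fk = -(dhdc * gck + dhdr2 * v2[m] / r2);
          F[3 * j + m] += fj;
          F[3 * k + m] += fk;
          F[3 * i + m] -= fj + fk;
          W += v1[m] * fj + v2[m] * fk;
        }
      }
    }
  }
}

static std::vector<double> mat_to_vec(const NumericMatrix& m) {
  int N = m.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = m(i, k);
  return x;
}

static NumericMatrix vec_to_mat(const std::vector<double>& x, int N) {
  NumericMatrix m(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) m(i, k) = x[3 * i + k];
  return m;
}

// [[Rcpp::export]]
List sw_eval_cpp(NumericMatrix pos, NumericVector box, List params) {
  SWParams s = sw_from_list(params);
  int N = pos.nrow();
  std::vector<double> x = mat_to_vec(pos);
  double bx[3] = {box[0], box[1], box[2]};
  NeighVec nl;
  build_neigh(x, N, bx, s.rc, nl);
  double U, W;
  std::vector<double> F;
  sw_compute(x, N, bx, s, nl, U, F, W);
  return List::create(_["U"] = U, _["forces"] = vec_to_mat(F, N),
                      _["virial"] = W);
}

// [[Rcpp::export]]
List neighbor_list_cpp(NumericMatrix pos, NumericVector box, double cutoff) {
  int N = pos.nrow();
  std::vector<double> x = mat_to_vec(pos);
  double bx[3] = {box[0], box[1], box[2]};
  NeighVec nl;
  build_neigh(x, N, bx, cutoff, nl);
  List out(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector v(nl[i].size());
    for (size_t u = 0; u < nl[i].size(); ++u) v[u] = nl[i][u] + 1;
    out[i] = v;
  }
  return out;
}

// Full MD driver.  ensemble: 0 = NVE, 1 = NVT (BAOAB Langevin),
// 2 = NPT (NVT + isotropic Langevin piston on ln V).
// Positions are kept unwrapped throughout (minimum image handles the rest).
// [[Rcpp::export]]
List run_md_cpp(NumericMatrix pos, NumericMatrix vel, NumericVector box,
                List params, int ensemble, int n_steps, double dt,
                double T, double damp_fs, double P_bar,
                double piston_period_fs, double piston_damp_fs,
                int sample_every) {
  SWParams s = sw_from_list(params);
  int N = pos.nrow();
  std::vector<double> x = mat_to_vec(pos), v = mat_to_vec(vel);
  double bx[3] = {box[0], box[1], box[2]};
  double skin = 0.8;
  double minbox = std::min(bx[0], std::min(bx[1], bx[2]));
  if (2.0 * s.rc > minbox) stop("box too small: every edge must exceed twice the cutoff");

  NeighVec nl;
  std::vector<double> x_ref;  // positions at last rebuild
  build_neigh(x, N, bx, s.rc + skin, nl);
  x_ref = x;

  double U, W;
  std::vector<double> F;
  sw_compute(x, N, bx, s, nl, U, F, W);

  double am = ACC_CONV / s.mass;           // F -> acceleration
  double c1 = (damp_fs > 0) ? std::exp(-dt / damp_fs) : 1.0;
  double c2 = std::sqrt((1.0 - c1 * c1) * KB_KCAL * T / (s.mass * MVV2E));
  // piston (log-volume) variables
  double V = bx[0] * bx[1] * bx[2];
  double Pint_ext = P_bar / PRESS_CONV;    // kcal/mol/A^3
  double Q = 3.0 * (N + 1) * KB_KCAL * std::max(T, 1.0) *
             piston_period_fs * piston_period_fs;
  double peps = 0.0;
  double c1p = (piston_damp_fs > 0) ? std::exp(-dt / piston_damp_fs) : 1.0;
  double c2p = std::sqrt((1.0 - c1p * c1p) * Q * KB_KCAL * T);

  int n_samples = (sample_every > 0) ? n_steps / sample_every : 0;
  List frames(n_samples);
  NumericMatrix series(n_samples, 6);  // t, U, K, T_inst, P_inst, V
  NumericMatrix boxes(n_samples, 3);
  int isample = 0;

  RNGScope scope;
  for (int step = 0; step < n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < 3 * N; ++i) v[i] += 0.5 * dt * F[i] * am;
    if (ensemble == 0) {
      for (int i = 0; i < 3 * N; ++i) x[i] += dt * v[i];
    } else {
      // A O A
      for (int i = 0; i < 3 * N; ++i) x[i] += 0.5 * dt * v[i];
      for (int i = 0; i < 3 * N; ++i) v[i] = c1 * v[i] + c2 * norm_rand();
      for (int i = 0; i < 3 * N; ++i) x[i] += 0.5 * dt * v[i];
    }
    // neighbour-list refresh on displacement
    double maxd2 = 0.0;
    for (int i = 0; i < N; ++i) {
      double dd = 0;
      for (int k = 0; k < 3; ++k) {
        double t = x[3 * i + k] - x_ref[3 * i + k];
        dd += t * t;
      }
      if (dd > maxd2) maxd2 = dd;
    }
    if (maxd2 > 0.25 * skin * skin) {
      build_neigh(x, N, bx, s.rc + skin, nl);
      x_ref = x;
    }
    sw_compute(x, N, bx, s, nl, U, F, W);
    for (int i = 0; i < 3 * N; ++i) v[i] += 0.5 * dt * F[i] * am;
    double K = 0.0;
    for (int i = 0; i < 3 * N; ++i) K += v[i] * v[i];
    K *= 0.5 * s.mass * MVV2E;
    if (!std::isfinite(U) || !std::isfinite(K))
      stop("integration error: non-finite energy (overlapping particles?)");

    if (ensemble == 2) {
      double Pint = (2.0 * K + W) / (3.0 * V);
      peps += dt * (3.0 * V * (Pint - Pint_ext) + 3.0 * KB_KCAL * T);
      peps = c1p * peps + c2p * norm_rand();
      double deps = dt * peps / Q;
      if (deps > 0.05) deps = 0.05;
      if (deps < -0.05) { deps = -0.05; Rf_warning("volume contraction clamped"); }
      double sc = std::exp(deps);
      for (int i = 0; i < 3 * N; ++i) { x[i] *= sc; x_ref[i] *= sc; }
      for (int k = 0; k < 3; ++k) bx[k] *= sc;
      V = bx[0] * bx[1] * bx[2];
      if (std::fabs(deps) > 1e-4) {  // affine change invalidates list margins
        build_neigh(x, N, bx, s.rc + skin, nl);
        x_ref = x;
        sw_compute(x, N, bx, s, nl, U, F, W);
      }
    }

    if (sample_every > 0 && (step + 1) % sample_every == 0 &&
        isample < n_samples) {
      frames[isample] = vec_to_mat(x, N);
      double Tinst = 2.0 * K / (3.0 * N * KB_KCAL);
      double Pinst = (2.0 * K + W) / (3.0 * V) * PRESS_CONV;
      series(isample, 0) = (step + 1) * dt * 1e-3;  // ps
      series(isample, 1) = U; series(isample, 2) = K;
      series(isample, 3) = Tinst; series(isample, 4) = Pinst;
      series(isample, 5) = V;
      boxes(isample, 0) = bx[0]; boxes(isample, 1) = bx[1];
      boxes(isample, 2) = bx[2];
      ++isample;
    }
  }

  double K = 0.0;
  for (int i = 0; i < 3 * N; ++i) K += v[i] * v[i];
  K *= 0.5 * s.mass * MVV2E;
  return List::create(
      _["pos"] = vec_to_mat(x, N), _["vel"] = vec_to_mat(v, N),
      _["box"] = NumericVector::create(bx[0], bx[1], bx[2]),
      _["U"] = U, _["K"] = K, _["W"] = W,
      _["frames"] = frames, _["series"] = series, _["boxes"] = boxes);
}

// per-frame raw pair-distance histogram for g(r)
// [[Rcpp::export]]
NumericVector rdf_count_cpp(NumericMatrix pos, NumericVector box,
                            double r_max, int n_bins) {
  int N = pos.nrow();
  std::vector<double> x = mat_to_vec(pos);
  double bx[3] = {box[0], box[1], box[2]};
  NumericVector h(n_bins);
  double d[3], dr = r_max / n_bins;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      min_image(d, &x[3 * i], &x[3 * j], bx);
      double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (r < r_max) h[(int)(r / dr)] += 2.0;
    }
  return h;
}
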
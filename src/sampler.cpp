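// Core Metropolis engine for confined discretised worm-like chains.
//
// State: N locus positions (nm) inside a sphere of radius R centred at the
// origin. Hard constraints (inextensible rods, confinement, on-sphere
// tethers) are preserved exactly by construction: every proposal is a rigid
// rotation of a contiguous subset of loci, so rod lengths never drift beyond
// floating-point rounding, and tethered loci are only ever moved by
// norm-preserving rotations about axes through the origin.
//
// Energies are in units of kT (beta = 1 by default):
//   bending     g*beta * sum_j (1 - t_j . t_{j+1})         (finite)
//   confinement 0 inside the sphere, +Inf outside           (sentinel)
//   clustering  -nu * (mu . x_hat) per tethered locus       (finite)
//   excluded    0, or +Inf if any non-neighbour pair < d_ev (sentinel)
//
// All randomness comes from R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

enum { MODE_NONE = 0, MODE_CEN = 1, MODE_TEL = 2 };
enum { MV_CRANK = 0, MV_PIVOT = 1, MV_ARM = 2, MV_RIGID = 3 };

struct Model {
  int N;
  double b;       // rod length (nm)
  double R;       // nuclear radius (nm)
  int cen;        // centromere locus, 0-based
  int mode;
  double gbeta;   // bending modulus, kT
  double nu;      // vMF concentration
  double beta;
  double mu[3];   // unit clustering direction
  bool ev;
  double ev2;     // squared hard-sphere distance
  int evw;        // adjacency window exempt from EV
};

static Model parse_model(const List& m) {
  Model md;
  md.N = as<int>(m["n_loci"]);
  md.b = as<double>(m["bond_length_nm"]);
  md.R = as<double>(m["radius_nm"]);
  md.cen = as<int>(m["centromere_index0"]);
  md.mode = as<int>(m["mode_code"]);
  md.gbeta = as<double>(m["bending_modulus_kT"]);
  md.nu = as<double>(m["nu"]);
  md.beta = as<double>(m["beta"]);
  NumericVector mu = m["mu"];
  md.mu[0] = mu[0]; md.mu[1] = mu[1]; md.mu[2] = mu[2];
  md.ev = as<bool>(m["excluded_volume"]);
  double evd = as<double>(m["ev_min_dist_nm"]);
  md.ev2 = evd * evd;
  md.evw = (int)std::ceil(evd / md.b);
  return md;
}

struct Rot {
  // Rodrigues rotation about axis (unit u) through anchor a.
  double u[3], a[3], c, s;
  void set(const double* axis, const double* anchor, double angle) {
    u[0] = axis[0]; u[1] = axis[1]; u[2] = axis[2];
    a[0] = anchor[0]; a[1] = anchor[1]; a[2] = anchor[2];
    c = std::cos(angle); s = std::sin(angle);
  }
  inline void apply(const double* p, double* q) const {
    double v0 = p[0] - a[0], v1 = p[1] - a[1], v2 = p[2] - a[2];
    double dot = u[0] * v0 + u[1] * v1 + u[2] * v2;
    double cx0 = u[1] * v2 - u[2] * v1;
    double cx1 = u[2] * v0 - u[0] * v2;
    double cx2 = u[0] * v1 - u[1] * v0;
    q[0] = a[0] + v0 * c + cx0 * s + u[0] * dot * (1.0 - c);
    q[1] = a[1] + v1 * c + cx1 * s + u[1] * dot * (1.0 - c);
    q[2] = a[2] + v2 * c + cx2 * s + u[2] * dot * (1.0 - c);
  }
};

class Sampler {
public:
  Model md;
  std::vector<double> px, py, pz;       // current positions
  std::vector<double> sx, sy, sz;       // proposal scratch for moved range
  int lo, hi;                           // moved range (inclusive), -1 if none
  double conf_eps;

  Sampler(const Model& m, const NumericMatrix& init) : md(m) {
    int N = md.N;
    px.resize(N); py.resize(N); pz.resize(N);
    sx.resize(N); sy.resize(N); sz.resize(N);
    for (int i = 0; i < N; ++i) {
      px[i] = init(i, 0); py[i] = init(i, 1); pz[i] = init(i, 2);
    }
    conf_eps = 1e-6;
    lo = 0; hi = -1;
  }

  inline void cur(int i, double* p) const { p[0] = px[i]; p[1] = py[i]; p[2] = pz[i]; }
  // position under the pending proposal
  inline void prop(int i, double* p) const {
    if (i >= lo && i <= hi) { p[0] = sx[i]; p[1] = sy[i]; p[2] = sz[i]; }
    else cur(i, p);
  }

  // cosine of joint k (between rods k and k+1), 0 <= k <= N-3
  template <bool PROPOSED>
  double joint_cos(int k) const {
    double a[3], b_[3], c[3];
    if (PROPOSED) { prop(k, a); prop(k + 1, b_); prop(k + 2, c); }
    else { cur(k, a); cur(k + 1, b_); cur(k + 2, c); }
    double t1x = b_[0] - a[0], t1y = b_[1] - a[1], t1z = b_[2] - a[2];
    double t2x = c[0] - b_[0], t2y = c[1] - b_[1], t2z = c[2] - b_[2];
    double n1 = std::sqrt(t1x * t1x + t1y * t1y + t1z * t1z);
    double n2 = std::sqrt(t2x * t2x + t2y * t2y + t2z * t2z);
    return (t1x * t2x + t1y * t2y + t1z * t2z) / (n1 * n2);
  }

  template <bool PROPOSED>
  double cluster_term(int i) const {
    double p[3];
    if (PROPOSED) prop(i, p); else cur(i, p);
    double n = std::sqrt(p[0] * p[0] + p[1] * p[1] + p[2] * p[2]);
    if (n <= 0.0) return 0.0;
    return -md.nu * (md.mu[0] * p[0] + md.mu[1] * p[1] + md.mu[2] * p[2]) / n;
  }

  template <bool PROPOSED>
  double full_bending() const {
    double e = 0.0;
    for (int k = 0; k <= md.N - 3; ++k) e += 1.0 - joint_cos<PROPOSED>(k);
    return md.gbeta * e;
  }

  template <bool PROPOSED>
  double full_clustering() const {
    if (md.mode == MODE_NONE || md.nu == 0.0) return 0.0;
    if (md.mode == MODE_CEN) return cluster_term<PROPOSED>(md.cen);
    return cluster_term<PROPOSED>(0) + cluster_term<PROPOSED>(md.N - 1);
  }

  bool confinement_ok_proposed() const {
    double lim = (md.R + conf_eps) * (md.R + conf_eps);
    for (int i = lo; i <= hi; ++i) {
      if (sx[i] * sx[i] + sy[i] * sy[i] + sz[i] * sz[i] > lim) return false;
    }
    return true;
  }

  // excluded-volume feasibility of the proposal (pairs involving moved loci)
  bool ev_ok_proposed() const {
    if (!md.ev) return true;
    double p[3], q[3];
    for (int i = lo; i <= hi; ++i) {
      prop(i, p);
      for (int m = 0; m < md.N; ++m) {
        if (std::abs(i - m) <= md.evw) continue;
        if (m >= lo && m <= hi && m >= i) continue; // count moved pairs once
        prop(m, q);
        double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
        if (dx * dx + dy * dy + dz * dz < md.ev2) return false;
      }
    }
    return true;
  }

  void commit() {
    for (int i = lo; i <= hi; ++i) { px[i] = sx[i]; py[i] = sy[i]; pz[i] = sz[i]; }
  }

  // --- proposal generation -------------------------------------------------
  // Fills scratch, sets [lo, hi], returns finite incremental dE for feasible
  // proposals, +Inf for infeasible, NaN for degenerate/no-op proposals.
  // check_conf: norm-changing moves must verify confinement.

  double propose(int type, double angle, int i, int j, const double* axis,
                 bool right_side) {
    int N = md.N;
    std::vector<int> joints;
    Rot rot;
    bool check_conf = true;

    if (type == MV_CRANK) {
      double a[3], b_[3];
      cur(i, a); cur(j, b_);
      double ux = b_[0] - a[0], uy = b_[1] - a[1], uz = b_[2] - a[2];
      double n = std::sqrt(ux * ux + uy * uy + uz * uz);
      if (n < 1e-9) return R_NaN; // degenerate axis
      double u[3] = { ux / n, uy / n, uz / n };
      rot.set(u, a, angle);
      lo = i + 1; hi = j - 1;
      if (i >= 1) joints.push_back(i - 1);
      if (j <= N - 2) joints.push_back(j - 1);
    } else if (type == MV_PIVOT) {
      double a[3];
      cur(i, a);
      rot.set(axis, a, angle);
      if (right_side) { lo = i + 1; hi = N - 1; } else { lo = 0; hi = i - 1; }
      if (i >= 1 && i <= N - 2) joints.push_back(i - 1);
    } else if (type == MV_ARM) {
      double a[3];
      cur(i, a);
      double n = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
      if (n < 1e-9) return R_NaN;
      double u[3] = { a[0] / n, a[1] / n, a[2] / n };
      double origin[3] = { 0.0, 0.0, 0.0 };
      rot.set(u, origin, angle);
      if (right_side) { lo = i + 1; hi = N - 1; } else { lo = 0; hi = i - 1; }
      if (i >= 1 && i <= N - 2) joints.push_back(i - 1);
      check_conf = false; // norms preserved
    } else { // MV_RIGID
      double origin[3] = { 0.0, 0.0, 0.0 };
      rot.set(axis, origin, angle);
      lo = 0; hi = N - 1;
      check_conf = false;
    }
    if (lo > hi) return R_NaN;

    double p[3], q[3];
    for (int k = lo; k <= hi; ++k) {
      cur(k, p);
      rot.apply(p, q);
      sx[k] = q[0]; sy[k] = q[1]; sz[k] = q[2];
    }
    if (check_conf && !confinement_ok_proposed()) return R_PosInf;
    if (!ev_ok_proposed()) return R_PosInf;

    double dE = 0.0;
    for (size_t t = 0; t < joints.size(); ++t) {
      int k = joints[t];
      dE += md.gbeta * (joint_cos<false>(k) - joint_cos<true>(k));
    }
    if (md.mode != MODE_NONE && md.nu != 0.0) {
      if (md.mode == MODE_CEN) {
        if (md.cen >= lo && md.cen <= hi)
          dE += cluster_term<true>(md.cen) - cluster_term<false>(md.cen);
      } else {
        if (0 >= lo && 0 <= hi)
          dE += cluster_term<true>(0) - cluster_term<false>(0);
        if (md.N - 1 >= lo && md.N - 1 <= hi)
          dE += cluster_term<true>(md.N - 1) - cluster_term<false>(md.N - 1);
      }
    }
    return dE;
  }
};

static inline int unif_int(int n) { // uniform on 0..n-1
  int k = (int)(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline void rand_axis(double* u) {
  double n = 0.0;
  do {
    u[0] = R::norm_rand(); u[1] = R::norm_rand(); u[2] = R::norm_rand();
    n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  } while (n < 1e-12);
  u[0] /= n; u[1] /= n; u[2] /= n;
}

// log-uniform segment length in [2, smax]
static inline int rand_seglen(int smax) {
  if (smax <= 2) return 2;
  double s = 2.0 * std::exp(R::unif_rand() * std::log(smax / 2.0));
  int k = (int)std::floor(s);
  if (k < 2) k = 2;
  if (k > smax) k = smax;
  return k;
}

struct MoveDraw {
  int type, i, j;
  bool right;
  double angle;
  double axis[3];
  bool valid;
};

// Draw one move according to the class mix; geometry respects tether mode.
static MoveDraw draw_move(const Model& md, const double* mix, const double* amp) {
  MoveDraw mv;
  mv.valid = true;
  int N = md.N;
  double r = R::unif_rand();
  int type = MV_RIGID;
  double acc = 0.0;
  for (int t = 0; t < 4; ++t) {
    acc += mix[t];
    if (r <= acc) { type = t; break; }
  }
  mv.type = type;
  mv.i = mv.j = 0; mv.right = true; mv.angle = 0.0;
  mv.axis[0] = mv.axis[1] = 0.0; mv.axis[2] = 1.0;

  if (type == MV_CRANK) {
    int lo0 = 0, hi0 = N - 1;
    if (md.mode == MODE_CEN) {
      // segment must not strictly contain the centromere
      int spanL = md.cen, spanR = N - 1 - md.cen;
      int wL = spanL >= 2 ? spanL - 1 : 0;
      int wR = spanR >= 2 ? spanR - 1 : 0;
      if (wL + wR == 0) { mv.valid = false; return mv; }
      if (R::unif_rand() * (wL + wR) < wL) { lo0 = 0; hi0 = md.cen; }
      else { lo0 = md.cen; hi0 = N - 1; }
    }
    int span = hi0 - lo0;
    if (span < 2) { mv.valid = false; return mv; }
    int s = rand_seglen(span);
    mv.i = lo0 + unif_int(span - s + 1);
    mv.j = mv.i + s;
    double a = amp[MV_CRANK] * std::sqrt(2.0 / s);
    if (a > M_PI) a = M_PI;
    mv.angle = (2.0 * R::unif_rand() - 1.0) * a;
  } else if (type == MV_PIVOT) {
    if (md.mode == MODE_TEL) { mv.valid = false; return mv; }
    if (md.mode == MODE_CEN) {
      int nR = N - 1 - md.cen, nL = md.cen; // valid pivot counts per side
      if (nR + nL == 0) { mv.valid = false; return mv; }
      if (R::unif_rand() * (nR + nL) < nR) {
        mv.right = true; mv.i = md.cen + unif_int(nR); // in [cen, N-2]
      } else {
        mv.right = false; mv.i = 1 + unif_int(nL);     // in [1, cen]
      }
    } else {
      mv.right = R::unif_rand() < 0.5;
      mv.i = mv.right ? unif_int(N - 1) : 1 + unif_int(N - 1);
    }
    rand_axis(mv.axis);
    mv.angle = (2.0 * R::unif_rand() - 1.0) * amp[MV_PIVOT];
  } else if (type == MV_ARM) {
    mv.i = 1 + unif_int(N - 2); // in [1, N-2]
    mv.right = R::unif_rand() < 0.5;
    mv.angle = (2.0 * R::unif_rand() - 1.0) * amp[MV_ARM];
  } else {
    rand_axis(mv.axis);
    mv.angle = (2.0 * R::unif_rand() - 1.0) * amp[MV_RIGID];
  }
  return mv;
}

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(NumericMatrix init, List model, double n_total,
                   double n_burn_in, int thin, NumericVector move_mix,
                   NumericVector step_angles, bool adapt) {
  Model md = parse_model(model);
  Sampler sm(md, init);
  int N = md.N;

  double mix[4] = { move_mix[0], move_mix[1], move_mix[2], move_mix[3] };
  double amp[4] = { step_angles[0], step_angles[1], step_angles[2], step_angles[3] };

  R_xlen_t M = (R_xlen_t)std::floor((n_total - n_burn_in) / thin);
  NumericVector samples((R_xlen_t)N * 3 * M);
  samples.attr("dim") = IntegerVector::create(N, 3, (int)M);
  double* out = REAL(samples);

  long att_cls[4] = {0, 0, 0, 0}, acc_cls[4] = {0, 0, 0, 0};
  long att_post = 0, acc_post = 0;
  R_xlen_t kept = 0;
  const long adapt_block = 2000;

  long long nt = (long long)n_total, nb = (long long)n_burn_in;
  for (long long t = 1; t <= nt; ++t) {
    MoveDraw mv = draw_move(md, mix, amp);
    bool burn = t <= nb;
    bool accepted = false;
    if (mv.valid) {
      double dE = sm.propose(mv.type, mv.angle, mv.i, mv.j, mv.axis, mv.right);
      if (R_finite(dE)) {
        if (dE <= 0.0 || R::unif_rand() < std::exp(-md.beta * dE)) {
          sm.commit();
          accepted = true;
        }
      }
      // NaN (degenerate) and +Inf (infeasible) both count as rejected
    }
    if (burn) {
      att_cls[mv.type]++;
      if (accepted) acc_cls[mv.type]++;
      if (adapt && att_cls[mv.type] >= adapt_block) {
        double rate = (double)acc_cls[mv.type] / att_cls[mv.type];
        if (rate < 0.3) amp[mv.type] *= 0.8;
        else if (rate > 0.5) amp[mv.type] = std::min(amp[mv.type] * 1.25, M_PI);
        if (amp[mv.type] < 1e-4) amp[mv.type] = 1e-4;
        att_cls[mv.type] = 0; acc_cls[mv.type] = 0;
      }
    } else {
      att_post++;
      if (accepted) acc_post++;
      long long done = t - nb;
      if (kept < M && done % thin == 0) {
        double* dst = out + (R_xlen_t)kept * N * 3;
        for (int i = 0; i < N; ++i) {
          dst[i] = sm.px[i];
          dst[i + N] = sm.py[i];
          dst[i + 2 * N] = sm.pz[i];
        }
        kept++;
      }
    }
    if ((t & 0x3FFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix fin(N, 3);
  for (int i = 0; i < N; ++i) {
    fin(i, 0) = sm.px[i]; fin(i, 1) = sm.py[i]; fin(i, 2) = sm.pz[i];
  }
  return List::create(
    _["samples"] = samples,
    _["retained_count"] = (double)kept,
    _["acceptance_rate"] = att_post > 0 ? (double)acc_post / att_post : NA_REAL,
    _["final_positions"] = fin,
    _["step_angles"] = NumericVector::create(amp[0], amp[1], amp[2], amp[3]),
    _["bending_kT"] = sm.full_bending<false>(),
    _["clustering_kT"] = sm.full_clustering<false>());
}

// Consistency check: incremental dE of random proposals vs full recompute.
// Returns the maximum absolute discrepancy over n_moves feasible proposals.
// [[Rcpp::export(name = ".delta_check_cpp")]]
double delta_check_cpp(NumericMatrix init, List model, int n_moves,
                       NumericVector move_mix, double step_angle) {
  Model md = parse_model(model);
  Sampler sm(md, init);
  double mix[4] = { move_mix[0], move_mix[1], move_mix[2], move_mix[3] };
  double amp[4] = { step_angle, step_angle, step_angle, step_angle };
  double worst = 0.0;
  for (int t = 0; t < n_moves; ++t) {
    MoveDraw mv = draw_move(md, mix, amp);
    if (!mv.valid) continue;
    double e0 = sm.full_bending<false>() + sm.full_clustering<false>();
    double dE = sm.propose(mv.type, mv.angle, mv.i, mv.j, mv.axis, mv.right);
    if (!R_finite(dE)) continue;
    double e1 = sm.full_bending<true>() + sm.full_clustering<true>();
    double diff = std::abs((e1 - e0) - dE);
    if (diff > worst) worst = diff;
    if (dE <= 0.0 || R::unif_rand() < std::exp(-md.beta * dE)) sm.commit();
  }
  return worst;
}

// --- distance-map accumulation --------------------------------------------

// Mean cross distances between paired samples of two ensembles (nm).
// a, b: N x 3 x M arrays. Returns mean matrix plus diagonal mean/sd.
// [[Rcpp::export(name = ".ldm_cross_cpp")]]
List ldm_cross_cpp(NumericVector a, NumericVector b) {
  IntegerVector da = a.attr("dim"), db = b.attr("dim");
  int N = da[0];
  R_xlen_t M = da[2];
  if (db[0] != N || db[2] != M) stop("ensemble dimensions differ");
  const double* pa = REAL(a);
  const double* pb = REAL(b);
  NumericMatrix mean(N, N);
  double* pm = REAL(mean);
  std::vector<double> dsum(N, 0.0), dsq(N, 0.0);
  for (R_xlen_t k = 0; k < M; ++k) {
    const double* A = pa + (R_xlen_t)k * N * 3;
    const double* B = pb + (R_xlen_t)k * N * 3;
    for (int i = 0; i < N; ++i) {
      double xi = A[i], yi = A[i + N], zi = A[i + 2 * N];
      for (int j = 0; j < N; ++j) {
        double dx = xi - B[j], dy = yi - B[j + N], dz = zi - B[j + 2 * N];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        pm[i + (R_xlen_t)j * N] += d;
        if (i == j) { dsum[i] += d; dsq[i] += d * d; }
      }
    }
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector dmean(N), dsd(N);
  for (int i = 0; i < N; ++i) {
    dmean[i] = dsum[i] / M;
    double var = M > 1 ? (dsq[i] - dsum[i] * dsum[i] / M) / (M - 1) : 0.0;
    dsd[i] = var > 0 ? std::sqrt(var) : 0.0;
  }
  for (R_xlen_t idx = 0; idx < (R_xlen_t)N * N; ++idx) pm[idx] /= M;
  return List::create(_["mean_nm"] = mean, _["diag_mean_nm"] = dmean,
                      _["diag_sd_nm"] = dsd, _["n_samples"] = (double)M);
}

// Mean intra-chromosome distances (nm): symmetric, zero diagonal.
// [[Rcpp::export(name = ".ldm_intra_cpp")]]
List ldm_intra_cpp(NumericVector a) {
  IntegerVector da = a.attr("dim");
  int N = da[0];
  R_xlen_t M = da[2];
  const double* pa = REAL(a);
  NumericMatrix mean(N, N);
  double* pm = REAL(mean);
  for (R_xlen_t k = 0; k < M; ++k) {
    const double* A = pa + (R_xlen_t)k * N * 3;
    for (int i = 0; i < N; ++i) {
      double xi = A[i], yi = A[i + N], zi = A[i + 2 * N];
      for (int j = i + 1; j < N; ++j) {
        double dx = xi - A[j], dy = yi - A[j + N], dz = zi - A[j + 2 * N];
        pm[i + (R_xlen_t)j * N] += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
    }
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double v = pm[i + (R_xlen_t)j * N] / M;
      pm[i + (R_xlen_t)j * N] = v;
      pm[j + (R_xlen_t)i * N] = v;
    }
  return List::create(_["mean_nm"] = mean, _["n_samples"] = (double)M);
}

// Per-locus mean and sd of allelic (same-index) distances only (nm).
// [[Rcpp::export(name = ".allelic_stats_cpp")]]
List allelic_stats_cpp(NumericVector a, NumericVector b) {
  IntegerVector da = a.attr("dim"), db = b.attr("dim");
  int N = da[0];
  R_xlen_t M = da[2];
  if (db[0] != N || db[2] != M) stop("ensemble dimensions differ");
  const double* pa = REAL(a);
  const double* pb = REAL(b);
  std::vector<double> dsum(N, 0.0), dsq(N, 0.0);
  for (R_xlen_t k = 0; k < M; ++k) {
    const double* A = pa + (R_xlen_t)k * N * 3;
    const double* B = pb + (R_xlen_t)k * N * 3;
    for (int i = 0; i < N; ++i) {
      double dx = A[i] - B[i], dy = A[i + N] - B[i + N], dz = A[i + 2 * N] - B[i + 2 * N];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      dsum[i] += d; dsq[i] += d * d;
    }
  }
  NumericVector dmean(N), dsd(N);
  for (int i = 0; i < N; ++i) {
    dmean[i] = dsum[i] / M;
    double var = M > 1 ? (dsq[i] - dsum[i] * dsum[i] / M) / (M - 1) : 0.0;
    dsd[i] = var > 0 ? std::sqrt(var) : 0.0;
  }
  return List::create(_["diag_mean_nm"] = dmean, _["diag_sd_nm"] = dsd,
                      _["n_samples"] = (double)M);
}
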
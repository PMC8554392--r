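// Hierarchical spatiotemporal Poisson log-rate model: joint log posterior,
// analytic gradients, and a No-U-Turn sampler with dual-averaging step-size
// and diagonal mass-matrix adaptation.
//
// Model (per sex):
//   log lambda[a,m,t] = alpha[a] + beta[a]*tc[t]
//                     + theta_m[m] + theta_d[d(m)] + theta_r[r(m)]
//                     + (phi_m[m] + phi_d[d(m)] + phi_r[r(m)]) * tc[t]
//                     + xi[a,m] + nu[a,t] + omega[m,t]
//   deaths[a,m,t] ~ Poisson(P[a,m,t] * lambda[a,m,t])
// alpha: RW1 over age (centred) with a weak anchor on the first element.
// beta: RW1 over age, non-centred (beta = beta0 + sigma * cumsum(z)).
// theta, phi, xi: zero-mean Gaussians (non-centred parameterisation).
// nu, omega: RW1 over time, anchored at 0 and centred (sum-to-zero), built
// from non-centred increments.  Scale parameters get half-normal priors and
// are sampled on the log scale.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NSIG = 11;
// sigma slots: 0 alpha_rw, 1 beta_rw, 2 theta_m, 3 theta_d, 4 theta_r,
//              5 phi_m, 6 phi_d, 7 phi_r, 8 xi, 9 nu, 10 omega

struct Layout {
  int A, M, T, D, R;
  bool inc_t, inc_m, inc_mt;
  int sig_active[NSIG];
  int o_alpha, o_beta, o_zthm, o_zthd, o_zthr, o_zphm, o_zphd, o_zphr;
  int o_zxi, o_zdnu, o_zdom, o_eta;
  int eta_of_slot[NSIG]; // index within eta block, -1 if fixed/inactive
  int n_eta, npar;
};

static Layout make_layout(int A, int M, int T, int D, int R,
                          const int* fixed) {
  Layout L;
  L.A = A; L.M = M; L.T = T; L.D = D; L.R = R;
  L.inc_t = T > 1; L.inc_m = M > 1; L.inc_mt = L.inc_t && L.inc_m;
  int act[NSIG] = {A > 1, (L.inc_t && A > 1), L.inc_m, L.inc_m, L.inc_m,
                   L.inc_mt, L.inc_mt, L.inc_mt, L.inc_m, L.inc_t, L.inc_mt};
  for (int j = 0; j < NSIG; j++) L.sig_active[j] = act[j];
  int o = 0;
  L.o_alpha = o; o += A;
  L.o_beta = o; if (L.inc_t) o += A;
  L.o_zthm = o; if (L.inc_m) o += M;
  L.o_zthd = o; if (L.inc_m) o += D;
  L.o_zthr = o; if (L.inc_m) o += R;
  L.o_zphm = o; if (L.inc_mt) o += M;
  L.o_zphd = o; if (L.inc_mt) o += D;
  L.o_zphr = o; if (L.inc_mt) o += R;
  L.o_zxi = o; if (L.inc_m) o += A * M;
  L.o_zdnu = o; if (L.inc_t) o += A * (T - 1);
  L.o_zdom = o; if (L.inc_mt) o += M * (T - 1);
  L.o_eta = o;
  L.n_eta = 0;
  for (int j = 0; j < NSIG; j++) {
    if (L.sig_active[j] && !fixed[j]) L.eta_of_slot[j] = L.n_eta++;
    else L.eta_of_slot[j] = -1;
  }
  L.npar = o + L.n_eta;
  return L;
}

struct ModelData {
  Layout L;
  std::vector<double> y, P, tc;
  std::vector<int> dom, rod; // 0-based maps
  double sig_value[NSIG];    // used when fixed
  double sig_prior[NSIG];    // half-normal scales
  int sig_fixed[NSIG];
  double anchor_alpha_mean, anchor_alpha_sd, anchor_beta_sd;
  // workspaces
  mutable std::vector<double> Theta, Phi, nu, om, gTheta, gPhi, gnu, gom,
      gThetaD, gThetaR, gPhiD, gPhiR, bnat, gB;
};

static double lp_grad(const ModelData& md, const double* q, double* g) {
  const Layout& L = md.L;
  const int A = L.A, M = L.M, T = L.T, D = L.D, R = L.R;
  std::fill(g, g + L.npar, 0.0);
  double sig[NSIG], deta[NSIG];
  for (int j = 0; j < NSIG; j++) {
    deta[j] = 0.0;
    if (!L.sig_active[j]) { sig[j] = 0.0; continue; }
    sig[j] = md.sig_fixed[j] ? md.sig_value[j]
                             : std::exp(q[L.o_eta + L.eta_of_slot[j]]);
  }
  const double* alpha = q + L.o_alpha;

  // beta block: [beta0, z_1..z_{A-1}], beta_a = beta0 + sig1 * cumsum(z)
  md.bnat.assign(A, 0.0);
  if (L.inc_t) {
    double c = q[L.o_beta];
    md.bnat[0] = c;
    for (int i = 1; i < A; i++) {
      c += sig[1] * q[L.o_beta + i];
      md.bnat[i] = c;
    }
  }
  const double* beta = md.bnat.data();

  // effects
  md.Theta.assign(M, 0.0); md.Phi.assign(M, 0.0);
  if (L.inc_m) {
    for (int m = 0; m < M; m++)
      md.Theta[m] = sig[2] * q[L.o_zthm + m] + sig[3] * q[L.o_zthd + md.dom[m]]
                  + sig[4] * q[L.o_zthr + md.rod[md.dom[m]]];
  }
  if (L.inc_mt) {
    for (int m = 0; m < M; m++)
      md.Phi[m] = sig[5] * q[L.o_zphm + m] + sig[6] * q[L.o_zphd + md.dom[m]]
                + sig[7] * q[L.o_zphr + md.rod[md.dom[m]]];
  }
  md.nu.assign(A * T, 0.0);
  if (L.inc_t) {
    for (int a = 0; a < A; a++) {
      double c = 0.0, mean = 0.0;
      for (int t = 1; t < T; t++) {
        c += sig[9] * q[L.o_zdnu + a * (T - 1) + t - 1];
        md.nu[a * T + t] = c; mean += c;
      }
      mean /= T;
      for (int t = 0; t < T; t++) md.nu[a * T + t] -= mean;
    }
  }
  md.om.assign(M * T, 0.0);
  if (L.inc_mt) {
    for (int m = 0; m < M; m++) {
      double c = 0.0, mean = 0.0;
      for (int t = 1; t < T; t++) {
        c += sig[10] * q[L.o_zdom + m * (T - 1) + t - 1];
        md.om[m * T + t] = c; mean += c;
      }
      mean /= T;
      for (int t = 0; t < T; t++) md.om[m * T + t] -= mean;
    }
  }

  // likelihood
  double lp = 0.0;
  md.gTheta.assign(M, 0.0); md.gPhi.assign(M, 0.0);
  md.gnu.assign(A * T, 0.0); md.gom.assign(M * T, 0.0);
  md.gB.assign(A, 0.0);
  double* gxi = L.inc_m ? g + L.o_zxi : nullptr; // accumulate d lp/d xi here
  for (int t = 0; t < T; t++) {
    const double tct = md.tc[t];
    for (int m = 0; m < M; m++) {
      const int base = A * (m + M * t);
      const double amt = md.Theta[m] + md.Phi[m] * tct + md.om[m * T + t];
      for (int a = 0; a < A; a++) {
        double ll = alpha[a] + amt;
        if (L.inc_t) ll += beta[a] * tct + md.nu[a * T + t];
        if (L.inc_m) ll += sig[8] * q[L.o_zxi + a + A * m];
        const double mu = md.P[base + a] * std::exp(ll);
        const double yy = md.y[base + a];
        lp += yy * ll - mu;
        const double r = yy - mu;
        g[L.o_alpha + a] += r;
        if (L.inc_t) { md.gB[a] += r * tct; md.gnu[a * T + t] += r; }
        if (L.inc_m) { md.gTheta[m] += r; gxi[a + A * m] += r; }
        if (L.inc_mt) { md.gPhi[m] += r * tct; md.gom[m * T + t] += r; }
      }
    }
  }
  if (!std::isfinite(lp)) return -std::numeric_limits<double>::infinity();

  // priors: alpha anchor + RW1
  {
    double d0 = (alpha[0] - md.anchor_alpha_mean) / md.anchor_alpha_sd;
    lp += -0.5 * d0 * d0;
    g[L.o_alpha] -= d0 / md.anchor_alpha_sd;
    if (A > 1) {
      const double s2 = sig[0] * sig[0];
      for (int i = 1; i < A; i++) {
        double d = alpha[i] - alpha[i - 1];
        lp += -0.5 * d * d / s2 - std::log(sig[0]);
        g[L.o_alpha + i] -= d / s2;
        g[L.o_alpha + i - 1] += d / s2;
        deta[0] += d * d / s2 - 1.0;
      }
    }
  }
  if (L.inc_t) { // beta: non-centred RW1 (beta0 anchor + std-normal increments)
    double b0 = q[L.o_beta];
    lp += -0.5 * (b0 / md.anchor_beta_sd) * (b0 / md.anchor_beta_sd);
    double gsum = 0.0;
    for (int a = 0; a < A; a++) gsum += md.gB[a];
    g[L.o_beta] = gsum - b0 / (md.anchor_beta_sd * md.anchor_beta_sd);
    double suf = 0.0;
    for (int k = A - 1; k >= 1; k--) {
      suf += md.gB[k];
      double z = q[L.o_beta + k];
      lp += -0.5 * z * z;
      g[L.o_beta + k] = sig[1] * suf - z;
      deta[1] += sig[1] * z * suf;
    }
  }
  // nested intercepts / slopes (non-centred)
  if (L.inc_m) {
    md.gThetaD.assign(D, 0.0); md.gThetaR.assign(R, 0.0);
    for (int m = 0; m < M; m++) {
      md.gThetaD[md.dom[m]] += md.gTheta[m];
      md.gThetaR[md.rod[md.dom[m]]] += md.gTheta[m];
    }
    for (int m = 0; m < M; m++) {
      double z = q[L.o_zthm + m];
      lp += -0.5 * z * z;
      g[L.o_zthm + m] += sig[2] * md.gTheta[m] - z;
      deta[2] += sig[2] * z * md.gTheta[m];
    }
    for (int d = 0; d < D; d++) {
      double z = q[L.o_zthd + d];
      lp += -0.5 * z * z;
      g[L.o_zthd + d] += sig[3] * md.gThetaD[d] - z;
      deta[3] += sig[3] * z * md.gThetaD[d];
    }
    for (int r = 0; r < R; r++) {
      double z = q[L.o_zthr + r];
      lp += -0.5 * z * z;
      g[L.o_zthr + r] += sig[4] * md.gThetaR[r] - z;
      deta[4] += sig[4] * z * md.gThetaR[r];
    }
    // xi: gxi currently holds likelihood gradient wrt xi effect
    for (int k = 0; k < A * M; k++) {
      double z = q[L.o_zxi + k], ge = gxi[k];
      lp += -0.5 * z * z;
      deta[8] += sig[8] * z * ge;
      g[L.o_zxi + k] = sig[8] * ge - z;
    }
  }
  if (L.inc_mt) {
    md.gPhiD.assign(D, 0.0); md.gPhiR.assign(R, 0.0);
    for (int m = 0; m < M; m++) {
      md.gPhiD[md.dom[m]] += md.gPhi[m];
      md.gPhiR[md.rod[md.dom[m]]] += md.gPhi[m];
    }
    for (int m = 0; m < M; m++) {
      double z = q[L.o_zphm + m];
      lp += -0.5 * z * z;
      g[L.o_zphm + m] += sig[5] * md.gPhi[m] - z;
      deta[5] += sig[5] * z * md.gPhi[m];
    }
    for (int d = 0; d < D; d++) {
      double z = q[L.o_zphd + d];
      lp += -0.5 * z * z;
      g[L.o_zphd + d] += sig[6] * md.gPhiD[d] - z;
      deta[6] += sig[6] * z * md.gPhiD[d];
    }
    for (int r = 0; r < R; r++) {
      double z = q[L.o_zphr + r];
      lp += -0.5 * z * z;
      g[L.o_zphr + r] += sig[7] * md.gPhiR[r] - z;
      deta[7] += sig[7] * z * md.gPhiR[r];
    }
  }
  // time random walks via centred-cumsum map
  if (L.inc_t) {
    for (int a = 0; a < A; a++) {
      double S = 0.0;
      for (int t = 0; t < T; t++) S += md.gnu[a * T + t];
      double suf = 0.0;
      for (int k = T - 2; k >= 0; k--) {
        suf += md.gnu[a * T + k + 1];
        double gd = suf - S * (double)(T - 1 - k) / T;
        double z = q[L.o_zdnu + a * (T - 1) + k];
        lp += -0.5 * z * z;
        deta[9] += sig[9] * z * gd;
        g[L.o_zdnu + a * (T - 1) + k] = sig[9] * gd - z;
      }
    }
  }
  if (L.inc_mt) {
    for (int m = 0; m < M; m++) {
      double S = 0.0;
      for (int t = 0; t < T; t++) S += md.gom[m * T + t];
      double suf = 0.0;
      for (int k = T - 2; k >= 0; k--) {
        suf += md.gom[m * T + k + 1];
        double gd = suf - S * (double)(T - 1 - k) / T;
        double z = q[L.o_zdom + m * (T - 1) + k];
        lp += -0.5 * z * z;
        deta[10] += sig[10] * z * gd;
        g[L.o_zdom + m * (T - 1) + k] = sig[10] * gd - z;
      }
    }
  }
  // half-normal hyperpriors on free scales (log parameterisation + Jacobian)
  for (int j = 0; j < NSIG; j++) {
    int e = L.eta_of_slot[j];
    if (e < 0) continue;
    double s = sig[j], S0 = md.sig_prior[j];
    lp += -0.5 * s * s / (S0 * S0) + std::log(s);
    deta[j] += -s * s / (S0 * S0) + 1.0;
    g[L.o_eta + e] = deta[j];
  }
  if (!std::isfinite(lp)) return -std::numeric_limits<double>::infinity();
  return lp;
}

static ModelData build_md(NumericVector y, NumericVector P, IntegerVector dims,
                          NumericVector tc, IntegerVector dom, IntegerVector rod,
                          LogicalVector sig_fixed, NumericVector sig_value,
                          NumericVector sig_prior, NumericVector anchors) {
  ModelData md;
  int fixed[NSIG];
  for (int j = 0; j < NSIG; j++) fixed[j] = sig_fixed[j] ? 1 : 0;
  md.L = make_layout(dims[0], dims[1], dims[2], dims[3], dims[4], fixed);
  md.y.assign(y.begin(), y.end());
  md.P.assign(P.begin(), P.end());
  md.tc.assign(tc.begin(), tc.end());
  md.dom.assign(dom.begin(), dom.end());
  md.rod.assign(rod.begin(), rod.end());
  for (int j = 0; j < NSIG; j++) {
    md.sig_fixed[j] = fixed[j];
    md.sig_value[j] = sig_value[j];
    md.sig_prior[j] = sig_prior[j];
  }
  md.anchor_alpha_mean = anchors[0];
  md.anchor_alpha_sd = anchors[1];
  md.anchor_beta_sd = anchors[2];
  return md;
}

// [[Rcpp::export]]
List cpp_param_layout(IntegerVector dims, LogicalVector sig_fixed) {
  int fixed[NSIG];
  for (int j = 0; j < NSIG; j++) fixed[j] = sig_fixed[j] ? 1 : 0;
  Layout L = make_layout(dims[0], dims[1], dims[2], dims[3], dims[4], fixed);
  IntegerVector eta(NSIG);
  for (int j = 0; j < NSIG; j++) eta[j] = L.eta_of_slot[j];
  return List::create(
      _["npar"] = L.npar, _["n_eta"] = L.n_eta,
      _["inc_t"] = L.inc_t, _["inc_m"] = L.inc_m, _["inc_mt"] = L.inc_mt,
      _["o_alpha"] = L.o_alpha, _["o_beta"] = L.o_beta,
      _["o_zthm"] = L.o_zthm, _["o_zthd"] = L.o_zthd, _["o_zthr"] = L.o_zthr,
      _["o_zphm"] = L.o_zphm, _["o_zphd"] = L.o_zphd, _["o_zphr"] = L.o_zphr,
      _["o_zxi"] = L.o_zxi, _["o_zdnu"] = L.o_zdnu, _["o_zdom"] = L.o_zdom,
      _["o_eta"] = L.o_eta, _["eta_of_slot"] = eta);
}

// [[Rcpp::export]]
List cpp_lp_grad(NumericVector q, NumericVector y, NumericVector P,
                 IntegerVector dims, NumericVector tc, IntegerVector dom,
                 IntegerVector rod, LogicalVector sig_fixed,
                 NumericVector sig_value, NumericVector sig_prior,
                 NumericVector anchors) {
  ModelData md = build_md(y, P, dims, tc, dom, rod, sig_fixed, sig_value,
                          sig_prior, anchors);
  if ((int)q.size() != md.L.npar) stop("q has wrong length");
  NumericVector g(md.L.npar);
  double lp = lp_grad(md, q.begin(), g.begin());
  return List::create(_["lp"] = lp, _["grad"] = g);
}

// ---------------- NUTS ----------------

struct NutsState {
  const ModelData* md;
  std::mt19937_64 rng;
  std::vector<double> minv; // inverse mass (diagonal)
  double eps;
  int max_depth;
  // per-iteration accumulators
  double sum_alpha; int n_alpha; bool divergent;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  std::normal_distribution<double> norm{0.0, 1.0};
};

struct Point { std::vector<double> q, p, g; double lp; };

static void leapfrog(NutsState& st, Point& z, double dir) {
  const int n = (int)z.q.size();
  const double e = dir * st.eps;
  for (int i = 0; i < n; i++) z.p[i] += 0.5 * e * z.g[i];
  for (int i = 0; i < n; i++) z.q[i] += e * st.minv[i] * z.p[i];
  z.lp = lp_grad(*st.md, z.q.data(), z.g.data());
  for (int i = 0; i < n; i++) z.p[i] += 0.5 * e * z.g[i];
}

static double joint_of(const NutsState& st, const Point& z) {
  double ke = 0.0;
  for (size_t i = 0; i < z.p.size(); i++) ke += st.minv[i] * z.p[i] * z.p[i];
  return z.lp - 0.5 * ke;
}

struct Tree {
  Point zm, zp, zprop;
  double n; bool s;
};

static bool uturn(const NutsState& st, const Point& zm, const Point& zp) {
  double dm = 0.0, dp = 0.0;
  for (size_t i = 0; i < zm.q.size(); i++) {
    double dq = zp.q[i] - zm.q[i];
    dm += dq * st.minv[i] * zm.p[i];
    dp += dq * st.minv[i] * zp.p[i];
  }
  return (dm < 0.0) || (dp < 0.0);
}

static Tree build_tree(NutsState& st, const Point& z0, double lu, double dir,
                       int depth, double joint0) {
  Tree tr;
  if (depth == 0) {
    Point z = z0;
    leapfrog(st, z, dir);
    double j = joint_of(st, z);
    bool ok = std::isfinite(j);
    tr.n = (ok && lu <= j) ? 1.0 : 0.0;
    tr.s = ok && (lu < j + 1000.0);
    if (!tr.s) st.divergent = true;
    double a = ok ? std::exp(std::min(0.0, j - joint0)) : 0.0;
    st.sum_alpha += a; st.n_alpha += 1;
    tr.zm = z; tr.zp = z; tr.zprop = z;
    return tr;
  }
  Tree t1 = build_tree(st, z0, lu, dir, depth - 1, joint0);
  if (!t1.s) return t1;
  const Point& edge = (dir > 0) ? t1.zp : t1.zm;
  Tree t2 = build_tree(st, edge, lu, dir, depth - 1, joint0);
  Tree tr2;
  tr2.zm = (dir > 0) ? t1.zm : t2.zm;
  tr2.zp = (dir > 0) ? t2.zp : t1.zp;
  tr2.n = t1.n + t2.n;
  if (t2.n > 0 && st.unif(st.rng) < t2.n / std::max(tr2.n, 1e-300))
    tr2.zprop = t2.zprop;
  else tr2.zprop = t1.zprop;
  tr2.s = t2.s && !uturn(st, tr2.zm, tr2.zp);
  return tr2;
}

static Point nuts_iter(NutsState& st, const Point& cur) {
  const int n = (int)cur.q.size();
  Point z = cur;
  for (int i = 0; i < n; i++)
    z.p[i] = st.norm(st.rng) / std::sqrt(st.minv[i]);
  double joint0 = joint_of(st, z);
  std::exponential_distribution<double> rexp(1.0);
  double lu = joint0 - rexp(st.rng);
  Point zm = z, zp = z, zsel = z;
  double ntot = 1.0; bool s = true;
  st.sum_alpha = 0.0; st.n_alpha = 0; st.divergent = false;
  for (int depth = 0; s && depth < st.max_depth; depth++) {
    double dir = (st.unif(st.rng) < 0.5) ? -1.0 : 1.0;
    Tree tr = build_tree(st, (dir > 0) ? zp : zm, lu, dir, depth, joint0);
    if (dir > 0) zp = tr.zp; else zm = tr.zm;
    if (tr.s && st.unif(st.rng) < tr.n / std::max(ntot, 1e-300))
      zsel = tr.zprop;
    ntot += tr.n;
    s = tr.s && !uturn(st, zm, zp);
  }
  return zsel;
}

// [[Rcpp::export]]
List cpp_nuts(NumericVector q0, NumericVector y, NumericVector P,
              IntegerVector dims, NumericVector tc, IntegerVector dom,
              IntegerVector rod, LogicalVector sig_fixed,
              NumericVector sig_value, NumericVector sig_prior,
              NumericVector anchors, int warmup, int iter, int thin,
              double target_accept, int max_depth, int seed,
              bool adapt_metric) {
  ModelData md = build_md(y, P, dims, tc, dom, rod, sig_fixed, sig_value,
                          sig_prior, anchors);
  const int n = md.L.npar;
  if ((int)q0.size() != n) stop("q0 has wrong length");
  NutsState st;
  st.md = &md;
  st.rng.seed((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  st.minv.assign(n, 1.0);
  st.max_depth = max_depth;

  Point cur;
  cur.q.assign(q0.begin(), q0.end());
  cur.p.assign(n, 0.0);
  cur.g.assign(n, 0.0);
  cur.lp = lp_grad(md, cur.q.data(), cur.g.data());
  if (!std::isfinite(cur.lp)) stop("non-finite log posterior at initial values");

  // reasonable initial step size: halve/double until accept prob ~ 0.5
  st.eps = 0.1;
  {
    Point z = cur;
    for (int i = 0; i < n; i++) z.p[i] = st.norm(st.rng);
    double j0 = joint_of(st, z);
    Point z1 = z;
    leapfrog(st, z1, 1.0);
    double dj = joint_of(st, z1) - j0;
    double a = (std::isfinite(dj) && dj > std::log(0.5)) ? 1.0 : -1.0;
    for (int k = 0; k < 50; k++) {
      st.eps *= (a > 0) ? 2.0 : 0.5;
      Point z2 = z;
      leapfrog(st, z2, 1.0);
      dj = joint_of(st, z2) - j0;
      if (!std::isfinite(dj)) dj = -1e300;
      if (a * dj <= a * std::log(0.5)) break;
    }
  }

  // dual averaging
  double mu = std::log(10.0 * st.eps), logeps = std::log(st.eps),
         logeps_bar = 0.0, hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // metric adaptation windows (Stan-like buffers)
  int winit = std::max(20, (int)(0.25 * warmup));
  int wterm = std::max(15, (int)(0.15 * warmup));
  bool do_metric = adapt_metric && warmup >= 60;
  int wstart = do_metric ? winit : warmup + 1;
  int wsize = std::max(25, (int)(0.1 * warmup));
  int wend = do_metric ? std::min(warmup - wterm, wstart + wsize) : warmup + 1;
  std::vector<double> wm(n, 0.0), ws(n, 0.0);
  long wn = 0;

  int n_keep = iter / thin;
  NumericMatrix draws(n_keep, n);
  NumericVector lps(n_keep);
  int divergences = 0, kept = 0;
  double sum_accept = 0.0;
  int n_accept = 0;

  for (int it = 0; it < warmup + iter; it++) {
    cur = nuts_iter(st, cur);
    double astat = (st.n_alpha > 0) ? st.sum_alpha / st.n_alpha : 0.0;
    if (it < warmup) {
      // dual averaging step-size update
      da_count++;
      double w = 1.0 / (da_count + t0);
      hbar = (1.0 - w) * hbar + w * (target_accept - astat);
      logeps = mu - std::sqrt((double)da_count) / gamma * hbar;
      double w2 = std::pow((double)da_count, -kappa);
      logeps_bar = w2 * logeps + (1.0 - w2) * logeps_bar;
      st.eps = std::exp(logeps);
      // metric accumulation
      if (do_metric && it >= wstart && it < wend) {
        wn++;
        for (int i = 0; i < n; i++) {
          double d = cur.q[i] - wm[i];
          wm[i] += d / wn;
          ws[i] += d * (cur.q[i] - wm[i]);
        }
        if (it == wend - 1 && wn > 1) {
          for (int i = 0; i < n; i++) {
            double v = ws[i] / (wn - 1);
            st.minv[i] = (double)wn / (wn + 5.0) * v + 1e-3 * 5.0 / (wn + 5.0);
          }
          std::fill(wm.begin(), wm.end(), 0.0);
          std::fill(ws.begin(), ws.end(), 0.0);
          wn = 0;
          wstart = wend;
          wsize *= 2;
          wend = std::min(warmup - wterm, wstart + wsize);
          if (warmup - wterm - wend < wsize) wend = warmup - wterm;
          // restart step-size adaptation around the current value
          mu = std::log(10.0 * st.eps);
          da_count = 0; hbar = 0.0; logeps_bar = std::log(st.eps);
        }
      }
      if (it == warmup - 1) st.eps = std::exp(logeps_bar);
    } else {
      sum_accept += astat; n_accept++;
      if (st.divergent) divergences++;
      if ((it - warmup + 1) % thin == 0 && kept < n_keep) {
        for (int i = 0; i < n; i++) draws(kept, i) = cur.q[i];
        lps[kept] = cur.lp;
        kept++;
      }
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["draws"] = draws, _["lp"] = lps, _["eps"] = st.eps,
      _["divergences"] = divergences,
      _["accept_rate"] = n_accept ? sum_accept / n_accept : NA_REAL,
      _["inv_mass"] = NumericVector(st.minv.begin(), st.minv.end()));
}
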
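// Numerical core: scaled forward / forward-backward recursions for the
// two-state HMM, a von Mises sampler, and the step-by-step path simulator.
// All random draws go through R's RNG so set.seed() controls everything.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093454836;

// Per-state constants of the emission densities, precomputed once per
// likelihood evaluation (the Bessel and lgamma terms dominate otherwise).
struct EmissionConsts {
  double shape[2], inv_scale[2], g_norm[2];  // gamma: -lgamma(shape)-shape*log(scale)
  double kappa[2], mang[2], vm_norm[2];      // von Mises: -log(2 pi I0(kappa))
};

static EmissionConsts emission_consts(const NumericVector& mu,
                                      const NumericVector& sigma,
                                      const NumericVector& kappa,
                                      const NumericVector& mang) {
  EmissionConsts ec;
  for (int s = 0; s < 2; ++s) {
    double shape = (mu[s] / sigma[s]) * (mu[s] / sigma[s]);
    double scale = sigma[s] * sigma[s] / mu[s];
    ec.shape[s] = shape;
    ec.inv_scale[s] = 1.0 / scale;
    ec.g_norm[s] = -std::lgamma(shape) - shape * std::log(scale);
    ec.kappa[s] = kappa[s];
    ec.mang[s] = mang[s];
    ec.vm_norm[s] = -LOG_2PI - (std::log(Rf_bessel_i(kappa[s], 0.0, 2.0)) + kappa[s]);
  }
  return ec;
}

static inline double emis_log(const EmissionConsts& ec, int s, double len,
                              double ang, bool has_ang) {
  double v = (ec.shape[s] - 1.0) * std::log(len) - len * ec.inv_scale[s] + ec.g_norm[s];
  if (has_ang)
    v += ec.kappa[s] * std::cos(ang - ec.mang[s]) + ec.vm_norm[s];
  return v;
}

static inline double plogis_(double eta) { return 1.0 / (1.0 + std::exp(-eta)); }

// Per-observation transition logits. X has one row per observation (covariates
// at the step's start, intercept NOT included); beta is 2 x (1 + ncov):
// row 0 = slow->fast, row 1 = fast->slow.
static inline void trans_probs(const NumericMatrix& X, int t,
                               const NumericMatrix& beta,
                               double& g_sf, double& g_fs) {
  double e1 = beta(0, 0), e2 = beta(1, 0);
  for (int j = 0; j < X.ncol(); ++j) {
    e1 += beta(0, j + 1) * X(t, j);
    e2 += beta(1, j + 1) * X(t, j);
  }
  g_sf = plogis_(e1);
  g_fs = plogis_(e2);
}

// Emission log-density matrix (T x 2). Missing turn angles (NA) contribute
// length only.
static NumericMatrix emission_logdens(const NumericVector& len,
                                      const NumericVector& ang,
                                      const NumericVector& mu,
                                      const NumericVector& sigma,
                                      const NumericVector& kappa,
                                      const NumericVector& mang) {
  int T = len.size();
  EmissionConsts ec = emission_consts(mu, sigma, kappa, mang);
  NumericMatrix ld(T, 2);
  for (int t = 0; t < T; ++t) {
    bool has_ang = !NumericVector::is_na(ang[t]);
    for (int s = 0; s < 2; ++s)
      ld(t, s) = emis_log(ec, s, len[t], ang[t], has_ang);
  }
  return ld;
}

// [[Rcpp::export]]
double hmm_loglik_cpp(NumericVector len, NumericVector ang, NumericMatrix X,
                      IntegerVector seg_start, NumericVector mu,
                      NumericVector sigma, NumericVector kappa,
                      NumericVector mang, NumericMatrix beta) {
  int T = len.size();
  NumericMatrix ld = emission_logdens(len, ang, mu, sigma, kappa, mang);
  double ll = 0.0, a0 = 0.0, a1 = 0.0;
  for (int t = 0; t < T; ++t) {
    double g_sf, g_fs;
    trans_probs(X, t, beta, g_sf, g_fs);
    double d0 = std::exp(ld(t, 0)), d1 = std::exp(ld(t, 1));
    double n0, n1;
    if (seg_start[t]) {
      // initial distribution: stationary at the first step's covariates
      double pi_f = g_sf / (g_sf + g_fs);
      n0 = (1.0 - pi_f) * d0;
      n1 = pi_f * d1;
    } else {
      n0 = (a0 * (1.0 - g_sf) + a1 * g_fs) * d0;
      n1 = (a0 * g_sf + a1 * (1.0 - g_fs)) * d1;
    }
    double c = n0 + n1;
    if (c <= 0.0 || !R_finite(c)) return -1e300;
    ll += std::log(c);
    a0 = n0 / c;
    a1 = n1 / c;
  }
  return ll;
}

// Forward-backward smoothing; returns T x 2 matrix of P(state | all data),
// column 0 = slow, column 1 = fast.
// [[Rcpp::export]]
NumericMatrix hmm_posterior_cpp(NumericVector len, NumericVector ang,
                                NumericMatrix X, IntegerVector seg_start,
                                NumericVector mu, NumericVector sigma,
                                NumericVector kappa, NumericVector mang,
                                NumericMatrix beta) {
  int T = len.size();
  NumericMatrix ld = emission_logdens(len, ang, mu, sigma, kappa, mang);
  NumericMatrix alpha(T, 2), bw(T, 2), out(T, 2);
  NumericVector gsf(T), gfs(T);
  for (int t = 0; t < T; ++t) {
    double g_sf, g_fs;
    trans_probs(X, t, beta, g_sf, g_fs);
    gsf[t] = g_sf; gfs[t] = g_fs;
    double d0 = std::exp(ld(t, 0)), d1 = std::exp(ld(t, 1));
    double n0, n1;
    if (seg_start[t]) {
      double pi_f = g_sf / (g_sf + g_fs);
      n0 = (1.0 - pi_f) * d0; n1 = pi_f * d1;
    } else {
      n0 = (alpha(t - 1, 0) * (1.0 - g_sf) + alpha(t - 1, 1) * g_fs) * d0;
      n1 = (alpha(t - 1, 0) * g_sf + alpha(t - 1, 1) * (1.0 - g_fs)) * d1;
    }
    double c = n0 + n1;
    alpha(t, 0) = n0 / c; alpha(t, 1) = n1 / c;
  }
  // backward pass within segments (scaled; rescale each step)
  for (int t = T - 1; t >= 0; --t) {
    bool last = (t == T - 1) || seg_start[t + 1];
    if (last) {
      bw(t, 0) = 1.0; bw(t, 1) = 1.0;
    } else {
      double d0 = std::exp(ld(t + 1, 0)), d1 = std::exp(ld(t + 1, 1));
      double b0 = (1.0 - gsf[t + 1]) * d0 * bw(t + 1, 0) + gsf[t + 1] * d1 * bw(t + 1, 1);
      double b1 = gfs[t + 1] * d0 * bw(t + 1, 0) + (1.0 - gfs[t + 1]) * d1 * bw(t + 1, 1);
      double c = b0 + b1;
      bw(t, 0) = b0 / c; bw(t, 1) = b1 / c;
    }
    double p0 = alpha(t, 0) * bw(t, 0), p1 = alpha(t, 1) * bw(t, 1);
    double c = p0 + p1;
    out(t, 0) = p0 / c; out(t, 1) = p1 / c;
  }
  return out;
}

// von Mises sampling, Best & Fisher (1979) rejection envelope.
static double rvm1(double m, double k) {
  if (k < 1e-10) return R::runif(-M_PI, M_PI);
  double a = 1.0 + std::sqrt(1.0 + 4.0 * k * k);
  double b = (a - std::sqrt(2.0 * a)) / (2.0 * k);
  double r = (1.0 + b * b) / (2.0 * b);
  double f, c;
  for (;;) {
    double u1 = R::unif_rand();
    double z = std::cos(M_PI * u1);
    f = (1.0 + r * z) / (r + z);
    c = k * (r - f);
    double u2 = R::unif_rand();
    if (c * (2.0 - c) - u2 > 0.0) break;
    if (std::log(c / u2) + 1.0 - c >= 0.0) break;
  }
  double u3 = R::unif_rand();
  double th = (u3 > 0.5 ? 1.0 : -1.0) * std::acos(f) + m;
  // wrap to (-pi, pi]
  th = std::fmod(th + M_PI, 2.0 * M_PI);
  if (th <= 0) th += 2.0 * M_PI;
  return th - M_PI;
}

// [[Rcpp::export]]
NumericVector rvonmises_cpp(int n, double m, double k) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rvm1(m, k);
  return out;
}

// --- path simulator ---------------------------------------------------------

struct Grid {
  double x0, y0, cs;
  int nr, nc;
  bool cell(double x, double y, int& r, int& c) const {
    c = (int)std::floor((x - x0) / cs);
    r = (int)std::floor((y - y0) / cs);
    return (c >= 0 && c < nc && r >= 0 && r < nr);
  }
};

static double dist_to_segs(double px, double py, const NumericMatrix& segs) {
  double best = R_PosInf;
  for (int i = 0; i < segs.nrow(); ++i) {
    double x1 = segs(i, 0), y1 = segs(i, 1), x2 = segs(i, 2), y2 = segs(i, 3);
    double dx = x2 - x1, dy = y2 - y1;
    double len2 = dx * dx + dy * dy, d;
    if (len2 == 0.0) {
      d = std::hypot(px - x1, py - y1);
    } else {
      double t = ((px - x1) * dx + (py - y1) * dy) / len2;
      t = std::max(0.0, std::min(1.0, t));
      d = std::hypot(px - (x1 + t * dx), py - (y1 + t * dy));
    }
    if (d < best) best = d;
  }
  return best;
}

// Simulate one path. `bundle` carries the scenario-adjusted model:
//   grid: list(x0, y0, cs, nr, nc); mask: logical matrix (TRUE = available)
//   end_layers: list of matrices; beta_end / beta_end_state / beta_end_chour
//   tcov_idx: integer vector, 1-based indices into end_layers giving the HMM
//             transition covariates AFTER c_hour (c_hour always first)
//   onoff: list per feature class: list(segs, cdist, beta, beta_state,
//          beta_chour); buffer in metres
//   beta_move: length 2 (step length km, cos turn angle) + state/chour copies
//   hmm: mu, sigma, kappa, mang (each length 2), beta (2 x (1 + 1 + n_tcov))
//   config: n_cand, fracs, boundary_threshold, boundary_cumulative, max_redraw,
//           stuck_limit, fix_h
// Returns list(path = (n+1) x 4 matrix [x, y, hour, state], reason,
//              n_proposed, n_outside, n_holds).
// [[Rcpp::export]]
List simulate_path_cpp(double x0, double y0, int start_state, double start_hour,
                       double start_bearing, int n_steps, List bundle) {
  List gl = bundle["grid"];
  Grid g{as<double>(gl["x0"]), as<double>(gl["y0"]), as<double>(gl["cs"]),
         as<int>(gl["nr"]), as<int>(gl["nc"])};
  LogicalMatrix mask = bundle["mask"];
  List end_layers = bundle["end_layers"];
  int nl = end_layers.size();
  std::vector<NumericMatrix> L(nl);
  for (int j = 0; j < nl; ++j) L[j] = as<NumericMatrix>(end_layers[j]);
  NumericVector be = bundle["beta_end"], bes = bundle["beta_end_state"],
                bec = bundle["beta_end_chour"];
  IntegerVector tcov_idx = bundle["tcov_idx"];
  List onoff = bundle["onoff"];
  double buffer = as<double>(bundle["buffer"]);
  int n_onoff = onoff.size();
  std::vector<NumericMatrix> osegs(n_onoff), ocdist(n_onoff);
  NumericVector ob(n_onoff), obs(n_onoff), obc(n_onoff);
  for (int j = 0; j < n_onoff; ++j) {
    List cl = onoff[j];
    osegs[j] = as<NumericMatrix>(cl["segs"]);
    ocdist[j] = as<NumericMatrix>(cl["cdist"]);
    ob[j] = as<double>(cl["beta"]);
    obs[j] = as<double>(cl["beta_state"]);
    obc[j] = as<double>(cl["beta_chour"]);
  }
  NumericVector bm = bundle["beta_move"], bms = bundle["beta_move_state"],
                bmc = bundle["beta_move_chour"];
  List hp = bundle["hmm"];
  NumericVector mu = hp["mu"], sigma = hp["sigma"], kappa = hp["kappa"],
                mang = hp["mang"];
  NumericMatrix tbeta = hp["beta"];
  List cfg = bundle["config"];
  int n_cand = as<int>(cfg["n_cand"]);
  NumericVector fracs = cfg["fracs"];
  double bthr = as<double>(cfg["boundary_threshold"]);
  bool bcum = as<bool>(cfg["boundary_cumulative"]);
  int max_redraw = as<int>(cfg["max_redraw"]);
  int stuck_limit = as<int>(cfg["stuck_limit"]);
  double fix_h = as<double>(cfg["fix_h"]);
  double half_diag = g.cs * std::sqrt(2.0) / 2.0;

  NumericMatrix path(n_steps + 1, 4);
  path(0, 0) = x0; path(0, 1) = y0; path(0, 2) = start_hour;
  path(0, 3) = start_state;

  double x = x0, y = y0, hour = start_hour, bearing = start_bearing;
  int state = start_state;  // 0 = slow, 1 = fast
  long n_prop = 0, n_out = 0;
  int n_holds = 0, consec_holds = 0, done = 0;
  std::string reason = "completed";

  std::vector<double> shape(2), scale(2);
  for (int s = 0; s < 2; ++s) {
    shape[s] = (mu[s] / sigma[s]) * (mu[s] / sigma[s]);
    scale[s] = sigma[s] * sigma[s] / mu[s];
  }

  for (int t = 1; t <= n_steps; ++t) {
    int r0, c0;
    g.cell(x, y, r0, c0);
    // transition probabilities at the step's start
    double chour = std::cos(2.0 * M_PI * hour / 24.0);
    double e_sf = tbeta(0, 0) + tbeta(0, 1) * chour;
    double e_fs = tbeta(1, 0) + tbeta(1, 1) * chour;
    for (int j = 0; j < tcov_idx.size(); ++j) {
      double v = L[tcov_idx[j] - 1](r0, c0);
      e_sf += tbeta(0, 2 + j) * v;
      e_fs += tbeta(1, 2 + j) * v;
    }
    double g_sf = plogis_(e_sf), g_fs = plogis_(e_fs);
    double p_switch = (state == 0) ? g_sf : g_fs;

    bool placed = false;
    long step_prop = 0, step_out = 0;
    for (int attempt = 0; attempt <= max_redraw && !placed; ++attempt) {
      std::vector<int> cst(n_cand), crow(n_cand), ccol(n_cand);
      std::vector<double> cx(n_cand), cy(n_cand), cturn(n_cand), clen(n_cand),
          ceta(n_cand);
      std::vector<bool> alive(n_cand, false);
      int n_alive = 0;
      for (int i = 0; i < n_cand; ++i) {
        int s_i = (R::unif_rand() < p_switch) ? 1 - state : state;
        double len = R::rgamma(shape[s_i], scale[s_i]);
        double turn = rvm1(mang[s_i], kappa[s_i]);
        double br = bearing + turn;
        double ex = x + len * std::cos(br), ey = y + len * std::sin(br);
        ++n_prop; ++step_prop;
        int er, ec;
        if (!g.cell(ex, ey, er, ec)) { ++n_out; ++step_out; continue; }
        // rejection: sample points along the step, all must be available
        bool ok = true;
        for (int f = 0; f < fracs.size() && ok; ++f) {
          double px = x + fracs[f] * (ex - x), py = y + fracs[f] * (ey - y);
          int pr, pc;
          if (!g.cell(px, py, pr, pc) || !mask(pr, pc)) ok = false;
        }
        if (!ok) continue;
        // selection score
        double eta = 0.0;
        for (int j = 0; j < nl; ++j)
          eta += (be[j] + s_i * bes[j] + chour * bec[j]) * L[j](er, ec);
        for (int j = 0; j < n_onoff; ++j) {
          double bsum = ob[j] + s_i * obs[j] + chour * obc[j];
          if (bsum == 0.0) continue;
          double dc = ocdist[j](er, ec);
          bool on;
          if (dc > buffer + half_diag) on = false;
          else if (dc <= buffer - half_diag) on = true;
          else on = (dist_to_segs(ex, ey, osegs[j]) <= buffer);
          if (on) eta += bsum;
        }
        eta += (bm[0] + s_i * bms[0] + chour * bmc[0]) * (len / 1000.0);
        eta += (bm[1] + s_i * bms[1] + chour * bmc[1]) * std::cos(turn);
        cst[i] = s_i; cx[i] = ex; cy[i] = ey; cturn[i] = turn; clen[i] = len;
        ceta[i] = eta; crow[i] = er; ccol[i] = ec; alive[i] = true;
        ++n_alive;
      }
      if (n_alive > 0) {
        // softmax over survivors
        double emax = -R_PosInf;
        for (int i = 0; i < n_cand; ++i)
          if (alive[i] && ceta[i] > emax) emax = ceta[i];
        double tot = 0.0;
        std::vector<double> w(n_cand, 0.0);
        for (int i = 0; i < n_cand; ++i)
          if (alive[i]) { w[i] = std::exp(ceta[i] - emax); tot += w[i]; }
        double u = R::unif_rand() * tot, acc = 0.0;
        int pick = -1;
        for (int i = 0; i < n_cand; ++i) {
          if (!alive[i]) continue;
          acc += w[i];
          if (u <= acc) { pick = i; break; }
        }
        if (pick < 0) for (int i = n_cand - 1; i >= 0; --i) if (alive[i]) { pick = i; break; }
        x = cx[pick]; y = cy[pick]; state = cst[pick];
        bearing = bearing + cturn[pick];
        placed = true;
        consec_holds = 0;
      }
    }
    if (!placed) {
      // hold position for this fix; resample state from the transition row
      state = (R::unif_rand() < p_switch) ? 1 - state : state;
      ++n_holds;
      ++consec_holds;
    }
    hour = std::fmod(hour + fix_h, 24.0);
    path(t, 0) = x; path(t, 1) = y; path(t, 2) = hour; path(t, 3) = state;
    done = t;
    if (consec_holds > stuck_limit) { reason = "stuck"; break; }
    double frac_out = bcum ? (n_prop > 0 ? (double)n_out / n_prop : 0.0)
                           : (step_prop > 0 ? (double)step_out / step_prop : 0.0);
    if (frac_out > bthr) { reason = "boundary"; break; }
  }
  NumericMatrix out(done + 1, 4);
  for (int i = 0; i <= done; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = path(i, j);
  colnames(out) = CharacterVector::create("x", "y", "hour", "state");
  return List::create(_["path"] = out, _["reason"] = reason,
                      _["n_proposed"] = (double)n_prop,
                      _["n_outside"] = (double)n_out,
                      _["n_holds"] = n_holds);
}
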
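#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Wiener first-passage-time density at the LOWER boundary, evaluated on the
// decision-time scale (t = rt - tau > 0), diffusion coefficient fixed at 1.
//   a : boundary separation (> 0)
//   w : relative starting point measured from the lower boundary (0, 1)
//   v : drift rate (signed; positive drives toward the UPPER boundary)
// The standardized density f(t/a^2; 0, 1, w) is computed with the
// small-time / large-time series pair; the number of terms for each expansion
// is chosen so the truncation error is below `eps`, and whichever expansion
// needs fewer terms is used.

static const double WFPT_EPS = 1e-7;

static double wfpt_lower_log(double t, double v, double a, double w) {
  if (t <= 0.0 || a <= 0.0 || w <= 0.0 || w >= 1.0) return R_NegInf;

  double tt = t / (a * a);  // standardized time

  // number of terms needed: small-time expansion
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * WFPT_EPS < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * WFPT_EPS * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  // large-time expansion
  double kl;
  if (M_PI * tt * WFPT_EPS < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * WFPT_EPS) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }

  double log_p;  // log of the standardized density f(tt; 0, 1, w)
  if (ks < kl) {  // small-time series, summed in log space (stable for
                  // decision times down to 1e-4 s and below)
    int K = (int)std::ceil(ks);
    int k_lo = -(K - 1) / 2, k_hi = K / 2;
    double m = R_NegInf;
    for (int k = k_lo; k <= k_hi; k++) {
      double x = w + 2.0 * k;
      double e = -x * x / (2.0 * tt);
      if (e > m) m = e;
    }
    double sum = 0.0;
    for (int k = k_lo; k <= k_hi; k++) {
      double x = w + 2.0 * k;
      sum += x * std::exp(-x * x / (2.0 * tt) - m);
    }
    if (sum <= 0.0 || !R_finite(sum)) return R_NegInf;
    log_p = m + std::log(sum) -
            0.5 * std::log(2.0 * M_PI * tt * tt * tt);
  } else {       // large-time series
    int K = (int)std::ceil(kl);
    double sum = 0.0;
    for (int k = 1; k <= K; k++) {
      sum += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
             std::sin(k * M_PI * w);
    }
    if (sum <= 0.0 || !R_finite(sum)) return R_NegInf;
    log_p = std::log(sum * M_PI);
  }

  // unstandardize and add the drift term
  return log_p - v * a * w - v * v * t / 2.0 - 2.0 * std::log(a);
}

// Tail mass beyond decision time t at the LOWER boundary: integral of the
// large-time series term by term, sum_k [pi/a^2 * e^{-vaw} * k sin(k pi w) /
// lambda_k] * e^{-lambda_k t} with lambda_k = (v^2 + k^2 pi^2 / a^2) / 2.
static double wfpt_lower_tail(double t, double v, double a, double w) {
  double pref = (M_PI / (a * a)) * std::exp(-v * a * w);
  double sum = 0.0;
  for (int k = 1; k <= 500; k++) {
    double lam = 0.5 * (v * v + k * k * M_PI * M_PI / (a * a));
    double mag = k * std::exp(-lam * t) / lam;
    sum += mag * std::sin(k * M_PI * w);
    if (mag * pref < 1e-12 && k > 3) break;
  }
  double out = pref * sum;
  return (out > 0.0) ? out : 0.0;
}

// Probability that the diffusion is still unabsorbed at decision time t
// (both boundaries); the upper-boundary tail follows by reflection.
// [[Rcpp::export(name = ".wfpt_survival_cpp")]]
double wfpt_survival_cpp(double t, double v, double a, double w) {
  if (t <= 0.0) return 1.0;
  double s = wfpt_lower_tail(t, v, a, w) + wfpt_lower_tail(t, -v, a, 1.0 - w);
  if (s > 1.0) s = 1.0;
  if (s < 0.0) s = 0.0;
  return s;
}

// log density of hitting the boundary that corresponds to the observed
// response, under accuracy coding: correct = upper boundary, start at z.
// The upper-boundary density follows from the reflection identity
//   f_upper(t; v, z) = f_lower(t; -v, 1 - z).
static double wfpt_log_response(double rt, bool correct, double v, double a,
                                double z, double tau) {
  double t = rt - tau;
  if (t <= 0.0) return R_NegInf;
  if (correct) return wfpt_lower_log(t, -v, a, 1.0 - z);
  return wfpt_lower_log(t, v, a, z);
}

// [[Rcpp::export(name = ".wfpt_log_cpp")]]
NumericVector wfpt_log_cpp(NumericVector rt, LogicalVector correct,
                           NumericVector v, NumericVector a, NumericVector z,
                           NumericVector tau) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    out[i] = wfpt_log_response(rt[i % rt.size()], correct[i % correct.size()],
                               v[i % v.size()], a[i % a.size()],
                               z[i % z.size()], tau[i % tau.size()]);
  }
  return out;
}

static double boundary_value(double a_base, double a_mod, int t_in_run,
                             int mapping) {
  // mapping: 0 = static, 1 = exponential (power), 2 = linear
  if (mapping == 1) return a_base * std::pow((double)t_in_run, a_mod);
  if (mapping == 2) return a_base + a_mod * (t_in_run - 1);
  return a_base;
}

// Replay the delta-rule recursion over one subject's ordered trials and
// evaluate the WFPT log density for each responded trial.
//
// run, trial_in_run : 1-based indices; pair_idx : 1-based pairing index
// status : 0 = missed, 1 = correct, 2 = incorrect
// feedback : 0/1 (ignored for missed trials)
// n_pairs : number of pairings per run (AS reset to 0.5 at run starts)
// pars : eta_pos, eta_neg, a_base, a_mod, tau, z, v_mod
//        (single-rate variants pass eta in both eta slots)
// floor_log : if true, clamp -Inf pointwise terms at -700
//
// Returns total, pointwise (responded trials, trial order), and the full
// per-trial derived series (as, pe, drift, boundary; pe is NA for missed).
// foil_idx: 1-based pairing index of the foil character on screen, or 0 when
// unknown (the foil association then counts at its as_init resting value)
// missed_mode: 0 = exclude missed trials from the likelihood entirely;
// 1 = censor (each missed trial contributes the log probability that the
// diffusion is unabsorbed at the deadline). Censored terms are summed into
// `censor_loglik` and added to `total`, but are not part of `pointwise`.
// [[Rcpp::export(name = ".seq_loglik_cpp")]]
List seq_loglik_cpp(IntegerVector run, IntegerVector trial_in_run,
                    IntegerVector pair_idx, IntegerVector foil_idx,
                    IntegerVector status,
                    IntegerVector feedback, int n_pairs, NumericVector pars,
                    int mapping, bool floor_log, NumericVector rt,
                    double as_init, double deadline, int missed_mode) {
  int n = run.size();
  double eta_pos = pars[0], eta_neg = pars[1], a_base = pars[2],
         a_mod = pars[3], tau = pars[4], z = pars[5], v_mod = pars[6];

  std::vector<double> as(n_pairs, as_init);
  NumericVector as_t(n), pe_t(n), drift_t(n), bound_t(n);
  std::vector<double> pw;
  pw.reserve(n);
  double total = 0.0, censor_total = 0.0;
  int cur_run = -1;

  for (int i = 0; i < n; i++) {
    if (run[i] != cur_run) {  // run boundary: fresh pairings
      cur_run = run[i];
      std::fill(as.begin(), as.end(), as_init);
    }
    int p = pair_idx[i] - 1;
    double as_cur = as[p];
    double as_foil = (foil_idx[i] > 0) ? as[foil_idx[i] - 1] : as_init;
    double drift = v_mod * (as_cur + as_foil) / 2.0;
    double bound = boundary_value(a_base, a_mod, trial_in_run[i], mapping);
    as_t[i] = as_cur;
    drift_t[i] = drift;
    bound_t[i] = bound;

    if (status[i] == 0) {  // missed: censor or exclude; never an AS update
      pe_t[i] = NA_REAL;
      if (missed_mode == 1) {
        double tmax = deadline - tau;
        double lc = (tmax <= 0.0) ? 0.0
          : std::log(std::max(wfpt_survival_cpp(tmax, drift, bound, z),
                              1e-300));
        if (floor_log && lc < -700.0) lc = -700.0;
        censor_total += lc;
        total += lc;
      }
      continue;
    }
    bool correct = (status[i] == 1);
    double ll = wfpt_log_response(rt[i], correct, drift, bound, z, tau);
    if (floor_log && ll < -700.0) ll = -700.0;
    pw.push_back(ll);
    total += ll;

    double outcome = (double)feedback[i];
    double pe = outcome - as_cur;
    double eta = (pe >= 0.0) ? eta_pos : eta_neg;
    as[p] = as_cur + eta * pe;
    pe_t[i] = pe;
  }

  return List::create(_["total"] = total, _["pointwise"] = NumericVector(pw.begin(), pw.end()),
                      _["censor_loglik"] = censor_total,
                      _["as"] = as_t, _["pe"] = pe_t, _["drift"] = drift_t,
                      _["boundary"] = bound_t);
}

// Barrier continuity correction for discretely monitored diffusion paths
// (Broadie-Glasserman-Kou): pull each barrier in by 0.5826*sigma*sqrt(dt)
// to compensate for crossings missed between Euler steps.
static double euler_barrier_shift(double a, double dt) {
  double d = 0.5826 * std::sqrt(dt);
  return (2.0 * d < 0.5 * a) ? d : 0.0;
}

// Total log likelihood only (no derived series, no pointwise vector) --
// the sampler's inner loop. Same conventions as seq_loglik_cpp.
// [[Rcpp::export(name = ".seq_total_cpp")]]
double seq_total_cpp(IntegerVector run, IntegerVector trial_in_run,
                     IntegerVector pair_idx, IntegerVector foil_idx,
                     IntegerVector status, IntegerVector feedback,
                     int n_pairs, NumericVector pars, int mapping,
                     NumericVector rt, double as_init, double deadline,
                     int missed_mode) {
  int n = run.size();
  double eta_pos = pars[0], eta_neg = pars[1], a_base = pars[2],
         a_mod = pars[3], tau = pars[4], z = pars[5], v_mod = pars[6];
  std::vector<double> as(n_pairs, as_init);
  double total = 0.0;
  int cur_run = -1;
  for (int i = 0; i < n; i++) {
    if (run[i] != cur_run) {
      cur_run = run[i];
      std::fill(as.begin(), as.end(), as_init);
    }
    int p = pair_idx[i] - 1;
    double as_cur = as[p];
    double as_foil = (foil_idx[i] > 0) ? as[foil_idx[i] - 1] : as_init;
    double drift = v_mod * (as_cur + as_foil) / 2.0;
    double bound = boundary_value(a_base, a_mod, trial_in_run[i], mapping);
    if (status[i] == 0) {
      if (missed_mode == 1) {
        double tmax = deadline - tau;
        double lc = (tmax <= 0.0) ? 0.0
          : std::log(std::max(wfpt_survival_cpp(tmax, drift, bound, z),
                              1e-300));
        total += (lc < -700.0) ? -700.0 : lc;
      }
      continue;
    }
    double ll = wfpt_log_response(rt[i], status[i] == 1, drift, bound, z, tau);
    total += (ll < -700.0) ? -700.0 : ll;
    double outcome = (double)feedback[i];
    double pe = outcome - as_cur;
    as[p] = as_cur + ((pe >= 0.0) ? eta_pos : eta_neg) * pe;
  }
  return total;
}

// Euler-Maruyama first-passage simulation of the diffusion between 0 and a,
// starting at z*a, drift v toward the upper (= correct) boundary.
// Returns per draw: response (1 correct, 0 incorrect, -1 missed) and rt.
// Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".euler_fp_cpp")]]
List euler_fp_cpp(int n, double v, double a, double z, double tau,
                  double deadline, double dt) {
  IntegerVector resp(n);
  NumericVector rt(n);
  double sdt = std::sqrt(dt);
  double tmax = deadline - tau;
  double d = euler_barrier_shift(a, dt);
  for (int i = 0; i < n; i++) {
    double x = z * a, t = 0.0;
    int r = -1;
    while (t < tmax) {
      x += v * dt + sdt * norm_rand();
      t += dt;
      if (x >= a - d) { r = 1; break; }
      if (x <= d) { r = 0; break; }
    }
    resp[i] = r;
    rt[i] = (r < 0) ? NA_REAL : tau + t;
  }
  return List::create(_["response"] = resp, _["rt"] = rt);
}

// Full generative loop for one subject: per trial derive drift/boundary from
// the current associative state, simulate the diffusion, apply feedback and
// update the chosen pairing. Trials must be ordered by run then trial.
// [[Rcpp::export(name = ".sim_subject_cpp")]]
List sim_subject_cpp(IntegerVector run, IntegerVector trial_in_run,
                     IntegerVector pair_idx, IntegerVector foil_idx,
                     int n_pairs, NumericVector pars,
                     int mapping, double deadline, double dt, double as_init) {
  int n = run.size();
  double eta_pos = pars[0], eta_neg = pars[1], a_base = pars[2],
         a_mod = pars[3], tau = pars[4], z = pars[5], v_mod = pars[6];
  std::vector<double> as(n_pairs, as_init);
  IntegerVector resp(n), fb(n);
  NumericVector rt(n);
  double sdt = std::sqrt(dt);
  int cur_run = -1;

  for (int i = 0; i < n; i++) {
    if (run[i] != cur_run) {
      cur_run = run[i];
      std::fill(as.begin(), as.end(), as_init);
    }
    int p = pair_idx[i] - 1;
    double as_foil = (foil_idx[i] > 0) ? as[foil_idx[i] - 1] : as_init;
    double drift = v_mod * (as[p] + as_foil) / 2.0;
    double bound = boundary_value(a_base, a_mod, trial_in_run[i], mapping);

    double x = z * bound, t = 0.0;
    int r = -1;
    double tmax = deadline - tau;
    double d = euler_barrier_shift(bound, dt);
    while (t < tmax) {
      x += drift * dt + sdt * norm_rand();
      t += dt;
      if (x >= bound - d) { r = 1; break; }
      if (x <= d) { r = 0; break; }
    }
    resp[i] = r;
    if (r < 0) {  // missed: no feedback-driven update
      rt[i] = NA_REAL;
      fb[i] = NA_INTEGER;
      continue;
    }
    rt[i] = tau + t;
    fb[i] = r;  // deterministic feedback: 1 iff correct
    double pe = (double)r - as[p];
    double eta = (pe >= 0.0) ? eta_pos : eta_neg;
    as[p] += eta * pe;
  }
  return List::create(_["response"] = resp, _["rt"] = rt, _["feedback"] = fb);
}
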
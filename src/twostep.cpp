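// Trial-loop core shared by likelihood evaluation and forward simulation.
//
// Encoded trial matrix columns (see encode_session() on the R side):
//   0 forced_stage (0 none / 1 / 2)
//   1 error flag (0/1)
//   2 a1 (1 = x, 2 = y; 0 missing)
//   3 s2 (1 = B, 2 = C; 0 missing)
//   4 a2 (1/2; 0 missing)
//   5 outcome level (1 low, 2 medium, 3 high; 0 missing)
//   6 normalized reward in [0, 1]
//   7 transition (1 common, 0 rare; -1 missing)
//
// Parameter vector (full, fixed order):
//   0 alpha1, 1 alpha2, 2 beta1, 3 beta2, 4 kappa1, 5 kappa2,
//   6 lambda, 7 omega, 8 zeta, 9 L1, 10 L2, 11 L3
//
// Model codes: mf 0 none / 1 SARSA / 2 Q; ms 0 none / 1..3 Forward variant.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct AgentState {
  // Q[state][action]; state 0 = A (first stage), 1 = B, 2 = C
  double Q[3][2];
  // transition-structure evidence: counts for mapping1 (x->B, y->C)
  // versus mapping2 (x->C, y->B)
  double n_map1, n_map2;
  int last_choice[3];       // 0 none, else 1/2 per state
  bool have_prev;           // a completed previous trial exists
  int prev_a1, prev_level;  // summary feeding the one-trial boost
  int prev_trans;           // 1 common, 0 rare

  void reset() {
    for (int s = 0; s < 3; ++s) {
      Q[s][0] = 0.0; Q[s][1] = 0.0;
      last_choice[s] = 0;
    }
    n_map1 = 0.0; n_map2 = 0.0;
    have_prev = false;
    prev_a1 = 0; prev_level = 0; prev_trans = -1;
  }
};

// P(s2 = B | a1) for both actions, under the requested transition model
inline void beliefs_pB(const AgentState& st, int ms, double zeta,
                       double out[2]) {
  if (ms == 1 || ms == 0) {            // known structure
    out[0] = 0.7; out[1] = 0.3;
    return;
  }
  if (ms == 2) {                       // majority-category counting
    if (st.n_map1 > st.n_map2)      { out[0] = 0.7; out[1] = 0.3; }
    else if (st.n_map2 > st.n_map1) { out[0] = 0.3; out[1] = 0.7; }
    else                            { out[0] = 0.5; out[1] = 0.5; }
    return;
  }
  // ms == 3: likelihood-ratio test of structured {0.7, 0.3} (majority
  // mapping) against uniform {0.5, 0.5}, blended with weight zeta
  double nmax = st.n_map1 > st.n_map2 ? st.n_map1 : st.n_map2;
  double nmin = st.n_map1 > st.n_map2 ? st.n_map2 : st.n_map1;
  double n = st.n_map1 + st.n_map2;
  double logLR = nmax * std::log(0.7) + nmin * std::log(0.3)
               - n * std::log(0.5);
  double z = zeta < 1e-12 ? 1e-12 : (zeta > 1.0 - 1e-12 ? 1.0 - 1e-12 : zeta);
  double logodds = std::log(z / (1.0 - z)) + logLR;
  double w = 1.0 / (1.0 + std::exp(-logodds));
  double pB_struct_x;
  if (st.n_map1 > st.n_map2) pB_struct_x = 0.7;
  else if (st.n_map2 > st.n_map1) pB_struct_x = 0.3;
  else pB_struct_x = 0.5;
  out[0] = w * pB_struct_x + (1.0 - w) * 0.5;
  out[1] = w * (1.0 - pB_struct_x) + (1.0 - w) * 0.5;
}

inline double qmax(const double q[2]) { return q[0] > q[1] ? q[0] : q[1]; }

// log-softmax over two options of beta * (q + kappa * rep)
inline void log_softmax2(const double q[2], double beta, double kappa,
                         int last, double logp[2]) {
  double x0 = beta * (q[0] + (last == 1 ? kappa : 0.0));
  double x1 = beta * (q[1] + (last == 2 ? kappa : 0.0));
  double m = x0 > x1 ? x0 : x1;
  double lse = m + std::log(std::exp(x0 - m) + std::exp(x1 - m));
  logp[0] = x0 - lse;
  logp[1] = x1 - lse;
}

// first-stage action values after MF/MS combination and one-trial boost
inline void stage1_values(const AgentState& st, const NumericVector& p,
                          int mf, int ms, int hplus, double q1[2]) {
  double omega = p[7];
  if (mf == 0) omega = 1.0;
  if (ms == 0) omega = 0.0;
  double pB[2];
  beliefs_pB(st, ms, p[8], pB);
  double maxB = qmax(st.Q[1]), maxC = qmax(st.Q[2]);
  for (int a = 0; a < 2; ++a) {
    double q_ms = pB[a] * maxB + (1.0 - pB[a]) * maxC;
    q1[a] = (1.0 - omega) * st.Q[0][a] + omega * q_ms;
  }
  if (hplus && st.have_prev) {
    // L indexed by previous outcome level: L1 high, L2 medium, L3 low
    double L = st.prev_level == 3 ? p[9] : (st.prev_level == 2 ? p[10] : p[11]);
    double sign = st.prev_trans == 1 ? 1.0 : -1.0;
    q1[st.prev_a1 - 1] += sign * L;
  }
}

// value updates + transition-model evidence + perseveration bookkeeping
inline void end_of_trial_update(AgentState& st, const NumericVector& p,
                                int mf, int ms, int a1, int s2, int a2,
                                double r, int trans, int level) {
  double d2 = r - st.Q[s2][a2 - 1];
  double d1;
  if (mf == 2) d1 = qmax(st.Q[s2]) - st.Q[0][a1 - 1];   // Q-learning
  else         d1 = st.Q[s2][a2 - 1] - st.Q[0][a1 - 1]; // SARSA
  st.Q[0][a1 - 1] += p[0] * d1;
  st.Q[s2][a2 - 1] += p[1] * d2;
  st.Q[0][a1 - 1] += p[0] * p[6] * d2;  // eligibility pass-through
  if ((a1 == 1 && s2 == 1) || (a1 == 2 && s2 == 2)) st.n_map1 += 1.0;
  else st.n_map2 += 1.0;
  st.last_choice[0] = a1;
  st.last_choice[s2] = a2;
  st.have_prev = true;
  st.prev_a1 = a1;
  st.prev_trans = trans;
  st.prev_level = level;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_session_logp(NumericMatrix trials, NumericVector params,
                               int mf, int ms, int hplus) {
  int n = trials.nrow();
  NumericMatrix out(n, 2);
  AgentState st;
  st.reset();
  for (int t = 0; t < n; ++t) {
    int forced = (int) trials(t, 0);
    int err = (int) trials(t, 1);
    if (err == 1) { out(t, 0) = NA_REAL; out(t, 1) = NA_REAL; continue; }
    int a1 = (int) trials(t, 2), s2 = (int) trials(t, 3);
    int a2 = (int) trials(t, 4), level = (int) trials(t, 5);
    double r = trials(t, 6);
    int trans = (int) trials(t, 7);
    if (a1 < 1 || a1 > 2 || s2 < 1 || s2 > 2 || a2 < 1 || a2 > 2)
      stop("trial %d: incomplete non-error trial", t + 1);
    double q1[2], lp1[2], lp2[2];
    stage1_values(st, params, mf, ms, hplus, q1);
    log_softmax2(q1, params[2], params[4], st.last_choice[0], lp1);
    out(t, 0) = forced == 1 ? 0.0 : lp1[a1 - 1];
    log_softmax2(st.Q[s2], params[3], params[5], st.last_choice[s2], lp2);
    out(t, 1) = forced == 2 ? 0.0 : lp2[a2 - 1];
    end_of_trial_update(st, params, mf, ms, a1, s2, a2, r, trans, level);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_session(IntegerMatrix levels, NumericMatrix juice,
                                   NumericVector params, int mf, int ms,
                                   int hplus, IntegerVector forced_stage,
                                   IntegerVector forced_opt,
                                   IntegerVector error_flag, double p_common,
                                   double r_scale) {
  int n = levels.nrow();
  if (juice.nrow() != n || forced_stage.size() != n ||
      forced_opt.size() != n || error_flag.size() != n)
    stop("schedule/forced/error inputs must align on trial count");
  NumericMatrix out(n, 8);
  AgentState st;
  st.reset();
  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    int forced = forced_stage[t];
    out(t, 0) = forced;
    if (error_flag[t] == 1) {
      out(t, 1) = 1;
      out(t, 2) = 0; out(t, 3) = 0; out(t, 4) = 0;
      out(t, 5) = 0; out(t, 6) = NA_REAL; out(t, 7) = -1;
      continue;
    }
    out(t, 1) = 0;
    double q1[2], lp1[2], lp2[2];
    stage1_values(st, params, mf, ms, hplus, q1);
    log_softmax2(q1, params[2], params[4], st.last_choice[0], lp1);
    int a1;
    if (forced == 1) a1 = forced_opt[t];
    else a1 = unif_rand() < std::exp(lp1[0]) ? 1 : 2;
    int majority = a1;  // x -> B, y -> C
    bool common = unif_rand() < p_common;
    int s2 = common ? majority : 3 - majority;
    log_softmax2(st.Q[s2], params[3], params[5], st.last_choice[s2], lp2);
    int a2;
    if (forced == 2) a2 = forced_opt[t];
    else a2 = unif_rand() < std::exp(lp2[0]) ? 1 : 2;
    // schedule columns: option index = 2 * (s2 - 1) + a2, 4 options
    int opt = 2 * (s2 - 1) + (a2 - 1);
    int level = levels(t, opt);
    double jms = juice(t, opt);
    double r = r_scale > 0 ? jms / r_scale : 0.0;
    out(t, 2) = a1; out(t, 3) = s2; out(t, 4) = a2;
    out(t, 5) = level; out(t, 6) = jms;  // raw juice; normalized in R
    out(t, 7) = common ? 1 : 0;
    end_of_trial_update(st, params, mf, ms, a1, s2, a2, r,
                        common ? 1 : 0, level);
  }
  return out;
}
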
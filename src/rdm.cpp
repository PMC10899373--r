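// Vectorised racing-diffusion likelihood kernels. One call evaluates a whole
// matrix of candidate parameter vectors (particles) against one subject's
// trials; this is the hot loop of the particle-Metropolis-within-Gibbs
// sampler and of the IS2 evidence estimator.
#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// log first-passage density of a single-boundary diffusion (s = 1)
static inline double wald_logpdf(double t, double drift, double dist) {
  double e = dist - drift * t;
  return std::log(dist) - 0.5 * (LOG2PI + 3.0 * std::log(t)) -
         e * e / (2.0 * t);
}

// log survival probability, floored at -700 against underflow
static inline double wald_logsurv(double t, double drift, double dist) {
  double sq = std::sqrt(t);
  double l1 = R::pnorm((dist - drift * t) / sq, 0.0, 1.0, 1, 1);
  double l2 = 2.0 * drift * dist +
              R::pnorm(-(dist + drift * t) / sq, 0.0, 1.0, 1, 1);
  double d = l2 - l1;
  double ls = (d >= 0.0) ? R_NegInf : l1 + std::log1p(-std::exp(d));
  return (ls < -700.0) ? -700.0 : ls;
}

// Advantage-framework learning tasks. Parameter columns:
//   rl_rev: alpha, V0, delta, sigma_sum, B, t0
//   rl_sat: alpha, V0_spd, V0_acc, delta, sigma_sum, B_spd, B_acc, t0
// Data columns: block, choice (1/2), reward, emphasis (1 spd / 2 acc / 0), rt.
// [[Rcpp::export]]
NumericVector cpp_loglik_rl(NumericMatrix par, NumericMatrix dat,
                            bool sat, double q0) {
  int np = par.nrow(), nt = dat.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double alpha, v0s, v0a, delta, ssum, bs, ba, t0;
    if (!sat) {
      alpha = par(p, 0); v0s = v0a = par(p, 1); delta = par(p, 2);
      ssum = par(p, 3); bs = ba = par(p, 4); t0 = par(p, 5);
    } else {
      alpha = par(p, 0); v0s = par(p, 1); v0a = par(p, 2); delta = par(p, 3);
      ssum = par(p, 4); bs = par(p, 5); ba = par(p, 6); t0 = par(p, 7);
    }
    if (!(alpha > 0.0 && alpha < 1.0) || bs <= 0.0 || ba <= 0.0 || t0 <= 0.0) {
      out[p] = R_NegInf; continue;
    }
    double ll = 0.0, q1 = q0, q2 = q0;
    int blk = -1;
    for (int i = 0; i < nt; ++i) {
      int b = (int) dat(i, 0);
      if (b != blk) { q1 = q0; q2 = q0; blk = b; }
      double dt = dat(i, 4) - t0;
      if (dt <= 0.0) { ll = R_NegInf; break; }
      bool spd = sat && ((int) dat(i, 3) == 1);
      double v0 = sat ? (spd ? v0s : v0a) : v0s;
      double bb = sat ? (spd ? bs : ba) : bs;
      double s = ssum * (q1 + q2);
      double d1 = v0 + delta * (q1 - q2) + s;
      double d2 = v0 + delta * (q2 - q1) + s;
      int ch = (int) dat(i, 1);
      double r = dat(i, 2);
      if (ch == 1) {
        ll += wald_logpdf(dt, d1, bb) + wald_logsurv(dt, d2, bb);
        q1 += alpha * (r - q1);
      } else {
        ll += wald_logpdf(dt, d2, bb) + wald_logsurv(dt, d1, bb);
        q2 += alpha * (r - q2);
      }
      if (!R_FINITE(ll)) { ll = R_NegInf; break; }
    }
    out[p] = ll;
  }
  return out;
}

// Reference-back. Parameter columns:
//   V0_tt1, V0_tt2, delta_r1t1, delta_r2t1, delta_r1t2, delta_r2t2,
//   B_st1, B_st2, t0
// Data columns: trial_type, correct_resp, type_trans, stim_trans, choice, rt.
// [[Rcpp::export]]
NumericVector cpp_loglik_rb(NumericMatrix par, NumericMatrix dat) {
  int np = par.nrow(), nt = dat.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double t0 = par(p, 8);
    if (par(p, 6) <= 0.0 || par(p, 7) <= 0.0 || t0 <= 0.0) {
      out[p] = R_NegInf; continue;
    }
    double ll = 0.0;
    for (int i = 0; i < nt; ++i) {
      double dt = dat(i, 5) - t0;
      if (dt <= 0.0) { ll = R_NegInf; break; }
      int tt = (int) dat(i, 0), cr = (int) dat(i, 1);
      int ttr = (int) dat(i, 2), str = (int) dat(i, 3), ch = (int) dat(i, 4);
      double v0 = par(p, ttr - 1);                 // V0_tt1 / V0_tt2
      double dl = par(p, 2 + (tt - 1) * 2 + (cr - 1)); // delta_r{cr}t{tt}
      double bb = par(p, 6 + (str - 1));           // B_st1 / B_st2
      double vc = v0 + dl, ve = v0 - dl;
      double vwin = (ch == cr) ? vc : ve;
      double vlos = (ch == cr) ? ve : vc;
      ll += wald_logpdf(dt, vwin, bb) + wald_logsurv(dt, vlos, bb);
      if (!R_FINITE(ll)) { ll = R_NegInf; break; }
    }
    out[p] = ll;
  }
  return out;
}

// Multi-source interference. Parameter columns:
//   v_flank, v_simon, delta, start_pos1, start_pos2, V0, B, t0
// Data columns: target, position, flanker, simon, choice, rt.
// [[Rcpp::export]]
NumericVector cpp_loglik_msit(NumericMatrix par, NumericMatrix dat) {
  int np = par.nrow(), nt = dat.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double vf = par(p, 0), vs = par(p, 1), delta = par(p, 2);
    double sp[3] = { par(p, 3), par(p, 4), 0.0 };
    double v0 = par(p, 5), B = par(p, 6), t0 = par(p, 7);
    if (B <= 0.0 || t0 <= 0.0) { out[p] = R_NegInf; continue; }
    double ll = 0.0;
    for (int i = 0; i < nt; ++i) {
      double dt = dat(i, 5) - t0;
      if (dt <= 0.0) { ll = R_NegInf; break; }
      int tg = (int) dat(i, 0), pos = (int) dat(i, 1);
      int fl = (int) dat(i, 2), si = (int) dat(i, 3), ch = (int) dat(i, 4);
      double drift[3] = { v0, v0, v0 };
      if (fl > 0) drift[fl - 1] += vf;
      if (si > 0) drift[si - 1] += vs;
      drift[tg - 1] += delta;
      double dist[3] = { B, B, B };
      dist[tg - 1] -= sp[pos - 1];
      if (dist[tg - 1] <= 0.0) { ll = R_NegInf; break; }
      for (int k = 0; k < 3; ++k) {
        ll += (k == ch - 1) ? wald_logpdf(dt, drift[k], dist[k])
                            : wald_logsurv(dt, drift[k], dist[k]);
      }
      if (!R_FINITE(ll)) { ll = R_NegInf; break; }
    }
    out[p] = ll;
  }
  return out;
}
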
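#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step 2nd-order Runge-Kutta (midpoint) integrators for the 8-unit
// PE microcircuit and the two-level hierarchy. All time constants are in ms
// and rates are rectified ([h]_+) at every right-hand-side evaluation.

static const int NU = 8; // nE, pE, nD, pD, PV1, PV2, SOM, VIP

static inline void circuit_rhs(const double* h, const NumericMatrix& W,
                               const NumericVector& wff,
                               const NumericVector& wfb,
                               const NumericVector& I,
                               const NumericVector& tau,
                               double ff, double fb, const double* pert,
                               double* dh) {
  double r[NU];
  for (int i = 0; i < NU; ++i) r[i] = h[i] > 0.0 ? h[i] : 0.0;
  for (int i = 0; i < NU; ++i) {
    double acc = -h[i] + wff[i] * ff + wfb[i] * fb + I[i] + pert[i];
    for (int j = 0; j < NU; ++j) acc += W(i, j) * r[j];
    dh[i] = acc / tau[i];
  }
}

// Integrate the isolated circuit with clamped feedforward / feedback drive
// until the rate change per ms drops below `tol` (steady-state probe).
// [[Rcpp::export]]
List steady_circuit_cpp(NumericMatrix W, NumericVector wff, NumericVector wfb,
                        NumericVector I, NumericVector tau,
                        double ff, double fb, NumericVector pert,
                        NumericVector h0, double dt, double tol,
                        double max_ms) {
  double h[NU], hm[NU], k1[NU], k2[NU], p[NU];
  for (int i = 0; i < NU; ++i) { h[i] = h0[i]; p[i] = pert[i]; }
  int nmax = (int)std::ceil(max_ms / dt);
  bool converged = false;
  int it = 0;
  for (it = 0; it < nmax; ++it) {
    circuit_rhs(h, W, wff, wfb, I, tau, ff, fb, p, k1);
    for (int i = 0; i < NU; ++i) hm[i] = h[i] + 0.5 * dt * k1[i];
    circuit_rhs(hm, W, wff, wfb, I, tau, ff, fb, p, k2);
    double dmax = 0.0;
    for (int i = 0; i < NU; ++i) {
      h[i] += dt * k2[i];
      double a = std::fabs(k2[i]);
      if (a > dmax) dmax = a;
      if (!std::isfinite(h[i])) stop("circuit state diverged (NaN/Inf)");
    }
    if (dmax < tol) { converged = true; break; }
  }
  NumericVector hout(NU), rout(NU);
  for (int i = 0; i < NU; ++i) {
    hout[i] = h[i];
    rout[i] = h[i] > 0.0 ? h[i] : 0.0;
  }
  return List::create(_["h"] = hout, _["r"] = rout,
                      _["converged"] = converged,
                      _["ms"] = (it + 1) * dt);
}

// Full trajectory of the isolated circuit under per-step clamped inputs.
// ff and fb are values per time step (each held for dt).
// [[Rcpp::export]]
List sim_circuit_cpp(NumericMatrix W, NumericVector wff, NumericVector wfb,
                     NumericVector I, NumericVector tau,
                     NumericVector ff, NumericVector fb, NumericVector pert,
                     NumericVector h0, double dt) {
  int n = ff.size();
  if (fb.size() != n) stop("ff and fb must have equal length");
  double h[NU], hm[NU], k1[NU], k2[NU], p[NU];
  for (int i = 0; i < NU; ++i) { h[i] = h0[i]; p[i] = pert[i]; }
  NumericMatrix rates(n, NU);
  for (int t = 0; t < n; ++t) {
    circuit_rhs(h, W, wff, wfb, I, tau, ff[t], fb[t], p, k1);
    for (int i = 0; i < NU; ++i) hm[i] = h[i] + 0.5 * dt * k1[i];
    circuit_rhs(hm, W, wff, wfb, I, tau, ff[t], fb[t], p, k2);
    for (int i = 0; i < NU; ++i) {
      h[i] += dt * k2[i];
      if (!std::isfinite(h[i])) stop("circuit state diverged (NaN/Inf)");
      rates(t, i) = h[i] > 0.0 ? h[i] : 0.0;
    }
  }
  NumericVector hout(NU);
  for (int i = 0; i < NU; ++i) hout[i] = h[i];
  return List::create(_["rates"] = rates, _["h"] = hout);
}

struct HierPars {
  const NumericMatrix *Wl, *Wh;
  const NumericVector *wffl, *wfbl, *Il, *wffh, *wfbh, *Ih, *tau;
  double wMn_l, wMp_l, wMn_h, wMp_h;
  double wVn_l, wVp_l, wVn_h, wVp_h;
  double tauE, tauV;
  int n_levels;
};

// state layout: h_low[0..7], h_high[8..15], M_low 16, V_low 17, M_high 18, V_high 19
static inline void hier_rhs(const double* y, const HierPars& P, double s,
                            const double* pl, const double* ph, double* dy) {
  circuit_rhs(y, *P.Wl, *P.wffl, *P.wfbl, *P.Il, *P.tau, s, y[16], pl, dy);
  double rn = y[0] > 0.0 ? y[0] : 0.0;
  double rp = y[1] > 0.0 ? y[1] : 0.0;
  dy[16] = (P.wMp_l * rp - P.wMn_l * rn) / P.tauE;
  double u = P.wVp_l * rp + P.wVn_l * rn;
  dy[17] = (-y[17] + u * u) / P.tauV;
  if (P.n_levels == 2) {
    circuit_rhs(y + NU, *P.Wh, *P.wffh, *P.wfbh, *P.Ih, *P.tau, y[16], y[18],
                ph, dy + NU);
    double rnh = y[8] > 0.0 ? y[8] : 0.0;
    double rph = y[9] > 0.0 ? y[9] : 0.0;
    dy[18] = (P.wMp_h * rph - P.wMn_h * rnh) / P.tauE;
    double uh = P.wVp_h * rph + P.wVn_h * rnh;
    dy[19] = (-y[19] + uh * uh) / P.tauV;
  } else {
    for (int i = NU; i < 2 * NU; ++i) dy[i] = 0.0;
    dy[18] = 0.0;
    dy[19] = 0.0;
  }
}

// Simulate the full hierarchy (or the single lower subnetwork when
// n_levels == 1) for one stimulus series. `stim` holds one value per 1-step
// of size dt. The perturbation inputs switch on at step `pert_onset`
// (1-based; use 0 or negative for never). Memory and variance rates are
// recorded every step; circuit rates every `rates_every` steps.
// [[Rcpp::export]]
List sim_hier_cpp(NumericMatrix Wl, NumericVector wffl, NumericVector wfbl,
                  NumericVector Il, NumericMatrix Wh, NumericVector wffh,
                  NumericVector wfbh, NumericVector Ih, NumericVector tau,
                  double wMn_l, double wMp_l, double wMn_h, double wMp_h,
                  double wVn_l, double wVp_l, double wVn_h, double wVp_h,
                  double tauE, double tauV, NumericVector stim,
                  NumericVector pert_low, NumericVector pert_high,
                  int pert_onset, double dt, int rates_every, int n_levels) {
  const int NS = 2 * NU + 4;
  int n = stim.size();
  HierPars P;
  P.Wl = &Wl; P.Wh = &Wh;
  P.wffl = &wffl; P.wfbl = &wfbl; P.Il = &Il;
  P.wffh = &wffh; P.wfbh = &wfbh; P.Ih = &Ih; P.tau = &tau;
  P.wMn_l = wMn_l; P.wMp_l = wMp_l; P.wMn_h = wMn_h; P.wMp_h = wMp_h;
  P.wVn_l = wVn_l; P.wVp_l = wVp_l; P.wVn_h = wVn_h; P.wVp_h = wVp_h;
  P.tauE = tauE; P.tauV = tauV; P.n_levels = n_levels;

  // all neurons initialized at r = 0
  double y[NS], ym[NS], k1[NS], k2[NS];
  for (int i = 0; i < NS; ++i) y[i] = 0.0;

  double zl[NU], zh[NU], pl[NU], ph[NU];
  for (int i = 0; i < NU; ++i) {
    zl[i] = 0.0; zh[i] = 0.0;
    pl[i] = pert_low[i]; ph[i] = pert_high[i];
  }

  int nrec = (rates_every > 0) ? (n / rates_every) : 0;
  NumericMatrix rlow(nrec, NU), rhigh(nrec, NU);
  NumericVector rtime(nrec);
  NumericVector Ml(n), Vl(n), Mh(n), Vh(n);
  int clipM = 0, clipV = 0, irec = 0;

  for (int t = 0; t < n; ++t) {
    bool on = (pert_onset > 0) && (t + 1 >= pert_onset);
    const double* cl = on ? pl : zl;
    const double* ch = on ? ph : zh;
    double s = stim[t];
    hier_rhs(y, P, s, cl, ch, k1);
    for (int i = 0; i < NS; ++i) ym[i] = y[i] + 0.5 * dt * k1[i];
    hier_rhs(ym, P, s, cl, ch, k2);
    for (int i = 0; i < NS; ++i) y[i] += dt * k2[i];
    // nonnegativity guards: memory rates (stimuli are nonnegative in all
    // protocols) and variance rates (variance is nonnegative by definition)
    if (y[16] < 0.0) { y[16] = 0.0; ++clipM; }
    if (y[18] < 0.0) { y[18] = 0.0; ++clipM; }
    if (y[17] < 0.0) { y[17] = 0.0; ++clipV; }
    if (y[19] < 0.0) { y[19] = 0.0; ++clipV; }
    if (!std::isfinite(y[16]) || !std::isfinite(y[0]))
      stop("network state diverged (NaN/Inf) at step %d", t + 1);
    Ml[t] = y[16]; Vl[t] = y[17]; Mh[t] = y[18]; Vh[t] = y[19];
    if (rates_every > 0 && ((t + 1) % rates_every == 0) && irec < nrec) {
      for (int i = 0; i < NU; ++i) {
        rlow(irec, i) = y[i] > 0.0 ? y[i] : 0.0;
        rhigh(irec, i) = y[NU + i] > 0.0 ? y[NU + i] : 0.0;
      }
      rtime[irec] = (t + 1) * dt;
      ++irec;
    }
  }
  return List::create(_["rM_low"] = Ml, _["rV_low"] = Vl,
                      _["rM_high"] = Mh, _["rV_high"] = Vh,
                      _["rates_low"] = rlow, _["rates_high"] = rhigh,
                      _["rate_times"] = rtime,
                      _["n_clip_M"] = clipM, _["n_clip_V"] = clipV);
}
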
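#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment respiratory-system model driven by a ventilator
// controller, integrated with forward Euler at a fine fixed step and
// down-sampled for output.
//
// State: V = volume above FRC [ml]. Effective compliance couples to the
// intra-abdominal pressure: C_eff = max(C_min, C0 - k*IAP + repo), where
// repo = dC_repo while an odd number of reposition toggles have passed.
//
// VCV: constant inspiratory flow Q = VT_target / T_insp, time-cycled.
// PCV: drive pressure slews from PEEP toward Pins_max at <= slew mbar/s;
//      flow Q = (drive - Palv) / R_aw, capped at flow_limit. Measured
//      airway pressure is Palv + R_aw*Q, so a binding flow cap leaves
//      PIP below Pins_max and tracking the elastic load.
// Expiration is passive through R_aw (time constant R_aw*C_eff, floored
// at 50 ms so the R_aw = 0 limit stays well posed); airway pressure sits
// at PEEP_set plus the residual elastic recoil not dropped across R_aw.
//
// Settings take effect at the inspiration onset following their
// scheduled time, as an anaesthesiologist's adjustment would.

// [[Rcpp::export]]
List lung_ode_cpp(double duration, double dt, int out_stride,
                  NumericVector iap, double iap_dt,
                  NumericVector sched_t, IntegerVector sched_mode,
                  NumericVector sched_vt, NumericVector sched_pins,
                  NumericVector sched_rr, NumericVector sched_ie,
                  NumericVector sched_peep,
                  double C0, double R_aw, double k, double C_min,
                  double dC_repo, NumericVector repo_times,
                  double slew, double flow_limit) {
  const int n_steps = (int)std::floor(duration / dt);
  const int n_out = n_steps / out_stride;
  NumericVector out_t(n_out), out_paw(n_out), out_q(n_out), out_v(n_out);

  std::vector<double> b_t0, b_texp, b_vt, b_ceff, b_ceff_end, b_ceff_max,
      b_qpos;
  const int n_iap = iap.size();
  const int n_sched = sched_t.size();
  const double R_eff = (R_aw > 1e-9) ? R_aw : 1e-9;

  // per-breath controller state
  int sched_idx = 0, repo_idx = 0;
  double V = 0.0, V_onset = 0.0, V_max = 0.0;
  double t_onset = 0.0, T_insp = 1.0, T_cycle = 5.0;
  int mode = 0;               // 0 = VCV, 1 = PCV
  double vt_tgt = 500, pins = 20, peep = 5, q_set = 0;
  double ceff_sum = 0.0; long ceff_n = 0;
  double ceff_end_insp = C0;          // C_eff at the last inspiratory step
  double ceff_max = 0.0;              // max C_eff within the breath
  double qpos_int = 0.0;              // integral of positive flow [ml]
  bool first = true;

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;

    // IAP by linear interpolation on its own grid
    double x = t / iap_dt;
    int j = (int)x; if (j >= n_iap - 1) j = n_iap - 2;
    double frac = x - j; if (frac < 0) frac = 0; if (frac > 1) frac = 1;
    double iap_t = iap[j] * (1 - frac) + iap[j + 1] * frac;

    while (repo_idx < repo_times.size() && t >= repo_times[repo_idx])
      ++repo_idx;
    double repo = (repo_idx % 2 == 1) ? dC_repo : 0.0;
    double Ceff = C0 - k * iap_t + repo;
    if (Ceff < C_min) Ceff = C_min;

    // breath cycling
    if (first || t - t_onset >= T_cycle) {
      if (!first) {
        b_t0.push_back(t_onset);
        b_texp.push_back(t_onset + T_insp);
        b_vt.push_back(V_max - V_onset);
        b_ceff.push_back(ceff_sum / (double)ceff_n);
        b_ceff_end.push_back(ceff_end_insp);
        b_ceff_max.push_back(ceff_max);
        b_qpos.push_back(qpos_int);
      }
      first = false;
      t_onset = t;
      while (sched_idx < n_sched - 1 && sched_t[sched_idx + 1] <= t)
        ++sched_idx;
      mode = sched_mode[sched_idx];
      vt_tgt = sched_vt[sched_idx];
      pins = sched_pins[sched_idx];
      peep = sched_peep[sched_idx];
      double rr = sched_rr[sched_idx], ie = sched_ie[sched_idx];
      T_cycle = 60.0 / rr;
      T_insp = T_cycle * ie / (1.0 + ie);
      q_set = vt_tgt / T_insp;          // ml/s, VCV
      V_onset = V; V_max = V;
      ceff_sum = 0.0; ceff_n = 0;
      ceff_max = 0.0; qpos_int = 0.0;
    }
    ceff_sum += Ceff; ++ceff_n;
    if (Ceff > ceff_max) ceff_max = Ceff;

    double tin = t - t_onset;
    bool insp = tin < T_insp;
    if (insp) ceff_end_insp = Ceff;
    double Palv = peep + V / Ceff;      // alveolar pressure above ambient
    double Q, Paw;

    if (insp) {
      if (mode == 0) {                  // VCV: constant flow source
        Q = q_set;
        Paw = peep + V / Ceff + R_aw * Q;
      } else {                          // PCV: slew-limited pressure drive
        double drive = pins;
        if (R_finite(slew)) {
          drive = peep + slew * tin;
          if (drive > pins) drive = pins;
        }
        // pressure regulation is bidirectional: excess recoil is vented
        Q = (drive - Palv) / R_eff;
        if (R_finite(flow_limit) && Q > flow_limit) Q = flow_limit;
        Paw = Palv + R_aw * Q;
      }
    } else {                            // passive expiration
      double tau = R_aw * Ceff;
      if (tau < 0.05) tau = 0.05;
      Q = -V / tau;
      // pressure at airway opening: PEEP plus recoil not dropped on R_aw
      Paw = peep + V / Ceff + R_aw * Q;
      if (Paw < peep) Paw = peep;
    }

    if (Q > 0) qpos_int += Q * dt;
    V += Q * dt;
    if (V < 0) V = 0;
    if (V > V_max) V_max = V;

    if (i % out_stride == 0) {
      int o = i / out_stride;
      out_t[o] = t; out_paw[o] = Paw; out_q[o] = Q;
      out_v[o] = V - V_onset;           // display volume, reset at onset
      if (out_v[o] < 0) out_v[o] = 0;
    }
  }
  // close the final breath
  b_t0.push_back(t_onset);
  b_texp.push_back(t_onset + T_insp);
  b_vt.push_back(V_max - V_onset);
  b_ceff.push_back(ceff_n > 0 ? ceff_sum / (double)ceff_n : C0);
  b_ceff_end.push_back(ceff_end_insp);
  b_ceff_max.push_back(ceff_max > 0 ? ceff_max : C0);
  b_qpos.push_back(qpos_int);

  return List::create(
    _["t"] = out_t, _["paw"] = out_paw, _["flow_ml_s"] = out_q,
    _["volume"] = out_v,
    _["breath_onset"] = wrap(b_t0), _["breath_exp_onset"] = wrap(b_texp),
    _["breath_vt"] = wrap(b_vt), _["breath_ceff"] = wrap(b_ceff),
    _["breath_ceff_end_insp"] = wrap(b_ceff_end),
    _["breath_ceff_max"] = wrap(b_ceff_max),
    _["breath_qpos_int"] = wrap(b_qpos));
}
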
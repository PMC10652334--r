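// Semi-implicit compartment stepper for the soil-plant-atmosphere dehydration
// model. One soil node and four plant nodes (root, trunk, branch, leaf) in a
// chain; backward-Euler on the linearized network per sub-step with adaptive
// sub-stepping, explicit evaporative sinks and capacitive apoplast release on
// cavitation. Water pools are tracked in moles; fluxes are antisymmetric, so
// mass is conserved by construction up to the reported clamp error.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double pv_psi(double r, double pi0, double eps) {
  double turgor = -pi0 - eps * (1.0 - r);
  if (turgor < 0.0) turgor = 0.0;
  return pi0 / r + turgor;
}

static inline double pv_dpsidr(double r, double pi0, double eps) {
  // d psi / d r, positive
  double d = -pi0 / (r * r);
  double turgor = -pi0 - eps * (1.0 - r);
  if (turgor > 0.0) d += eps;
  return d;
}

static inline double plc_of(double psi, double p50, double slope) {
  return 100.0 / (1.0 + std::exp((slope / 25.0) * (psi - p50)));
}

static inline double vpd_of(double t, double rh) {
  double es = 0.61078 * std::exp(17.27 * t / (t + 237.3));
  return es * (1.0 - rh / 100.0);
}

static inline double gres_T(double t, double gres, double tp, double q10a,
                            double q10b, double tref) {
  if (t <= tp)
    return gres * std::pow(q10a, (t - tref) / 10.0);
  double gtp = gres * std::pow(q10a, (tp - tref) / 10.0);
  return gtp * std::pow(q10b, (t - tp) / 10.0);
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector traitv, NumericVector netv, NumericVector soilv,
              NumericVector clim_time, NumericVector clim_tair,
              NumericVector clim_rh, NumericVector clim_par,
              NumericVector opts) {
  // trait unpacking
  const double pi0 = traitv[0], eps = traitv[1], gs_max = traitv[2],
               g_res = traitv[3], t_p = traitv[4], q10a = traitv[5],
               q10b = traitv[6], p50 = traitv[7], slope = traitv[8];
  const bool deciduous = traitv[9] > 0.5;
  const double shed_rate = traitv[10], shed_half = traitv[11];

  const double la0 = netv[0], bark_trunk = netv[1], bark_branch = netv[2];
  double v_sym[4], v_apo[4], k_ax[4];
  for (int i = 0; i < 4; ++i) {
    v_sym[i] = netv[3 + i];
    v_apo[i] = netv[7 + i];
    k_ax[i] = netv[11 + i]; // mmol s-1 MPa-1: root, trunk, branch, leaf
  }

  const double pot_mol = soilv[0], rwc_sat = soilv[1], rwc_res = soilv[3],
               b_ret = soilv[4], psi_e = soilv[5], ksat_sr = soilv[6],
               theta_init = soilv[7], psi_clip = soilv[8];

  const double dt_max = opts[0], dt_min = opts[1], stop_plc = opts[2],
               max_days = opts[3], par_thr = opts[4], t_ref = opts[5],
               patm = opts[6], dpsi_max = opts[7];

  const int n_clim = clim_time.size();
  const double t_end = max_days * 86400.0;
  const double r_floor = 0.01;

  // state
  double theta_rel = theta_init;
  double W_soil = pot_mol * theta_rel / 100.0;
  double psi0 = psi_e * std::pow((theta_init - rwc_res) / (rwc_sat - rwc_res),
                                 -b_ret);
  if (psi0 < psi_clip) psi0 = psi_clip;
  double W[4], plc[4], psi[5];
  psi[0] = psi0;
  for (int i = 0; i < 4; ++i) {
    // start in equilibrium with the soil
    double rr = 1.0;
    // invert pv at psi0 (turgid branch quadratic)
    double tlp = pi0 / (1.0 + pi0 / eps);
    if (psi0 <= tlp) rr = pi0 / psi0;
    else {
      double bq = pi0 + eps + psi0;
      rr = (bq + std::sqrt(bq * bq - 4.0 * eps * pi0)) / (2.0 * eps);
    }
    if (rr > 1.0) rr = 1.0;
    W[i] = v_sym[i] * rr;
    psi[i + 1] = pv_psi(rr, pi0, eps);
    plc[i] = plc_of(psi[i + 1], p50, slope);
  }

  double plf_max = deciduous ?
    100.0 / (1.0 + std::exp(shed_rate * (psi[4] - shed_half))) : 0.0;
  double la_rem = la0 * (1.0 - plf_max / 100.0);

  double apo_store = 0.0; // remaining releasable apoplast water
  for (int i = 0; i < 4; ++i) apo_store += v_apo[i] * (1.0 - plc[i] / 100.0);
  double cum_loss = 0.0, clamp_err = 0.0;
  const double total_init = W_soil + W[0] + W[1] + W[2] + W[3] + apo_store;

  // output buffers (hourly)
  std::vector<double> o_time, o_tair, o_vpd, o_par, o_psi_soil, o_psi_root,
      o_psi_trunk, o_psi_branch, o_psi_leaf, o_gs, o_e_can, o_e_res,
      o_plc_leaf, o_plc_stem, o_theta, o_la, o_cum, o_total;

  double t = 0.0, dt = dt_max;
  int clim_idx = 0;
  bool failed = false, aborted = false;
  double next_rec = 0.0;

  auto record = [&](double tair, double vpd, double par, double gs,
                    double e_can, double e_res) {
    o_time.push_back(t / 3600.0);
    o_tair.push_back(tair);
    o_vpd.push_back(vpd);
    o_par.push_back(par);
    o_psi_soil.push_back(psi[0]);
    o_psi_root.push_back(psi[1]);
    o_psi_trunk.push_back(psi[2]);
    o_psi_branch.push_back(psi[3]);
    o_psi_leaf.push_back(psi[4]);
    o_gs.push_back(gs);
    o_e_can.push_back(e_can);
    o_e_res.push_back(e_res);
    o_plc_leaf.push_back(plc[3]);
    o_plc_stem.push_back(plc[2]);
    o_theta.push_back(theta_rel);
    o_la.push_back(la_rem);
    o_cum.push_back(cum_loss);
    o_total.push_back(W_soil + W[0] + W[1] + W[2] + W[3] + apo_store);
  };

  // initial record
  {
    double tair = clim_tair[0], rh = clim_rh[0], par = clim_par[0];
    double vpd = vpd_of(tair, rh);
    double gres_now = gres_T(tair, g_res, t_p, q10a, q10b, t_ref);
    double turgor = -pi0 - eps * (1.0 - W[3] / v_sym[3]);
    if (turgor < 0.0) turgor = 0.0;
    double gs = (par >= par_thr) ? gs_max * turgor / (-pi0) : 0.0;
    record(tair, vpd, par, gs, gs * vpd / patm * la_rem,
           gres_now * vpd / patm * la_rem +
             2.0 * gres_now * vpd / patm * (bark_trunk + bark_branch));
    next_rec = 3600.0;
  }

  while (t < t_end && !failed) {
    if (dt > dt_max) dt = dt_max;
    if (t + dt > next_rec) dt = next_rec - t;
    if (dt < dt_min) dt = dt_min;

    bool accepted = false;
    double psi_new[5];
    double tair = 0, rh = 0, par = 0, vpd = 0, gres_now = 0, gs = 0;
    double E[5] = {0, 0, 0, 0, 0};
    double K[4];

    while (!accepted) {
      // forcing at sub-step midpoint
      double tm = (t + 0.5 * dt) / 3600.0;
      while (clim_idx < n_clim - 2 && clim_time[clim_idx + 1] < tm) ++clim_idx;
      while (clim_idx > 0 && clim_time[clim_idx] > tm) --clim_idx;
      double t0 = clim_time[clim_idx], t1 = clim_time[clim_idx + 1];
      double w = (tm - t0) / (t1 - t0);
      if (w < 0.0) w = 0.0;
      if (w > 1.0) w = 1.0;
      tair = clim_tair[clim_idx] * (1 - w) + clim_tair[clim_idx + 1] * w;
      rh = clim_rh[clim_idx] * (1 - w) + clim_rh[clim_idx + 1] * w;
      par = clim_par[clim_idx] * (1 - w) + clim_par[clim_idx + 1] * w;
      vpd = vpd_of(tair, rh);
      gres_now = gres_T(tair, g_res, t_p, q10a, q10b, t_ref);

      // current potentials and capacitances
      double r[4], C[5];
      for (int i = 0; i < 4; ++i) {
        r[i] = W[i] / v_sym[i];
        if (r[i] < r_floor) r[i] = r_floor;
        if (r[i] > 1.0) r[i] = 1.0;
        psi[i + 1] = pv_psi(r[i], pi0, eps);
        C[i + 1] = v_sym[i] / pv_dpsidr(r[i], pi0, eps);
      }
      double theta_eff = (theta_rel - rwc_res) / (rwc_sat - rwc_res);
      if (theta_eff < 1e-12) theta_eff = 1e-12;
      double psi_soil = psi_e * std::pow(theta_eff, -b_ret);
      bool clipped = psi_soil < psi_clip;
      if (clipped) psi_soil = psi_clip;
      psi[0] = psi_soil;
      double C_soil = clipped ? 1e-9 :
        pot_mol * (rwc_sat - rwc_res) / 100.0 *
          std::pow(theta_eff, b_ret + 1.0) / (-b_ret * psi_e);
      C[0] = C_soil;

      // stomatal conductance from leaf turgor (explicit)
      double turgor = -pi0 - eps * (1.0 - r[3]);
      if (turgor < 0.0) turgor = 0.0;
      gs = (par >= par_thr) ? gs_max * turgor / (-pi0) : 0.0;

      // evaporative sinks, mol s-1
      double gb = 2.0 * gres_now;
      E[2] = gb * vpd / patm * bark_trunk * 1e-3;
      E[3] = gb * vpd / patm * bark_branch * 1e-3;
      E[4] = (gs + gres_now) * vpd / patm * la_rem * 1e-3;

      // edge conductances, mol s-1 MPa-1
      double k_sr = ksat_sr * std::pow(theta_eff > 1.0 ? 1.0 : theta_eff,
                                       2.0 * b_ret + 3.0);
      double cav = 1.0 - plc[2] / 100.0; // stem (branch) cavitation
      if (cav < 1e-3) cav = 1e-3;
      K[0] = (k_sr <= 0.0 || k_ax[0] <= 0.0) ? 0.0 :
        1e-3 / (1.0 / k_sr + 1.0 / k_ax[0]);
      K[1] = 1e-3 * k_ax[1] * cav;
      K[2] = 1e-3 * k_ax[2] * cav;
      K[3] = 1e-3 * k_ax[3] * cav;

      // tridiagonal backward-Euler solve for new potentials
      double a[5], bq[5], c[5], d[5];
      for (int i = 0; i < 5; ++i) {
        double cd = C[i] / dt;
        bq[i] = cd;
        d[i] = cd * psi[i] - E[i];
        a[i] = 0.0;
        c[i] = 0.0;
      }
      for (int e = 0; e < 4; ++e) {
        bq[e] += K[e];
        bq[e + 1] += K[e];
        c[e] = -K[e];
        a[e + 1] = -K[e];
      }
      // Thomas
      for (int i = 1; i < 5; ++i) {
        double m = a[i] / bq[i - 1];
        bq[i] -= m * c[i - 1];
        d[i] -= m * d[i - 1];
      }
      psi_new[4] = d[4] / bq[4];
      for (int i = 3; i >= 0; --i)
        psi_new[i] = (d[i] - c[i] * psi_new[i + 1]) / bq[i];

      double dpsi = 0.0;
      for (int i = 1; i < 5; ++i) {
        double dd = std::fabs(psi_new[i] - psi[i]);
        if (dd > dpsi) dpsi = dd;
      }
      if (dpsi > dpsi_max && dt > dt_min) {
        dt *= 0.5;
        if (dt < dt_min) dt = dt_min;
        continue;
      }
      accepted = true;
      // commit: fluxes at new potentials
      double F[4];
      for (int e = 0; e < 4; ++e) F[e] = K[e] * (psi_new[e] - psi_new[e + 1]);
      W_soil += dt * (-F[0]);
      W[0] += dt * (F[0] - F[1]);
      W[1] += dt * (F[1] - F[2] - E[2]);
      W[2] += dt * (F[2] - F[3] - E[3]);
      W[3] += dt * (F[3] - E[4]);
      cum_loss += dt * (E[2] + E[3] + E[4]);
      // clamp pools (tracked as mass-balance error)
      for (int i = 0; i < 4; ++i) {
        double w_min = v_sym[i] * r_floor;
        if (W[i] < w_min) { clamp_err += w_min - W[i]; W[i] = w_min; }
        if (W[i] > v_sym[i]) { clamp_err += W[i] - v_sym[i]; W[i] = v_sym[i]; }
      }
      if (W_soil < 0.0) { clamp_err += -W_soil; W_soil = 0.0; }
      theta_rel = 100.0 * W_soil / pot_mol;

      // cavitation state: running maximum of PLC; apoplast release
      for (int i = 0; i < 4; ++i) {
        double p_new = plc_of(psi_new[i + 1], p50, slope);
        if (p_new > plc[i]) {
          double rel = v_apo[i] * (p_new - plc[i]) / 100.0;
          W[i] += rel;
          apo_store -= rel;
          plc[i] = p_new;
          if (W[i] > v_sym[i]) { clamp_err += W[i] - v_sym[i]; W[i] = v_sym[i]; }
        }
      }
      // irreversible leaf shedding
      if (deciduous) {
        double plf = 100.0 / (1.0 + std::exp(shed_rate *
                                             (psi_new[4] - shed_half)));
        if (plf > plf_max) plf_max = plf;
        la_rem = la0 * (1.0 - plf_max / 100.0);
      }
      for (int i = 0; i < 5; ++i) psi[i] = psi_new[i];
      t += dt;
      if (dpsi < 0.25 * dpsi_max && dt < dt_max) dt = std::min(dt * 1.5, dt_max);
    }

    if (plc[3] >= stop_plc) failed = true;
    if (t >= next_rec - 1e-6 || failed) {
      record(tair, vpd, par, gs, gs * vpd / patm * la_rem * 1.0,
             gres_now * vpd / patm * la_rem +
               2.0 * gres_now * vpd / patm * (bark_trunk + bark_branch));
      next_rec += 3600.0;
    }
  }

  double total_final = W_soil + W[0] + W[1] + W[2] + W[3] + apo_store;
  double mb_err = total_init - total_final - cum_loss - clamp_err;

  int n = o_time.size();
  DataFrame traj = DataFrame::create(
    _["time"] = wrap(o_time), _["t_air"] = wrap(o_tair),
    _["vpd"] = wrap(o_vpd), _["par"] = wrap(o_par),
    _["psi_soil"] = wrap(o_psi_soil), _["psi_root"] = wrap(o_psi_root),
    _["psi_trunk"] = wrap(o_psi_trunk), _["psi_branch"] = wrap(o_psi_branch),
    _["psi_leaf"] = wrap(o_psi_leaf), _["gs"] = wrap(o_gs),
    _["e_canopy"] = wrap(o_e_can), _["e_residual"] = wrap(o_e_res),
    _["plc_leaf"] = wrap(o_plc_leaf), _["plc_stem"] = wrap(o_plc_stem),
    _["theta_rel"] = wrap(o_theta), _["la_remaining"] = wrap(o_la),
    _["cum_loss"] = wrap(o_cum), _["total_water"] = wrap(o_total)
  );
  return List::create(
    _["trajectory"] = traj,
    _["failed"] = failed,
    _["aborted"] = aborted,
    _["final_time_days"] = t / 86400.0,
    _["initial_water"] = total_init,
    _["mass_balance_error"] = mb_err,
    _["clamp_error"] = clamp_err,
    _["n_records"] = n
  );
}
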
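#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-dimensional enthalpy-marching freezing simulator for a vial of
// solution cooled in a freeze-dryer.  All quantities in SI units.
//
// Thermodynamic state per node: specific enthalpy u (J/kg, zero for liquid
// at T_eq), ice mass fraction f, and a phase tag:
//   0 LIQUID  - single phase, may supercool (pre-nucleation)
//   1 SLUSH   - post-nucleation mush whose ice fraction is kinetically
//               limited (crystals grow only slowly away from the front)
//   2 ACTIVE  - mush on the liquidus, in contact with the solid front;
//               freezes as fast as heat removal allows
//   3 SOLID   - ice fraction at its ceiling f_max, sensible cooling only
//
// The caloric equation of state is u(T,f) = cp_l (T - T_eq) - f dHf(T)
// with dHf(T) = L0 - (cp_l - cp_i) (T_eq - T), so du/dT at fixed f is the
// mixture heat capacity (1-f) cp_l + f cp_i.  The liquidus encodes
// cryoscopic depression of the freeze-concentrated solution:
// T_liq(f) = Tm - d0 / (1 - f), Tm = T_eq + d0, d0 = 273.15 - T_eq.

namespace {

struct Thermo {
  double cp_l, cp_i, L0, Teq, d0, Tm, f_max, u_solidus;

  double dHf(double T) const { return L0 - (cp_l - cp_i) * (Teq - T); }

  double Tliq(double f) const {
    if (d0 <= 1e-12) return Tm;
    double den = 1.0 - f;
    if (den < 1e-9) den = 1e-9;
    return Tm - d0 / den;
  }

  // enthalpy on the liquidus at ice fraction f
  double u_liq(double f) const {
    double T = Tliq(f);
    return cp_l * (T - Teq) - f * dHf(T);
  }

  // invert u at fixed f (linear: sensible branch)
  double T_of_u_fixed_f(double u, double f) const {
    double c = cp_l - f * (cp_l - cp_i);
    return Teq + (u + f * L0) / c;
  }

  // invert u on the liquidus: find f in [0, f_max] with u_liq(f) = u
  double f_of_u_liquidus(double u) const {
    if (u >= 0.0) return 0.0;
    if (u <= u_solidus) return f_max;
    if (d0 <= 1e-12) return -u / L0;
    double lo = 0.0, hi = f_max;
    for (int it = 0; it < 60; ++it) {
      double mid = 0.5 * (lo + hi);
      if (u_liq(mid) > u) lo = mid; else hi = mid;
    }
    return 0.5 * (lo + hi);
  }
};

} // namespace

// [[Rcpp::export]]
List freeze_march_cpp(List pr) {
  const int n = as<int>(pr["n_nodes"]);
  const double H = as<double>(pr["height_m"]);
  const double dx = H / n;

  Thermo th;
  th.cp_l = as<double>(pr["cp_l"]);
  th.cp_i = as<double>(pr["cp_i"]);
  th.L0 = as<double>(pr["L0"]);
  th.Teq = as<double>(pr["T_eq"]);
  th.d0 = 273.15 - th.Teq;
  if (th.d0 < 0) th.d0 = 0;
  th.Tm = th.Teq + th.d0;
  const double sol_window = as<double>(pr["sol_window"]);
  th.f_max = (th.d0 <= 1e-12) ? 1.0 : 1.0 - th.d0 / (th.d0 + sol_window);
  th.u_solidus = th.u_liq(th.f_max);

  const double k_i = as<double>(pr["k_ice"]);
  const double k_l = as<double>(pr["k_liquid"]);
  const double rho = as<double>(pr["rho"]);
  const double PA = as<double>(pr["perim_over_area"]); // 2/r for a cylinder

  const double h_bottom = as<double>(pr["h_bottom"]);
  const double h_side = as<double>(pr["h_side"]);
  const double h_top = as<double>(pr["h_top"]);
  const double env_offset = as<double>(pr["env_offset"]);
  const double liq_top_bias = as<double>(pr["liquid_top_bias"]);
  const double fin_gain = as<double>(pr["fin_gain"]);
  const double fin_len = as<double>(pr["fin_length_m"]);

  const double T_init = as<double>(pr["T_init"]);
  const double T_shelf_pre = as<double>(pr["T_shelf_pre"]);
  const double T_shelf_hold = as<double>(pr["T_shelf_hold"]);
  const double hold_s = as<double>(pr["hold_s"]);
  const double ramp_rate = as<double>(pr["ramp_rate_K_s"]);
  const double pull_rate = as<double>(pr["pull_rate_K_s"]);
  const double T_final = as<double>(pr["T_final"]);

  const int mode = as<int>(pr["nucleation_mode"]); // 0 spontaneous, 1 VISF
  const double Tn_target = as<double>(pr["Tn_target"]);
  const double Tn_tol = as<double>(pr["Tn_tol"]);
  const double equil_hold_s = as<double>(pr["equil_hold_s"]);
  const double visf_trigger = as<double>(pr["visf_trigger_K"]);
  const double h_evap = as<double>(pr["h_evap"]);
  const double evap_sink = as<double>(pr["evap_sink_K"]);
  const double z_decay = as<double>(pr["evap_decay_m"]);
  const double visf_min_delay = as<double>(pr["visf_min_delay_s"]);
  const double spont_wait = as<double>(pr["spont_wait_s"]);
  const double pulse_override = as<double>(pr["pulse_start_override"]); // <0 disables

  const int slush_equilibrium = as<int>(pr["slush_equilibrium"]); // 1 = OFF-shelf emulation
  const double kin_rate = as<double>(pr["kin_rate"]); // 1/(K s)
  const double strat_K_per_m = as<double>(pr["strat_K_per_m"]);
  const double strat_tau = as<double>(pr["strat_tau_s"]);

  const double t_max = as<double>(pr["t_max"]);
  const double dt_out = as<double>(pr["dt_out"]);
  const double stop_temp = as<double>(pr["stop_temp"]);
  const bool early_stop = as<bool>(pr["early_stop"]);

  // node geometry
  std::vector<double> z(n);
  for (int i = 0; i < n; ++i) z[i] = (i + 0.5) * dx;

  // side-loss axial profile: uniform + exponential end boosts ("fin" ends)
  std::vector<double> fin_bot(n), fin_top(n);
  for (int i = 0; i < n; ++i) {
    fin_bot[i] = fin_gain * std::exp(-z[i] / fin_len);
    fin_top[i] = fin_gain * std::exp(-(H - z[i]) / fin_len);
  }

  // evaporative-pulse depth weights, normalised so sum(w * dx) = 1
  std::vector<double> wev(n);
  {
    double s = 0.0;
    for (int i = 0; i < n; ++i) { wev[i] = std::exp(-(H - z[i]) / z_decay); s += wev[i] * dx; }
    for (int i = 0; i < n; ++i) wev[i] /= s;
  }

  // state
  std::vector<double> T(n, T_init), u(n), f(n, 0.0), kth(n);
  std::vector<int> st(n, 0);
  for (int i = 0; i < n; ++i) u[i] = th.cp_l * (T_init - th.Teq);

  // stability-bounded explicit step
  const double k_hi = std::max(k_i, k_l);
  const double h_hi = std::max(std::max(h_bottom, h_top) * std::max(1.0, liq_top_bias), h_evap) +
                      h_side * (1.0 + fin_gain) * PA * dx;
  double dt = 0.4 * rho * th.cp_i * dx * dx / (2.0 * k_hi + h_hi * dx);
  if (dt > dt_out) dt = dt_out;

  const int n_out_max = (int)std::floor(t_max / dt_out) + 2;
  NumericMatrix T_out(n, n_out_max), f_out(n, n_out_max);
  NumericVector t_out(n_out_max), shelf_out(n_out_max), front_out(n_out_max), fro_frac(n_out_max);

  double t = 0.0, T_shelf = T_shelf_pre;
  bool nucleated = false, pulsing = false, holding = false;
  double t_nuc = NA_REAL, t_pulse = NA_REAL, t_hold = NA_REAL;
  double below_accum = 0.0; // time spent with bottom <= Tn_target (spontaneous clock)
  int m = 0;
  double next_out = 0.0;
  NumericVector f_nuc_nodes(n, NA_REAL), T_pre_nuc(n, NA_REAL);

  auto front_pos = [&]() -> double {
    // height (m) where f crosses 0.5, scanning upward from the bottom
    if (f[0] < 0.5) return 0.0;
    for (int i = 1; i < n; ++i) {
      if (f[i] < 0.5) {
        double fr = (f[i - 1] - 0.5) / (f[i - 1] - f[i]);
        return z[i - 1] + fr * dx;
      }
    }
    return H;
  };

  auto record = [&](double tstamp) {
    if (m >= n_out_max) return;
    if (m > 0 && tstamp - t_out[m - 1] < dt_out * 0.5) return; // no duplicates
    double fsum = 0.0;
    for (int i = 0; i < n; ++i) {
      T_out(i, m) = T[i];
      f_out(i, m) = f[i];
      fsum += f[i];
    }
    t_out[m] = tstamp; shelf_out[m] = T_shelf; front_out[m] = front_pos();
    fro_frac[m] = fsum / n;
    ++m;
  };

  record(0.0); next_out = dt_out;

  double t_since_stop_ok = -1.0;

  while (t < t_max) {
    // ---- shelf setpoint tracking (rate-limited) ----
    double target, rate;
    if (!nucleated) { target = T_shelf_pre; rate = pull_rate; }
    else if (t - t_nuc < hold_s) { target = T_shelf_hold; rate = pull_rate; }
    else { target = T_final; rate = ramp_rate; }
    const double ramp_dt = rate * dt;
    if (T_shelf < target) T_shelf = std::min(T_shelf + ramp_dt, target);
    else T_shelf = std::max(T_shelf - ramp_dt, target);
    const double T_env = T_shelf + env_offset;

    // ---- nucleation state machine ----
    if (!nucleated) {
      if (mode == 1) { // VISF
        if (pulse_override >= 0.0) {
          if (!pulsing && t >= pulse_override) { pulsing = true; t_pulse = t; }
        } else {
          if (!holding && !pulsing && T[0] <= Tn_target + Tn_tol) {
            holding = true; t_hold = t;
          }
          if (holding && t - t_hold >= equil_hold_s) {
            holding = false; pulsing = true; t_pulse = t;
          }
        }
        if (pulsing && t - t_pulse >= visf_min_delay && T[n - 1] <= visf_trigger) {
          nucleated = true; t_nuc = t;
        }
      } else { // spontaneous: exponential clock while supercooled
        double Tmin = T[0];
        for (int i = 1; i < n; ++i) Tmin = std::min(Tmin, T[i]);
        if (Tmin <= Tn_target) below_accum += dt;
        if (below_accum >= spont_wait) { nucleated = true; t_nuc = t; }
      }
      if (nucleated) {
        // instantaneous partial solidification: each supercooled node jumps
        // to its (depressed) equilibrium temperature releasing latent heat
        for (int i = 0; i < n; ++i) {
          T_pre_nuc[i] = T[i];
          double sc = th.Teq - T[i];
          double fi = 0.0;
          if (sc > 0) fi = th.cp_l * sc / th.dHf(T[i]);
          if (fi < 1e-4) fi = 1e-4;
          if (fi > 0.6) fi = 0.6;
          f_nuc_nodes[i] = fi;
          f[i] = fi;
          double Ti = th.Tliq(fi);
          T[i] = Ti;
          u[i] = th.cp_l * (Ti - th.Teq) - fi * th.dHf(Ti);
          st[i] = slush_equilibrium ? 2 : 1;
        }
        if (!slush_equilibrium) st[0] = 2; // solid front nucleates at the cold base
        pulsing = false;
      }
    }

    // ---- fluxes ----
    for (int i = 0; i < n; ++i) kth[i] = k_l + (k_i - k_l) * f[i];

    const bool liq_phase = !nucleated;
    double bias_t = 1.0, bias_b = 1.0;
    if (liq_phase && liq_top_bias > 1.0) { bias_t = liq_top_bias; bias_b = 1.0 / liq_top_bias; }

    double hb = h_bottom * bias_b, ht = h_top * bias_t;
    double Ub = 1.0 / (1.0 / hb + dx / (2.0 * kth[0]));
    double Ut = 1.0 / (1.0 / ht + dx / (2.0 * kth[n - 1]));

    // du accumulators (J/kg per step)
    static std::vector<double> du; du.assign(n, 0.0);

    for (int i = 0; i < n - 1; ++i) {
      double kh = 2.0 * kth[i] * kth[i + 1] / (kth[i] + kth[i + 1]);
      double q = kh * (T[i + 1] - T[i]) / dx; // W/m2, positive into node i
      du[i] += q; du[i + 1] -= q;
    }
    du[0] += Ub * (T_shelf - T[0]);
    du[n - 1] += Ut * (T_env - T[n - 1]);

    for (int i = 0; i < n; ++i) {
      double sfac = 1.0 + fin_bot[i] * bias_b + fin_top[i] * bias_t;
      // buoyant stratification in the liquid: cold water (< 277 K) rises,
      // so suspended vials cool preferentially from the top of the bulk
      if (liq_phase && liq_top_bias > 1.0) {
        sfac *= 1.0 + (liq_top_bias - 1.0) * (z[i] / H);
      }
      du[i] += h_side * sfac * (T_env - T[i]) * PA * dx;
      if (pulsing) du[i] += h_evap * (evap_sink - T[i]) * wev[i] * dx;
    }

    for (int i = 0; i < n; ++i) u[i] += du[i] * dt / (rho * dx);

    // ---- invert enthalpy, apply kinetics and promotions ----
    for (int i = 0; i < n; ++i) {
      switch (st[i]) {
      case 0:
        T[i] = th.Teq + u[i] / th.cp_l;
        break;
      case 1: { // slush: kinetic freezing toward the liquidus
        double und = th.Tliq(f[i]) - T[i];
        if (und > 0) {
          f[i] += kin_rate * und * dt;
          if (f[i] >= th.f_max) { f[i] = th.f_max; st[i] = 3; }
        }
        T[i] = th.T_of_u_fixed_f(u[i], f[i]);
        break;
      }
      case 2: { // active mush pinned to the liquidus
        if (u[i] <= th.u_solidus) {
          f[i] = th.f_max; st[i] = 3;
          T[i] = th.T_of_u_fixed_f(u[i], f[i]);
        } else if (u[i] >= 0.0) {
          f[i] = 0.0; T[i] = th.Teq + u[i] / th.cp_l;
        } else {
          f[i] = th.f_of_u_liquidus(u[i]);
          T[i] = th.Tliq(f[i]);
        }
        break;
      }
      default: // solid
        T[i] = th.T_of_u_fixed_f(u[i], th.f_max);
        if (T[i] > th.Tliq(th.f_max) + 1e-9) { st[i] = 2; } // re-melt guard
        break;
      }
    }
    // buoyant stratification of the supercooled liquid in suspended vials:
    // below the density maximum the coldest water rises, holding a stable
    // inverse gradient (bottom warmest) that pure conduction cannot give.
    // Energy-conserving relaxation toward a linear stratified profile.
    if (!nucleated && strat_K_per_m > 0.0) {
      double beta = dt / strat_tau;
      if (beta > 1.0) beta = 1.0;
      double Tbar = 0.0;
      for (int i = 0; i < n; ++i) Tbar += T[i];
      Tbar /= n;
      for (int i = 0; i < n; ++i) {
        if (st[i] != 0) continue;
        double target = Tbar + strat_K_per_m * (0.5 * H - z[i]);
        T[i] += beta * (target - T[i]);
        u[i] = th.cp_l * (T[i] - th.Teq);
      }
    }

    if (nucleated && !slush_equilibrium) {
      // contiguous crystal growth: slush joins the active front once its
      // neighbour toward the front is at least half frozen (dendrites run
      // ahead of complete local solidification)
      for (int i = 0; i < n; ++i) {
        bool below = i > 0 && st[i - 1] >= 2 && f[i - 1] >= 0.5;
        bool above = i < n - 1 && st[i + 1] >= 2 && f[i + 1] >= 0.5;
        if (st[i] == 1 && (below || above)) st[i] = 2;
      }
    }

    t += dt;
    if (t + 1e-9 >= next_out) { record(next_out); next_out += dt_out; }

    if (early_stop && nucleated && t > t_nuc + 120.0) {
      double Tmx = T[0];
      for (int i = 1; i < n; ++i) Tmx = std::max(Tmx, T[i]);
      if (Tmx <= stop_temp) {
        if (t_since_stop_ok < 0) t_since_stop_ok = t;
        if (t - t_since_stop_ok > 60.0) break;
      } else t_since_stop_ok = -1.0;
    }
  }
  record(std::round(t / dt_out) * dt_out);

  NumericVector zz(n);
  for (int i = 0; i < n; ++i) zz[i] = z[i] * 1000.0; // mm

  return List::create(
    _["time_s"] = t_out[Range(0, m - 1)],
    _["T_axial"] = T_out(_, Range(0, m - 1)),
    _["f_axial"] = f_out(_, Range(0, m - 1)),
    _["node_heights_mm"] = zz,
    _["front_position_mm"] = NumericVector(front_out[Range(0, m - 1)]) * 1000.0,
    _["frozen_fraction"] = fro_frac[Range(0, m - 1)],
    _["T_shelf"] = shelf_out[Range(0, m - 1)],
    _["t_nucleation_s"] = t_nuc,
    _["t_pulse_start_s"] = t_pulse,
    _["t_equil_hold_s"] = t_hold,
    _["f_nucleation"] = f_nuc_nodes,
    _["T_pre_nucleation"] = T_pre_nuc,
    _["dt_s"] = dt);
}
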
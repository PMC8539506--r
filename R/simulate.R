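#' Construct a vial thermal history
#'
#' Container for the simulated (or hand-built) axial temperature field of a
#' single vial during freezing.  Rows of `T_axial` are nodes ordered from
#' the vial bottom; columns are time points.
#'
#' @param time_s time grid (s).
#' @param T_axial `n_nodes x n_times` temperature matrix (K).
#' @param node_heights_mm node-centre heights above the vial bottom (mm).
#' @param front_position_mm freezing-front height series (mm), or `NULL`.
#' @param t_nucleation_s nucleation time (s), `NA` if none.
#' @param frozen_fraction overall frozen-fraction series, or `NULL`.
#' @param ... further fields stored verbatim (e.g. simulator diagnostics).
#' @return An object of class `vial_thermal_history`.
#' @export
vial_thermal_history <- function(time_s, T_axial, node_heights_mm,
                                 front_position_mm = NULL,
                                 t_nucleation_s = NA_real_,
                                 frozen_fraction = NULL, ...) {
  T_axial <- as.matrix(T_axial)
  stopifnot(ncol(T_axial) == length(time_s),
            nrow(T_axial) == length(node_heights_mm),
            all(is.finite(T_axial)))
  if (!is.null(frozen_fraction)) {
    stopifnot(all(frozen_fraction >= -1e-9), all(frozen_fraction <= 1 + 1e-9))
  }
  structure(c(list(time_s = time_s, T_axial = T_axial,
                   node_heights_mm = node_heights_mm,
                   front_position_mm = front_position_mm,
                   t_nucleation_s = t_nucleation_s,
                   frozen_fraction = frozen_fraction),
              list(...)),
            class = "vial_thermal_history")
}

#' Simulate freezing of one vial
#'
#' One-dimensional enthalpy-marching simulation (explicit scheme with a
#' stability-bounded time step) of a 10 mm liquid column cooled in a
#' freeze-dryer.  The run has three phases: sensible cooling of the liquid
#' toward the shelf setpoint; nucleation (a VISF vacuum pulse with
#' evaporative surface cooling, or a stochastic exponential clock while the
#' product is supercooled), at which every supercooled node jumps to its
#' equilibrium temperature with the frozen fraction of
#' [instant_freeze_fraction()]; then front propagation.  ON-shelf vials
#' grow a solid layer from the base while the slush above it freezes only
#' kinetically (so the camera-visible temperature maximum rides on the
#' front); OFF-shelf vials are emulated with symmetric end cooling and an
#' equilibrium mush, reproducing the mid-height maximum the camera reports.
#'
#' @param protocol a [freezing_protocol()].
#' @param props a [physical_properties()]; its `loading` should match.
#' @param n_nodes number of axial nodes (>= 4).
#' @param seed integer seed for the stochastic elements (spontaneous
#'   nucleation clock, VISF delay jitter).
#' @param cake_height_mm liquid fill height (mm).
#' @param dt_out_s output sampling interval (s).
#' @param early_stop stop once everything is 2 K below the 263 K analysis
#'   threshold (single-vial runs); batch runs disable this to share a grid.
#' @param h_scale multiplier applied to all heat-transfer coefficients
#'   (vial-to-vial variability in a batch).
#' @param visf_trigger_K surface temperature (K) at which the evaporatively
#'   cooled top layer nucleates during the VISF pulse.
#' @param h_evap,evap_sink_K,evap_decay_mm evaporative-pulse strength
#'   (W/(m^2 K)), effective sink temperature (K) and convective penetration
#'   depth (mm) of the surface cooling.
#' @param spont_rate spontaneous nucleation rate (1/s) of the exponential
#'   clock counting time spent supercooled.
#' @param T_init initial liquid temperature (K).
#' @param pulse_start_s externally imposed VISF pulse onset (s): the
#'   chamber pressure drop is a batch-wide event, so batch runs determine
#'   it once (probe vial) and impose it on every vial. `NA` lets the
#'   vial's own equilibration hold schedule the pulse.
#' @return A [vial_thermal_history()] with simulator diagnostics attached
#'   (`f_axial`, `T_shelf`, `t_pulse_start_s`, `f_nucleation`, ...).
#' @export
simulate_vial_freezing <- function(protocol, props = physical_properties(loading = protocol$loading),
                                   n_nodes = 32, seed = 1,
                                   cake_height_mm = 10, dt_out_s = 10,
                                   early_stop = TRUE, h_scale = 1,
                                   visf_trigger_K = 264.5,
                                   h_evap = 20, evap_sink_K = 230,
                                   evap_decay_mm = 8,
                                   spont_rate = 1 / 300,
                                   T_init = 283, pulse_start_s = NA) {
  stopifnot(inherits(protocol, "freezing_protocol"),
            inherits(props, "physical_properties"),
            n_nodes >= 4)
  if (protocol$loading != props$loading) {
    stop("protocol and properties describe different loading configurations")
  }
  set.seed(seed)
  spont_wait <- stats::rexp(1, spont_rate)
  visf_min_delay <- 2 + stats::runif(1, 0, 15)

  pr <- list(
    n_nodes = as.integer(n_nodes),
    height_m = cake_height_mm / 1000,
    cp_l = props$cp_liquid * 1000, cp_i = props$cp_ice * 1000,
    L0 = props$latent_heat_eq * 1000,
    T_eq = props$T_eq, sol_window = props$sol_window_K,
    k_ice = props$k_ice, k_liquid = props$k_liquid,
    rho = props$density * 1000,
    perim_over_area = 2 / (props$vial_radius_mm / 1000),
    h_bottom = props$h_bottom * h_scale,
    h_side = props$h_side * h_scale,
    h_top = props$h_top * h_scale,
    env_offset = props$env_offset_K,
    liquid_top_bias = props$liquid_top_bias,
    fin_gain = props$fin_gain, fin_length_m = props$fin_length_mm / 1000,
    T_init = T_init, T_shelf_pre = protocol$T_shelf_pre,
    T_shelf_hold = protocol$T_shelf_hold,
    hold_s = protocol$hold_minutes * 60,
    ramp_rate_K_s = protocol$ramp_rate / 60,
    pull_rate_K_s = protocol$pull_rate / 60,
    T_final = protocol$T_final,
    nucleation_mode = if (protocol$nucleation_mode == "VISF") 1L else 0L,
    Tn_target = protocol$Tn_target, Tn_tol = 0.2,
    equil_hold_s = 600,
    visf_trigger_K = visf_trigger_K,
    h_evap = h_evap * h_scale, evap_sink_K = evap_sink_K,
    evap_decay_m = evap_decay_mm / 1000,
    visf_min_delay_s = visf_min_delay,
    spont_wait_s = spont_wait,
    pulse_start_override = if (is.na(pulse_start_s)) -1 else pulse_start_s,
    slush_equilibrium = if (protocol$loading == "OFF_SHELF") 1L else 0L,
    kin_rate = props$kinetic_rate,
    strat_K_per_m = props$stratification_K_per_mm * 1000,
    strat_tau_s = props$stratification_tau_s,
    t_max = protocol$sim_duration_s, dt_out = dt_out_s,
    stop_temp = 261, early_stop = early_stop
  )
  out <- freeze_march_cpp(pr)
  vial_thermal_history(
    time_s = out$time_s, T_axial = out$T_axial,
    node_heights_mm = out$node_heights_mm,
    front_position_mm = out$front_position_mm,
    t_nucleation_s = out$t_nucleation_s,
    frozen_fraction = out$frozen_fraction,
    f_axial = out$f_axial, T_shelf = out$T_shelf,
    t_pulse_start_s = out$t_pulse_start_s,
    t_equil_hold_s = out$t_equil_hold_s,
    f_nucleation = out$f_nucleation,
    T_pre_nucleation = out$T_pre_nucleation,
    protocol = protocol, props = props, dt_s = out$dt_s, seed = seed
  )
}

#' Simulate a batch of vials on a shared time grid
#'
#' Runs [simulate_vial_freezing()] for `n_vials` vials with lognormal
#' vial-to-vial variability of the heat-transfer coefficients (coefficient
#' of variation `h_cv`) and independent nucleation stochastics, without
#' early stopping so all histories share the protocol's time grid.
#'
#' @inheritParams simulate_vial_freezing
#' @param n_vials number of vials.
#' @param h_cv coefficient of variation of the per-vial heat-transfer
#'   multiplier.
#' @param ... passed to [simulate_vial_freezing()].
#' @return List of `vial_thermal_history` objects.
#' @export
simulate_batch <- function(protocol, props = physical_properties(loading = protocol$loading),
                           n_vials = 10, seed = 1, h_cv = 0.05, ...) {
  set.seed(seed)
  h_mult <- exp(stats::rnorm(n_vials, -h_cv^2 / 2, h_cv))
  vial_seeds <- sample.int(2^31 - 2, n_vials)
  pulse_start <- NA
  if (protocol$nucleation_mode == "VISF") {
    # the pressure drop is chamber-wide: schedule it once with a probe vial
    probe <- simulate_vial_freezing(protocol, props, seed = seed,
                                    early_stop = FALSE, ...)
    pulse_start <- probe$t_pulse_start_s
  }
  lapply(seq_len(n_vials), function(v) {
    simulate_vial_freezing(protocol, props, seed = vial_seeds[v],
                           early_stop = FALSE, h_scale = h_mult[v],
                           pulse_start_s = pulse_start, ...)
  })
}

#' @export
print.vial_thermal_history <- function(x, ...) {
  cat(sprintf("<vial_thermal_history> %d nodes x %d times (%.0f s span); nucleation at %s s\n",
              nrow(x$T_axial), ncol(x$T_axial), max(x$time_s),
              format(x$t_nucleation_s)))
  invisible(x)
}
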
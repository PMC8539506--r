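#' Freezing protocol description
#'
#' Captures the freezing portion of a lyophilization recipe: vial loading
#' configuration, nucleation control, target nucleation temperature, shelf
#' setpoints and the post-nucleation ramp.
#'
#' @param loading `"ON_SHELF"` (vials in direct contact with the shelf,
#'   conduction dominated) or `"OFF_SHELF"` (suspended vials, natural
#'   convection plus radiation).
#' @param nucleation_mode `"SPONTANEOUS"` (stochastic nucleation once the
#'   product is supercooled) or `"VISF"` (vacuum-induced surface freezing:
#'   an equilibration hold at `Tn_target` followed by a vacuum pulse that
#'   evaporatively cools the liquid surface until nucleation).
#' @param Tn_target target nucleation temperature (K), below 273.15.
#' @param T_shelf_hold shelf holding temperature Th (K) maintained after
#'   nucleation.
#' @param T_shelf_pre shelf setpoint (K) before nucleation; defaults to
#'   `T_shelf_hold` (they differ only for mild-supercooling VISF recipes).
#' @param ramp_rate shelf ramp rate (K/min) toward `T_final` after the hold.
#' @param pull_rate shelf rate (K/min) for the drop from `T_shelf_pre` to
#'   `T_shelf_hold` right after nucleation (dryers pull this step faster
#'   than the final ramp).
#' @param T_final final shelf setpoint (K).
#' @param hold_minutes duration (min) of the Th hold after nucleation.
#' @param sim_duration_s total simulated time budget (s) when early stopping
#'   is disabled (batch runs share this grid).
#' @return An object of class `freezing_protocol`.
#' @export
freezing_protocol <- function(loading = c("ON_SHELF", "OFF_SHELF"),
                              nucleation_mode = c("VISF", "SPONTANEOUS"),
                              Tn_target = 271,
                              T_shelf_hold = if (match.arg(loading) == "ON_SHELF") 258 else 248,
                              T_shelf_pre = NULL,
                              ramp_rate = 0.5,
                              pull_rate = 2,
                              T_final = 223,
                              hold_minutes = 60,
                              sim_duration_s = NULL) {
  loading <- match.arg(loading)
  nucleation_mode <- match.arg(nucleation_mode)
  if (is.null(T_shelf_pre)) T_shelf_pre <- T_shelf_hold
  if (is.null(sim_duration_s)) {
    sim_duration_s <- if (loading == "ON_SHELF") 4500 else 7500
  }
  stopifnot(Tn_target < 273.15, ramp_rate > 0, pull_rate > 0)
  if (!(T_final <= T_shelf_hold && T_shelf_hold <= Tn_target + 10)) {
    stop("require T_final <= T_shelf_hold <= Tn_target + 10")
  }
  structure(list(
    loading = loading, nucleation_mode = nucleation_mode,
    Tn_target = Tn_target, T_shelf_hold = T_shelf_hold,
    T_shelf_pre = T_shelf_pre, ramp_rate = ramp_rate,
    pull_rate = pull_rate,
    T_final = T_final, hold_minutes = hold_minutes,
    sim_duration_s = sim_duration_s
  ), class = "freezing_protocol")
}

#' Physical properties of the solution and its heat-transfer environment
#'
#' Thermophysical constants for a dilute aqueous excipient solution plus the
#' effective heat-transfer coefficients of the vial in its loading
#' configuration.  The paper-grade water constants are the defaults
#' (cp liquid 4.18 J/(g K), cp ice 2.1 J/(g K), latent heat 334 J/g at the
#' equilibrium temperature, ice conductivity 2.14 W/(m K)).  The
#' heat-transfer coefficients are calibration knobs: dryer-specific values
#' are not published, so the defaults were chosen once to reproduce the
#' magnitudes of the observed freezing dynamics (about 20 min freezing
#' ON-shelf versus about 45 min OFF-shelf).
#'
#' @param cp_liquid,cp_ice specific heat, J/(g K).
#' @param latent_heat_eq latent heat of fusion at `T_eq`, J/g.
#' @param T_eq equilibrium freezing temperature of the solution (K);
#'   273.0 K approximates the cryoscopic depression of 5 % w/w solutions,
#'   use 273.15 for pure water.
#' @param k_ice,k_liquid thermal conductivity, W/(m K).
#' @param density g/cm^3.
#' @param h_bottom,h_side,h_top effective heat-transfer coefficients,
#'   W/(m^2 K).  Defaults depend on `loading`: ON-shelf concentrates heat
#'   removal at the base (shelf contact plus gas conduction at ambient
#'   pressure), OFF-shelf removes heat from both ends and the side wall by
#'   natural convection and radiation.
#' @param loading used only to pick coefficient defaults.
#' @param vial_radius_mm inner radius used for the side-area to volume ratio.
#' @param env_offset_K gas/wall environment temperature above the shelf
#'   setpoint (the chamber is warmer than the temperature-controlled shelf).
#' @param liquid_top_bias pre-nucleation redistribution of end cooling for
#'   suspended vials: buoyancy in water below 277 K carries the coldest
#'   liquid to the top, so the top of a suspended vial leads the cooling
#'   (bottom pixel warmest before nucleation).  1 disables the bias.
#' @param fin_gain,fin_length_mm axial boost of side cooling near the two
#'   ends of a suspended vial (glass above/below the product acting as a
#'   thermal fin); emulates in 1-D the mid-height temperature maximum the
#'   camera reports for OFF-shelf vials.
#' @param stratification_K_per_mm strength (K/mm) of the buoyant inverse
#'   stratification of the supercooled liquid in suspended vials: below
#'   water's density maximum the coldest liquid rises, so OFF-shelf vials
#'   show a stable bottom-warmest gradient before nucleation that pure
#'   conduction cannot reproduce.  0 for ON-shelf vials.
#' @param stratification_tau_s convective overturn time (s) with which the
#'   liquid relaxes toward the stratified profile.
#' @param kinetic_rate crystal-growth rate constant (1/(K s)) limiting how
#'   fast mush away from the solid front can freeze; gives the slush its
#'   observed slight undercooling in ON-shelf vials.
#' @param sol_window_K width (K) of the liquidus span between nominal
#'   freezing point and the operational solidus; sets the ice-fraction
#'   ceiling f_max = 1 - d0/(d0 + sol_window) with d0 = 273.15 - T_eq.
#' @return An object of class `physical_properties`.
#' @export
physical_properties <- function(cp_liquid = 4.18, cp_ice = 2.1,
                                latent_heat_eq = 334, T_eq = 273.0,
                                k_ice = 2.14, k_liquid = 0.6,
                                density = 1.0,
                                loading = c("ON_SHELF", "OFF_SHELF"),
                                h_bottom = NULL, h_side = NULL, h_top = NULL,
                                vial_radius_mm = 7,
                                env_offset_K = 3,
                                liquid_top_bias = NULL,
                                stratification_K_per_mm = NULL,
                                stratification_tau_s = 5,
                                fin_gain = NULL, fin_length_mm = 2.5,
                                kinetic_rate = 1e-5,
                                sol_window_K = 2) {
  loading <- match.arg(loading)
  on <- loading == "ON_SHELF"
  if (is.null(h_bottom)) h_bottom <- if (on) 250 else 24
  if (is.null(h_side)) h_side <- if (on) 24 else 8
  if (is.null(h_top)) h_top <- if (on) 3 else 12
  if (is.null(liquid_top_bias)) liquid_top_bias <- if (on) 1 else 2.5
  if (is.null(stratification_K_per_mm)) stratification_K_per_mm <- if (on) 0 else 0.45
  if (is.null(fin_gain)) fin_gain <- if (on) 0 else 2
  vals <- c(cp_liquid, cp_ice, latent_heat_eq, k_ice, k_liquid, density,
            h_bottom, h_side, h_top)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("physical properties must be finite and strictly positive")
  }
  if (k_ice <= k_liquid) stop("require k_ice > k_liquid")
  if (T_eq > 273.15) stop("require T_eq <= 273.15")
  structure(list(
    cp_liquid = cp_liquid, cp_ice = cp_ice, latent_heat_eq = latent_heat_eq,
    T_eq = T_eq, k_ice = k_ice, k_liquid = k_liquid, density = density,
    loading = loading, h_bottom = h_bottom, h_side = h_side, h_top = h_top,
    vial_radius_mm = vial_radius_mm, env_offset_K = env_offset_K,
    liquid_top_bias = liquid_top_bias,
    stratification_K_per_mm = stratification_K_per_mm,
    stratification_tau_s = stratification_tau_s,
    fin_gain = fin_gain,
    fin_length_mm = fin_length_mm, kinetic_rate = kinetic_rate,
    sol_window_K = sol_window_K
  ), class = "physical_properties")
}

#' Instantaneously frozen fraction at nucleation
#'
#' Adiabatic heat balance of nucleation: a supercooled liquid at `Tn` jumps
#' back to the equilibrium temperature, and the sensible heat gained is paid
#' for by the latent heat of the fraction that solidifies instantly,
#' \deqn{f = c_{p,l}\,(T_{eq} - T_n) / \Delta H_f(T_n),}
#' with the latent heat corrected to the nucleation temperature,
#' \eqn{\Delta H_f(T_n) = \Delta H_f(T_{eq}) - (c_{p,l} - c_{p,ice})(T_{eq} - T_n)}.
#' With standard water constants this gives about 3 % at 271 K and about
#' 14 % at 263 K.
#'
#' @param Tn nucleation temperature (K); vectorised.
#' @param props a [physical_properties()] object.
#' @return Frozen mass fraction(s) in `[0, 1)`.
#' @export
instant_freeze_fraction <- function(Tn, props = physical_properties()) {
  stopifnot(inherits(props, "physical_properties"))
  if (any(Tn > props$T_eq)) {
    stop("Tn exceeds the equilibrium temperature: no supercooling, no nucleation")
  }
  sc <- props$T_eq - Tn
  dHf <- props$latent_heat_eq - (props$cp_liquid - props$cp_ice) * sc
  f <- props$cp_liquid * sc / dHf
  stopifnot(all(f >= 0), all(f < 1))
  f
}

#' @export
print.freezing_protocol <- function(x, ...) {
  cat(sprintf("<freezing_protocol> %s / %s  Tn = %g K, Th = %g K (pre %g K), ramp %g K/min to %g K\n",
              x$loading, x$nucleation_mode, x$Tn_target, x$T_shelf_hold,
              x$T_shelf_pre, x$ramp_rate, x$T_final))
  invisible(x)
}

#' @export
print.physical_properties <- function(x, ...) {
  cat(sprintf("<physical_properties> %s: cp_l %g, cp_ice %g J/(g K); dHf %g J/g at Teq %g K; k_ice %g W/(m K)\n",
              x$loading, x$cp_liquid, x$cp_ice, x$latent_heat_eq, x$T_eq, x$k_ice))
  cat(sprintf("  h (W/m2K): bottom %g, side %g, top %g; env offset %g K\n",
              x$h_bottom, x$h_side, x$h_top, x$env_offset_K))
  invisible(x)
}
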
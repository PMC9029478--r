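#' Parameter set for one simulated muscle strip
#'
#' Bundles every constant the forward model needs to generate recordings for
#' one isolated atrial strip: geometry, Ca-transient kinetics, the
#' Ca-to-force coupling, the force-length maps, the slow-force-response (SFR)
#' and post-rest-potentiation (PRP) envelopes, measurement noise, and
#' inter-muscle variability.
#'
#' @param group_label `"CONT"` (healthy) or `"MCT"` (monocrotaline-treated).
#' @param l_max_um Absolute muscle length at maximal active tension (um).
#'   Preloads are expressed as a percentage of this length.
#' @param diameter_um Larger transversal width of the strip (um); the
#'   elliptic cross-section is `pi * d^2 / 12`.
#' @param tau_ca_rise,tau_ca_decay Rise and decay time constants of the
#'   two-exponential Ca transient (ms); the rise constant must be smaller.
#' @param ca_dia Diastolic Ca-transient level (F/F0 units).
#' @param ca_amp Ca-transient amplitude above the diastolic level at the
#'   reference preload (F/F0 units).
#' @param k_act,k_rel Activation and relaxation rate constants of the
#'   first-order force activation ODE (1/s).
#' @param hill_n,hill_k Effective cooperativity exponent and half-activation
#'   constant (F/F0 units above diastolic) of the Hill coupling from Ca to
#'   force activation.
#' @param f_ref Force at full activation at 100% of `l_max_um` (mN); sets the
#'   absolute force scale.
#' @param fl_active Length-dependence of active force: a list with
#'   `min_scale` (scale at 75% L_MAX) and `gamma` (shape exponent); the scale
#'   rises monotonically from `min_scale` at 75% to 1 at 100% L_MAX.
#' @param fl_passive Exponential passive force-length map: a list with
#'   `alpha_mN`, `beta` and `ell0` giving
#'   `P(L) = alpha_mN * (exp(beta * (L/l_max - ell0)) - 1)` (0 below `ell0`).
#' @param sfr_gain_ca,sfr_gain_sens,sfr_tau Slow-force-response envelope:
#'   fractional steady-state change of Ca-transient amplitude, of myofilament
#'   sensitivity (1/hill_k), and their shared time constant (s). Gains may be
#'   negative (the CONT Ca amplitude declines during SFR).
#' @param sfr_dia_gain Fractional slow rise of the diastolic Ca level during
#'   SFR (about 0.01).
#' @param prp_load_gain,prp_load_tau Rest-induced growth of the releasable Ca
#'   load: fractional gain at saturation and its time constant (s).
#' @param prp_recirc Per-beat geometric recovery fraction toward the pre-pause
#'   steady state after a pause (strictly between 0 and 1).
#' @param prp_dia_dip,prp_dia_rise,prp_dia_tau_beats Shape of the post-pause
#'   diastolic Ca envelope: fractional dip during the first three beats,
#'   fractional late rise, and the beat-count time constant of the approach.
#' @param noise_sd_force,noise_sd_fluor Additive white Gaussian measurement
#'   noise SD on the force channel (mN) and on each fluorescence channel
#'   (arbitrary units).
#' @param cv_inter_muscle Coefficient of variation of the lognormal per-muscle
#'   multipliers applied to the slow-response gains and the force scale.
#' @param cv_kinetics Coefficient of variation of the lognormal per-muscle
#'   multipliers applied to time constants and rate constants.
#'
#' @return An object of class `muscle_params` (a validated named list).
#' @seealso [default_params()] for the calibrated CONT/MCT defaults,
#'   [make_cohort()] and [simulate_protocol()].
#' @export
muscle_params <- function(group_label,
                          l_max_um,
                          diameter_um,
                          tau_ca_rise,
                          tau_ca_decay,
                          ca_dia,
                          ca_amp,
                          k_act,
                          k_rel,
                          hill_n,
                          hill_k,
                          f_ref,
                          fl_active,
                          fl_passive,
                          sfr_gain_ca,
                          sfr_gain_sens,
                          sfr_tau,
                          sfr_dia_gain,
                          prp_load_gain,
                          prp_load_tau,
                          prp_recirc,
                          prp_dia_dip = 0.02,
                          prp_dia_rise = 0.01,
                          prp_dia_tau_beats = 6,
                          noise_sd_force = 4e-4,
                          noise_sd_fluor = 4e-3,
                          cv_inter_muscle = 0.02,
                          cv_kinetics = 0.02) {
  p <- list(
    group_label = match.arg(group_label, c("CONT", "MCT")),
    l_max_um = l_max_um, diameter_um = diameter_um,
    tau_ca_rise = tau_ca_rise, tau_ca_decay = tau_ca_decay,
    ca_dia = ca_dia, ca_amp = ca_amp,
    k_act = k_act, k_rel = k_rel,
    hill_n = hill_n, hill_k = hill_k, f_ref = f_ref,
    fl_active = fl_active, fl_passive = fl_passive,
    sfr_gain_ca = sfr_gain_ca, sfr_gain_sens = sfr_gain_sens,
    sfr_tau = sfr_tau, sfr_dia_gain = sfr_dia_gain,
    prp_load_gain = prp_load_gain, prp_load_tau = prp_load_tau,
    prp_recirc = prp_recirc,
    prp_dia_dip = prp_dia_dip, prp_dia_rise = prp_dia_rise,
    prp_dia_tau_beats = prp_dia_tau_beats,
    noise_sd_force = noise_sd_force, noise_sd_fluor = noise_sd_fluor,
    cv_inter_muscle = cv_inter_muscle, cv_kinetics = cv_kinetics
  )
  class(p) <- "muscle_params"
  validate_muscle_params(p)
}

validate_muscle_params <- function(p) {
  for (nm in c("l_max_um", "diameter_um", "tau_ca_rise", "tau_ca_decay",
               "ca_dia", "ca_amp", "k_act", "k_rel", "hill_n", "hill_k",
               "f_ref", "sfr_tau", "prp_load_tau", "prp_dia_tau_beats")) {
    stopifnot_scalar_pos(p[[nm]], nm)
  }
  for (nm in c("noise_sd_force", "noise_sd_fluor", "cv_inter_muscle",
               "cv_kinetics")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0) {
      stop(sprintf("`%s` must be a non-negative scalar", nm), call. = FALSE)
    }
  }
  if (p$tau_ca_rise >= p$tau_ca_decay) {
    stop("`tau_ca_rise` must be smaller than `tau_ca_decay` ",
         "(the transient rises faster than it decays)", call. = FALSE)
  }
  if (p$prp_recirc <= 0 || p$prp_recirc >= 1) {
    stop("`prp_recirc` must lie strictly between 0 and 1", call. = FALSE)
  }
  fa <- p$fl_active
  if (!is.list(fa) || is.null(fa$min_scale) || is.null(fa$gamma) ||
      fa$min_scale < 0 || fa$min_scale > 1 || fa$gamma <= 0) {
    stop("`fl_active` must be list(min_scale in [0,1], gamma > 0)",
         call. = FALSE)
  }
  fp <- p$fl_passive
  if (!is.list(fp) || is.null(fp$alpha_mN) || is.null(fp$beta) ||
      is.null(fp$ell0) || fp$alpha_mN < 0 || fp$beta <= 0) {
    stop("`fl_passive` must be list(alpha_mN >= 0, beta > 0, ell0)",
         call. = FALSE)
  }
  p
}

#' Active-force scale at a given preload
#'
#' Monotone map from preload (% of L_MAX, on 75-100%) to the active-force
#' scale, equal to 1 at 100% L_MAX by the definition of L_MAX.
#'
#' @param params A [muscle_params()] object.
#' @param preload_pct Preload as % of L_MAX (vectorized, 75-100).
#' @return Dimensionless scale in `[min_scale, 1]`.
#' @export
fl_active_scale <- function(params, preload_pct) {
  if (any(preload_pct < 75 - 1e-9 | preload_pct > 100 + 1e-9)) {
    stop("preload must lie within 75-100% L_MAX", call. = FALSE)
  }
  fa <- params$fl_active
  fa$min_scale + (1 - fa$min_scale) * pmin(pmax((preload_pct - 75) / 25, 0), 1)^fa$gamma
}

#' Passive force at a given length
#'
#' Exponential resting tension-length map
#' `P = alpha * (exp(beta * (L/L_max - ell0)) - 1)`, clipped at zero below
#' the zero-tension length fraction `ell0`.
#'
#' @param params A [muscle_params()] object.
#' @param length_um Absolute muscle length (um, vectorized).
#' @return Passive force in mN.
#' @export
fl_passive_force <- function(params, length_um) {
  fp <- params$fl_passive
  rel <- length_um / params$l_max_um - fp$ell0
  pmax(fp$alpha_mN * (exp(fp$beta * rel) - 1), 0)
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf("<muscle_params> group=%s  L_max=%.0f um  d=%.0f um\n",
              x$group_label, x$l_max_um, x$diameter_um))
  cat(sprintf("  CaT: tau_rise=%.2f ms  tau_decay=%.2f ms  dia=%.3f  amp=%.3f (F/F0)\n",
              x$tau_ca_rise, x$tau_ca_decay, x$ca_dia, x$ca_amp))
  cat(sprintf("  force: k_act=%.2f /s  k_rel=%.2f /s  hill n=%.2f  K=%.3f  F_ref=%.4f mN\n",
              x$k_act, x$k_rel, x$hill_n, x$hill_k, x$f_ref))
  cat(sprintf("  SFR: g_ca=%+.4f  g_sens=%+.4f  g_dia=%+.4f  tau=%.0f s\n",
              x$sfr_gain_ca, x$sfr_gain_sens, x$sfr_dia_gain, x$sfr_tau))
  cat(sprintf("  PRP: load gain=%.4f  tau=%.0f s  recirc=%.2f\n",
              x$prp_load_gain, x$prp_load_tau, x$prp_recirc))
  invisible(x)
}

#' Calibrated default parameter sets
#'
#' Returns the committed default `muscle_params` for the healthy (CONT) or
#' monocrotaline-treated (MCT) group. The kinetic constants, the effective
#' Hill cooperativity, and the slow-response gains were fixed once by
#' [calibrate_defaults()] against the reference endpoint table shipped with
#' the package (see [calibration_targets()]); geometry, noise levels and
#' variability coefficients are design choices documented in the methods
#' vignette.
#'
#' @param group `"CONT"` or `"MCT"`.
#' @return A [muscle_params()] object.
#' @export
default_params <- function(group = c("CONT", "MCT")) {
  group <- match.arg(group)
  if (group == "CONT") {
    muscle_params(
      group_label = "CONT",
      l_max_um = 2500, diameter_um = 250,
      tau_ca_rise  = 16.672010,
      tau_ca_decay = 81.981618,
      ca_dia = 1.0, ca_amp = 0.45,
      k_act = 175.177345, k_rel = 22.146354,
      hill_n = 13.451671, hill_k = 0.54,
      f_ref = 0.4908642,
      fl_active = list(min_scale = 0.35, gamma = 1),
      fl_passive = list(alpha_mN = 0.004698985, beta = 12, ell0 = 0.70),
      sfr_gain_ca = -0.09534820, sfr_gain_sens = 0.09416116,
      sfr_tau = 40, sfr_dia_gain = 0.01,
      prp_load_gain = 0.20565676, prp_load_tau = 25, prp_recirc = 0.75
    )
  } else {
    muscle_params(
      group_label = "MCT",
      l_max_um = 2500, diameter_um = 280,
      tau_ca_rise  = 34.412900,
      tau_ca_decay = 68.263475,
      ca_dia = 1.0, ca_amp = 0.45,
      k_act = 2460.876841, k_rel = 26.929125,
      hill_n = 27.620099, hill_k = 0.54,
      f_ref = 0.6156915,
      fl_active = list(min_scale = 0.35, gamma = 1),
      fl_passive = list(alpha_mN = 0.005894407, beta = 12, ell0 = 0.70),
      sfr_gain_ca = 0.04363187, sfr_gain_sens = -0.04763272,
      sfr_tau = 40, sfr_dia_gain = 0.01,
      prp_load_gain = 0.10447803, prp_load_tau = 25, prp_recirc = 0.75
    )
  }
}
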
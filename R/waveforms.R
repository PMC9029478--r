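#' Closed-form peak time of the two-exponential Ca transient
#'
#' The within-beat Ca transient is modeled as
#' `dia + A * (exp(-t/tau_d) - exp(-t/tau_r))`; its peak above baseline
#' occurs at `t* = tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @param tau_rise,tau_decay Rise and decay time constants (any common unit);
#'   `tau_rise < tau_decay`.
#' @return Peak time in the same unit as the inputs.
#' @export
cat_peak_time <- function(tau_rise, tau_decay) {
  if (any(tau_rise <= 0) || any(tau_decay <= 0) || any(tau_rise >= tau_decay)) {
    stop("need 0 < tau_rise < tau_decay", call. = FALSE)
  }
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' Simulate one Ca-transient beat
#'
#' Deterministic two-exponential Ca transient for one inter-stimulus
#' interval, in F/F0 units. The waveform is
#' `ca_dia * dia_mult + A * (exp(-t/tau_d) - exp(-t/tau_r))` with `A` scaled
#' so that the peak above baseline equals `ca_amp * amp_mult`.
#'
#' @param params A [muscle_params()] object.
#' @param beat_env Per-beat multipliers: list with `amp_mult` (>= 0; 0 gives
#'   a flat trace at the diastolic level) and `dia_mult` (> 0).
#' @param t_grid Time samples within the beat (s), starting at the stimulus.
#' @return Numeric vector of F/F0 values on `t_grid`.
#' @export
simulate_cat_beat <- function(params,
                              beat_env = list(amp_mult = 1, dia_mult = 1),
                              t_grid) {
  amp_mult <- beat_env$amp_mult %||% 1
  dia_mult <- beat_env$dia_mult %||% 1
  if (amp_mult < 0 || dia_mult <= 0) {
    stop("beat multipliers must be positive (amp_mult may be zero)",
         call. = FALSE)
  }
  tr <- params$tau_ca_rise / 1000   # s
  td <- params$tau_ca_decay / 1000
  base <- params$ca_dia * dia_mult
  if (amp_mult == 0) return(rep(base, length(t_grid)))
  tstar <- cat_peak_time(tr, td)
  gpk <- exp(-tstar / td) - exp(-tstar / tr)
  a <- params$ca_amp * amp_mult / gpk
  base + a * (exp(-t_grid / td) - exp(-t_grid / tr))
}

## Hill coupling from Ca (F/F0 above the resting diastolic level) to the
## activation drive, with sensitivity expressed as a divisor of hill_k.
hill_activation <- function(params, ca, sens_mult = 1) {
  k_eff <- params$hill_k / sens_mult
  x <- pmax(ca - params$ca_dia, 0) / k_eff
  xn <- x^params$hill_n
  xn / (1 + xn)
}

#' Simulate one isometric force beat
#'
#' Integrates the first-order activation ODE
#' `dA/dt = k_act * H(Ca) * (1 - A) - k_rel * A`, where `H` is a Hill
#' function of the Ca level above the resting diastolic level with
#' half-activation constant `hill_k / sens_mult`, and returns total force
#' `fl_active(preload) * f_ref * A + fl_passive(preload)`. Integration uses
#' an exponential (exactly A-stable) one-step scheme on the sampling grid.
#'
#' @param params A [muscle_params()] object.
#' @param ca_waveform Ca trace on `t_grid` (F/F0), e.g. from
#'   [simulate_cat_beat()].
#' @param sens_mult Myofilament sensitivity multiplier (> 0).
#' @param preload_pct Preload as % of L_MAX (75-100).
#' @param t_grid Time samples (s), uniformly spaced.
#' @param a_init Initial activation state (default 0; the twitch relaxes
#'   back to within 1% of the passive level before the next stimulus at the
#'   default 2 Hz pacing).
#' @return Numeric vector of total force (mN) on `t_grid`.
#' @export
simulate_force_beat <- function(params, ca_waveform, sens_mult = 1,
                                preload_pct = 95, t_grid, a_init = 0) {
  if (sens_mult <= 0) stop("`sens_mult` must be positive", call. = FALSE)
  if (length(ca_waveform) != length(t_grid)) {
    stop("`ca_waveform` and `t_grid` lengths differ", call. = FALSE)
  }
  dt <- t_grid[2L] - t_grid[1L]
  h <- hill_activation(params, ca_waveform, sens_mult)
  a_drive <- params$k_act * h
  ## midpoint-averaged drive per step; the exponential step is A-stable, so
  ## the guard below is about resolving the drive's time course, not blow-up
  n <- length(a_drive)
  a_mid <- c((a_drive[-n] + a_drive[-1L]) / 2, a_drive[n])
  r <- a_mid + params$k_rel
  if (max(r) * dt > 1.5) {
    stop("time grid too coarse for the activation rates ",
         "(max rate * dt > 1.5); increase the sampling rate", call. = FALSE)
  }
  act <- force_ode_states(a_mid, r, dt, a_init)
  scale <- fl_active_scale(params, preload_pct) * params$f_ref
  L <- preload_pct / 100 * params$l_max_um
  scale * act + fl_passive_force(params, L)
}

## Exponential-integrator recursion for the activation states. Kept as a
## plain loop: the recursion coefficients vary with time so it cannot be
## expressed as a fixed-coefficient filter.
force_ode_states <- function(a_drive, r, dt, a_init = 0) {
  n <- length(a_drive)
  e <- exp(-r * dt)
  gain <- a_drive / r * (1 - e)
  act <- numeric(n)
  a <- a_init
  for (i in seq_len(n)) {
    act[i] <- a
    a <- a * e[i] + gain[i]
  }
  act
}
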
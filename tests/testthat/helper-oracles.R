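# Independent oracles used across the suite.

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(nx+ny, nx) rank assignments (no ties assumed).
enum_mwu_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Continuous two-exponential waveform and its timing descriptors evaluated
# on a very fine grid (reference for the sampled extraction path).
twoexp_curve <- function(tau_r, tau_d, t) exp(-t / tau_d) - exp(-t / tau_r)

twoexp_t50_oracle <- function(tau_r, tau_d, oversample_ms = 1e-3) {
  t <- seq(0, 20 * tau_d, by = oversample_ms)   # ms grid, 100x+ oversampled
  y <- twoexp_curve(tau_r, tau_d, t)
  ipk <- which.max(y)
  half <- y[ipk] / 2
  j <- which(y[ipk:length(y)] <= half)[1L]
  (j - 1L) * oversample_ms
}

# Build a beat_window directly from channel vectors (bypassing the
# recording layer) for waveform-level extraction tests.
make_beat <- function(force, ca = force, fs = 1000, pre_n = 50,
                      preload = 95) {
  n <- length(force)
  structure(
    list(stimulus_time = 1.0,
         t = (seq_len(n) - pre_n - 1L) / fs,
         force = force,
         ca = ca,
         preload_pct = preload,
         tags = character(0),
         fs = fs,
         index = 1L),
    class = "beat_window")
}

# Synthetic paced recording with a prescribed per-beat amplitude envelope
# on both channels; used to feed the protocol analyses known arithmetic.
synth_recording <- function(amps, protocol = c("SFR", "PRP"),
                            fs = 1000, rest_s = 10, pre_beats = 12) {
  protocol <- match.arg(protocol)
  shape <- function(tg) twoexp_curve(0.02, 0.08, tg) / 0.4724928
  beat_len <- round(0.5 * fs)
  tg <- (seq_len(beat_len) - 1L) / fs
  one_beat <- shape(tg)
  if (protocol == "SFR") {
    pre <- rep(1, pre_beats)
    stim <- 0.25 + 0.5 * (seq_len(pre_beats + length(amps)) - 1L)
    stretch_start <- 0.25 + 0.5 * pre_beats - 0.20
    events <- data.frame(
      time_s = c(0, stretch_start, stretch_start + 0.1),
      type = c("preload_change", "stretch_start", "stretch_end"),
      value = c(85, NA, 95))
    all_amps <- c(pre, amps)
  } else {
    stim_pre <- 0.25 + 0.5 * (seq_len(pre_beats) - 1L)
    rest_start <- 0.5 * pre_beats
    rest_end <- rest_start + rest_s
    stim_post <- rest_end + 0.25 + 0.5 * (seq_along(amps) - 1L)
    stim <- c(stim_pre, stim_post)
    events <- data.frame(
      time_s = c(0, rest_start, rest_end),
      type = c("preload_change", "rest_start", "rest_end"),
      value = c(95, NA, NA))
    all_amps <- c(rep(1, pre_beats), amps)
  }
  total_s <- max(stim) + 0.5
  n <- round(total_s * fs)
  force <- rep(0.05, n)      # constant resting level
  ca <- rep(1.0, n)
  for (b in seq_along(stim)) {
    i0 <- round(stim[b] * fs) + 1L
    idx <- i0:min(i0 + beat_len - 1L, n)
    force[idx] <- force[idx] + 0.1 * all_amps[b] * one_beat[seq_along(idx)]
    ca[idx] <- ca[idx] + 0.4 * all_amps[b] * one_beat[seq_along(idx)]
  }
  f380 <- rep(2, n)
  trace_recording(sampling_rate = fs, force = force,
                  length = rep(0.95 * 2500, n),
                  f340 = ca * 0.85 * 2, f380 = f380,
                  stimulus_times = stim, events = events,
                  f0_reference = 0.85,
                  meta = list(diameter_um = 250, l_max_um = 2500,
                              group_label = "CONT", protocol = protocol))
}
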
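#' Fura-2 ratiometric Ca trace
#'
#' Elementwise `(f340 / f380) / f0_reference`: the fluorescence ratio
#' normalized to the quiescent reference F0, giving the Ca transient in
#' F/F0 units.
#'
#' @param f340,f380 Fluorescence channels of equal length; `f380` must be
#'   positive everywhere.
#' @param f0_reference Quiescent non-stretched ratio F0 (> 0).
#' @return Numeric vector of F/F0 values.
#' @export
fura_ratio <- function(f340, f380, f0_reference) {
  if (length(f340) != length(f380)) {
    stop("f340 and f380 must have equal length", call. = FALSE)
  }
  if (!is.numeric(f0_reference) || length(f0_reference) != 1L ||
      f0_reference <= 0) {
    stop("`f0_reference` must be a positive scalar", call. = FALSE)
  }
  if (any(f380 <= 0)) {
    stop("f380 contains non-positive samples; ratio undefined", call. = FALSE)
  }
  (f340 / f380) / f0_reference
}

#' Cross-sectional area of a muscle strip
#'
#' Elliptic approximation `S = pi * d^2 / 12` with `d` the larger transversal
#' width in micrometers; returned in mm^2.
#'
#' @param d Larger transversal width (um, > 0).
#' @return Cross-section in mm^2.
#' @export
cross_section <- function(d) {
  if (any(d <= 0)) stop("`d` must be positive", call. = FALSE)
  pi * d^2 / 12 * 1e-6
}

#' Muscle geometry
#'
#' @param diameter_um Larger transversal width of the strip (um).
#' @return List with `diameter_um` and `cross_section_mm2`
#'   (class `muscle_geometry`).
#' @export
muscle_geometry <- function(diameter_um) {
  structure(list(diameter_um = diameter_um,
                 cross_section_mm2 = cross_section(diameter_um)),
            class = "muscle_geometry")
}

#' Cut a recording into stimulus-aligned beat windows
#'
#' One window per stimulus, spanning `pre_window_ms` before the stimulus up
#' to the next stimulus (capped at one pacing period). Beats whose window
#' contains a protocol event (stretch, rest boundary, preload change) are
#' tagged with the event type so protocol analyses can exclude them; each
#' beat also carries the preload in force at its stimulus (from the last
#' preceding `preload_change` event).
#'
#' @param recording A [trace_recording()].
#' @param pre_window_ms Baseline window before the stimulus (ms, default 50).
#' @return List of `beat_window` objects (class `beat_windows`). Each window
#'   has fields `stimulus_time`, `t` (s, relative to the stimulus), `force`
#'   (mN), `ca` (F/F0), `preload_pct`, `tags`, `fs`, `index`.
#' @export
segment_beats <- function(recording, pre_window_ms = 50) {
  stopifnot(inherits(recording, "trace_recording"))
  stim <- recording$stimulus_times
  if (length(stim) < 1L) stop("no stimulus annotations", call. = FALSE)
  if (length(stim) > 1L && any(diff(stim) < 0.010)) {
    stop("overlapping stimuli (< 10 ms apart)", call. = FALSE)
  }
  fs <- recording$sampling_rate
  n <- nrow(recording$channels)
  ca_full <- fura_ratio(recording$channels$f340, recording$channels$f380,
                        recording$f0_reference)
  force_full <- recording$channels$force_mN
  pre_n <- round(pre_window_ms / 1000 * fs)

  ev <- recording$events
  pc <- ev[ev$type == "preload_change", , drop = FALSE]

  nxt <- c(stim[-1L], Inf)
  win_end <- pmin(nxt, stim + PACING_PERIOD_S)

  beats <- vector("list", length(stim))
  for (b in seq_along(stim)) {
    i_stim <- round(stim[b] * fs) + 1L
    i0 <- max(i_stim - pre_n, 1L)
    i1 <- min(round(win_end[b] * fs), n)
    if (i1 <= i_stim) next
    idx <- i0:i1
    in_win <- ev$time_s >= stim[b] & ev$time_s < win_end[b]
    tags <- unique(ev$type[in_win])
    preload <- if (nrow(pc) > 0) {
      j <- findInterval(stim[b], pc$time_s)
      if (j >= 1L) pc$value[j] else NA_real_
    } else NA_real_
    beats[[b]] <- structure(
      list(stimulus_time = stim[b],
           t = (idx - i_stim) / fs,
           force = force_full[idx],
           ca = ca_full[idx],
           preload_pct = preload,
           tags = tags,
           fs = fs,
           index = b),
      class = "beat_window")
  }
  beats <- beats[!vapply(beats, is.null, logical(1))]
  structure(beats, class = "beat_windows")
}

#' @export
print.beat_windows <- function(x, ...) {
  cat(sprintf("<beat_windows> %d beats", length(x)))
  tagged <- sum(vapply(x, function(b) length(b$tags) > 0, logical(1)))
  cat(sprintf(" (%d tagged with events)\n", tagged))
  invisible(x)
}

## Shared scalar-descriptor extraction for a single waveform within a beat
## window. Timing in ms, normalized rates in 1/s. The peak, amplitude and
## timing features are measured on the raw samples; only the derivative
## features use a centered moving-average smoothed copy of the trace.
extract_waveform_features <- function(t, y, fs, smooth_ms = 3,
                                      degenerate_k = 3) {
  pre <- t < 0
  post <- !pre
  if (!any(pre) || sum(post) < 5L) {
    stop("beat window lacks a baseline or post-stimulus samples",
         call. = FALSE)
  }
  baseline <- mean(y[pre])
  noise_sd <- stats::sd(y[pre])
  ypost <- y[post]
  tpost <- t[post]
  ipk <- which.max(ypost)
  peak <- ypost[ipk]
  amplitude <- peak - baseline
  thr <- max(degenerate_k * noise_sd, 1e-12, na.rm = TRUE)
  if (!is.finite(amplitude) || amplitude <= thr) {
    return(list(baseline = baseline, peak = peak, amplitude = amplitude,
                ttp_ms = NA_real_, t50_ms = NA_real_,
                max_norm_rise = NA_real_, max_norm_decline = NA_real_,
                degenerate = TRUE))
  }
  ttp_ms <- tpost[ipk] * 1000

  ## half-amplitude crossing after the peak, linearly interpolated
  target <- baseline + amplitude / 2
  after <- ypost[ipk:length(ypost)]
  j <- which(after <= target)[1L]
  t50_ms <- if (is.na(j) || j == 1L) NA_real_ else {
    y1 <- after[j - 1L]; y2 <- after[j]
    frac <- (y1 - target) / (y1 - y2)
    ((ipk + j - 2L + frac) - ipk) / fs * 1000
  }

  sm <- moving_average(y, round(smooth_ms / 1000 * fs))
  d <- central_diff(sm, 1 / fs)[post]
  list(baseline = baseline, peak = peak, amplitude = amplitude,
       ttp_ms = ttp_ms, t50_ms = t50_ms,
       max_norm_rise = max(d) / amplitude,
       max_norm_decline = max(-d) / amplitude,
       degenerate = FALSE)
}

#' Per-twitch mechanical descriptors
#'
#' Extracts the isometric-twitch characteristics from one beat window:
#' passive (resting) level from the pre-stimulus baseline, peak total level,
#' active amplitude, time-to-peak from the stimulus, relaxation time from
#' the peak to 50% of the active amplitude (T50, linear interpolation
#' between the bracketing samples), and maximal normalized rates of rise and
#' decline (max |dF/dt| divided by the active amplitude, on a trace smoothed
#' with a centered moving average before differentiation). When `geometry`
#' is supplied, force levels are converted to tension (mN/mm^2) by the
#' strip's cross-section; otherwise they stay in mN. A twitch whose
#' amplitude is below `degenerate_k` times the baseline noise SD is flagged
#' degenerate and its features are `NA`.
#'
#' @param beat A `beat_window` from [segment_beats()].
#' @param geometry Optional [muscle_geometry()].
#' @param smooth_ms Moving-average width used before differentiation (ms).
#' @param degenerate_k Noise-floor multiple for the degenerate-twitch flag.
#' @return One-row data.frame (class `twitch_features`).
#' @export
extract_twitch <- function(beat, geometry = NULL, smooth_ms = 3,
                           degenerate_k = 3) {
  stopifnot(inherits(beat, "beat_window"))
  f <- extract_waveform_features(beat$t, beat$force, beat$fs,
                                 smooth_ms, degenerate_k)
  s <- if (is.null(geometry)) 1 else geometry$cross_section_mm2
  out <- data.frame(
    passive_tension = f$baseline / s,
    peak_total_tension = f$peak / s,
    active_amplitude = f$amplitude / s,
    ttp_ms = f$ttp_ms,
    t50_relax_ms = f$t50_ms,
    max_norm_rise = f$max_norm_rise,
    max_norm_decline = f$max_norm_decline,
    degenerate = f$degenerate
  )
  attr(out, "units") <- if (is.null(geometry)) "mN" else "mN/mm^2"
  class(out) <- c("twitch_features", class(out))
  out
}

#' Per-beat Ca-transient descriptors
#'
#' Same conventions as [extract_twitch()], applied to the F/F0 channel:
#' diastolic level from the pre-stimulus baseline, amplitude above it,
#' time-to-peak, decay time from the peak to 50% of the amplitude (T50) and
#' maximal normalized rates of rise and decay.
#'
#' @inheritParams extract_twitch
#' @return One-row data.frame (class `cat_features`).
#' @export
extract_cat <- function(beat, smooth_ms = 3, degenerate_k = 3) {
  stopifnot(inherits(beat, "beat_window"))
  f <- extract_waveform_features(beat$t, beat$ca, beat$fs,
                                 smooth_ms, degenerate_k)
  out <- data.frame(
    diastolic_level = f$baseline,
    amplitude = f$amplitude,
    ttp_ms = f$ttp_ms,
    t50_decay_ms = f$t50_ms,
    max_norm_rise = f$max_norm_rise,
    max_norm_decay = f$max_norm_decline,
    degenerate = f$degenerate
  )
  class(out) <- c("cat_features", class(out))
  out
}

#' Stimulus-aligned ensemble average of beats
#'
#' Pointwise mean of ~30 consecutive steady-state beats, used to improve the
#' signal-to-noise ratio before feature extraction. Beats are aligned on
#' their stimulus sample; the average is truncated to the shortest common
#' pre- and post-stimulus extent.
#'
#' @param beats A `beat_windows` list (or plain list of `beat_window`s) from
#'   one steady-state segment; mixing preloads is an error, fewer than 5
#'   beats a warning.
#' @return A single averaged `beat_window`.
#' @export
ensemble_average <- function(beats) {
  beats <- unclass(beats)
  if (length(beats) == 0L) stop("no beats to average", call. = FALSE)
  if (length(beats) < 5L) {
    warning("averaging fewer than 5 beats; poor noise suppression",
            call. = FALSE)
  }
  pl <- unique(vapply(beats, function(b) b$preload_pct, numeric(1)))
  if (length(pl[!is.na(pl)]) > 1L) {
    stop("cannot ensemble-average beats recorded at different preloads",
         call. = FALSE)
  }
  n_pre <- min(vapply(beats, function(b) sum(b$t < 0), integer(1)))
  n_post <- min(vapply(beats, function(b) sum(b$t >= 0), integer(1)))
  fs <- beats[[1L]]$fs
  acc_f <- 0; acc_c <- 0
  for (b in beats) {
    i_stim <- sum(b$t < 0) + 1L
    idx <- (i_stim - n_pre):(i_stim + n_post - 1L)
    acc_f <- acc_f + b$force[idx]
    acc_c <- acc_c + b$ca[idx]
  }
  structure(
    list(stimulus_time = beats[[1L]]$stimulus_time,
         t = ((-n_pre):(n_post - 1L)) / fs,
         force = acc_f / length(beats),
         ca = acc_c / length(beats),
         preload_pct = pl[1L],
         tags = "ensemble",
         fs = fs,
         index = beats[[1L]]$index),
    class = "beat_window")
}

#' Self-normalized beat
#'
#' Rescales each channel of a beat to `(trace - baseline) / amplitude`, so
#' the baseline maps to 0 and the peak to exactly 1 — the form used to
#' compare twitch and Ca-transient shapes across preloads and groups. The
#' operation is idempotent.
#'
#' @param beat A `beat_window`.
#' @return The beat with unitless normalized `force` and `ca` channels.
#' @export
self_normalize <- function(beat) {
  stopifnot(inherits(beat, "beat_window"))
  norm1 <- function(t, y, fs) {
    f <- extract_waveform_features(t, y, fs)
    if (f$degenerate) {
      stop("cannot self-normalize a degenerate beat", call. = FALSE)
    }
    (y - f$baseline) / f$amplitude
  }
  beat$force <- norm1(beat$t, beat$force, beat$fs)
  beat$ca <- norm1(beat$t, beat$ca, beat$fs)
  beat
}

#' Tidy per-beat feature table
#'
#' Runs [extract_twitch()] and [extract_cat()] over a set of beat windows
#' and returns one row per beat with the beat index, stimulus time, preload
#' and tags alongside the force (`force_` prefix) and Ca-transient (`cat_`
#' prefix) features.
#'
#' @param beats A `beat_windows` list.
#' @param geometry Optional [muscle_geometry()] for tension units.
#' @param ... Passed on to the extractors.
#' @return A data.frame, one row per beat.
#' @export
beat_features <- function(beats, geometry = NULL, ...) {
  rows <- lapply(unclass(beats), function(b) {
    tw <- extract_twitch(b, geometry, ...)
    ca <- extract_cat(b, ...)
    names(tw) <- paste0("force_", names(tw))
    names(ca) <- paste0("cat_", names(ca))
    cbind(data.frame(beat = b$index, stimulus_time = b$stimulus_time,
                     preload_pct = b$preload_pct,
                     tagged = length(b$tags) > 0),
          as.data.frame(tw), as.data.frame(ca))
  })
  do.call(rbind, rows)
}
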
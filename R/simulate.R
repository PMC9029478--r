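#' Protocol specifications
#'
#' Constructors for the three experimental protocols the simulator and the
#' analysis functions understand. All protocols pace at 2 Hz.
#'
#' * `fl_protocol()`: isometric force-length run — the strip is held at each
#'   preload of `grid` (% of L_MAX) in turn for `beats_per_preload` beats.
#' * `sfr_protocol()`: slow-force-response run — `pre_s` seconds at
#'   `from_pct`, a rapid ramp stretch (duration `ramp_ms`) to `to_pct`, then
#'   `post_s` seconds of twitch-by-twitch recording.
#' * `prp_protocol()`: post-rest-potentiation run — `pre_s` seconds of paced
#'   beats at `preload_pct`, a stimulation pause of `rest_s` seconds, then
#'   `post_s` seconds of paced beats.
#'
#' @param grid Preload grid, a subset of `c(75, 80, 85, 90, 95, 100)`.
#' @param beats_per_preload Beats recorded at each preload.
#' @param from_pct,to_pct Preload before and after the rapid stretch (% L_MAX).
#' @param ramp_ms Stretch ramp duration (ms).
#' @param pre_s,post_s Durations of the segments before/after the
#'   stretch or pause (s).
#' @param rest_s Pause duration (s); 0 gives an uninterrupted run.
#' @param preload_pct Preload for the post-rest protocol (% L_MAX).
#' @return A protocol specification (classed list) for [simulate_protocol()].
#' @name protocol_spec
NULL

#' @rdname protocol_spec
#' @export
fl_protocol <- function(grid = c(75, 80, 85, 90, 95, 100),
                        beats_per_preload = 35) {
  allowed <- c(75, 80, 85, 90, 95, 100)
  if (!all(grid %in% allowed)) {
    stop("FL preload grid must be a subset of {75,80,85,90,95,100}% L_MAX",
         call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) grid <- sort(unique(grid))
  structure(list(type = "FL", grid = grid,
                 beats_per_preload = as.integer(beats_per_preload)),
            class = "protocol_spec")
}

#' @rdname protocol_spec
#' @export
sfr_protocol <- function(from_pct = 85, to_pct = 95, ramp_ms = 100,
                         pre_s = 10, post_s = 180) {
  if (from_pct < 75 || to_pct > 100 || from_pct >= to_pct) {
    stop("SFR stretch must go upward within 75-100% L_MAX", call. = FALSE)
  }
  structure(list(type = "SFR", from_pct = from_pct, to_pct = to_pct,
                 ramp_ms = ramp_ms, pre_s = pre_s, post_s = post_s),
            class = "protocol_spec")
}

#' @rdname protocol_spec
#' @export
prp_protocol <- function(rest_s = 60, preload_pct = 95,
                         pre_s = 15, post_s = 30) {
  if (rest_s < 0) stop("`rest_s` must be >= 0", call. = FALSE)
  if (preload_pct < 75 || preload_pct > 100) {
    stop("preload must lie within 75-100% L_MAX", call. = FALSE)
  }
  structure(list(type = "PRP", rest_s = rest_s, preload_pct = preload_pct,
                 pre_s = pre_s, post_s = post_s),
            class = "protocol_spec")
}

PACING_PERIOD_S <- 0.5  # 2 Hz pacing throughout

#' Simulate a full protocol recording
#'
#' Forward model for one muscle strip: generates the synchronized force,
#' length and fluorescence channels for a force-length, slow-force-response
#' (SFR) or post-rest-potentiation (PRP) run, with stimulus and event
#' annotations sufficient for blind re-analysis by [segment_beats()] and the
#' `analyze_*` functions.
#'
#' Slow dynamics are imposed as per-beat envelope multipliers on the beat
#' generator ([simulate_cat_beat()] / [simulate_force_beat()]):
#' * SFR (time `t` from the end of the stretch ramp):
#'   `amp_mult = 1 + sfr_gain_ca  * (1 - exp(-t/sfr_tau))`,
#'   `sens_mult = 1 + sfr_gain_sens * (1 - exp(-t/sfr_tau))`,
#'   `dia_mult = 1 + sfr_dia_gain * (1 - exp(-t/sfr_tau))`.
#' * PRP (post-pause beat index `k` = 0, 1, ...): the first-beat Ca amplitude
#'   multiplier is `M0 = 1 + prp_load_gain * (1 - exp(-rest_s/prp_load_tau))`
#'   and subsequent beats return geometrically,
#'   `amp_mult_k = 1 + (M0 - 1) * prp_recirc^k`; the diastolic envelope dips
#'   below 1 for the first three beats and then recovers above it.
#'
#' @param params A [muscle_params()] object.
#' @param protocol_spec A specification from [fl_protocol()],
#'   [sfr_protocol()] or [prp_protocol()].
#' @param seed Integer seed for the measurement noise; mandatory when either
#'   noise SD in `params` is positive. Identical (params, protocol, seed)
#'   yield bit-identical recordings.
#' @param fs Sampling rate (Hz), default 1000; configurable up to
#'   acquisition-grade 10 kHz.
#' @param f0_reference Quiescent fluorescence ratio F0 used to construct the
#'   fluorescence channels.
#' @param f380_base Baseline level of the F380 channel (arbitrary units).
#' @return A [trace_recording()].
#' @export
simulate_protocol <- function(params, protocol_spec, seed = NULL, fs = 1000,
                              f0_reference = 0.85, f380_base = 2.0) {
  if (!inherits(params, "muscle_params")) {
    stop("`params` must be a muscle_params object", call. = FALSE)
  }
  if (!inherits(protocol_spec, "protocol_spec") ||
      !protocol_spec$type %in% c("FL", "SFR", "PRP")) {
    stop("unknown protocol specification", call. = FALSE)
  }
  if (is.null(seed) &&
      (params$noise_sd_force > 0 || params$noise_sd_fluor > 0)) {
    stop("`seed` is required when measurement noise is enabled", call. = FALSE)
  }
  tl <- switch(protocol_spec$type,
               FL = timeline_fl(params, protocol_spec),
               SFR = timeline_sfr(params, protocol_spec),
               PRP = timeline_prp(params, protocol_spec))
  n <- round(tl$total_s * fs)
  time <- (seq_len(n) - 1L) / fs
  dt <- 1 / fs

  ## length channel and per-sample passive force
  length_um <- tl$length_fun(time) * params$l_max_um / 100
  force <- fl_passive_force(params, length_um)

  ## diastolic Ca envelope interpolated across beats
  beats <- tl$beats
  dia_env <- if (nrow(beats) > 0) {
    approx(beats$stim, beats$dia_mult, xout = time, rule = 2)$y
  } else rep(1, n)
  ca <- params$ca_dia * dia_env

  ## add each beat's transient and active force; identical beats are cached
  cache <- new.env(parent = emptyenv())
  for (b in seq_len(nrow(beats))) {
    i0 <- round(beats$stim[b] * fs) + 1L
    i1 <- min(round(beats$win_end[b] * fs), n)
    if (i1 < i0) next
    m <- i1 - i0 + 1L
    key <- paste(beats$amp_mult[b], beats$dia_mult[b], beats$sens_mult[b],
                 beats$preload[b], m, sep = "|")
    parts <- cache[[key]]
    if (is.null(parts)) {
      tg <- (seq_len(m) - 1L) * dt
      env <- list(amp_mult = beats$amp_mult[b], dia_mult = beats$dia_mult[b])
      cab <- simulate_cat_beat(params, env, tg)
      ftot <- simulate_force_beat(params, cab, beats$sens_mult[b],
                                  beats$preload[b], tg)
      L <- beats$preload[b] / 100 * params$l_max_um
      parts <- list(ca_tr = cab - params$ca_dia * beats$dia_mult[b],
                    f_act = ftot - fl_passive_force(params, L))
      cache[[key]] <- parts
    }
    idx <- i0:i1
    ca[idx] <- ca[idx] + parts$ca_tr
    force[idx] <- force[idx] + parts$f_act
  }

  f380 <- rep(f380_base, n)
  f340 <- ca * f0_reference * f380_base
  if (params$noise_sd_force > 0 || params$noise_sd_fluor > 0) {
    noise <- with_seed(seed, list(
      f = rnorm(n, 0, params$noise_sd_force),
      a = rnorm(n, 0, params$noise_sd_fluor),
      b = rnorm(n, 0, params$noise_sd_fluor)
    ))
    force <- force + noise$f
    f340 <- f340 + noise$a
    f380 <- f380 + noise$b
  }

  trace_recording(
    sampling_rate = fs,
    force = force, length = length_um, f340 = f340, f380 = f380,
    stimulus_times = beats$stim,
    events = tl$events,
    f0_reference = f0_reference,
    meta = list(group_label = params$group_label,
                diameter_um = params$diameter_um,
                l_max_um = params$l_max_um,
                protocol = protocol_spec$type,
                seed = seed)
  )
}

## --- timeline builders -----------------------------------------------------
## Each returns list(total_s, beats = data.frame(stim, win_end, preload,
## amp_mult, dia_mult, sens_mult), events, length_fun(time) -> % L_MAX).

paced_stimuli <- function(from_s, to_s) {
  ## stimuli at from_s + 0.25, 0.75, ... with a complete 0.5 s window
  first <- from_s + PACING_PERIOD_S / 2
  s <- seq(first, to_s, by = PACING_PERIOD_S)
  s[s + PACING_PERIOD_S <= to_s + 1e-9]
}

beat_frame <- function(stim, preload, amp = 1, dia = 1, sens = 1) {
  if (length(stim) == 0L) {
    return(data.frame(stim = numeric(0), win_end = numeric(0),
                      preload = numeric(0), amp_mult = numeric(0),
                      dia_mult = numeric(0), sens_mult = numeric(0)))
  }
  win_end <- c(stim[-1L], Inf)
  win_end <- pmin(win_end, stim + 1.5)  # let tails decay across a pause
  data.frame(stim = stim, win_end = win_end, preload = preload,
             amp_mult = amp, dia_mult = dia, sens_mult = sens)
}

timeline_fl <- function(params, spec) {
  seg_s <- spec$beats_per_preload * PACING_PERIOD_S
  total <- seg_s * length(spec$grid)
  starts <- (seq_along(spec$grid) - 1L) * seg_s
  stim <- unlist(lapply(starts, function(s0) paced_stimuli(s0, s0 + seg_s)))
  preload <- spec$grid[findInterval(stim, starts)]
  events <- data.frame(time_s = starts, type = "preload_change",
                       value = spec$grid, stringsAsFactors = FALSE)
  grid <- spec$grid
  length_fun <- function(time) grid[pmax(findInterval(time, starts), 1L)]
  list(total_s = total, beats = beat_frame(stim, preload),
       events = events, length_fun = length_fun)
}

timeline_sfr <- function(params, spec) {
  total <- spec$pre_s + spec$post_s + 0.5
  stim <- paced_stimuli(0, total)
  stretch_start <- spec$pre_s + 0.05
  stretch_end <- stretch_start + spec$ramp_ms / 1000
  preload <- ifelse(stim < stretch_start, spec$from_pct, spec$to_pct)
  post <- stim >= stretch_end
  t_env <- pmax(stim - stretch_end, 0)
  w <- (1 - exp(-t_env / params$sfr_tau)) * post
  beats <- beat_frame(stim, preload,
                      amp = 1 + params$sfr_gain_ca * w,
                      dia = 1 + params$sfr_dia_gain * w,
                      sens = 1 + params$sfr_gain_sens * w)
  events <- data.frame(
    time_s = c(0, stretch_start, stretch_end),
    type = c("preload_change", "stretch_start", "stretch_end"),
    value = c(spec$from_pct, NA, spec$to_pct), stringsAsFactors = FALSE)
  from <- spec$from_pct; to <- spec$to_pct
  length_fun <- function(time) {
    frac <- pmin(pmax((time - stretch_start) / (stretch_end - stretch_start), 0), 1)
    from + (to - from) * frac
  }
  list(total_s = total, beats = beats, events = events,
       length_fun = length_fun)
}

timeline_prp <- function(params, spec) {
  total <- spec$pre_s + spec$rest_s + spec$post_s
  rest_start <- spec$pre_s
  rest_end <- spec$pre_s + spec$rest_s
  if (spec$rest_s > 0) {
    stim_pre <- paced_stimuli(0, rest_start)
    stim_post <- paced_stimuli(rest_end, total)
  } else {
    ## no pause: one uninterrupted 2 Hz train, split at the nominal boundary
    stim <- paced_stimuli(0, total)
    stim_pre <- stim[stim < rest_end]
    stim_post <- stim[stim >= rest_end]
  }
  k <- seq_along(stim_post) - 1L
  if (spec$rest_s > 0) {
    m0 <- 1 + params$prp_load_gain * (1 - exp(-spec$rest_s / params$prp_load_tau))
    amp_post <- 1 + (m0 - 1) * params$prp_recirc^k
    dia_post <- ifelse(
      k < 3, 1 - params$prp_dia_dip,
      1 + params$prp_dia_rise - (params$prp_dia_rise + params$prp_dia_dip) *
        exp(-(k - 3) / params$prp_dia_tau_beats))
  } else {
    amp_post <- rep(1, length(k))
    dia_post <- rep(1, length(k))
  }
  beats <- rbind(
    beat_frame(stim_pre, spec$preload_pct),
    beat_frame(stim_post, spec$preload_pct, amp = amp_post, dia = dia_post)
  )
  ## pre-pause tail may extend into the rest period; cap handled by win_end
  if (length(stim_pre) > 0) {
    beats$win_end[length(stim_pre)] <-
      min(stim_pre[length(stim_pre)] + 1.5,
          if (length(stim_post) > 0) stim_post[1L] else total)
  }
  events <- data.frame(
    time_s = c(0, rest_start, rest_end),
    type = c("preload_change", "rest_start", "rest_end"),
    value = c(spec$preload_pct, NA, NA), stringsAsFactors = FALSE)
  pl <- spec$preload_pct
  list(total_s = total, beats = beats, events = events,
       length_fun = function(time) rep(pl, length(time)))
}
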
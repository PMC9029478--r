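#' Locate L_MAX from a stepwise stretch series
#'
#' Given active twitch amplitudes measured while a strip is stretched in
#' small (typically 50 um) steps, returns the length of maximal active
#' amplitude. If the amplitude is still rising at the last step the maximum
#' is not interior and the result is flagged as not reached.
#'
#' @param steps Data frame with columns `length_um` (strictly increasing) and
#'   `active_amplitude`; at least 3 steps.
#' @return List with `l_max_um`, `index`, and `reached` (logical; `FALSE`
#'   when the maximum sits on the last step).
#' @export
find_lmax <- function(steps) {
  if (!is.data.frame(steps) ||
      !all(c("length_um", "active_amplitude") %in% names(steps))) {
    stop("`steps` needs columns length_um and active_amplitude", call. = FALSE)
  }
  if (nrow(steps) < 3L) stop("need at least 3 stretch steps", call. = FALSE)
  if (is.unsorted(steps$length_um, strictly = TRUE)) {
    stop("lengths must be strictly increasing", call. = FALSE)
  }
  i <- which.max(steps$active_amplitude)
  reached <- i < nrow(steps)
  if (!reached) {
    warning("active amplitude still rising at the last step; ",
            "L_MAX not reached", call. = FALSE)
  }
  list(l_max_um = steps$length_um[i], index = i, reached = reached)
}

## beats without event tags
untagged <- function(beats) {
  Filter(function(b) length(b$tags) == 0L, unclass(beats))
}

#' Analyze a force-length recording
#'
#' For each preload segment: drops the equilibration beats right after the
#' preload change and any beats whose amplitude is still drifting (linear
#' drift over a trailing 10-beat window above `drift_tol_pct`), ensemble-
#' averages up to `n_avg` steady beats, and extracts twitch and Ca-transient
#' features. Tension values are normalized by the strip cross-section.
#'
#' @param recording A [trace_recording()] with `preload_change` events.
#' @param geometry [muscle_geometry()]; defaults to the diameter stored in
#'   the recording metadata.
#' @param n_avg Beats per ensemble average (default 30).
#' @param equil_beats Beats discarded after each preload change.
#' @param drift_tol_pct Allowed amplitude drift in % per 10 beats.
#' @param ... Passed to the feature extractors.
#' @return An `fl_result`: list with `features` (one row per preload: force
#'   features prefixed `force_`, Ca features prefixed `cat_`), `grid`, and
#'   `geometry`.
#' @export
analyze_fl <- function(recording, geometry = NULL, n_avg = 30,
                       equil_beats = 5, drift_tol_pct = 2, ...) {
  if (is.null(geometry)) {
    d <- recording$meta$diameter_um
    if (is.null(d)) stop("missing geometry (strip diameter)", call. = FALSE)
    geometry <- muscle_geometry(d)
  }
  beats <- untagged(segment_beats(recording))
  pls <- vapply(beats, function(b) b$preload_pct, numeric(1))
  grid <- sort(unique(pls[!is.na(pls)]))
  if (length(grid) < 2L) stop("need at least 2 preloads", call. = FALSE)
  if (any(grid < 75 | grid > 100)) {
    stop("preload outside the 75-100% L_MAX range", call. = FALSE)
  }
  rows <- lapply(grid, function(pl) {
    seg <- beats[!is.na(pls) & pls == pl]
    if (length(seg) > equil_beats) seg <- seg[-seq_len(equil_beats)]
    seg <- drop_drifting(seg, drift_tol_pct)
    if (length(seg) < 5L) {
      stop(sprintf("fewer than 5 steady beats at %g%% L_MAX", pl),
           call. = FALSE)
    }
    seg <- seg[max(1L, length(seg) - n_avg + 1L):length(seg)]
    avg <- ensemble_average(seg)
    tw <- extract_twitch(avg, geometry, ...)
    ca <- extract_cat(avg, ...)
    names(tw) <- paste0("force_", names(tw))
    names(ca) <- paste0("cat_", names(ca))
    cbind(data.frame(preload_pct = pl, n_beats = length(seg)),
          as.data.frame(tw), as.data.frame(ca))
  })
  structure(list(features = do.call(rbind, rows), grid = grid,
                 geometry = geometry),
            class = "fl_result")
}

## Remove leading beats until the trailing amplitude drift (slope of a
## linear fit, expressed in % per 10 beats) is inside tolerance.
drop_drifting <- function(seg, drift_tol_pct) {
  amp_of <- function(b) {
    post <- b$t >= 0
    max(b$force[post]) - mean(b$force[b$t < 0])
  }
  amps <- vapply(seg, amp_of, numeric(1))
  while (length(amps) > 10L) {
    k <- seq_along(amps)
    fit <- stats::lm.fit(cbind(1, k), amps)
    drift <- fit$coefficients[2L] * 10 / mean(amps) * 100
    if (abs(drift) <= drift_tol_pct) break
    seg <- seg[-1L]
    amps <- amps[-1L]
  }
  seg
}

#' @export
print.fl_result <- function(x, ...) {
  cat("<fl_result> preload grid:", paste0(x$grid, "%"), "\n")
  print(x$features[, c("preload_pct", "force_active_amplitude",
                       "force_passive_tension", "force_ttp_ms",
                       "cat_amplitude", "cat_ttp_ms")], row.names = FALSE)
  invisible(x)
}

#' Analyze a slow-force-response recording
#'
#' Builds the per-twitch time courses of the slow force response: every
#' post-stretch beat's force amplitude, force time-to-peak, force T50,
#' Ca-transient diastolic level, amplitude and T50, expressed as a
#' percentage of the first twitch after the stretch. The SFR magnitude is
#' the mean force-amplitude percentage over the final `end_window` beats;
#' the Ca amplitude endpoint (`cat_end_pct`) is defined the same way.
#'
#' @param recording A [trace_recording()] with stretch events.
#' @param end_window Number of final beats defining "end of SFR" (default 10).
#' @param ... Passed to the feature extractors.
#' @return An `sfr_result`: list with `series` (data.frame: `beat`, `time_s`
#'   since stretch end, six `*_pct` columns), `sfr_magnitude`, `end_pct`
#'   (named vector for all six series) and `end_window`.
#' @export
analyze_sfr <- function(recording, end_window = 10, ...) {
  stretch_end <- event_time(recording, "stretch_end")
  if (is.null(stretch_end)) stop("no stretch event in recording", call. = FALSE)
  beats <- untagged(segment_beats(recording))
  post <- Filter(function(b) b$stimulus_time >= stretch_end, beats)
  if (length(post) == 0L) stop("no post-stretch beats", call. = FALSE)
  if (length(post) < end_window + 1L) {
    stop("too few post-stretch beats for the end-of-SFR window", call. = FALSE)
  }
  ft <- beat_features(post, geometry = NULL, ...)
  cols <- c(force_amp = "force_active_amplitude", force_ttp = "force_ttp_ms",
            force_t50 = "force_t50_relax_ms", cat_dia = "cat_diastolic_level",
            cat_amp = "cat_amplitude", cat_t50 = "cat_t50_decay_ms")
  series <- data.frame(beat = seq_len(nrow(ft)),
                       time_s = ft$stimulus_time - stretch_end)
  for (nm in names(cols)) {
    series[[paste0(nm, "_pct")]] <- 100 * ft[[cols[nm]]] / ft[[cols[nm]]][1L]
  }
  tail_idx <- (nrow(series) - end_window + 1L):nrow(series)
  end_pct <- vapply(paste0(names(cols), "_pct"),
                    function(cn) mean(series[[cn]][tail_idx], na.rm = TRUE),
                    numeric(1))
  structure(list(series = series,
                 sfr_magnitude = unname(end_pct["force_amp_pct"]),
                 cat_end_pct = unname(end_pct["cat_amp_pct"]),
                 end_pct = end_pct,
                 end_window = end_window),
            class = "sfr_result")
}

#' @export
print.sfr_result <- function(x, ...) {
  cat(sprintf("<sfr_result> %d post-stretch beats; SFR magnitude %.1f%% ",
              nrow(x$series), x$sfr_magnitude))
  cat(sprintf("(CaT amplitude endpoint %.1f%%)\n", x$cat_end_pct))
  invisible(x)
}

#' Analyze a post-rest-potentiation recording
#'
#' Uses the last complete pre-pause twitch as the reference and expresses
#' every post-pause beat's force amplitude, Ca diastolic level and Ca
#' amplitude as a percentage of it. The potentiation extent is the maximal
#' force-amplitude percentage over the first `search_beats` post-pause
#' beats (the first beats are the highest, but the search is robust to the
#' early diastolic dip); `cat_first_beat_pct` is the first post-pause beat's
#' Ca-transient amplitude percentage; `recovery_beats` counts beats until
#' the force amplitude first returns to within `recovery_tol_pct` of the
#' pre-pause level.
#'
#' @param recording A [trace_recording()] with rest events (>= 10 s rest).
#' @param search_beats Beats searched for the maximal effect (default 10).
#' @param recovery_tol_pct Recovery band around 100% (default 5).
#' @param ... Passed to the feature extractors.
#' @return A `prp_result`: list with `series`, `prp_extent`,
#'   `cat_first_beat_pct`, `recovery_beats` and `reference` (pre-pause
#'   feature row).
#' @export
analyze_prp <- function(recording, search_beats = 10, recovery_tol_pct = 5,
                        ...) {
  rest_start <- event_time(recording, "rest_start")
  rest_end <- event_time(recording, "rest_end")
  if (is.null(rest_start) || is.null(rest_end)) {
    stop("no rest event in recording", call. = FALSE)
  }
  rest_s <- rest_end - rest_start
  beats <- untagged(segment_beats(recording))
  pre <- Filter(function(b) {
    b$stimulus_time + PACING_PERIOD_S <= rest_start + 1e-9
  }, beats)
  post <- Filter(function(b) b$stimulus_time >= rest_end, beats)
  if (rest_s > 0 && (length(pre) < 10L || length(post) < 20L)) {
    stop("need >= 10 pre-pause and >= 20 post-pause beats", call. = FALSE)
  }
  ref_beat <- pre[[length(pre)]]
  ref <- cbind(extract_twitch(ref_beat, NULL, ...),
               extract_cat(ref_beat, ...))
  ft <- beat_features(post, geometry = NULL, ...)
  series <- data.frame(
    beat = seq_len(nrow(ft)),
    time_s = ft$stimulus_time - rest_end,
    force_amp_pct = 100 * ft$force_active_amplitude / ref$active_amplitude,
    cat_dia_pct = 100 * ft$cat_diastolic_level / ref$diastolic_level,
    cat_amp_pct = 100 * ft$cat_amplitude / ref$amplitude)
  k <- seq_len(min(search_beats, nrow(series)))
  extent <- max(series$force_amp_pct[k], na.rm = TRUE)
  rec_k <- which(abs(series$force_amp_pct - 100) <= recovery_tol_pct)[1L]
  structure(list(series = series,
                 prp_extent = extent,
                 cat_first_beat_pct = series$cat_amp_pct[1L],
                 recovery_beats = if (is.na(rec_k)) NA_integer_ else rec_k,
                 rest_s = rest_s,
                 reference = ref),
            class = "prp_result")
}

#' @export
print.prp_result <- function(x, ...) {
  cat(sprintf(
    "<prp_result> rest %.0f s; extent %.0f%% of pre-pause force, first-beat CaT %.1f%%\n",
    x$rest_s, x$prp_extent, x$cat_first_beat_pct))
  invisible(x)
}
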
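#' Construct a trace recording
#'
#' A `trace_recording` holds the synchronized sampled channels of one muscle
#' run (force, length, and the two fura-2 fluorescence channels), the
#' stimulus annotations, typed protocol event markers, the quiescent
#' fluorescence reference F0, and per-muscle metadata. Time is implied by
#' the sample index and the sampling rate.
#'
#' @param sampling_rate Sampling rate (Hz).
#' @param force Force channel (mN).
#' @param length Muscle length channel (um).
#' @param f340,f380 Fluorescence channels (arbitrary units); `f380` must be
#'   positive everywhere for the ratio to be well defined (a violation is
#'   reported with a warning at construction and an error at ratio time).
#' @param stimulus_times Strictly increasing stimulus times (s); spacing is
#'   0.5 s during paced segments (2 Hz pacing).
#' @param events Data frame with columns `time_s`, `type` (e.g.
#'   `"preload_change"`, `"stretch_start"`, `"stretch_end"`, `"rest_start"`,
#'   `"rest_end"`) and `value` (numeric; target preload in % L_MAX for
#'   `preload_change`, otherwise `NA`).
#' @param f0_reference Fluorescence ratio of the quiescent, non-stretched
#'   strip (F0), used to express Ca transients in F/F0 units.
#' @param meta Named list of metadata; recognized entries include
#'   `diameter_um`, `l_max_um`, `group_label`, `protocol`.
#' @return An object of class `trace_recording`.
#' @export
trace_recording <- function(sampling_rate, force, length, f340, f380,
                            stimulus_times, events = empty_events(),
                            f0_reference, meta = list()) {
  stopifnot_scalar_pos(sampling_rate, "sampling_rate")
  stopifnot_scalar_pos(f0_reference, "f0_reference")
  n <- base::length(force)
  if (base::length(length) != n || base::length(f340) != n ||
      base::length(f380) != n) {
    stop("all channels must have the same length", call. = FALSE)
  }
  if (is.unsorted(stimulus_times, strictly = TRUE)) {
    stop("`stimulus_times` must be strictly increasing", call. = FALSE)
  }
  if (any(f380 <= 0)) {
    warning("f380 contains non-positive samples; the fluorescence ratio ",
            "will not be computable", call. = FALSE)
  }
  if (!is.data.frame(events) ||
      !all(c("time_s", "type", "value") %in% names(events))) {
    stop("`events` must be a data.frame with columns time_s, type, value",
         call. = FALSE)
  }
  structure(
    list(sampling_rate = sampling_rate,
         channels = data.frame(force_mN = force, length_um = length,
                               f340 = f340, f380 = f380),
         stimulus_times = stimulus_times,
         events = events,
         f0_reference = f0_reference,
         meta = meta),
    class = "trace_recording"
  )
}

empty_events <- function() {
  data.frame(time_s = numeric(0), type = character(0), value = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.trace_recording <- function(x, ...) {
  n <- nrow(x$channels)
  cat(sprintf("<trace_recording> %d samples @ %g Hz (%.1f s), %d stimuli, %d events\n",
              n, x$sampling_rate, n / x$sampling_rate,
              length(x$stimulus_times), nrow(x$events)))
  if (!is.null(x$meta$group_label)) {
    cat(sprintf("  group=%s  diameter=%s um  protocol=%s\n",
                x$meta$group_label,
                format(x$meta$diameter_um %||% NA),
                x$meta$protocol %||% "?"))
  }
  invisible(x)
}

rec_time <- function(rec) {
  (seq_len(nrow(rec$channels)) - 1L) / rec$sampling_rate
}

event_time <- function(rec, type) {
  t <- rec$events$time_s[rec$events$type == type]
  if (length(t) == 0L) NULL else t[1L]
}
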
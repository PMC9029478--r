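#' Read and write trace recordings
#'
#' Recordings are stored as a CSV file with header columns `time_s`,
#' `force_mN`, `length_um`, `f340`, `f380` (values serialized with 9
#' significant digits) plus a YAML sidecar (same path with the `.csv`
#' extension replaced by `.meta.yaml`) holding `sampling_rate`,
#' `f0_reference`, the geometry and group metadata, `stimulus_times` and the
#' typed `events`. `write_recording()` followed by `read_recording()` (and
#' vice versa) is the identity up to float round-trip.
#'
#' @param recording A [trace_recording()].
#' @param path Path of the CSV file; the sidecar path is derived from it.
#' @return `read_recording()` returns a [trace_recording()];
#'   `write_recording()` returns `path` invisibly.
#' @name recording_io
NULL

sidecar_path <- function(path) sub("\\.csv$", ".meta.yaml", path)

#' @rdname recording_io
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "trace_recording"))
  if (!grepl("\\.csv$", path)) path <- paste0(path, ".csv")
  ch <- recording$channels
  df <- data.frame(time_s = signif(rec_time(recording), 9),
                   force_mN = signif(ch$force_mN, 9),
                   length_um = signif(ch$length_um, 9),
                   f340 = signif(ch$f340, 9),
                   f380 = signif(ch$f380, 9))
  data.table::fwrite(df, path)
  meta <- list(
    sampling_rate = recording$sampling_rate,
    f0_reference = recording$f0_reference,
    diameter_um = recording$meta$diameter_um,
    l_max_um = recording$meta$l_max_um,
    group_label = recording$meta$group_label,
    protocol = recording$meta$protocol,
    stimulus_times = as.numeric(recording$stimulus_times),
    events = lapply(seq_len(nrow(recording$events)), function(i) {
      list(time_s = recording$events$time_s[i],
           type = recording$events$type[i],
           value = if (is.na(recording$events$value[i])) NULL
                   else recording$events$value[i])
    })
  )
  meta <- Filter(Negate(is.null), meta)
  yaml::write_yaml(meta, sidecar_path(path), precision = 12)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing metadata sidecar: ", sc, call. = FALSE)
  }
  parse_fail <- function(c) {
    stop("failed to parse ", path, ": ", conditionMessage(c), call. = FALSE)
  }
  ## fread downgrades ragged/truncated input to a warning; collect its
  ## diagnostics (letting the parser finish cleanly) and then fail hard so
  ## silent truncation cannot slip through
  diags <- character(0)
  df <- withCallingHandlers(
    tryCatch(
      as.data.frame(data.table::fread(path, fill = FALSE,
                                      showProgress = FALSE)),
      error = parse_fail),
    warning = function(w) {
      diags <<- c(diags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (length(diags) > 0L) {
    stop("failed to parse ", path, ": ", paste(diags, collapse = "; "),
         call. = FALSE)
  }
  need <- c("time_s", "force_mN", "length_um", "f340", "f380")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df[need])) {
    bad <- which(rowSums(is.na(df[need])) > 0)[1L]
    stop(sprintf("incomplete record at data line %d of %s", bad, path),
         call. = FALSE)
  }
  meta <- yaml::read_yaml(sc)
  fs <- meta$sampling_rate
  if (is.null(fs)) stop("sidecar lacks sampling_rate", call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("time column not strictly increasing", call. = FALSE)
  if (max(abs(dt - 1 / fs)) > 1e-6 / fs + 1e-12) {
    stop("non-uniform time column, or sampling_rate inconsistent with it",
         call. = FALSE)
  }
  events <- if (length(meta$events) > 0L) {
    do.call(rbind, lapply(meta$events, function(e) {
      data.frame(time_s = e$time_s, type = e$type,
                 value = e$value %||% NA_real_, stringsAsFactors = FALSE)
    }))
  } else empty_events()
  trace_recording(
    sampling_rate = fs,
    force = df$force_mN, length = df$length_um,
    f340 = df$f340, f380 = df$f380,
    stimulus_times = as.numeric(unlist(meta$stimulus_times)),
    events = events,
    f0_reference = meta$f0_reference,
    meta = list(diameter_um = meta$diameter_um,
                l_max_um = meta$l_max_um,
                group_label = meta$group_label,
                protocol = meta$protocol)
  )
}
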
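#' Simulate and analyze a cohort
#'
#' Generates a cohort of muscles with [make_cohort()], simulates the given
#' protocol for each muscle (per-muscle seeds derived deterministically from
#' `seed`), and runs the matching protocol analysis ([analyze_fl()],
#' [analyze_sfr()] or [analyze_prp()]).
#'
#' @param group `"CONT"` or `"MCT"`.
#' @param n Cohort size.
#' @param protocol A [fl_protocol()], [sfr_protocol()] or [prp_protocol()].
#' @param seed Integer master seed.
#' @param fs Sampling rate (Hz).
#' @return List with `group`, `params` (the cohort) and `analyses` (one
#'   protocol result per muscle).
#' @export
run_cohort <- function(group, n, protocol, seed, fs = 1000) {
  cohort <- make_cohort(group, n, seed)
  analyzer <- switch(protocol$type,
                     FL = analyze_fl,
                     SFR = analyze_sfr,
                     PRP = analyze_prp)
  analyses <- lapply(seq_along(cohort), function(i) {
    rec <- simulate_protocol(cohort[[i]], protocol, seed = seed + 7919L * i,
                             fs = fs)
    analyzer(rec)
  })
  list(group = group, params = cohort, analyses = analyses)
}

#' Reproduce the endpoint statistics of the reference experiment
#'
#' Runs the full simulated experiment at the reference cohort sizes (CONT
#' n = 12, MCT n = 11): force-length runs over the 75-100% L_MAX grid, SFR
#' runs (85 to 95% L_MAX rapid stretch, 3 min of post-stretch beats), and
#' PRP runs (60 s pause at 95% L_MAX), then assembles the endpoint
#' statistics with group means, SDs and Mann-Whitney p-values.
#'
#' @param seed Integer master seed for the whole experiment.
#' @param n_cont,n_mct Cohort sizes.
#' @param fs Sampling rate (Hz).
#' @return List with
#'   `endpoints` (named numeric vector of the headline quantities),
#'   `tables` (per-protocol summary data frames with p-values), and the raw
#'   per-muscle endpoint tables in `muscle_endpoints`.
#' @export
reproduce_endpoints <- function(seed, n_cont = 12, n_mct = 11, fs = 1000) {
  sfr_c <- run_cohort("CONT", n_cont, sfr_protocol(), seed, fs)
  sfr_m <- run_cohort("MCT", n_mct, sfr_protocol(), seed + 1L, fs)
  prp_c <- run_cohort("CONT", n_cont, prp_protocol(), seed + 2L, fs)
  prp_m <- run_cohort("MCT", n_mct, prp_protocol(), seed + 3L, fs)
  fl_c <- run_cohort("CONT", n_cont, fl_protocol(), seed + 4L, fs)
  fl_m <- run_cohort("MCT", n_mct, fl_protocol(), seed + 5L, fs)

  sfr_tbl <- rbind(sfr_endpoint_rows(sfr_c), sfr_endpoint_rows(sfr_m))
  prp_tbl <- rbind(prp_endpoint_rows(prp_c), prp_endpoint_rows(prp_m))
  fl_tbl <- rbind(fl_feature_rows(fl_c), fl_feature_rows(fl_m))

  sfr_sum <- summarize_features(sfr_tbl)
  prp_sum <- summarize_features(prp_tbl)
  fl_sum <- summarize_features(fl_tbl)

  gmean <- function(s, char, grp) {
    s$mean[s$characteristic == char & s$group == grp][1L]
  }
  ## preload-averaged MCT-vs-CONT kinetic contrasts from the FL summary
  contrast <- function(char, what = c("excess_pct", "prolong")) {
    what <- match.arg(what)
    sub <- fl_sum[fl_sum$characteristic == char, ]
    per <- vapply(split(sub, sub$preload_pct), function(cell) {
      mc <- cell$mean[cell$group == "MCT"]
      co <- cell$mean[cell$group == "CONT"]
      if (what == "excess_pct") 100 * (mc - co) / co else mc - co
    }, numeric(1))
    mean(per)
  }

  endpoints <- c(
    sfr_magnitude_cont = gmean(sfr_sum, "sfr_magnitude", "CONT"),
    sfr_magnitude_mct = gmean(sfr_sum, "sfr_magnitude", "MCT"),
    sfr_cat_end_cont = gmean(sfr_sum, "cat_end_pct", "CONT"),
    sfr_cat_end_mct = gmean(sfr_sum, "cat_end_pct", "MCT"),
    fl_force_ttp_excess_pct = contrast("force_ttp_ms", "excess_pct"),
    fl_cat_ttp_excess_pct = contrast("cat_ttp_ms", "excess_pct"),
    fl_cat_ttp_prolong_ms = contrast("cat_ttp_ms", "prolong"),
    fl_cat_t50_prolong_ms = contrast("cat_t50_decay_ms", "prolong"),
    prp_extent_cont = gmean(prp_sum, "prp_extent", "CONT"),
    prp_extent_mct = gmean(prp_sum, "prp_extent", "MCT"),
    prp_cat_first_cont = gmean(prp_sum, "cat_first_beat_pct", "CONT"),
    prp_cat_first_mct = gmean(prp_sum, "cat_first_beat_pct", "MCT")
  )
  list(endpoints = endpoints,
       tables = list(sfr = sfr_sum, prp = prp_sum, fl = fl_sum),
       muscle_endpoints = list(sfr = sfr_tbl, prp = prp_tbl, fl = fl_tbl))
}

sfr_endpoint_rows <- function(run) {
  do.call(rbind, lapply(seq_along(run$analyses), function(i) {
    a <- run$analyses[[i]]
    data.frame(group = run$group, muscle = run$params[[i]]$muscle_id,
               characteristic = c("sfr_magnitude", "cat_end_pct"),
               value = c(a$sfr_magnitude, a$cat_end_pct),
               units = "%", stringsAsFactors = FALSE)
  }))
}

prp_endpoint_rows <- function(run) {
  do.call(rbind, lapply(seq_along(run$analyses), function(i) {
    a <- run$analyses[[i]]
    data.frame(group = run$group, muscle = run$params[[i]]$muscle_id,
               characteristic = c("prp_extent", "cat_first_beat_pct"),
               value = c(a$prp_extent, a$cat_first_beat_pct),
               units = "%", stringsAsFactors = FALSE)
  }))
}

## tidy per-muscle, per-preload FL feature table
fl_feature_rows <- function(run) {
  chars <- c("force_active_amplitude", "force_passive_tension",
             "force_ttp_ms", "force_t50_relax_ms", "force_max_norm_rise",
             "force_max_norm_decline", "cat_amplitude",
             "cat_diastolic_level", "cat_ttp_ms", "cat_t50_decay_ms",
             "cat_max_norm_rise", "cat_max_norm_decay")
  units <- c(rep("mN/mm^2", 2), "ms", "ms", "1/s", "1/s",
             "F/F0", "F/F0", "ms", "ms", "1/s", "1/s")
  do.call(rbind, lapply(seq_along(run$analyses), function(i) {
    ft <- run$analyses[[i]]$features
    do.call(rbind, lapply(seq_along(chars), function(j) {
      data.frame(group = run$group, muscle = run$params[[i]]$muscle_id,
                 characteristic = chars[j], preload_pct = ft$preload_pct,
                 value = ft[[chars[j]]], units = units[j],
                 stringsAsFactors = FALSE)
    }))
  }))
}
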
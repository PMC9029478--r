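test_that("identical (params, protocol, seed) give bit-identical recordings", {
  p <- default_params("CONT")
  r1 <- simulate_protocol(p, sfr_protocol(post_s = 20), seed = 11)
  r2 <- simulate_protocol(p, sfr_protocol(post_s = 20), seed = 11)
  expect_identical(r1, r2)
  r3 <- simulate_protocol(p, sfr_protocol(post_s = 20), seed = 12)
  expect_false(identical(r3$channels, r1$channels))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_protocol(default_params("CONT"),
                              prp_protocol(pre_s = 5, post_s = 5, rest_s = 5),
                              seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("stimuli are paced at 2 Hz and annotated per protocol", {
  p <- default_params("CONT")
  rec <- simulate_protocol(p, fl_protocol(beats_per_preload = 10), seed = 1)
  gap_fl <- diff(rec$stimulus_times)
  expect_true(all(abs(gap_fl - 0.5) < 1e-9 | gap_fl > 0.5))
  expect_equal(sum(rec$events$type == "preload_change"), 6)
  expect_true(all(rec$channels$f380 > 0))

  rec2 <- simulate_protocol(p, prp_protocol(rest_s = 30, pre_s = 10,
                                            post_s = 10), seed = 2)
  gap <- diff(rec2$stimulus_times)
  expect_equal(sum(gap > 1), 1L)       # exactly one pause
  expect_gte(max(gap), 30)
  expect_true(all(c("rest_start", "rest_end") %in% rec2$events$type))
})

test_that("seed is mandatory only when noise is enabled", {
  p <- default_params("CONT")
  expect_error(simulate_protocol(p, sfr_protocol(post_s = 10)), "seed")
  p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
  expect_silent(rec <- simulate_protocol(p, sfr_protocol(post_s = 10)))
  expect_s3_class(rec, "trace_recording")
})

test_that("unknown protocol specifications are rejected", {
  p <- default_params("CONT")
  bad <- structure(list(type = "RAMP"), class = "protocol_spec")
  expect_error(simulate_protocol(p, bad, seed = 1), "unknown protocol")
  expect_error(simulate_protocol(p, list(type = "SFR"), seed = 1),
               "unknown protocol")
})

test_that("zero-gain, zero-noise SFR yields identical post-stretch beats", {
  p <- default_params("CONT")
  p$sfr_gain_ca <- 0; p$sfr_gain_sens <- 0; p$sfr_dia_gain <- 0
  p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
  rec <- simulate_protocol(p, sfr_protocol(post_s = 30))
  beats <- segment_beats(rec)
  post <- Filter(function(b) b$stimulus_time >= 10.15 + 0.5, unclass(beats))
  ref <- post[[1L]]
  for (b in post[-1L]) {
    expect_equal(b$force, ref$force)
    expect_equal(b$ca, ref$ca)
  }
})

test_that("SFR per-beat Ca amplitude follows the saturating envelope", {
  p <- default_params("CONT")
  p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
  rec <- simulate_protocol(p, sfr_protocol(post_s = 60))
  res <- analyze_sfr(rec, end_window = 5)
  s <- res$series
  w <- 1 - exp(-s$time_s / p$sfr_tau)
  predicted <- 100 * (1 + p$sfr_gain_ca * w) / (1 + p$sfr_gain_ca * w[1L])
  expect_equal(s$cat_amp_pct, predicted, tolerance = 5e-3)
})

test_that("PRP without rest has inert multipliers; with rest the envelope is geometric", {
  p <- default_params("CONT")
  p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
  rec0 <- simulate_protocol(p, prp_protocol(rest_s = 0, pre_s = 10,
                                            post_s = 10))
  res0 <- analyze_prp(rec0)
  expect_equal(res0$prp_extent, 100, tolerance = 1e-6)
  expect_equal(res0$cat_first_beat_pct, 100, tolerance = 1e-6)

  rec <- simulate_protocol(p, prp_protocol())
  res <- analyze_prp(rec)
  # log-linear fit of the Ca amplitude residuals recovers the per-beat
  # recirculation fraction
  resid <- res$series$cat_amp_pct - 100
  k <- 2:10   # the first beat's baseline sits in the pause, not in a
              # preceding twitch tail, so its convention differs slightly
  fit <- stats::lm(log(resid[k]) ~ k)
  expect_equal(exp(unname(stats::coef(fit)[2L])), p$prp_recirc,
               tolerance = 0.02)
  # first post-pause diastolic level dips below the pre-pause level, then
  # recovers above it
  expect_lt(res$series$cat_dia_pct[1L], 100)
  expect_gt(res$series$cat_dia_pct[nrow(res$series)], 100)
})

test_that("fluorescence channels reconstruct the simulated Ca ratio", {
  p <- default_params("CONT")
  p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
  rec <- simulate_protocol(p, prp_protocol(rest_s = 0, pre_s = 3, post_s = 3))
  ca <- fura_ratio(rec$channels$f340, rec$channels$f380, rec$f0_reference)
  expect_equal(min(ca), p$ca_dia, tolerance = 1e-6)
  expect_equal(max(ca), p$ca_dia + p$ca_amp, tolerance = 1e-3)
})
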
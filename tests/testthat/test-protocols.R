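test_that("find_lmax returns the argmax and flags boundary maxima", {
  steps <- data.frame(length_um = c(2300, 2350, 2400, 2450, 2500),
                      active_amplitude = c(2, 5, 9, 10, 9.5))
  res <- find_lmax(steps)
  expect_equal(res$l_max_um, 2450)
  expect_true(res$reached)
  rising <- data.frame(length_um = c(2300, 2350, 2400),
                       active_amplitude = c(1, 2, 3))
  expect_warning(res2 <- find_lmax(rising), "not reached")
  expect_false(res2$reached)
  bad <- data.frame(length_um = c(2300, 2250, 2400),
                    active_amplitude = c(1, 2, 3))
  expect_error(find_lmax(bad), "increasing")
  expect_error(find_lmax(rising[1:2, ]), "3 stretch steps")
})

test_that("L_MAX is recovered within one step from a simulated stepwise stretch", {
  p <- default_params("CONT")
  p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
  tg <- seq(0, 0.499, by = 1e-3)
  ca <- simulate_cat_beat(p, list(amp_mult = 1, dia_mult = 1), tg)
  lengths <- seq(0.75, 1, by = 0.02) * p$l_max_um   # 50 um steps
  amps <- vapply(lengths, function(L) {
    f <- simulate_force_beat(p, ca, 1, L / p$l_max_um * 100, tg)
    max(f) - fl_passive_force(p, L)
  }, numeric(1))
  res <- suppressWarnings(
    find_lmax(data.frame(length_um = lengths, active_amplitude = amps)))
  expect_lt(abs(res$l_max_um - p$l_max_um), 50 + 1e-9)
})

test_that("noise-free FL run reproduces the active force-length map exactly", {
  p <- default_params("CONT")
  p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
  rec <- simulate_protocol(p, fl_protocol())
  res <- analyze_fl(rec)
  ft <- res$features
  expect_equal(ft$preload_pct, c(75, 80, 85, 90, 95, 100))
  rel <- ft$force_active_amplitude / ft$force_active_amplitude[6L]
  expect_equal(rel, fl_active_scale(p, ft$preload_pct), tolerance = 1e-3)
  # tension normalization by the elliptic cross-section
  s <- cross_section(p$diameter_um)
  expect_equal(ft$force_active_amplitude[6L] * s,
               max(rec$channels$force_mN) -
                 fl_passive_force(p, p$l_max_um), tolerance = 1e-3)
  # active tension is nondecreasing, passive strictly increasing
  expect_true(all(diff(ft$force_active_amplitude) >= 0))
  expect_true(all(diff(ft$force_passive_tension) > 0))
})

test_that("calibrated defaults place passive above active tension at high preloads", {
  for (g in c("CONT", "MCT")) {
    p <- default_params(g)
    p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
    ft <- analyze_fl(simulate_protocol(p, fl_protocol()))$features
    hi <- ft$preload_pct %in% c(95, 100)
    expect_true(all(ft$force_passive_tension[hi] >=
                      ft$force_active_amplitude[hi]))
  }
})

test_that("MCT force time-to-peak exceeds CONT at every preload", {
  run1 <- function(g) {
    p <- default_params(g)
    p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
    analyze_fl(simulate_protocol(p, fl_protocol()))$features
  }
  fc <- run1("CONT"); fm <- run1("MCT")
  expect_true(all(fm$force_ttp_ms > fc$force_ttp_ms))
  expect_true(all(fm$cat_ttp_ms > fc$cat_ttp_ms))
  expect_true(all(fm$cat_t50_decay_ms > fc$cat_t50_decay_ms))
})

test_that("SFR magnitude is 100% for a constant-amplitude sequence", {
  rec <- synth_recording(rep(1, 60), protocol = "SFR")
  res <- analyze_sfr(rec)
  expect_equal(res$sfr_magnitude, 100, tolerance = 1e-9)
  expect_equal(res$series$force_amp_pct[1L], 100)
})

test_that("SFR magnitude tracks a known saturating amplitude envelope", {
  k <- seq_len(400)
  t_k <- (k - 1L) * 0.5
  amps <- 1 + 0.3 * (1 - exp(-t_k / 30))
  rec <- synth_recording(amps, protocol = "SFR")
  res <- analyze_sfr(rec)
  expect_equal(res$sfr_magnitude, 130, tolerance = 0.01)
  expect_equal(res$cat_end_pct, 130, tolerance = 0.01)
})

test_that("SFR analysis recovers envelope plateau and time constant at zero noise", {
  p <- default_params("CONT")
  p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
  p$sfr_gain_ca <- 0; p$sfr_dia_gain <- 0
  tg <- seq(0, 0.499, by = 1e-3)
  ca <- simulate_cat_beat(p, list(amp_mult = 1, dia_mult = 1), tg)
  amp_at <- function(sens) {
    f <- simulate_force_beat(p, ca, sens, 95, tg)
    max(f) - fl_passive_force(p, 0.95 * p$l_max_um)
  }
  for (gs in c(0.05, 0.10)) {
    for (tau in c(30, 50)) {
      q <- p; q$sfr_gain_sens <- gs; q$sfr_tau <- tau
      res <- analyze_sfr(simulate_protocol(q, sfr_protocol()))
      s <- res$series
      w <- 1 - exp(-s$time_s / tau)
      # plateau: single-beat composition of the envelope with the coupling
      plateau <- 100 * amp_at(1 + gs) / amp_at(1 + gs * w[1L])
      expect_equal(res$sfr_magnitude, plateau, tolerance = 0.02)
      # time constant from a log-linear fit of the amplitude residuals
      resid <- plateau - s$force_amp_pct
      use <- which(s$time_s < 2.5 * tau & resid > 0)[-1]
      fit <- stats::lm(log(resid[use]) ~ s$time_s[use])
      expect_equal(-1 / unname(stats::coef(fit)[2L]), tau, tolerance = 0.1)
    }
  }
})

test_that("protocol ratio outputs are invariant to force-channel rescaling", {
  p <- default_params("CONT")
  p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
  rec <- simulate_protocol(p, sfr_protocol(post_s = 40))
  res1 <- analyze_sfr(rec, end_window = 5)
  rec$channels$force_mN <- rec$channels$force_mN * 37.5
  res2 <- analyze_sfr(rec, end_window = 5)
  expect_equal(res2$sfr_magnitude, res1$sfr_magnitude)
  expect_equal(res2$series$force_amp_pct, res1$series$force_amp_pct)

  recp <- simulate_protocol(p, prp_protocol())
  r1 <- analyze_prp(recp)
  recp$channels$force_mN <- recp$channels$force_mN / 8
  r2 <- analyze_prp(recp)
  expect_equal(r2$prp_extent, r1$prp_extent)
})

test_that("PRP geometric recovery: within 5% of baseline after 5 beats for r = 0.5", {
  k <- 0:39
  amps <- 1 + 1.0 * 0.5^k          # first beat at 200%
  rec <- synth_recording(amps, protocol = "PRP", rest_s = 10)
  res <- analyze_prp(rec)
  # ~0.3% slack: the pre-pause reference baseline contains the preceding
  # twitch's tail while the first post-pause baseline does not
  expect_equal(res$prp_extent, 200, tolerance = 0.01)
  expect_equal(res$series$force_amp_pct[1:3], c(200, 150, 125),
               tolerance = 0.01)
  expect_equal(res$recovery_beats, 6L)  # 100 * (1 + 0.5^5) = 103.125
  expect_equal(res$cat_first_beat_pct, 200, tolerance = 0.01)
})

test_that("protocol analyses enforce their event preconditions", {
  p <- default_params("CONT")
  rec_fl <- simulate_protocol(p, fl_protocol(beats_per_preload = 10), seed = 1)
  expect_error(analyze_sfr(rec_fl), "stretch")
  expect_error(analyze_prp(rec_fl), "rest")
  rec_sfr <- simulate_protocol(p, sfr_protocol(post_s = 20), seed = 1)
  expect_error(analyze_sfr(rec_sfr, end_window = 100), "too few")
})
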
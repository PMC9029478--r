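test_that("fura ratio normalizes and validates", {
  expect_equal(fura_ratio(rep(2, 5), rep(2, 5), 1), rep(1, 5))
  expect_equal(fura_ratio(rep(4, 5), rep(2, 5), 2), rep(1, 5))
  # round trip: channels constructed from a known F/F0 waveform
  ca <- 1 + 0.4 * sin(seq(0, pi, length.out = 100))^2
  f380 <- runif(100, 1.5, 2.5)
  expect_equal(fura_ratio(ca * 0.85 * f380, f380, 0.85), ca)
  expect_error(fura_ratio(c(1, 2), c(1, 0), 1), "non-positive")
  expect_error(fura_ratio(1:3, c(1, 2), 1), "equal length")
  expect_error(fura_ratio(1:3, 1:3, 0), "positive")
})

test_that("cross-section follows the elliptic formula", {
  expect_equal(cross_section(100), 2.61799e-3, tolerance = 1e-5)
  expect_equal(cross_section(200), 4 * cross_section(100))
  expect_equal(cross_section(250), pi * 250^2 / 12 * 1e-6)
  expect_error(cross_section(0), "positive")
  expect_error(cross_section(-10), "positive")
})

test_that("beat segmentation: one window per stimulus, none during rest", {
  p <- default_params("CONT")
  p$noise_sd_force <- 0; p$noise_sd_fluor <- 0
  rec <- simulate_protocol(p, prp_protocol(rest_s = 30, pre_s = 10,
                                           post_s = 10))
  beats <- segment_beats(rec)
  expect_equal(length(beats), length(rec$stimulus_times))
  stim <- vapply(unclass(beats), function(b) b$stimulus_time, numeric(1))
  expect_false(any(stim > 10 & stim < 40))
  expect_true(all(vapply(unclass(beats), function(b) b$preload_pct == 95,
                         logical(1))))
})

test_that("segmentation rejects overlapping stimuli", {
  n <- 2000
  rec <- trace_recording(1000, rnorm(n, 1, 1e-3), rep(2400, n),
                         rep(1.7, n), rep(2, n),
                         stimulus_times = c(0.5, 0.505, 1.0),
                         f0_reference = 0.85)
  expect_error(segment_beats(rec), "overlapping")
})

test_that("the first post-stretch beat is the first stimulus at/after stretch end", {
  p <- default_params("CONT")
  rec <- simulate_protocol(p, sfr_protocol(post_s = 20), seed = 5)
  stretch_end <- rec$events$time_s[rec$events$type == "stretch_end"]
  beats <- unclass(segment_beats(rec))
  tagged <- vapply(beats, function(b) length(b$tags) > 0, logical(1))
  stim <- vapply(beats, function(b) b$stimulus_time, numeric(1))
  first_post <- min(stim[stim >= stretch_end & !tagged])
  # stretch ends at 10.15 s; the next stimulus on the 2 Hz grid is 10.25 s
  expect_equal(first_post, 10.25)
  # the beat bisected by the stretch carries the event tags
  bisected <- beats[[which(stim < stretch_end & stim + 0.5 > stretch_end)]]
  expect_true(all(c("stretch_start", "stretch_end") %in% bisected$tags))
})

test_that("twitch descriptors match closed-form waveforms", {
  fs <- 1000
  t_post <- seq(0, 0.449, by = 1 / fs)
  # saturating exponential rise, tau = 50 ms: max normalized rate = 1/tau
  rise <- c(rep(0, 50), 1 - exp(-t_post / 0.05))
  ft <- extract_twitch(make_beat(rise, fs = fs))
  expect_equal(ft$max_norm_rise, 20, tolerance = 0.05)
  # pure exponential decay from the peak, tau = 80 ms: t50 = tau * ln 2
  decay <- c(rep(0, 50), exp(-t_post / 0.08))
  ft <- extract_twitch(make_beat(decay, fs = fs))
  expect_equal(ft$t50_relax_ms, 80 * log(2), tolerance = 1e-3)
  # two-exponential: time-to-peak within one sample of the closed form
  ca2 <- extract_cat(make_beat(rep(1, 500), c(rep(1, 50),
                     1 + twoexp_curve(20, 100, t_post * 1000))))
  expect_lt(abs(ca2$ttp_ms - 40.23595), 1 + 1e-9)
})

test_that("timing and normalized-rate features are affine invariant", {
  fs <- 1000
  t_post <- seq(0, 0.449, by = 1 / fs)
  y <- c(rep(0.2, 50), 0.2 + twoexp_curve(18, 90, t_post * 1000))
  base <- extract_twitch(make_beat(y, fs = fs))
  for (a in c(0.5, 10)) {
    for (b in c(-3, 7)) {
      tr <- extract_twitch(make_beat(a * y + b, fs = fs))
      expect_equal(tr$ttp_ms, base$ttp_ms)
      expect_equal(tr$t50_relax_ms, base$t50_relax_ms)
      expect_equal(tr$max_norm_rise, base$max_norm_rise)
      expect_equal(tr$max_norm_decline, base$max_norm_decline)
      expect_equal(tr$active_amplitude, a * base$active_amplitude)
    }
  }
})

test_that("t50 interpolation stays within one sample of an oversampled oracle", {
  fs <- 1000
  t_post <- seq(0, 0.449, by = 1 / fs)
  for (tau_d in c(40, 80, 160)) {
    for (ratio in c(3, 5, 10)) {
      tau_r <- tau_d / ratio
      y <- c(rep(0, 50), twoexp_curve(tau_r, tau_d, t_post * 1000))
      ft <- extract_twitch(make_beat(y, fs = fs))
      expect_lt(abs(ft$t50_relax_ms - twoexp_t50_oracle(tau_r, tau_d)),
                1000 / fs)
    }
  }
})

test_that("decay-time inversion approaches tau_d for well-separated kinetics", {
  # t50/ln2 converges to tau_d as the shape parameter grows; the relative
  # error is a property of the waveform family itself
  err_of <- function(ratio) {
    tau_d <- 80; tau_r <- tau_d / ratio
    abs(twoexp_t50_oracle(tau_r, tau_d) / log(2) - tau_d) / tau_d
  }
  errs <- vapply(c(5, 10, 20, 50), err_of, numeric(1))
  expect_true(all(diff(errs) < 0))   # monotone improvement
  # convergence is slow: ~25% at ratio 5, still ~7% at ratio 20; the
  # inversion is only trustworthy for very well separated time constants
  expect_lt(errs[3], 0.08)
  expect_lt(errs[4], 0.03)
  expect_gt(errs[1], 0.15)
})

test_that("degenerate twitches are flagged and features nulled", {
  flat <- make_beat(rep(1, 500))
  ft <- extract_twitch(flat)
  expect_true(ft$degenerate)
  expect_true(is.na(ft$ttp_ms))
  noisy_flat <- make_beat(rnorm(500, 1, 0.01))
  expect_true(extract_twitch(noisy_flat)$degenerate)
  expect_error(self_normalize(flat), "degenerate")
})

test_that("ensemble averaging suppresses noise at the 1/sqrt(n) rate", {
  fs <- 1000
  t_post <- seq(0, 0.449, by = 1 / fs)
  clean <- c(rep(0, 50), twoexp_curve(20, 100, t_post * 1000))
  set.seed(123)
  sigma <- 0.05
  beats <- lapply(1:30, function(i) {
    make_beat(clean + rnorm(length(clean), 0, sigma), fs = fs)
  })
  avg <- ensemble_average(beats)
  resid_sd <- sd(avg$force - clean)
  expect_lt(abs(resid_sd - sigma / sqrt(30)) / (sigma / sqrt(30)), 0.2)
  # averaging identical beats returns the input
  same <- ensemble_average(lapply(1:30, function(i) make_beat(clean)))
  expect_equal(same$force, clean)
})

test_that("ensemble averaging enforces its contract", {
  fs <- 1000
  y <- c(rep(0, 50), twoexp_curve(20, 100, seq(0, 449)))
  b85 <- make_beat(y, fs = fs, preload = 85)
  b95 <- make_beat(y, fs = fs, preload = 95)
  expect_error(ensemble_average(list(b85, b95, b85, b95, b85)),
               "different preloads")
  expect_warning(ensemble_average(list(b85, b85, b85)), "fewer than 5")
  expect_error(ensemble_average(list()), "no beats")
})

test_that("self-normalization maps baseline to 0, peak to 1, and is idempotent", {
  y <- c(rep(0.3, 50), 0.3 + 0.7 * twoexp_curve(20, 100, seq(0, 449)) / 0.5314)
  b <- make_beat(y, ca = 1 + y)
  nb <- self_normalize(b)
  expect_equal(max(nb$force), 1, tolerance = 1e-9)
  expect_equal(mean(nb$force[nb$t < 0]), 0, tolerance = 1e-12)
  nb2 <- self_normalize(nb)
  expect_equal(nb2$force, nb$force)
  expect_equal(max(nb$ca), 1, tolerance = 1e-9)
})

test_that("normalized MCT waveforms are wider than CONT (half-max width)", {
  tg <- seq(0, 0.499, by = 1e-3)
  width_at_half <- function(p) {
    ca <- simulate_cat_beat(p, list(amp_mult = 1, dia_mult = 1), tg)
    y <- (ca - p$ca_dia) / max(ca - p$ca_dia)
    above <- which(y >= 0.5)
    (max(above) - min(above)) / 1000
  }
  expect_gt(width_at_half(default_params("MCT")),
            width_at_half(default_params("CONT")))
})
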
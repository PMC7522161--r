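test_that("session spec validation enforces the physiological ranges", {
  expect_error(session_spec(duration_s = 60), ">= 120")
  expect_error(session_spec(ecg_mean_bpm = 20), "ecg_mean_bpm")
  expect_error(session_spec(scl_tonic = -1), "scl_tonic")
  expect_error(session_spec(tmp_baseline = 15), "tmp_baseline")
  expect_error(session_spec(missing_window_prob = 1.2), "missing_window_prob")
  expect_error(event_marks(100, 90, 300), "strictly increasing")
  expect_error(event_marks(100, 140, 300), "60 s apart")
  expect_error(
    synth_femg(session_spec(duration_s = 240, fs = 256,
                            anchors = event_marks(10, 110, 230)),
               "corrugator", rng_stream(1)),
    ">= 512"
  )
})

test_that("fEMG synthesis honours the envelope contract", {
  sp <- quick_spec()
  r <- rng_stream(7)
  zero <- synth_femg(sp, "zygomaticus", r,
                     envelope_mean = c(start = 0, cecum = 0, end = 0))
  expect_true(all(zero$signal$value == 0))

  fe <- synth_femg(sp, "zygomaticus", rng_stream(8))
  expect_equal(nrow(fe$signal), 240 * 512)
  # ground-truth envelope passes through the per-segment means at anchors
  env <- fe$envelope$value
  centres <- c(start = 10 + 30, cecum = 110, end = 230 - 30)
  mu <- sp$femg_envelope_mean$zygomaticus
  for (a in names(centres)) {
    expect_equal(env[round(centres[[a]] * 512) + 1], mu[[a]],
                 tolerance = 1e-6)
  }
  # with a constant envelope the spectrum is confined to 20-250 Hz exactly
  flat <- synth_femg(sp, "zygomaticus", rng_stream(8),
                     envelope_mean = c(start = 5, cecum = 5, end = 5))
  sp_pow <- Mod(stats::fft(flat$signal$value))^2
  f_axis <- (seq_along(sp_pow) - 1) * 512 / length(sp_pow)
  f_axis <- pmin(f_axis, 512 - f_axis)
  out_band <- f_axis < 19.9 | f_axis > 250.1
  in_band <- !out_band
  expect_lt(sum(sp_pow[out_band]), 1e-9 * sum(sp_pow[in_band]))
})

test_that("conditioned window means track specified envelopes across sessions", {
  sp <- session_spec(duration_s = 120, fs = 512,
                     anchors = event_marks(30, NA, 119))
  b <- window_bounds(sp$anchors, "start", 512)
  idx <- (b[1] + 1):b[2]
  set.seed(61)
  targets <- stats::runif(12, 2, 12)
  rel_err <- vapply(seq_along(targets), function(i) {
    ov <- rep(targets[i], 3); names(ov) <- c("start", "cecum", "end")
    fe <- synth_femg(sp, "zygomaticus", rng_stream(100 + i),
                     envelope_mean = ov)
    m <- mean(condition_femg(fe$signal)$value[idx])
    abs(m - targets[i]) / targets[i]
  }, numeric(1))
  expect_lt(mean(rel_err), 0.10)
})

test_that("ECG synthesis places beats as specified", {
  sp0 <- quick_spec(ecg_mean_bpm = 60, ecg_rr_jitter_sd = 0, ecg_noise_sd = 0,
                    duration_s = 120, anchors = event_marks(5, NA, 119))
  ec <- synth_ecg(sp0, rng_stream(9))
  in_min <- ec$r_peaks[ec$r_peaks < 60]
  expect_true(abs(length(in_min) - 60) <= 1)
  expect_equal(unique(round(diff(ec$r_peaks), 10)), 1.0)

  spj <- session_spec(duration_s = 300, fs = 512,
                      anchors = event_marks(10, 150, 290),
                      ecg_mean_bpm = 72, ecg_rr_jitter_sd = 0.02)
  ecj <- synth_ecg(spj, rng_stream(10))
  expect_equal(mean(60 / diff(ecj$r_peaks)), 72, tolerance = 1 / 72)
  expect_true(all(diff(ecj$r_peaks) >= 0.25))
})

test_that("SCL and TMP models behave as documented", {
  spc <- quick_spec(scl_scr_rate = 0, scl_noise_sd = 0, scl_tonic = 2)
  scl <- synth_scl(spc, rng_stream(11))
  expect_equal(unique(scl$value), 2)

  spb <- quick_spec(scl_tonic = 2, scl_scr_rate = 4, scl_noise_sd = 0)
  bumpy <- synth_scl(spb, rng_stream(12))
  expect_gte(mean(bumpy$value), 2)
  expect_true(all(bumpy$value >= 0))

  spt <- session_spec(duration_s = 600, fs = 512,
                      anchors = event_marks(30, 300, 590),
                      tmp_drift = 0.1, tmp_noise_sd = 0.02)
  tm <- synth_tmp(spt, rng_stream(13))
  fit <- stats::lm(tm$value ~ tm$time_s)
  expect_equal(unname(stats::coef(fit)[2]) * 60, 0.1, tolerance = 0.05)
})

test_that("cohort generation is seed-deterministic and correctly labelled", {
  cs <- cohort_spec(n_control = 3, n_music = 3, seed = 17, base = quick_spec())
  c1 <- generate_cohort(cs, channels = c("femg_zygomaticus", "tmp"))
  c2 <- generate_cohort(cs, channels = c("femg_zygomaticus", "tmp"))
  expect_identical(c1$sex, c2$sex)
  for (i in seq_len(nrow(c1))) {
    expect_identical(c1$recording[[i]]$femg_zygomaticus,
                     c2$recording[[i]]$femg_zygomaticus)
  }
  expect_equal(table(c1$group), table(c(rep("control", 3), rep("music", 3))))

  rec <- generate_session(quick_spec(), rng_stream(19))
  expect_setequal(recording_channels(rec),
                  c("femg_corrugator", "femg_zygomaticus", "ecg", "scl", "tmp"))
  expect_equal(recording_units(rec)[["scl"]], "uS")
  expect_equal(nrow(rec), 240 * 512)
})

test_that("the music arm scales fEMG envelope draws", {
  base <- quick_spec()
  cs <- cohort_spec(n_control = 12, n_music = 12, seed = 23, base = base,
                    music_femg_scale = 0.3, cecum_missing_prob = 0)
  coh <- generate_cohort(cs, channels = "femg_zygomaticus")
  env_mean <- vapply(coh$recording, function(r) {
    mean(attr(r, "truth")$envelopes$femg_zygomaticus)
  }, numeric(1))
  m_ctl <- mean(env_mean[coh$group == "control"])
  m_mus <- mean(env_mean[coh$group == "music"])
  expect_lt(m_mus, m_ctl * 0.7)
})
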
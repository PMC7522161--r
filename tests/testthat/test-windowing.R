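test_that("window geometry matches the anchor definitions exactly", {
  marks <- event_marks(120, 600, 900)
  expect_equal(window_bounds(marks, "start", 512), c(61440, 92160))
  expect_equal(window_bounds(marks, "cecum", 512), c(291840, 322560))
  b <- window_bounds(marks, "end", 512)
  expect_equal(b[2] - b[1], 60 * 512)
  expect_equal(b[2], 900 * 512)

  expect_null(window_bounds(event_marks(120, NA, 900), "cecum", 512))
  expect_error(window_bounds(event_marks(10, 90, 170), "end", 512,
                             n_total = 170 * 512 - 100), "beyond")
  expect_error(window_bounds(event_marks(10, NA, 170), "cecum", 512),
               NA) # NULL, silently
})

test_that("every non-discarded window holds exactly 60 * fs samples", {
  sp <- quick_spec()
  rec <- generate_session(sp, rng_stream(33))
  pr <- process_session(rec)
  expect_true(all(pr$qc$qc %in% c("kept", "corrected")))
  wins <- cut_windows(
    biostress:::new_recording(tibble::as_tibble(rec), sp$fs,
                              recording_units(rec), recording_marks(rec)),
    biostress:::new_recording(tibble::as_tibble(rec), sp$fs,
                              recording_units(rec), recording_marks(rec))
  )
  expect_true(all(wins$b - wins$a == 60 * 512))
})

test_that("screening discards saturation and flat windows, corrects spikes", {
  set.seed(71)
  chan <- rnorm(60 * 512 * 3)
  cs <- channel_stats(chan)
  win <- chan[1:(60 * 512)]
  expect_identical(screen_window(win, cs)$status, "kept")

  clipped <- win
  clipped[1:round(0.1 * length(win))] <- max(chan)
  cs2 <- channel_stats(c(clipped, chan[-(1:length(win))]))
  scr <- screen_window(clipped, cs2)
  expect_identical(scr$status, "discarded")
  expect_identical(scr$reason, "saturation")

  expect_identical(screen_window(rep(1.0, 100), cs)$status, "discarded")
  expect_identical(screen_window(rep(1.0, 100), cs)$reason, "flat")

  # three isolated spikes: corrected by interpolation, close to the original
  t <- seq(0, 59.9, length.out = length(win))
  smooth <- 5 + sin(2 * pi * 0.1 * t) + 0.3 * rnorm(length(win))
  chan_s <- rep(smooth, 3)
  cs3 <- channel_stats(chan_s)
  spiked <- smooth
  at <- c(5000, 15000, 25000)
  spiked[at] <- 50
  scr3 <- screen_window(spiked, cs3)
  expect_identical(scr3$status, "corrected")
  expect_setequal(scr3$spike_idx, at)
  rms_err <- sqrt(mean((scr3$values - smooth)^2)) / sqrt(mean(smooth^2))
  expect_lt(rms_err, 0.05)
})

test_that("added corruption never improves a window's QC status", {
  rank_of <- c(kept = 1, corrected = 2, discarded = 3)
  set.seed(73)
  chan <- rnorm(60 * 512 * 3)
  cs <- channel_stats(chan)
  win <- chan[1:(60 * 512)]
  lim <- 8 * 1.4826 * cs$mad
  status_at <- function(n_spikes) {
    w <- win
    if (n_spikes > 0) {
      w[seq_len(n_spikes) * 6] <- cs$med + 2 * lim
    }
    screen_window(w, cs)$status
  }
  counts <- c(0, 3, 50, 1000, 5000)
  ranks <- rank_of[vapply(counts, status_at, character(1))]
  expect_true(all(diff(ranks) >= 0))
})

test_that("simulated missingness propagates to discarded windows and N", {
  sp <- quick_spec(missing_window_prob = 0.5)
  cs <- cohort_spec(n_control = 3, n_music = 3, seed = 29, base = sp,
                    cecum_missing_prob = 0)
  coh <- generate_cohort(cs, channels = c("femg_zygomaticus", "scl"))
  ft <- build_feature_table(coh)
  n_disc <- sum(ft$qc$qc == "discarded")
  expect_gt(n_disc, 0)
  expect_equal(sum(is.na(ft$features$value)), n_disc)
  # per-cell N never exceeds the arm size
  ct <- compare_groups(ft)
  expect_true(all(ct$n_control <= 3 & ct$n_music <= 3))
})
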
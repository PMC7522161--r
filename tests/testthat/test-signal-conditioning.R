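test_that("decimation keeps DC, length and in-band sinusoids", {
  s <- signal_tbl(rep(3.5, 8192), fs = 2048, unit = "uV", channel = "femg_corrugator")
  d <- decimate_signal(s, 512)
  expect_equal(nrow(d), 2048)
  expect_equal(signal_fs(d), 512)
  expect_equal(d$value, rep(3.5, 2048), tolerance = 1e-9)
  expect_identical(signal_unit(d), "uV")

  t <- (0:16383) / 2048
  sine <- signal_tbl(sin(2 * pi * 50 * t), fs = 2048)
  d50 <- decimate_signal(sine, 512)
  # dominant spectral peak still at 50 Hz, amplitude within 2%
  sp <- Mod(stats::fft(d50$value))[1:(nrow(d50) / 2)]
  f_axis <- (seq_along(sp) - 1) * 512 / nrow(d50)
  expect_equal(f_axis[which.max(sp)], 50, tolerance = 0.05)
  core <- d50$value[1000:3000]
  expect_equal(max(abs(core)), 1, tolerance = 0.02)

  expect_error(decimate_signal(s, 500), "integer multiple")
})

test_that("zero-phase Butterworth gains match the analytic magnitude", {
  bp <- filter_spec("bandpass", c(20, 250), order = 4)
  # DC rejection
  dc <- signal_tbl(rep(1, 4096), fs = 512)
  y <- apply_filter(dc, bp)$value
  expect_lt(max(abs(y[512:3584])), 0.01)
  # frequency grid, in and out of band; zero-phase gain = |H|^2
  for (f in c(5, 10, 20, 35, 50, 100, 150, 200, 240, 250)) {
    expected <- butter_mag_sq("bandpass", c(20, 250), 4, f, 512)
    g <- measured_gain(f, bp)
    if (expected > 0.05) {
      expect_equal(g, expected, tolerance = 0.02)
    } else {
      expect_lt(abs(g - expected), 0.01)
    }
  }
  expect_equal(measured_gain(100, bp), 1, tolerance = 0.05)
  expect_lt(measured_gain(5, bp), 0.01)
  # corner at/above Nyquist rejected
  expect_error(apply_filter(dc, filter_spec("lowpass", 300)), "Nyquist")
})

test_that("filtering is homogeneous to machine precision", {
  set.seed(11)
  s <- signal_tbl(rnorm(2048), fs = 512)
  bp <- filter_spec("bandpass", c(20, 250))
  y1 <- apply_filter(s, bp)$value
  s2 <- signal_tbl(7 * s$value, fs = 512)
  y2 <- apply_filter(s2, bp)$value
  expect_equal(y2, 7 * y1, tolerance = 1e-12)
})

test_that("Hilbert envelope demodulates amplitude", {
  fs <- 512
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  z <- signal_tbl(numeric(100), fs)
  expect_equal(hilbert_envelope(z)$value, numeric(100))

  s <- signal_tbl(2 * sin(2 * pi * 50 * t), fs)
  env <- hilbert_envelope(s)$value
  interior <- env[(2 * fs):(6 * fs)]
  expect_true(all(abs(interior - 2) < 0.02))
  expect_true(all(env >= 0))

  mod <- 1 + 0.5 * sin(2 * pi * 1 * t)
  am <- signal_tbl(mod * sin(2 * pi * 50 * t), fs)
  rec <- apply_filter(hilbert_envelope(am), filter_spec("lowpass", 4))$value
  core <- (2 * fs):(6 * fs)
  expect_gt(stats::cor(rec[core], mod[core]), 0.99)
})

test_that("moving average matches closed forms and shrinks at edges", {
  s <- signal_tbl(rep(4.2, 500), fs = 512)
  expect_equal(moving_average(s, 67)$value, rep(4.2, 500), tolerance = 1e-12)

  imp <- numeric(501); imp[251] <- 1
  m <- moving_average(signal_tbl(imp, 512), 67)$value
  covering <- 251 + (-33:33)
  expect_equal(m[covering], rep(1 / 67, 67), tolerance = 1e-12)
  expect_equal(m[100], 0)

  # variance reduction of white noise ~ 1/n on interior samples
  set.seed(21)
  mids <- replicate(300, {
    x <- rnorm(1200)
    moving_average_vec(x, 513)[600]
  })
  expect_equal(stats::var(mids), 1 / 513, tolerance = 0.2)

  expect_error(moving_average(s, 0), "positive integer")
})

test_that("linear detrend removes exactly a line", {
  fs <- 512
  ramp <- signal_tbl(seq(0, 1, length.out = 1024), fs)
  expect_lt(max(abs(detrend_linear(ramp)$value)), 1e-9)
  cst <- signal_tbl(rep(5, 256), fs)
  expect_lt(max(abs(detrend_linear(cst)$value)), 1e-9)

  t <- (0:4095) / fs
  wave <- sin(2 * pi * 10 * t)
  s <- signal_tbl(wave + 0.3 * t, fs)
  resid <- detrend_linear(s)$value
  # the sine is zero-mean and (essentially) trend-free over whole periods
  expect_lt(sqrt(mean((resid - (wave - mean(wave)))^2)) / sqrt(mean(wave^2)),
            0.01)
})

test_that("conditioning chains preserve length, rate and units", {
  sp <- quick_spec()
  r <- rng_stream(31)
  fe <- synth_femg(sp, "zygomaticus", r)
  env <- condition_femg(fe$signal)
  expect_equal(nrow(env), nrow(fe$signal))
  expect_equal(signal_fs(env), signal_fs(fe$signal))
  expect_identical(signal_unit(env), "uV")

  scl <- synth_scl(sp, r)
  expect_equal(condition_scl(scl)$value[1000], 5, tolerance = 0.5)
  ec <- synth_ecg(sp, r)
  ce <- condition_ecg(ec$signal)
  expect_equal(nrow(ce), nrow(ec$signal))
  expect_equal(mean(ce$value), 0, tolerance = 1e-9)
})

test_that("fEMG chain recovers a constant envelope and is 1-homogeneous", {
  sp <- quick_spec()
  r <- rng_stream(41)
  ov <- c(start = 6, cecum = 6, end = 6)
  fe <- synth_femg(sp, "corrugator", r, envelope_mean = ov)
  env <- condition_femg(fe$signal)
  b <- window_bounds(sp$anchors, "start", 512)
  m <- mean(env$value[(b[1] + 1):b[2]])
  expect_equal(m, 6, tolerance = 0.1 * 6)

  z <- condition_femg(signal_tbl(numeric(2048), 512, "uV", "femg_corrugator"))
  expect_equal(z$value, numeric(2048), tolerance = 1e-12)

  dbl <- condition_femg(signal_rewrap(fe$signal, 2 * fe$signal$value))
  expect_equal(dbl$value, 2 * env$value, tolerance = 1e-9)
})

test_that("temperature smoothing keeps the drift slope", {
  sp <- session_spec(duration_s = 600, fs = 512,
                     anchors = event_marks(30, 300, 590),
                     tmp_drift = 0.1, tmp_noise_sd = 0.02)
  r <- rng_stream(51)
  tm <- synth_tmp(sp, r)
  sm <- condition_tmp(tm)
  slope_of <- function(v) unname(stats::coef(stats::lm(v ~ tm$time_s))[2])
  expect_equal(slope_of(sm$value) * 60, 0.1, tolerance = 0.02)
})
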
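#' Procedure event marks
#'
#' The three anchors of a colonoscopy session: examination start, the moment
#' the cecum is reached (optional — cecal intubation can fail), and
#' examination end. Times are seconds from the start of the recording.
#'
#' @param exam_start,exam_end Times in seconds.
#' @param cecum Time in seconds, or `NA` when the cecum was not reached.
#' @return A list of class `bst_marks`.
#' @export
event_marks <- function(exam_start, cecum = NA_real_, exam_end) {
  m <- list(exam_start = as.numeric(exam_start), cecum = as.numeric(cecum),
            exam_end = as.numeric(exam_end))
  present <- unlist(m[!is.na(m)])
  if (is.unsorted(present, strictly = TRUE)) {
    stop("event marks must be strictly increasing (start < cecum < end).",
         call. = FALSE)
  }
  if (any(diff(present) < 60)) {
    stop("event marks must be at least 60 s apart.", call. = FALSE)
  }
  structure(m, class = "bst_marks")
}

#' Synthetic session specification
#'
#' All parameters of one simulated colonoscopy session. Defaults emulate the
#' study conditions: acquisition at 2048 Hz; fEMG envelope means and
#' between-patient SDs per site and per anchor segment set to the control
#' arm's observed values (corrugator 8.15/6.86/7.23 uV, zygomaticus
#' 7.70/4.82/5.17 uV at start/cecum/end); resting heart rate around 70 bpm
#' with beat-to-beat jitter; tonic skin conductance near 5 uS with about
#' four spontaneous responses per minute; finger temperature near 32 C with
#' a slow drift. Session length is kept at 6 simulated minutes — long enough
#' to hold the three interior one-minute windows, which are all the analysis
#' consumes.
#'
#' @param duration_s Session length in seconds (>= 120).
#' @param fs Sampling rate in Hz.
#' @param anchors An [event_marks()] triple.
#' @param femg_envelope_mean,femg_envelope_sd Named lists
#'   (`corrugator`, `zygomaticus`) of length-3 vectors (start, cecum, end),
#'   in uV on the conditioned-envelope scale. The SDs are between-patient
#'   SDs used when drawing a cohort.
#' @param ecg_mean_bpm Mean heart rate, beats/min, in \[30, 200\].
#' @param ecg_rr_jitter_sd SD of beat-to-beat RR jitter, seconds.
#' @param ecg_amp_mv R-peak amplitude, mV.
#' @param ecg_noise_sd Additive ECG noise SD, mV.
#' @param ecg_wander_amp_mv,ecg_wander_hz Optional sinusoidal baseline
#'   wander (amplitude in mV; 0 disables).
#' @param scl_tonic Tonic skin conductance, uS (>= 0).
#' @param scl_scr_rate Spontaneous skin-conductance responses per minute.
#' @param scl_scr_amp Mean response amplitude, uS.
#' @param scl_noise_sd SCL measurement-noise SD, uS.
#' @param tmp_baseline Finger temperature baseline, C, in \[20, 40\].
#' @param tmp_drift Temperature drift, C per minute.
#' @param tmp_noise_sd Smoothed temperature-noise SD, C.
#' @param missing_window_prob Probability that any given (channel, anchor)
#'   window is corrupted by a saturation artifact, in \[0, 1\].
#' @return A list of class `bst_session_spec`.
#' @examples
#' sp <- session_spec(duration_s = 240, fs = 512,
#'                    anchors = event_marks(10, 110, 230))
#' @export
session_spec <- function(duration_s = 360,
                         fs = 2048,
                         anchors = event_marks(30, 180, 350),
                         femg_envelope_mean = list(
                           corrugator = c(start = 8.15, cecum = 6.86, end = 7.23),
                           zygomaticus = c(start = 7.70, cecum = 4.82, end = 5.17)
                         ),
                         femg_envelope_sd = list(
                           corrugator = c(start = 7.72, cecum = 5.46, end = 5.87),
                           zygomaticus = c(start = 5.56, cecum = 3.42, end = 3.80)
                         ),
                         ecg_mean_bpm = 70, ecg_rr_jitter_sd = 0.03,
                         ecg_amp_mv = 1, ecg_noise_sd = 0.1,
                         ecg_wander_amp_mv = 0, ecg_wander_hz = 0.3,
                         scl_tonic = 5, scl_scr_rate = 4, scl_scr_amp = 0.3,
                         scl_noise_sd = 0.02,
                         tmp_baseline = 32, tmp_drift = 0.02,
                         tmp_noise_sd = 0.05,
                         missing_window_prob = 0) {
  spec <- list(
    duration_s = duration_s, fs = fs, anchors = anchors,
    femg_envelope_mean = femg_envelope_mean,
    femg_envelope_sd = femg_envelope_sd,
    ecg_mean_bpm = ecg_mean_bpm, ecg_rr_jitter_sd = ecg_rr_jitter_sd,
    ecg_amp_mv = ecg_amp_mv, ecg_noise_sd = ecg_noise_sd,
    ecg_wander_amp_mv = ecg_wander_amp_mv, ecg_wander_hz = ecg_wander_hz,
    scl_tonic = scl_tonic, scl_scr_rate = scl_scr_rate,
    scl_scr_amp = scl_scr_amp, scl_noise_sd = scl_noise_sd,
    tmp_baseline = tmp_baseline, tmp_drift = tmp_drift,
    tmp_noise_sd = tmp_noise_sd,
    missing_window_prob = missing_window_prob
  )
  class(spec) <- "bst_session_spec"
  validate_session_spec(spec)
}

validate_session_spec <- function(spec) {
  stopifnot(inherits(spec, "bst_session_spec"))
  if (spec$duration_s < 120) stop("duration_s must be >= 120 s.", call. = FALSE)
  if (spec$fs <= 0) stop("fs must be positive.", call. = FALSE)
  m <- spec$anchors
  if (!inherits(m, "bst_marks")) stop("anchors must be event_marks().", call. = FALSE)
  if (m$exam_start < 0 || m$exam_end > spec$duration_s) {
    stop("event marks must lie within the session duration.", call. = FALSE)
  }
  if (spec$ecg_mean_bpm < 30 || spec$ecg_mean_bpm > 200) {
    stop("ecg_mean_bpm must be in [30, 200].", call. = FALSE)
  }
  sds <- c(unlist(spec$femg_envelope_sd), spec$ecg_rr_jitter_sd,
           spec$ecg_noise_sd, spec$scl_noise_sd, spec$tmp_noise_sd)
  if (any(sds < 0)) stop("variance parameters must be >= 0.", call. = FALSE)
  if (any(unlist(spec$femg_envelope_mean) < 0)) {
    stop("fEMG envelope means must be >= 0 uV.", call. = FALSE)
  }
  if (spec$scl_tonic < 0) stop("scl_tonic must be >= 0 uS.", call. = FALSE)
  if (spec$tmp_baseline < 20 || spec$tmp_baseline > 40) {
    stop("tmp_baseline must be in [20, 40] C.", call. = FALSE)
  }
  if (spec$missing_window_prob < 0 || spec$missing_window_prob > 1) {
    stop("missing_window_prob must be in [0, 1].", call. = FALSE)
  }
  spec
}

# Segment centres of the three anchor windows (cecum dropped when missing).
anchor_centres <- function(marks, window_s = 60) {
  half <- window_s / 2
  ct <- c(start = marks$exam_start + half, cecum = marks$cecum,
          end = marks$exam_end - half)
  ct[!is.na(ct)]
}

# Piecewise-linear envelope through the per-segment means, flat outside the
# first/last anchor centre.
envelope_trace <- function(t, marks, seg_means, window_s = 60) {
  ct <- anchor_centres(marks, window_s)
  mu <- seg_means[names(ct)]
  if (length(ct) == 1) return(rep(mu, length(t)))
  stats::approx(ct, mu, xout = t, rule = 2)$y
}

# Zero-mean Gaussian noise with a flat spectrum on [lo, hi] Hz and unit
# variance, synthesised by masking the FFT of white noise.
band_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  mask <- f >= lo & f <= hi
  if (!any(mask)) stop("band contains no FFT bins.", call. = FALSE)
  X[!mask] <- 0
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  y * sqrt(n / sum(mask))                    # restore unit variance
}

# Amplitude gain of the decimation + band-pass chain on flat 20-250 Hz
# noise, from the filters' digital frequency responses. Used so the
# conditioned envelope mean equals the requested uV value regardless of the
# (slight) band-edge attenuation of the analysis filters.
femg_chain_gain <- function(fs, params = NULL, analysis_fs = 512) {
  p <- cond_params(params)
  f <- seq(p$femg_band_hz[1], p$femg_band_hz[2], length.out = 401)
  pow <- rep(1, length(f))
  if (fs > analysis_fs) {
    dec <- butter_from_spec(filter_spec("lowpass", 0.8 * analysis_fs / 2, 6), fs)
    pow <- pow * Mod(digital_response(dec, f, fs))^4   # filtfilt: |H|^2 amp
  }
  bp <- butter_from_spec(filter_spec("bandpass", p$femg_band_hz, p$order),
                         analysis_fs)
  pow <- pow * Mod(digital_response(bp, f, analysis_fs))^4
  sqrt(mean(pow))
}

digital_response <- function(bf, f, fs) {
  w <- 2 * pi * f / fs
  num <- exp(-1i * outer(w, seq_along(bf$b) - 1)) %*% bf$b
  den <- exp(-1i * outer(w, seq_along(bf$a) - 1)) %*% bf$a
  as.vector(num / den)
}

#' Synthesise a facial-EMG channel
#'
#' Band-limited (20-250 Hz) Gaussian noise amplitude-modulated by a smooth
#' positive envelope whose segment-wise mean equals the spec's envelope mean
#' for the site, interpolated linearly between the three anchor segments.
#' The envelope parameter lives on the conditioned (rectified-envelope)
#' scale: the generator divides by `sqrt(pi/2)` (the Rayleigh mean of a
#' Gaussian's analytic magnitude) and by the analysis chain's band gain, so
#' the conditioning pipeline recovers the requested uV value without bias.
#'
#' @param spec A [session_spec()].
#' @param site `"corrugator"` or `"zygomaticus"`.
#' @param rng A [rng_stream()].
#' @param envelope_mean Optional length-3 override (start, cecum, end) of the
#'   spec's per-segment means for this site.
#' @return A list: `signal` (the raw channel, uV) and `envelope` (the
#'   ground-truth conditioned-scale envelope, for oracle tests).
#' @export
synth_femg <- function(spec, site = c("corrugator", "zygomaticus"), rng,
                       envelope_mean = NULL) {
  validate_session_spec(spec)
  site <- match.arg(site)
  if (spec$fs < 512) {
    stop("fs must be >= 512 Hz to carry the 20-250 Hz fEMG band.",
         call. = FALSE)
  }
  n <- round(spec$duration_s * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  mu <- envelope_mean %||% spec$femg_envelope_mean[[site]]
  if (is.null(names(mu))) names(mu) <- c("start", "cecum", "end")
  env <- envelope_trace(t, spec$anchors, mu)
  channel <- paste0("femg_", switch(site, corrugator = "corrugator",
                                    zygomaticus = "zygomaticus"))
  if (all(env == 0)) {
    sig <- signal_tbl(numeric(n), spec$fs, "uV", channel)
    return(list(signal = sig, envelope = signal_rewrap(sig, env)))
  }
  gain <- femg_chain_gain(spec$fs)
  w <- with_rng(rng, band_noise(n, spec$fs, 20, 250))
  x <- env * sqrt(2 / pi) / gain * w
  list(
    signal = signal_tbl(x, spec$fs, "uV", channel),
    envelope = signal_tbl(env, spec$fs, "uV", paste0(channel, "_envelope"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# P-QRS-T beat template as a sum of Gaussian bumps, offset in seconds from
# the R peak; amplitudes relative to a unit R wave.
ecg_template <- function(dt) {
  bump <- function(a, m, s) a * exp(-0.5 * ((dt - m) / s)^2)
  bump(0.12, -0.20, 0.030) + bump(-0.15, -0.030, 0.010) +
    bump(1.00, 0, 0.012) + bump(-0.25, 0.030, 0.012) +
    bump(0.35, 0.30, 0.060)
}

#' Synthesise an ECG channel with known beat times
#'
#' Concatenated P-QRS-T templates (sums of Gaussian bumps, unit-amplitude R
#' wave scaled to `ecg_amp_mv`) at RR intervals `60 / ecg_mean_bpm` plus
#' Gaussian jitter; any drawn RR below 0.25 s is resampled. Additive
#' Gaussian noise and an optional sinusoidal baseline wander complete the
#' channel. The exact R-peak times are returned as ground truth.
#'
#' @inheritParams synth_femg
#' @return A list: `signal` (mV) and `r_peaks` (times in seconds).
#' @export
synth_ecg <- function(spec, rng) {
  validate_session_spec(spec)
  n <- round(spec$duration_s * spec$fs)
  rr0 <- 60 / spec$ecg_mean_bpm
  peaks <- with_rng(rng, {
    tms <- numeric(0)
    t <- rr0 / 2                      # first beat half an interval in
    while (t < spec$duration_s) {
      tms <- c(tms, t)
      repeat {
        rr <- rr0 + stats::rnorm(1, 0, spec$ecg_rr_jitter_sd)
        if (rr >= 0.25) break
      }
      t <- t + rr
    }
    tms
  })
  x <- numeric(n)
  half <- 0.55                        # template support around the R peak
  for (tp in peaks) {
    i0 <- max(1L, floor((tp - half) * spec$fs) + 1L)
    i1 <- min(n, ceiling((tp + half) * spec$fs) + 1L)
    idx <- i0:i1
    x[idx] <- x[idx] + ecg_template((idx - 1) / spec$fs - tp)
  }
  x <- x * spec$ecg_amp_mv
  if (spec$ecg_noise_sd > 0) {
    x <- x + with_rng(rng, stats::rnorm(n, 0, spec$ecg_noise_sd))
  }
  if (spec$ecg_wander_amp_mv > 0) {
    x <- x + spec$ecg_wander_amp_mv *
      sin(2 * pi * spec$ecg_wander_hz * (seq_len(n) - 1) / spec$fs)
  }
  list(signal = signal_tbl(x, spec$fs, "mV", "ecg"), r_peaks = peaks)
}

#' Synthesise skin conductance and temperature channels
#'
#' `synth_scl()`: tonic level plus Poisson-arriving phasic responses (fast
#' rise, exponential decay, gamma-distributed amplitudes) plus low-amplitude
#' noise, clamped at zero so conductance is never negative.
#' `synth_tmp()`: baseline plus linear drift (`tmp_drift` C/min) plus
#' smoothed noise.
#'
#' @inheritParams synth_femg
#' @return A `bst_signal` (uS for SCL, C for TMP).
#' @export
synth_scl <- function(spec, rng) {
  validate_session_spec(spec)
  n <- round(spec$duration_s * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  x <- rep(spec$scl_tonic, n)
  with_rng(rng, {
    n_scr <- stats::rpois(1, spec$scl_scr_rate * spec$duration_s / 60)
    if (n_scr > 0) {
      onsets <- sort(stats::runif(n_scr, 0, spec$duration_s))
      amps <- stats::rgamma(n_scr, shape = 2, scale = spec$scl_scr_amp / 2)
      tau_r <- 0.75; tau_d <- 3
      for (k in seq_len(n_scr)) {
        rel <- t - onsets[k]
        on <- rel > 0 & rel < 8 * tau_d
        shp <- exp(-rel[on] / tau_d) - exp(-rel[on] / tau_r)
        peak <- max(shp)
        if (peak > 0) x[on] <- x[on] + amps[k] * shp / peak
      }
    }
    if (spec$scl_noise_sd > 0) {
      x <- x + smoothed_noise(n, spec$fs, spec$scl_noise_sd)
    }
  })
  signal_tbl(pmax(x, 0), spec$fs, "uS", "scl")
}

#' @rdname synth_scl
#' @export
synth_tmp <- function(spec, rng) {
  validate_session_spec(spec)
  n <- round(spec$duration_s * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  x <- spec$tmp_baseline + spec$tmp_drift * t / 60
  if (spec$tmp_noise_sd > 0) {
    x <- x + with_rng(rng, smoothed_noise(n, spec$fs, spec$tmp_noise_sd))
  }
  signal_tbl(x, spec$fs, "degC", "tmp")
}

# Slow noise: white noise smoothed over ~2 s and rescaled to the target SD.
smoothed_noise <- function(n, fs, sd) {
  w <- moving_average_vec(stats::rnorm(n), max(3L, as.integer(2 * fs)))
  s <- stats::sd(w)
  if (s == 0) return(numeric(n))
  w * (sd / s)
}
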
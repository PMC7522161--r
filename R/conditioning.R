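#' Butterworth filter specification
#'
#' The conditioning chains use zero-phase (forward-backward) Butterworth
#' filters throughout: 20-250 Hz band-pass for facial EMG, 4 Hz low-pass for
#' the demodulated EMG envelope, 8 Hz low-pass for skin conductance. Order
#' defaults to 4; forward-backward application doubles the effective order
#' and cancels phase so event-anchored windows are not shifted.
#'
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param corners Corner frequency in Hz; length 2 (low, high) for bandpass,
#'   length 1 for lowpass. Must lie strictly inside (0, fs/2).
#' @param order Filter order (per pass), a positive integer.
#' @param zero_phase Apply forward-backward (`TRUE`, default)?
#' @return A list of class `bst_filter_spec`.
#' @examples
#' filter_spec("bandpass", c(20, 250))
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass"), corners, order = 4,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(corners) || any(!is.finite(corners)) || any(corners <= 0)) {
    stop("`corners` must be positive finite frequencies in Hz.", call. = FALSE)
  }
  n_exp <- if (kind == "bandpass") 2L else 1L
  if (length(corners) != n_exp) {
    stop(sprintf("`%s` filter needs %d corner frequencies.", kind, n_exp),
         call. = FALSE)
  }
  if (kind == "bandpass" && corners[1] >= corners[2]) {
    stop("bandpass corners must satisfy low < high.", call. = FALSE)
  }
  if (!is.numeric(order) || length(order) != 1 || order < 1 ||
      order != round(order)) {
    stop("`order` must be a positive integer.", call. = FALSE)
  }
  structure(
    list(kind = kind, corners = as.numeric(corners), order = as.integer(order),
         zero_phase = isTRUE(zero_phase)),
    class = "bst_filter_spec"
  )
}

butter_from_spec <- function(spec, fs) {
  nyq <- fs / 2
  if (any(spec$corners >= nyq)) {
    stop(sprintf(
      "filter corner (%s Hz) at or above Nyquist (%g Hz) for fs = %g Hz.",
      paste(spec$corners, collapse = ", "), nyq, fs
    ), call. = FALSE)
  }
  w <- spec$corners / nyq
  if (spec$kind == "bandpass") {
    signal::butter(spec$order, w, type = "pass")
  } else {
    signal::butter(spec$order, w, type = "low")
  }
}

#' Apply a Butterworth filter to a signal
#'
#' Linear filtering with the design in `spec`. The default zero-phase mode
#' realises the forward-backward response exactly in the frequency domain:
#' the signal's FFT is multiplied by the squared Butterworth magnitude
#' `|H(w)|^2` (the transfer function a forward-backward pass converges to),
#' so passband gains match the analytic magnitude to machine precision and
#' no phase distortion shifts event-anchored windows. Boundary behaviour is
#' circular, which is why analysis windows are always interior. With
#' `zero_phase = FALSE` a single causal pass is run instead. Length,
#' sampling rate and unit are preserved; the operation is homogeneous:
#' filtering `k * x` returns `k *` the filtered `x`.
#'
#' @param s A [signal_tbl()] signal.
#' @param spec A [filter_spec()].
#' @return The filtered `bst_signal`.
#' @examples
#' s <- signal_tbl(sin(2 * pi * 100 * seq(0, 2, by = 1 / 512)), fs = 512)
#' f <- apply_filter(s, filter_spec("bandpass", c(20, 250)))
#' @export
apply_filter <- function(s, spec) {
  assert_signal(s)
  stopifnot(inherits(spec, "bst_filter_spec"))
  fs <- signal_fs(s)
  y <- if (spec$zero_phase) {
    fft_zero_phase(s$value, spec, fs)
  } else {
    bf <- butter_from_spec(spec, fs)
    causal_filter(bf$b, bf$a, s$value)
  }
  signal_rewrap(s, y)
}

# Zero-phase filtering in the frequency domain: multiply the spectrum by
# |H|^2 of the Butterworth design. The magnitude vector is cached per
# (filter, fs, n) since pipelines filter many equally long channels.
.mag_cache <- new.env(parent = emptyenv())

fft_zero_phase <- function(x, spec, fs) {
  n <- length(x)
  key <- paste(spec$kind, paste(spec$corners, collapse = "-"), spec$order,
               fs, n, sep = "|")
  mag2 <- .mag_cache[[key]]
  if (is.null(mag2)) {
    bf <- butter_from_spec(spec, fs)
    w <- 2 * pi * (seq_len(n) - 1) / n          # digital rad/sample, 0..2pi
    mag2 <- Mod(polyval_unit_circle(bf$b, w) /
                  polyval_unit_circle(bf$a, w))^2
    if (length(ls(.mag_cache)) > 32) rm(list = ls(.mag_cache),
                                        envir = .mag_cache)
    .mag_cache[[key]] <- mag2
  }
  Re(stats::fft(stats::fft(x) * mag2, inverse = TRUE)) / n
}

# Evaluate a polynomial in z^-1 at e^{iw} by Horner recursion.
polyval_unit_circle <- function(coef, w) {
  z <- exp(-1i * w)
  acc <- rep(coef[length(coef)] + 0i, length(w))
  for (k in rev(seq_len(length(coef) - 1))) {
    acc <- acc * z + coef[k]
  }
  acc
}

# Single causal IIR pass with zero initial conditions (direct form).
causal_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  xp <- c(numeric(nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb - 1 + seq_along(x)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Downsample a signal by an integer factor
#'
#' Recordings are acquired at 2048 Hz and analysed at 512 Hz. The decimator
#' low-pass filters at 0.8 x the target Nyquist (6th-order Butterworth,
#' zero-phase, so DC gain is exactly 1) and then keeps every `factor`-th
#' sample starting from the first, giving `ceiling(n / factor)` samples.
#'
#' @param s A [signal_tbl()] signal.
#' @param target_fs Target sampling rate; `fs(s)` must be an integer
#'   multiple of it.
#' @return The decimated `bst_signal` at `target_fs`.
#' @examples
#' s <- signal_tbl(rnorm(8192), fs = 2048)
#' nrow(decimate_signal(s, 512)) # 2048
#' @export
decimate_signal <- function(s, target_fs) {
  assert_signal(s)
  fs <- signal_fs(s)
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop(sprintf(
      "fs (%g Hz) must be an integer multiple of target_fs (%g Hz); got factor %g.",
      fs, target_fs, factor
    ), call. = FALSE)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(s)
  aa <- filter_spec("lowpass", 0.8 * target_fs / 2, order = 6)
  y <- fft_zero_phase(s$value, aa, fs)
  keep <- seq(1L, length(y), by = factor)
  signal_tbl(y[keep], fs = target_fs, unit = signal_unit(s),
             channel = signal_channel(s), t0 = s$time_s[1])
}

#' Hilbert envelope (analytic-signal magnitude)
#'
#' Demodulates the amplitude of an oscillatory signal: the analytic signal
#' is formed in the frequency domain (positive frequencies doubled, negative
#' zeroed) and its modulus returned. For `A * sin(2 pi f t)` the interior of
#' the envelope is `A`; the first and last second carry edge effects, which
#' is why analysis windows are cut well inside the recording.
#'
#' @param s A [signal_tbl()] signal of length >= 2.
#' @return A non-negative `bst_signal` of the same length and rate.
#' @export
hilbert_envelope <- function(s) {
  assert_signal(s)
  x <- s$value
  n <- length(x)
  if (n < 2) stop("need at least 2 samples for an analytic signal.", call. = FALSE)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(h * stats::fft(x), inverse = TRUE) / n
  signal_rewrap(s, Mod(analytic))
}

#' Centred moving average
#'
#' Smooths with a centred boxcar of `n` samples; at the edges the window
#' shrinks to the available samples, so constants are preserved exactly and
#' the output has the input's length. Used with `n = 67` for ECG and
#' `n = 513` for skin temperature at 512 Hz.
#'
#' @param s A [signal_tbl()] signal.
#' @param n Window length in samples, `1 <= n <= length`.
#' @return The smoothed `bst_signal`.
#' @export
moving_average <- function(s, n) {
  assert_signal(s)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer number of samples.", call. = FALSE)
  }
  len <- nrow(s)
  if (n > len) stop("`n` exceeds the signal length.", call. = FALSE)
  signal_rewrap(s, moving_average_vec(s$value, as.integer(n)))
}

# O(N) centred boxcar with shrink-at-edges, via cumulative sums.
moving_average_vec <- function(x, n) {
  len <- length(x)
  hl <- (n - 1L) %/% 2L          # samples to the left of centre
  hr <- n - 1L - hl              # samples to the right
  cs <- c(0, cumsum(x))
  i <- seq_len(len)
  lo <- pmax(i - hl, 1L)
  hi <- pmin(i + hr, len)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Remove the least-squares linear trend
#'
#' Fits `value ~ a + b * t` by ordinary least squares and returns the
#' residuals, which have zero mean and zero slope. Applied to the smoothed
#' ECG trace.
#'
#' @param s A [signal_tbl()] signal of length >= 2.
#' @return The detrended `bst_signal`.
#' @export
detrend_linear <- function(s) {
  assert_signal(s)
  n <- nrow(s)
  if (n < 2) stop("need at least 2 samples to detrend.", call. = FALSE)
  t <- s$time_s - mean(s$time_s)
  x <- s$value
  b <- sum(t * (x - mean(x))) / sum(t * t)
  signal_rewrap(s, x - mean(x) - b * t)
}

#' Per-modality conditioning chains
#'
#' The four chains applied to 512 Hz channels before feature extraction:
#' * `condition_femg()`: 20-250 Hz band-pass, Hilbert-envelope magnitude,
#'   4 Hz low-pass — a slow non-negative EMG amplitude envelope in uV
#'   (the final low-pass can undershoot slightly near sharp bursts).
#' * `condition_scl()`: 8 Hz low-pass of the skin conductance level.
#' * `condition_ecg()`: 67-sample moving average, then linear detrend.
#' * `condition_tmp()`: 513-sample moving average of finger temperature.
#'
#' Corner frequencies and window lengths come from `params` so a study can
#' tune them; defaults are [pipeline_config()]'s.
#'
#' @param s A [signal_tbl()] channel at the analysis rate (512 Hz).
#' @param params A [pipeline_config()] (or its `conditioning` sub-list).
#' @return The conditioned `bst_signal`.
#' @examples
#' raw <- synth_femg(session_spec(duration_s = 120), site = "zygomaticus",
#'                   rng = rng_stream(1))
#' env <- condition_femg(decimate_signal(raw$signal, 512))
#' @name conditioning-chains
NULL

cond_params <- function(params) {
  if (is.null(params)) return(pipeline_config()$conditioning)
  if (!is.null(params$conditioning)) params$conditioning else params
}

#' @rdname conditioning-chains
#' @export
condition_femg <- function(s, params = NULL) {
  p <- cond_params(params)
  s |>
    apply_filter(filter_spec("bandpass", p$femg_band_hz, order = p$order)) |>
    hilbert_envelope() |>
    apply_filter(filter_spec("lowpass", p$femg_envelope_lp_hz, order = p$order))
}

#' @rdname conditioning-chains
#' @export
condition_scl <- function(s, params = NULL) {
  p <- cond_params(params)
  apply_filter(s, filter_spec("lowpass", p$scl_lp_hz, order = p$order))
}

#' @rdname conditioning-chains
#' @export
condition_ecg <- function(s, params = NULL) {
  p <- cond_params(params)
  detrend_linear(moving_average(s, p$ecg_ma_samples))
}

#' @rdname conditioning-chains
#' @export
condition_tmp <- function(s, params = NULL) {
  p <- cond_params(params)
  moving_average(s, p$tmp_ma_samples)
}
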
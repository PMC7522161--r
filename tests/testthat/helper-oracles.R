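# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Analytic digital Butterworth power response (bilinear transform with
# frequency warping). Returns |H(f)|^2 of a single pass; a zero-phase
# application has gain |H|^2 on amplitude, i.e. this value.
butter_mag_sq <- function(kind, corners, order, f, fs) {
  warp <- function(freq) tan(pi * freq / fs)
  W <- warp(f)
  if (kind == "lowpass") {
    Wc <- warp(corners[1])
    1 / (1 + (W / Wc)^(2 * order))
  } else {
    Wl <- warp(corners[1]); Wh <- warp(corners[2])
    ratio <- (W^2 - Wl * Wh) / (W * (Wh - Wl))
    1 / (1 + ratio^(2 * order))
  }
}

# Steady-state amplitude of a filtered unit sinusoid, measured on the
# interior of the output.
measured_gain <- function(freq, spec, fs = 512, dur = 8) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  s <- biostress::signal_tbl(sin(2 * pi * freq * t), fs)
  y <- biostress::apply_filter(s, spec)$value
  core <- y[round(length(y) * 0.25):round(length(y) * 0.75)]
  tt <- t[round(length(y) * 0.25):round(length(y) * 0.75)]
  # least-squares amplitude of the sinusoid at `freq` (phase-free)
  a <- 2 * mean(core * sin(2 * pi * freq * tt))
  b <- 2 * mean(core * cos(2 * pi * freq * tt))
  sqrt(a^2 + b^2)
}

# Brute-force Mann-Whitney one-sided ("first group less") p by enumerating
# every labelling of the pooled sample.
enum_u_p_less <- function(a, b) {
  n <- length(a)
  pool <- c(a, b)
  N <- length(pool)
  r <- rank(pool)
  u_of <- function(ix) sum(r[ix]) - n * (n + 1) / 2
  uobs <- u_of(seq_len(n))
  cmb <- utils::combn(N, n)
  us <- apply(cmb, 2, u_of)
  mean(us <= uobs + 1e-9)
}

# Match detected peak times to ground truth within a tolerance (greedy,
# one-to-one); returns sensitivity, positive predictivity and F1.
match_peaks <- function(detected, truth, tol = 0.075) {
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol)
    if (length(j)) {
      used[j[which.min(abs(truth[j] - d))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  sens <- if (length(truth)) tp / (tp + fn) else NA_real_
  ppv <- if (length(detected)) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) 0 else {
    2 * sens * ppv / (sens + ppv)
  }
  list(sens = sens, ppv = ppv, f1 = f1, tp = tp, fp = fp, fn = fn)
}

# Small 512 Hz session spec used widely in the tests.
quick_spec <- function(..., duration_s = 240, fs = 512,
                       anchors = biostress::event_marks(10, 110, 230)) {
  biostress::session_spec(duration_s = duration_s, fs = fs,
                          anchors = anchors, ...)
}
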
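#' Hamilton-Tompkins QRS detection
#'
#' Detects R peaks on a 512 Hz ECG with the classic energy-based stages:
#' QRS-band band-pass (8-16 Hz), first difference, rectification, 80 ms
#' moving-window integration, then peak picking with adaptive signal/noise
#' thresholds (running averages of the last eight QRS and noise peak
#' heights, detection threshold `noise + 0.3125 * (signal - noise)`), a
#' 200 ms refractory period, and a search-back with half the threshold when
#' no beat is found within 1.5x the running RR average. Accepted detections
#' are refined to the local maximum of the input ECG within +/- 40 ms.
#' Thresholds adapt to the signal scale, so detection is invariant to
#' multiplying the ECG by any positive constant.
#'
#' @param s A [signal_tbl()] ECG channel, at least 5 s long.
#' @param params A [pipeline_config()] (or its `qrs` sub-list) with the
#'   detector constants.
#' @return A tibble of class `bst_peaks` with columns `time_s` and
#'   `sample` (1-based index), attribute `fs`. A zero-variance input yields
#'   zero rows.
#' @examples
#' sp <- session_spec(duration_s = 180, fs = 512,
#'                    anchors = event_marks(5, 80, 175))
#' ec <- synth_ecg(sp, rng_stream(1))
#' pk <- detect_r_peaks(ec$signal)
#' @export
detect_r_peaks <- function(s, params = NULL) {
  assert_signal(s)
  fs <- signal_fs(s)
  p <- if (is.null(params)) pipeline_config()$qrs
       else if (!is.null(params$qrs)) params$qrs else params
  x <- s$value
  n <- length(x)
  if (n < 5 * fs) stop("ECG must be at least 5 s long.", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(new_peak_train(numeric(0), integer(0), fs))
  }
  # --- energy transform ---------------------------------------------------
  y <- fft_zero_phase(x, filter_spec("bandpass", p$band_hz, p$band_order), fs)
  d <- c(0, diff(y))
  r <- abs(d)
  wi <- max(3L, as.integer(round(p$integration_ms / 1000 * fs)))
  e <- moving_average_vec(r, wi)
  # --- candidate peaks: local maxima of the energy signal ------------------
  is_peak <- e > c(-Inf, e[-n]) & e >= c(e[-1], -Inf) & e > 0
  cand <- which(is_peak)
  if (!length(cand)) return(new_peak_train(numeric(0), integer(0), fs))
  refr <- as.integer(round(p$refractory_s * fs))
  # initial levels from the first two seconds of energy
  init <- e[seq_len(min(n, as.integer(2 * fs)))]
  spk <- max(init) * 0.7
  npk <- mean(init) * 0.5
  qrs <- integer(0)
  thr <- function() npk + p$threshold_coef * (spk - npk)
  accept <- function(i) {
    spk <<- 0.875 * spk + 0.125 * e[i]
    qrs <<- c(qrs, i)
  }
  for (i in cand) {
    last <- if (length(qrs)) qrs[length(qrs)] else -Inf
    if ((i - last) < refr) {
      # band-pass ringing can put a sidelobe just before the true QRS
      # maximum: inside the refractory window the larger peak wins.
      if (e[i] > e[last]) {
        qrs[length(qrs)] <- i
        spk <- 0.875 * spk + 0.125 * e[i]
      } else {
        npk <- 0.875 * npk + 0.125 * e[i]
      }
      next
    }
    if (e[i] > thr()) {
      accept(i)
    } else {
      npk <- 0.875 * npk + 0.125 * e[i]
      # search-back: expected beat overdue?
      if (length(qrs) >= 3) {
        rr_hist <- utils::tail(diff(qrs), 8) / fs
        if ((i - qrs[length(qrs)]) / fs >
              p$searchback_factor * mean(rr_hist)) {
          seg <- cand[cand > qrs[length(qrs)] + refr & cand <= i]
          if (length(seg)) {
            j <- seg[which.max(e[seg])]
            if (e[j] > 0.5 * thr()) accept(j)
          }
        }
      }
    }
  }
  if (!length(qrs)) return(new_peak_train(numeric(0), integer(0), fs))
  # --- refine to the local raw-signal maximum ------------------------------
  half <- as.integer(round(p$refine_ms / 1000 * fs))
  ref <- vapply(qrs, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce refractory after refinement (keep the larger peak)
  keep <- rep(TRUE, length(ref))
  last <- 1L
  for (k in seq_along(ref)[-1]) {
    if (ref[k] - ref[last] < refr) {
      if (x[ref[k]] > x[ref[last]]) { keep[last] <- FALSE; last <- k }
      else keep[k] <- FALSE
    } else last <- k
  }
  ref <- ref[keep]
  new_peak_train((ref - 1) / fs, ref, fs)
}

new_peak_train <- function(time_s, sample, fs) {
  out <- tibble::tibble(time_s = time_s, sample = as.integer(sample))
  attr(out, "fs") <- fs
  class(out) <- c("bst_peaks", class(out))
  out
}

#' Heart rate from a peak train over a window
#'
#' Beats per minute over `[from, to)` seconds: `60 * k / T`, where `k` is
#' the number of RR intervals fully inside the window and `T` their summed
#' duration. With fewer than two peaks in the window the rate is undefined
#' and `NA` is returned.
#'
#' @param peaks A `bst_peaks` from [detect_r_peaks()].
#' @param from,to Window bounds in seconds (half-open).
#' @return Beats/min, or `NA_real_`.
#' @export
heart_rate_bpm <- function(peaks, from, to) {
  stopifnot(inherits(peaks, "bst_peaks"))
  t <- peaks$time_s[peaks$time_s >= from & peaks$time_s < to]
  if (length(t) < 2) return(NA_real_)
  rr <- diff(t)
  60 * length(rr) / sum(rr)
}
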
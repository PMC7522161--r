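#' Anchor-window sample bounds
#'
#' Converts an event mark to the half-open, 0-based sample range of its
#' one-minute analysis window: `[t0, t0 + 60)` at examination start,
#' `[tc - 30, tc + 30)` around the cecum, `[tend - 60, tend)` at
#' examination end. Mark times are rounded down to the nearest sample.
#'
#' @param marks An [event_marks()].
#' @param anchor `"start"`, `"cecum"` or `"end"`.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds (default 60).
#' @param n_total Total samples in the recording (bounds are checked
#'   against it when given).
#' @return Integer vector `c(a, b)`, 0-based half-open, with
#'   `b - a == window_s * fs`; or `NULL` when the cecum mark is absent.
#' @examples
#' window_bounds(event_marks(120, 600, 900), "start", fs = 512)
#' @export
window_bounds <- function(marks, anchor = c("start", "cecum", "end"), fs,
                          window_s = 60, n_total = NULL) {
  stopifnot(inherits(marks, "bst_marks"))
  anchor <- match.arg(anchor)
  wlen <- as.integer(round(window_s * fs))
  t_from <- switch(anchor,
    start = marks$exam_start,
    cecum = if (is.na(marks$cecum)) return(NULL) else marks$cecum - window_s / 2,
    end = marks$exam_end - window_s
  )
  a <- as.integer(floor(t_from * fs))
  b <- a + wlen
  if (a < 0) {
    stop(sprintf("'%s' window starts %.2f s before the recording begins.",
                 anchor, -t_from), call. = FALSE)
  }
  if (!is.null(n_total) && b > n_total) {
    stop(sprintf("'%s' window ends beyond the recording (needs sample %d of %d).",
                 anchor, b, n_total), call. = FALSE)
  }
  c(a, b)
}

#' Automated artifact screening of an analysis window
#'
#' An automated stand-in for per-window visual inspection, with explicit
#' criteria (all configurable via `pipeline_config()$windowing$qc`):
#' * **discarded / "saturation"** — more than 5% of samples within 1% of
#'   the channel's recorded min/max rails;
#' * **discarded / "flat"** — the excerpt's range is below `flat_eps`;
#' * **discarded / "outlier"** — samples beyond `k = 8` robust SDs
#'   (median +/- k * 1.4826 * MAD of the whole channel) for more than 10%
#'   of the window;
#' * **corrected / "spikes"** — a small fraction of outlying samples
#'   (up to the discard threshold) is replaced by linear interpolation;
#' * **kept** otherwise.
#'
#' Corruption can only move a window down the ordering kept -> corrected ->
#' discarded, never up.
#'
#' @param values Numeric excerpt (one window of one channel).
#' @param channel_stats Named list with the whole channel's `lo`, `hi`,
#'   `med`, `mad` (see [channel_stats()]).
#' @param criteria QC thresholds (default `pipeline_config()$windowing$qc`).
#' @return A list: `status` (`"kept"|"corrected"|"discarded"`), `reason`,
#'   `values` (corrected when applicable), `spike_idx`.
#' @export
screen_window <- function(values, channel_stats, criteria = NULL) {
  qc <- criteria %||% pipeline_config()$windowing$qc
  n <- length(values)
  cs <- channel_stats
  span <- cs$hi - cs$lo
  tol <- qc$rail_tol_frac * span
  sat_frac <- if (span > 0) {
    mean(values >= cs$hi - tol | values <= cs$lo + tol)
  } else 1
  if (sat_frac > qc$saturation_frac) {
    return(list(status = "discarded", reason = "saturation", values = values,
                spike_idx = integer(0)))
  }
  if (diff(range(values)) < qc$flat_eps) {
    return(list(status = "discarded", reason = "flat", values = values,
                spike_idx = integer(0)))
  }
  lim <- qc$outlier_k * 1.4826 * cs$mad
  out_idx <- if (cs$mad > 0) which(abs(values - cs$med) > lim) else integer(0)
  frac <- length(out_idx) / n
  if (frac > qc$outlier_frac) {
    return(list(status = "discarded", reason = "outlier", values = values,
                spike_idx = out_idx))
  }
  if (length(out_idx) > 0) {
    return(list(status = "corrected", reason = "spikes",
                values = interpolate_spikes(values, out_idx),
                spike_idx = out_idx))
  }
  list(status = "kept", reason = "clean", values = values,
       spike_idx = integer(0))
}

#' @rdname screen_window
#' @param x Full channel samples.
#' @details `channel_stats()` estimates the channel's recording rails as the
#'   0.1% / 99.9% sample quantiles rather than the literal min/max: a
#'   clipped plateau still sits on its rail after anti-alias filtering,
#'   whereas the literal extremum is inflated by filter ringing at the
#'   plateau edges.
#' @export
channel_stats <- function(x) {
  n <- length(x)
  s <- sort(x)
  qat <- function(p) {            # type-7 quantile on the sorted vector
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  med <- qat(0.5)
  list(lo = qat(0.001), hi = qat(0.999), med = med,
       mad = stats::median(abs(x - med)))
}

# Replace flagged samples by linear interpolation over their neighbours.
interpolate_spikes <- function(values, idx) {
  good <- setdiff(seq_along(values), idx)
  if (length(good) < 2) return(values)
  values[idx] <- stats::approx(good, values[good], xout = idx, rule = 2)$y
  values
}

#' Cut and screen all analysis windows of a processed session
#'
#' For every channel and every available anchor, extracts the one-minute
#' window from the raw (analysis-rate) channel, screens it with
#' [screen_window()], and — when kept or corrected — carries the matching
#' excerpt of the conditioned channel (with spike samples interpolated at
#' the positions found in the raw excerpt) for feature extraction.
#'
#' @param raw,conditioned `bst_recording`s at the analysis rate with the
#'   same channels and length (`conditioned` holds the per-modality
#'   conditioned traces).
#' @param config A [pipeline_config()].
#' @return A tibble with one row per (channel, anchor): `channel`, `anchor`,
#'   `a`, `b` (0-based half-open sample bounds), `qc`, `qc_reason`, and a
#'   `data` list-column holding the conditioned excerpt (`NULL` when
#'   discarded).
#' @export
cut_windows <- function(raw, conditioned, config = pipeline_config()) {
  stopifnot(inherits(raw, "bst_recording"), inherits(conditioned, "bst_recording"))
  fs <- recording_fs(raw)
  marks <- recording_marks(raw)
  window_s <- config$windowing$window_s
  qc <- config$windowing$qc
  chans <- recording_channels(raw)
  anchors <- c("start", "cecum", "end")
  rows <- list()
  for (ch in chans) {
    cs <- channel_stats(raw[[ch]])
    for (an in anchors) {
      b <- window_bounds(marks, an, fs, window_s, n_total = nrow(raw))
      if (is.null(b)) next
      idx <- (b[1] + 1L):b[2]
      scr <- screen_window(raw[[ch]][idx], cs, qc)
      dat <- if (scr$status == "discarded") NULL else {
        v <- conditioned[[ch]][idx]
        if (length(scr$spike_idx)) v <- interpolate_spikes(v, scr$spike_idx)
        v
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        channel = ch, anchor = an, a = b[1], b = b[2],
        qc = scr$status, qc_reason = scr$reason, data = list(dat)
      )
    }
  }
  dplyr::bind_rows(rows)
}
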
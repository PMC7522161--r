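#' Multi-channel session recordings
#'
#' A `bst_recording` is a wide tibble — `time_s` plus one column per channel
#' (`femg_corrugator`, `femg_zygomaticus`, `ecg`, `scl`, `tmp`) — with
#' attributes: `fs` (Hz), `units` (named character), `marks`
#' ([event_marks()]), and `meta` (patient id, group, sex). Simulated
#' recordings additionally carry `truth` (ground-truth envelopes, R-peak
#' times and the list of windows flagged for artifact injection).
#'
#' @param data Tibble with `time_s` and channel columns.
#' @param fs Sampling rate, Hz.
#' @param units Named character vector, one unit per channel column.
#' @param marks An [event_marks()].
#' @param meta Named list: `patient_id`, `group`, `sex`.
#' @param truth Optional ground-truth list (simulated sessions).
#' @return A tibble of class `bst_recording`.
#' @export
new_recording <- function(data, fs, units, marks, meta = list(), truth = NULL) {
  stopifnot(is.data.frame(data), "time_s" %in% names(data))
  chans <- setdiff(names(data), "time_s")
  if (!all(chans %in% names(units))) {
    stop("every channel column needs a unit.", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  attr(out, "fs") <- fs
  attr(out, "units") <- units[chans]
  attr(out, "marks") <- marks
  attr(out, "meta") <- meta
  attr(out, "truth") <- truth
  class(out) <- c("bst_recording", class(out))
  out
}

#' @rdname new_recording
#' @param rec A `bst_recording`.
#' @export
recording_fs <- function(rec) attr(rec, "fs")

#' @rdname new_recording
#' @export
recording_channels <- function(rec) setdiff(names(rec), "time_s")

#' @rdname new_recording
#' @export
recording_marks <- function(rec) attr(rec, "marks")

#' @rdname new_recording
#' @export
recording_meta <- function(rec) attr(rec, "meta")

#' @rdname new_recording
#' @export
recording_units <- function(rec) attr(rec, "units")

# Pull one channel out as a bst_signal.
recording_signal <- function(rec, channel) {
  stopifnot(channel %in% recording_channels(rec))
  signal_tbl(rec[[channel]], recording_fs(rec),
             unit = recording_units(rec)[[channel]], channel = channel)
}

#' @export
print.bst_recording <- function(x, ...) {
  meta <- recording_meta(x)
  cat(sprintf(
    "# bst_recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
    length(recording_channels(x)), nrow(x), recording_fs(x),
    nrow(x) / recording_fs(x)
  ))
  if (length(meta)) {
    cat(sprintf("# patient %s, group %s, sex %s\n",
                meta$patient_id %||% "?", meta$group %||% "?",
                meta$sex %||% "?"))
  }
  m <- recording_marks(x)
  cat(sprintf("# marks: start %.1f s, cecum %s, end %.1f s\n", m$exam_start,
              if (is.na(m$cecum)) "not reached" else sprintf("%.1f s", m$cecum),
              m$exam_end))
  NextMethod()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bst_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
                              names_to = "channel", values_to = "value")
  marks <- recording_marks(object)
  mk <- tibble::tibble(
    mark = c("exam_start", "cecum", "exam_end"),
    time_s = c(marks$exam_start, marks$cecum, marks$exam_end)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::geom_vline(
      data = mk[!is.na(mk$time_s), ],
      ggplot2::aes(xintercept = .data$time_s), linetype = "dashed",
      colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Generate one synthetic session
#'
#' Draws all requested channels from a [session_spec()], shares the sampling
#' rate and duration across channels, and injects saturation artifacts
#' (rail-to-rail clipping over a contiguous fifth of the window) into any
#' (channel, anchor) window flagged with probability `missing_window_prob`,
#' so the quality screener sees realistic corruption. Ground truth
#' (envelopes, R-peak times, flagged windows) is attached for oracle tests.
#'
#' @param spec A [session_spec()].
#' @param rng A [rng_stream()].
#' @param meta Named list (`patient_id`, `group`, `sex`) carried on the
#'   recording.
#' @param channels Channels to generate (default all five).
#' @return A `bst_recording`.
#' @examples
#' rec <- generate_session(session_spec(duration_s = 240, fs = 512,
#'                                      anchors = event_marks(10, 110, 230)),
#'                         rng_stream(7))
#' @export
generate_session <- function(spec, rng,
                             meta = list(patient_id = "p1", group = "control",
                                         sex = "female"),
                             channels = c("femg_corrugator",
                                          "femg_zygomaticus", "ecg", "scl",
                                          "tmp")) {
  validate_session_spec(spec)
  channels <- match.arg(channels, several.ok = TRUE)
  n <- round(spec$duration_s * spec$fs)
  cols <- list(time_s = (seq_len(n) - 1) / spec$fs)
  truth <- list(envelopes = list(), r_peaks = NULL, flagged = NULL)
  units <- c(femg_corrugator = "uV", femg_zygomaticus = "uV", ecg = "mV",
             scl = "uS", tmp = "degC")
  for (ch in channels) {
    if (ch %in% c("femg_corrugator", "femg_zygomaticus")) {
      site <- sub("femg_", "", ch)
      fe <- synth_femg(spec, site, rng)
      cols[[ch]] <- fe$signal$value
      truth$envelopes[[ch]] <- fe$envelope$value
    } else if (ch == "ecg") {
      ec <- synth_ecg(spec, rng)
      cols[[ch]] <- ec$signal$value
      truth$r_peaks <- ec$r_peaks
    } else if (ch == "scl") {
      cols[[ch]] <- synth_scl(spec, rng)$value
    } else if (ch == "tmp") {
      cols[[ch]] <- synth_tmp(spec, rng)$value
    }
  }
  # flag windows for artifact injection
  anchors <- names(anchor_centres(spec$anchors))
  grid <- expand.grid(channel = channels, anchor = anchors,
                      stringsAsFactors = FALSE)
  flag <- with_rng(rng, stats::runif(nrow(grid)) < spec$missing_window_prob)
  flagged <- tibble::as_tibble(grid[flag, , drop = FALSE])
  for (k in seq_len(nrow(flagged))) {
    ch <- flagged$channel[k]
    b <- window_bounds(spec$anchors, flagged$anchor[k], spec$fs, n_total = n)
    idx <- (b[1] + 1L):b[2]
    seg <- idx[seq.int(round(0.4 * length(idx)), round(0.6 * length(idx)))]
    rail <- max(abs(cols[[ch]][is.finite(cols[[ch]])]))
    if (rail == 0) rail <- 1
    cols[[ch]][seg] <- rail
  }
  new_recording(tibble::as_tibble(cols), fs = spec$fs, units = units,
                marks = spec$anchors, meta = meta,
                truth = c(truth, list(flagged = flagged)))
}

#' Cohort specification and generation
#'
#' `cohort_spec()` encodes the two-arm design: `n_control` patients with
#' standard care and `n_music` with self-chosen music, sharing a base
#' [session_spec()]. Per patient, per fEMG site and per anchor segment, the
#' envelope mean is drawn from a Gamma distribution moment-matched to the
#' base spec's (mean, between-patient SD); in the music arm the means are
#' first multiplied by `music_femg_scale` (scalar, or length 3 for
#' start/cecum/end). Heart rate, tonic conductance and temperature baseline
#' also vary between patients. `generate_cohort()` is fully reproducible
#' from `seed`.
#'
#' @param n_control,n_music Patients per arm (>= 1).
#' @param base A [session_spec()] holding the control-arm parameters.
#' @param music_femg_scale Multiplier (> 0) applied to fEMG envelope means
#'   in the music arm; 1 simulates the null of no music effect.
#' @param cecum_missing_prob Probability a session never reaches the cecum
#'   (its cecum window is then absent), as cecal intubation occasionally
#'   fails.
#' @param seed Integer seed for the whole cohort.
#' @param channels Channels to generate per session.
#' @return `cohort_spec()`: a list of class `bst_cohort_spec`.
#'   `generate_cohort()`: a tibble with one row per patient — `patient_id`,
#'   `group`, `sex`, and a `recording` list-column of `bst_recording`s.
#' @examples
#' coh <- generate_cohort(cohort_spec(
#'   n_control = 2, n_music = 2, seed = 1,
#'   base = session_spec(duration_s = 240, fs = 512,
#'                       anchors = event_marks(10, 110, 230))
#' ))
#' @export
cohort_spec <- function(n_control = 98, n_music = 98, base = session_spec(),
                        music_femg_scale = 1, cecum_missing_prob = 9 / 196,
                        seed = 1L) {
  if (n_control < 1 || n_music < 1) {
    stop("each arm needs at least one patient.", call. = FALSE)
  }
  if (any(music_femg_scale <= 0)) {
    stop("music_femg_scale must be > 0.", call. = FALSE)
  }
  if (!length(music_femg_scale) %in% c(1L, 3L)) {
    stop("music_femg_scale must have length 1 or 3.", call. = FALSE)
  }
  validate_session_spec(base)
  structure(
    list(n_control = as.integer(n_control), n_music = as.integer(n_music),
         base = base, music_femg_scale = music_femg_scale,
         cecum_missing_prob = cecum_missing_prob, seed = as.integer(seed)),
    class = "bst_cohort_spec"
  )
}

# Gamma draw moment-matched to (mean, sd); degenerate at the mean when a
# moment is zero.
rgamma_ms <- function(n, mean, sd) {
  if (mean <= 0 || sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

#' @rdname cohort_spec
#' @param cohort A `bst_cohort_spec`.
#' @export
generate_cohort <- function(cohort,
                            channels = c("femg_corrugator",
                                         "femg_zygomaticus", "ecg", "scl",
                                         "tmp")) {
  stopifnot(inherits(cohort, "bst_cohort_spec"))
  root <- rng_stream(cohort$seed)
  n_tot <- cohort$n_control + cohort$n_music
  groups <- rep(c("control", "music"), c(cohort$n_control, cohort$n_music))
  scale3 <- rep(cohort$music_femg_scale, length.out = 3)
  sessions <- vector("list", n_tot)
  ids <- sprintf("p%03d", seq_len(n_tot))
  sexes <- character(n_tot)
  for (i in seq_len(n_tot)) {
    rng <- rng_child(root, i)
    base <- cohort$base
    draw <- with_rng(rng, {
      list(
        sex = if (stats::runif(1) < 0.515) "male" else "female",
        cecum_missed = stats::runif(1) < cohort$cecum_missing_prob,
        bpm = min(200, max(30, stats::rnorm(1, base$ecg_mean_bpm, 8))),
        tonic = max(0.05, stats::rnorm(1, base$scl_tonic, base$scl_tonic / 3)),
        baseline = min(40, max(20, stats::rnorm(1, base$tmp_baseline, 1.2)))
      )
    })
    # per-site, per-segment envelope means (gamma, moment-matched)
    mult <- if (groups[i] == "music") scale3 else c(1, 1, 1)
    env <- base$femg_envelope_mean
    for (site in names(env)) {
      mu <- base$femg_envelope_mean[[site]] * mult
      sd <- base$femg_envelope_sd[[site]]
      env[[site]] <- with_rng(rng, {
        vapply(seq_along(mu), function(k) rgamma_ms(1, mu[k], sd[k]),
               numeric(1))
      })
      names(env[[site]]) <- names(mu)
    }
    spec_i <- base
    spec_i$femg_envelope_mean <- env
    spec_i$ecg_mean_bpm <- draw$bpm
    spec_i$scl_tonic <- draw$tonic
    spec_i$tmp_baseline <- draw$baseline
    if (draw$cecum_missed) spec_i$anchors$cecum <- NA_real_
    sexes[i] <- draw$sex
    sessions[[i]] <- generate_session(
      spec_i, rng,
      meta = list(patient_id = ids[i], group = groups[i], sex = draw$sex),
      channels = channels
    )
  }
  tibble::tibble(patient_id = ids, group = groups, sex = sexes,
                 recording = sessions)
}
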
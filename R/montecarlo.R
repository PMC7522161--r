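#' Monte-Carlo rejection rate of the one-sided fEMG comparison
#'
#' Repeatedly simulates two-arm cohorts and reports how often the
#' pre-declared one-sided Mann-Whitney test rejects at `alpha`. With
#' `music_mean == control_mean` this measures the type-I error (null
#' calibration); with the music mean below the control mean it measures
#' power.
#'
#' Two levels of simulation are available:
#' * `level = "signal"` — every patient contributes a two-minute 512 Hz
#'   fEMG channel (band-limited noise modulated by the patient's drawn
#'   envelope level) that is pushed through the package's own conditioning
#'   chain, window extraction, artifact screening and window mean before
#'   the test, i.e. the full analysis pipeline for the feature under test.
#' * `level = "feature"` — patients' window means are drawn directly from
#'   the between-patient envelope distribution (Gamma, moment-matched to
#'   the group mean/SD) and compared through [compare_groups()]. This is
#'   appropriate for power analyses: the signal-layer measurement error is
#'   a few percent of a window mean, negligible against between-patient
#'   SDs, and the signal layer's unbiasedness is established separately.
#'
#' @param n_control,n_music Patients per arm in each replicate.
#' @param control_mean,control_sd Control-arm envelope mean/SD, uV
#'   (between-patient).
#' @param music_mean,music_sd Music-arm envelope mean/SD, uV; default the
#'   control values (the null).
#' @param n_rep Number of replicate cohorts.
#' @param seed Integer seed.
#' @param alpha One-sided significance level.
#' @param level `"signal"` or `"feature"` (see Details).
#' @param site fEMG site label for the simulated channel.
#' @param config A [pipeline_config()].
#' @return A list of class `bst_mc`: `p_values` (length `n_rep`),
#'   `rejection_rate`, `alpha`, `n_rep`, `n_control`, `n_music`, `level`.
#' @examples
#' mc <- mc_rejection_rate(n_control = 10, n_music = 10, n_rep = 50,
#'                         seed = 1, level = "feature")
#' mc$rejection_rate
#' @export
mc_rejection_rate <- function(n_control = 30, n_music = 30,
                              control_mean = 7.70, control_sd = 5.56,
                              music_mean = control_mean,
                              music_sd = control_sd,
                              n_rep = 200, seed = 1L, alpha = 0.05,
                              level = c("signal", "feature"),
                              site = "zygomaticus",
                              config = pipeline_config()) {
  level <- match.arg(level)
  rng <- rng_stream(seed)
  channel <- paste0("femg_", site)
  p_values <- numeric(n_rep)
  if (level == "signal") {
    fs <- config$analysis_fs
    spec <- session_spec(duration_s = 120, fs = fs,
                         anchors = event_marks(30, NA, 119),
                         missing_window_prob = 0)
    b <- window_bounds(spec$anchors, "start", fs, config$windowing$window_s)
    idx <- (b[1] + 1L):b[2]
    qc <- config$windowing$qc
    one_mean <- function(mu, sd, r) {
      m_i <- with_rng(r, rgamma_ms(1, mu, sd))
      ov <- c(start = m_i, cecum = m_i, end = m_i)
      fe <- synth_femg(spec, site, r, envelope_mean = ov)
      cond <- condition_femg(fe$signal, config)
      scr <- screen_window(fe$signal$value[idx],
                           channel_stats(fe$signal$value), qc)
      v <- cond$value[idx]
      if (length(scr$spike_idx)) v <- interpolate_spikes(v, scr$spike_idx)
      window_mean(v, scr$status)
    }
    for (r in seq_len(n_rep)) {
      child <- rng_child(rng, r)
      ctl <- vapply(seq_len(n_control), function(i)
        one_mean(control_mean, control_sd, child), numeric(1))
      mus <- vapply(seq_len(n_music), function(i)
        one_mean(music_mean, music_sd, child), numeric(1))
      p_values[r] <- mann_whitney_u(mus[!is.na(mus)], ctl[!is.na(ctl)],
                                    alternative = "less")$p_one_sided
    }
  } else {
    n_tot <- n_control + n_music
    template <- tibble::tibble(
      patient_id = sprintf("p%03d", seq_len(n_tot)),
      group = rep(c("control", "music"), c(n_control, n_music)),
      sex = rep_len(c("female", "male"), n_tot),
      channel = channel, anchor = "start", unit = "uV", qc = "kept"
    )
    plan <- stats::setNames(list("less"), channel)
    for (r in seq_len(n_rep)) {
      child <- rng_child(rng, r)
      ft <- template
      ft$value <- with_rng(child, c(
        rgamma_ms(n_control, control_mean, control_sd),
        rgamma_ms(n_music, music_mean, music_sd)
      ))
      ct <- compare_groups(ft, plan = plan, alpha = alpha)
      p_values[r] <- ct$p_one_sided[ct$stratum == "all"]
    }
  }
  structure(
    list(p_values = p_values, rejection_rate = mean(p_values <= alpha),
         alpha = alpha, n_rep = n_rep, n_control = n_control,
         n_music = n_music, level = level),
    class = "bst_mc"
  )
}

#' @export
print.bst_mc <- function(x, ...) {
  cat(sprintf(
    "# Monte-Carlo (%s level, %d replicates, %d vs %d): one-sided rejection rate %.3f at alpha = %.2f\n",
    x$level, x$n_rep, x$n_control, x$n_music, x$rejection_rate, x$alpha
  ))
  invisible(x)
}

#' @rdname tidy.bst_test
#' @exportS3Method generics::glance
glance.bst_mc <- function(x, ...) {
  tibble::tibble(rejection_rate = x$rejection_rate, alpha = x$alpha,
                 n_rep = x$n_rep, n_control = x$n_control,
                 n_music = x$n_music, level = x$level)
}
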
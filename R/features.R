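#' Window mean
#'
#' The scalar feature of a kept or corrected analysis window: the
#' arithmetic mean of the conditioned excerpt, in channel units (uV for
#' fEMG, uS for SCL, degC for TMP). Discarded windows yield `NA`.
#'
#' @param values Numeric excerpt, or `NULL`.
#' @param qc QC status of the window.
#' @return A single number, or `NA_real_` for discarded windows.
#' @examples
#' window_mean(rep(5, 100), "kept") # 5
#' @export
window_mean <- function(values, qc = "kept") {
  if (identical(qc, "discarded") || is.null(values)) return(NA_real_)
  mean(values)
}

#' Process one session through the conditioning pipeline
#'
#' Decimates each channel to the analysis rate, applies the per-modality
#' conditioning chain, detects R peaks on the (raw, analysis-rate) ECG,
#' cuts and screens the anchor windows, and reduces them to features:
#' window means for fEMG/SCL/TMP and beats-per-minute for ECG.
#'
#' @param rec A `bst_recording`.
#' @param config A [pipeline_config()].
#' @return A list: `features` (tibble: patient_id, group, sex, channel,
#'   anchor, value, unit, qc), `qc` (per-window QC report incl. the ECG
#'   rows), and `peaks` (the detected `bst_peaks`).
#' @export
process_session <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "bst_recording"))
  fs0 <- recording_fs(rec)
  target <- config$analysis_fs
  chans <- recording_channels(rec)
  raw_cols <- list()
  cond_cols <- list()
  for (ch in chans) {
    s <- recording_signal(rec, ch)
    if (fs0 != target) s <- decimate_signal(s, target)
    raw_cols[[ch]] <- s$value
    cond_cols[[ch]] <- switch(
      sub("_.*", "", ch),
      femg = condition_femg(s, config)$value,
      ecg = condition_ecg(s, config)$value,
      scl = condition_scl(s, config)$value,
      tmp = condition_tmp(s, config)$value
    )
  }
  n_an <- length(raw_cols[[1]])
  tvec <- (seq_len(n_an) - 1) / target
  units <- recording_units(rec)
  marks <- recording_marks(rec)
  meta <- recording_meta(rec)
  raw_an <- new_recording(tibble::as_tibble(c(list(time_s = tvec), raw_cols)),
                          target, units, marks, meta)
  cond_an <- new_recording(tibble::as_tibble(c(list(time_s = tvec), cond_cols)),
                           target, units, marks, meta)
  wins <- cut_windows(raw_an, cond_an, config)
  peaks <- if ("ecg" %in% chans) {
    detect_r_peaks(recording_signal(raw_an, "ecg"), config)
  } else {
    new_peak_train(numeric(0), integer(0), target)
  }
  feats <- wins |>
    dplyr::rowwise() |>
    dplyr::mutate(
      value = if (.data$channel == "ecg") {
        if (.data$qc == "discarded") NA_real_ else {
          heart_rate_bpm(peaks, .data$a / target, .data$b / target)
        }
      } else {
        window_mean(.data$data[[1]] %||% NULL, .data$qc)
      },
      feature = if (.data$channel == "ecg") "bpm" else .data$channel,
      unit = if (.data$channel == "ecg") "bpm" else units[[.data$channel]]
    ) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      patient_id = meta$patient_id %||% NA_character_,
      group = meta$group %||% NA_character_,
      sex = meta$sex %||% NA_character_,
      channel = .data$feature, anchor = .data$anchor,
      value = .data$value, unit = .data$unit, qc = .data$qc
    )
  qc_report <- dplyr::mutate(
    wins[, c("channel", "anchor", "qc", "qc_reason")],
    patient_id = meta$patient_id %||% NA_character_, .before = 1
  )
  list(features = feats, qc = qc_report, peaks = peaks)
}

#' Assemble the cohort feature table
#'
#' Runs [process_session()] over every recording of a cohort and binds the
#' per-window features into one long table, ordered by (patient, channel,
#' anchor). Discarded windows contribute rows with `NA` values so per-cell
#' N in downstream comparisons reflects the screening, mirroring cohorts
#' where not every patient yields every window.
#'
#' @param cohort A tibble with `patient_id`, `group`, `sex` and a
#'   `recording` list-column, as returned by [generate_cohort()].
#' @param config A [pipeline_config()].
#' @return A list of class `bst_features`: `features` (the long tibble) and
#'   `qc` (the bound QC report).
#' @export
build_feature_table <- function(cohort, config = pipeline_config()) {
  stopifnot(is.data.frame(cohort), "recording" %in% names(cohort))
  if (anyDuplicated(cohort$patient_id)) {
    stop("duplicate patient ids in cohort.", call. = FALSE)
  }
  res <- purrr::map(cohort$recording, process_session, config = config)
  feats <- purrr::map(res, "features") |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$patient_id, .data$channel, .data$anchor)
  qc <- dplyr::bind_rows(purrr::map(res, "qc"))
  structure(list(features = feats, qc = qc), class = "bst_features")
}

#' Write / read a feature table as CSV
#'
#' Long format with a documented header (`patient_id, group, sex, channel,
#' anchor, value, unit, qc`); round-trips losslessly at full precision.
#'
#' @param ft The `features` tibble (or a `bst_features`).
#' @param path File path.
#' @return `write_feature_table()` the path, invisibly;
#'   `read_feature_table()` the tibble.
#' @export
write_feature_table <- function(ft, path) {
  if (inherits(ft, "bst_features")) ft <- ft$features
  readr::write_csv(ft, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), group = readr::col_character(),
    sex = readr::col_character(), channel = readr::col_character(),
    anchor = readr::col_character(), value = readr::col_double(),
    unit = readr::col_character(), qc = readr::col_character()
  ))
}
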
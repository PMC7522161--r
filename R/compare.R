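#' Between-group comparison table
#'
#' For every (feature channel, anchor) cell and for the strata `all`,
#' `female`, `male`, computes group means, SDs, per-cell N (patients with a
#' usable window) and the one-sided Mann-Whitney p-value in the
#' pre-declared direction — by default music below control for fEMG, SCL
#' and heart rate (the stress-reduction hypothesis) and above control for
#' finger temperature. Directions are fixed in the plan, never inferred
#' from the data. No multiple-testing adjustment is applied by default; set
#' `adjust = "holm"` to add Holm-adjusted p-values.
#'
#' @param ft A feature tibble (or `bst_features`) from
#'   [build_feature_table()].
#' @param plan Named list mapping feature channels to `"less"`, `"greater"`
#'   or `"two_sided"` (music arm relative to control). Default:
#'   `pipeline_config()$stats$directions`.
#' @param alpha Significance level for the `significant` flag.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A tibble of class `bst_comparison`: one row per (channel,
#'   anchor, stratum) with `mean_control`, `sd_control`, `n_control`,
#'   `mean_music`, `sd_music`, `n_music`, `direction`, `p_one_sided`,
#'   `significant`, `computable`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_spec(
#'   n_control = 3, n_music = 3, seed = 2,
#'   base = session_spec(duration_s = 240, fs = 512,
#'                       anchors = event_marks(10, 110, 230))
#' ))
#' compare_groups(build_feature_table(coh))
#' }
#' @export
compare_groups <- function(ft, plan = NULL, alpha = 0.05,
                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (inherits(ft, "bst_features")) ft <- ft$features
  stopifnot(all(c("patient_id", "group", "sex", "channel", "anchor", "value")
                %in% names(ft)))
  n_pat <- dplyr::n_distinct(ft$patient_id[ft$group == "control"]) >= 2 &&
    dplyr::n_distinct(ft$patient_id[ft$group == "music"]) >= 2
  if (!n_pat) stop("need at least two patients per group.", call. = FALSE)
  plan <- plan %||% pipeline_config()$stats$directions
  cells <- tidyr::expand_grid(
    channel = unique(ft$channel),
    anchor = intersect(c("start", "cecum", "end"), unique(ft$anchor)),
    stratum = c("all", "female", "male")
  )
  one_cell <- function(channel, anchor, stratum) {
    sub <- ft[ft$channel == channel & ft$anchor == anchor & !is.na(ft$value), ]
    if (stratum != "all") sub <- sub[sub$sex == stratum, ]
    ctl <- sub$value[sub$group == "control"]
    mus <- sub$value[sub$group == "music"]
    dir <- plan[[channel]] %||% "two_sided"
    ok <- length(ctl) >= 1 && length(mus) >= 1
    p <- NA_real_
    if (ok) {
      tst <- mann_whitney_u(mus, ctl, alternative = dir)
      p <- if (dir == "two_sided") tst$p_two_sided else tst$p_one_sided
    }
    tibble::tibble(
      channel = channel, anchor = anchor, stratum = stratum,
      mean_control = if (length(ctl)) mean(ctl) else NA_real_,
      sd_control = if (length(ctl) > 1) stats::sd(ctl) else NA_real_,
      n_control = length(ctl),
      mean_music = if (length(mus)) mean(mus) else NA_real_,
      sd_music = if (length(mus) > 1) stats::sd(mus) else NA_real_,
      n_music = length(mus),
      direction = dir, p_one_sided = p, computable = ok
    )
  }
  out <- purrr::pmap(cells, one_cell) |> dplyr::bind_rows()
  if (adjust == "holm") {
    out$p_adjusted <- NA_real_
    idx <- out$stratum == "all" & !is.na(out$p_one_sided)
    out$p_adjusted[idx] <- stats::p.adjust(out$p_one_sided[idx], "holm")
  }
  out$significant <- !is.na(out$p_one_sided) & out$p_one_sided <= alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("bst_comparison", class(out))
  out
}

#' Render a comparison table as aligned plain text
#'
#' One block per feature channel and stratum, anchors as column groups with
#' Mean, SD, N and the one-sided p-level, in the layout conventional for
#' two-arm psychophysiology cohort tables. Significant cells (p <= alpha)
#' are starred.
#'
#' @param ct A `bst_comparison`.
#' @param digits Digits for means/SDs.
#' @return A character vector of lines, invisibly; printed when
#'   `print = TRUE`.
#' @param print Print to the console?
#' @export
render_comparison <- function(ct, digits = 2, print = TRUE) {
  stopifnot(inherits(ct, "bst_comparison"))
  alpha <- attr(ct, "alpha") %||% 0.05
  lines <- character(0)
  fmt <- function(x) ifelse(is.na(x), "-", formatC(x, digits = digits,
                                                   format = "f"))
  for (ch in unique(ct$channel)) {
    for (st in unique(ct$stratum)) {
      sub <- ct[ct$channel == ch & ct$stratum == st, ]
      if (!nrow(sub) || all(!sub$computable)) next
      lines <- c(lines, sprintf("== %s [%s] ==", ch, st),
                 sprintf("%-8s %8s %8s %4s %8s %8s %4s %10s", "anchor",
                         "ctl_mean", "ctl_sd", "n", "mus_mean", "mus_sd",
                         "n", "p(1-side)"))
      for (k in seq_len(nrow(sub))) {
        star <- if (isTRUE(sub$significant[k])) "*" else ""
        lines <- c(lines, sprintf(
          "%-8s %8s %8s %4d %8s %8s %4d %9.3f%s",
          sub$anchor[k], fmt(sub$mean_control[k]), fmt(sub$sd_control[k]),
          sub$n_control[k], fmt(sub$mean_music[k]), fmt(sub$sd_music[k]),
          sub$n_music[k], sub$p_one_sided[k], star
        ))
      }
      lines <- c(lines, "")
    }
  }
  lines <- c(lines, sprintf("(* one-sided p <= %.2f)", alpha))
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}

#' @exportS3Method ggplot2::autoplot
autoplot.bst_comparison <- function(object, stratum = "all", ...) {
  sub <- object[object$stratum == stratum & object$computable, ]
  long <- dplyr::bind_rows(
    tibble::tibble(channel = sub$channel, anchor = sub$anchor,
                   group = "control", mean = sub$mean_control,
                   sd = sub$sd_control),
    tibble::tibble(channel = sub$channel, anchor = sub$anchor,
                   group = "music", mean = sub$mean_music,
                   sd = sub$sd_music)
  )
  long$anchor <- factor(long$anchor, levels = c("start", "cecum", "end"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$anchor, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "anchor window", y = "window mean (channel units)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Write a comparison table or QC report as CSV
#'
#' @param x A `bst_comparison` or QC tibble.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_comparison <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
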
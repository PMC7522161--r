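#' Uniformly sampled signal excerpts as tibbles
#'
#' A `bst_signal` is a tibble with columns `time_s` and `value` plus
#' attributes carrying the sampling rate (`fs`, Hz), the physical `unit`
#' (`"uV"`, `"mV"`, `"uS"`, `"degC"`, ...) and a `channel` label. All
#' conditioning verbs take and return this shape so chains can be piped.
#'
#' @param value Numeric vector of samples, in channel units.
#' @param fs Sampling rate in Hz (single positive number).
#' @param unit Unit label for the samples.
#' @param channel Channel label (e.g. `"femg_zygomaticus"`).
#' @param t0 Time of the first sample in seconds (default 0).
#'
#' @return A tibble of class `bst_signal` with columns `time_s`, `value`.
#' @examples
#' s <- signal_tbl(sin(2 * pi * 5 * seq(0, 1, by = 1 / 512)), fs = 512)
#' signal_fs(s)
#' @export
signal_tbl <- function(value, fs, unit = "a.u.", channel = "signal", t0 = 0) {
  stopifnot(is.numeric(value), length(value) >= 1)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz).", call. = FALSE)
  }
  value <- as.numeric(value)
  out <- tibble::new_tibble(
    list(time_s = t0 + (seq_along(value) - 1) / fs, value = value),
    nrow = length(value)
  )
  attr(out, "fs") <- fs
  attr(out, "unit") <- unit
  attr(out, "channel") <- channel
  class(out) <- c("bst_signal", class(out))
  out
}

#' @rdname signal_tbl
#' @param s A `bst_signal`.
#' @export
signal_fs <- function(s) attr(s, "fs")

#' @rdname signal_tbl
#' @export
signal_unit <- function(s) attr(s, "unit")

#' @rdname signal_tbl
#' @export
signal_channel <- function(s) attr(s, "channel")

# Rebuild a signal with new samples, keeping fs/unit/channel metadata.
signal_rewrap <- function(s, value, fs = signal_fs(s), unit = signal_unit(s),
                          channel = signal_channel(s)) {
  signal_tbl(value, fs = fs, unit = unit, channel = channel, t0 = s$time_s[1])
}

assert_signal <- function(s, arg = deparse(substitute(s))) {
  if (!inherits(s, "bst_signal")) {
    stop(sprintf("`%s` must be a `bst_signal` (see signal_tbl()).", arg),
         call. = FALSE)
  }
  invisible(s)
}

#' @export
print.bst_signal <- function(x, ...) {
  cat(sprintf(
    "# bst_signal: channel %s, %d samples @ %g Hz (%.3f s), unit %s\n",
    signal_channel(x), nrow(x), signal_fs(x), nrow(x) / signal_fs(x),
    signal_unit(x)
  ))
  NextMethod()
}

#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.bst_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)",
      y = sprintf("%s (%s)", signal_channel(object), signal_unit(object))
    ) +
    ggplot2::theme_minimal()
}
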
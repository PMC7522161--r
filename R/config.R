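#' Pipeline configuration
#'
#' One nested list holding every numeric parameter of the pipeline, with the
#' analysis-chain values used throughout as defaults: acquisition at 2048 Hz
#' downsampled to 512 Hz; fEMG band-pass 20-250 Hz, envelope low-pass 4 Hz;
#' SCL low-pass 8 Hz; moving averages of 67 (ECG) and 513 (TMP) samples;
#' 60 s analysis windows; Hamilton-Tompkins detector constants; one-sided
#' test directions (music below control for fEMG, SCL and heart rate; above
#' for finger temperature, which rises with relaxation) at alpha = 0.05.
#'
#' @param ... Named overrides, e.g. `stats = list(alpha = 0.01)`. Sub-lists
#'   are merged; unknown names are rejected.
#' @return A list of class `bst_config`.
#' @examples
#' cfg <- pipeline_config(stats = list(alpha = 0.01))
#' cfg$stats$alpha
#' @export
pipeline_config <- function(...) {
  base <- list(
    acquisition_fs = 2048,
    analysis_fs = 512,
    conditioning = list(
      order = 4L,
      femg_band_hz = c(20, 250),
      femg_envelope_lp_hz = 4,
      scl_lp_hz = 8,
      ecg_ma_samples = 67L,
      tmp_ma_samples = 513L
    ),
    qrs = list(
      band_hz = c(8, 16),
      band_order = 3L,
      integration_ms = 80,
      refractory_s = 0.2,
      threshold_coef = 0.3125,
      searchback_factor = 1.5,
      refine_ms = 40
    ),
    windowing = list(
      window_s = 60,
      qc = list(
        saturation_frac = 0.05,
        rail_tol_frac = 0.01,
        flat_eps = 1e-9,
        outlier_k = 8,
        outlier_frac = 0.10,
        spike_frac = 0.005
      )
    ),
    stats = list(
      alpha = 0.05,
      directions = list(
        femg_corrugator = "less", femg_zygomaticus = "less",
        scl = "less", bpm = "less", tmp = "greater"
      ),
      adjust = "none"
    ),
    seed = 1L
  )
  as_config(merge_config(base, list(...), path = ""))
}

merge_config <- function(base, over, path) {
  if (length(over) == 0) return(base)
  nm <- names(over)
  if (is.null(nm) || any(nm == "")) {
    stop("configuration overrides must be named.", call. = FALSE)
  }
  bad <- setdiff(nm, names(base))
  if (length(bad)) {
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(bad) > 1) "s" else "",
                 paste0(path, bad, collapse = ", ")), call. = FALSE)
  }
  for (k in nm) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], as.list(over[[k]]),
                                path = paste0(path, k, "$"))
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

as_config <- function(x) {
  class(x) <- "bst_config"
  x
}

#' Save / load a pipeline configuration
#'
#' YAML round-trip: `load_config(save_config(cfg, path))` reproduces `cfg`.
#' Unknown keys in the file are rejected on load.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `save_config()` returns `path` invisibly; `load_config()` a
#'   `bst_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "bst_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml flattens length-2 numeric vectors fine, but integers come back
  # numeric; normalise through the same merge/validation path.
  cfg <- pipeline_config()
  cfg <- as_config(merge_config(cfg, raw, path = ""))
  cfg$conditioning$order <- as.integer(cfg$conditioning$order)
  cfg$conditioning$ecg_ma_samples <- as.integer(cfg$conditioning$ecg_ma_samples)
  cfg$conditioning$tmp_ma_samples <- as.integer(cfg$conditioning$tmp_ma_samples)
  cfg$qrs$band_order <- as.integer(cfg$qrs$band_order)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Reproducible random-number streams
#'
#' A `bst_rng` wraps an R RNG state seeded once from an integer; every
#' generator draws from the stream it is handed and advances it, so a cohort
#' is bit-reproducible from its seed regardless of the global RNG.
#'
#' @param seed Integer seed.
#' @return An environment of class `bst_rng`.
#' @examples
#' r <- rng_stream(42)
#' with_rng(r, rnorm(2))
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed_init <- as.integer(seed)
  e$state <- NULL
  class(e) <- "bst_rng"
  e
}

#' @rdname rng_stream
#' @param rng A `bst_rng`.
#' @param code Expression evaluated with the stream's RNG state active.
#' @export
with_rng <- function(rng, code) {
  stopifnot(inherits(rng, "bst_rng"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  if (is.null(rng$state)) {
    set.seed(rng$seed_init)
  } else {
    assign(".Random.seed", rng$state, globalenv())
  }
  val <- force(code)
  rng$state <- get(".Random.seed", globalenv())
  val
}

# Derive an independent child stream (used per session within a cohort);
# keeps every derived seed well inside 32-bit range.
rng_child <- function(rng, index) {
  base <- with_rng(rng, sample.int(2147483392L, 1L))
  rng_stream((base + index) %% 2147483392L)
}
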
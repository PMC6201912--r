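# Formats and configuration: multi-frame TIFF series, trace/bias CSVs,
# JSON configuration and provenance.

#' Read / write a multi-frame TIFF series
#'
#' Frames are stored as 32-bit grayscale TIFF pages quantized to the
#' `2^32 - 1` level grid, with the affine restoration
#' (`value = stored * scale + offset`) recorded in a small JSON sidecar
#' (`<path>.json`), so intensities of any sign and magnitude round-trip to
#' at worst 1 part in `2^32` of the data range, and a
#' write-read-write-read cycle is bitwise stable.  TIFFs from other tools
#' are read as plain normalized grayscale; integer inputs (e.g. 8-bit) are
#' promoted to double with their normalized values (`k / 255`) preserved
#' exactly.
#'
#' @param path File path.
#' @return `read_series`: a list of numeric matrices (all the same shape).
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e) stop("not a readable TIFF: ", path,
                                              " (", conditionMessage(e), ")"))
  if (!is.list(frames)) frames <- list(frames)
  scale <- 1; offset <- 0; ours <- FALSE
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (identical(meta$format, "lagbias-series")) {
      scale <- as.numeric(meta$scale)
      offset <- as.numeric(meta$offset)
      ours <- TRUE
    }
  }
  frames <- lapply(frames, function(f) {
    # our writer quantizes by round(u * (2^32-1)); the reader divides by
    # 2^32, so undo that asymmetry before the affine restoration
    if (ours) f <- f * (2^32 / (2^32 - 1)) * scale + offset
    attributes(f) <- list(dim = dim(f))
    storage.mode(f) <- "double"
    f
  })
  dims <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), dims), logical(1))))
    stop("mixed frame shapes in ", path)
  frames
}

#' @rdname read_series
#' @param frames A numeric matrix or list of matrices.
#' @export
write_series <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  dims <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), dims), logical(1))))
    stop("mixed frame shapes")
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  offset <- if (lo < 0) lo else 0
  scale <- if (hi - offset > 1) hi - offset else 1
  M <- 2^32 - 1
  q <- lapply(frames, function(f) round((f - offset) / scale * M) / M)
  suppressWarnings(
    tiff::writeTIFF(q, path, bits.per.sample = 32L, reduce = FALSE))
  jsonlite::write_json(list(format = "lagbias-series", scale = scale,
                            offset = offset, n_frames = length(frames),
                            n_rows = dims[1], n_cols = dims[2]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write eye traces and bias traces as CSV
#'
#' Eye traces use columns `t_s`, `x_arcmin`, `y_arcmin`; bias traces use
#' `row`, `xhat_px`, `yhat_px`, `n_valid_x`, `n_valid_y`.
#'
#' @param trace An `eye_trace` (or data.frame `t`, `x`, `y`).
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  write.csv(data.frame(t_s = trace$t, x_arcmin = trace$x,
                       y_arcmin = trace$y),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- read.csv(path)
  structure(data.frame(t = d$t_s, x = d$x_arcmin, y = d$y_arcmin),
            class = c("eye_trace", "data.frame"))
}

#' @rdname write_trace
#' @param bias A `bias_trace`.
#' @export
write_bias <- function(bias, path) {
  write.csv(data.frame(row = bias$row, xhat_px = bias$xhat,
                       yhat_px = bias$yhat, n_valid_x = bias$n_valid_x,
                       n_valid_y = bias$n_valid_y),
            path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated bundle of every tunable of the registration / lag-bias
#' pipeline.  Serialized verbatim into provenance files.
#'
#' @param W Strip width in original pixels (9 suits SLO-like data, 7
#'   OCT-like).
#' @param k Fourier oversampling factor.
#' @param increment Strip increment in original rows (1 = densest).
#' @param f_c Expected cone frequency in cycles/px (for reference
#'   selection).
#' @param fence Apply Tukey fencing?
#' @param fence_multiplier Fence multiplier.
#' @param fence_mode `"frame"` or `"strip"`.
#' @param interp_method Dewarp interpolation, `"linear"` or `"nearest"`.
#' @param flip_sign Flip the bias sign convention in the coordinate grids.
#' @param max_lag Search half-range in original pixels.
#' @param min_overlap Minimum correlation overlap in (oversampled) pixels.
#' @param selection_strip_height Strip height for reference selection.
#' @param averages Build first/second-round registered averages in
#'   [run_pipeline()]?
#' @param seed Optional integer seed recorded in provenance.
#' @return A list of class `pipeline_config` with derived field
#'   `increment_os` (strip increment in oversampled rows).
#' @export
pipeline_config <- function(W = 9L, k = 3L, increment = 1L, f_c = 0.22,
                            fence = TRUE, fence_multiplier = 1.5,
                            fence_mode = c("frame", "strip"),
                            interp_method = c("linear", "nearest"),
                            flip_sign = FALSE, max_lag = 30L,
                            min_overlap = 100L,
                            selection_strip_height = 32L,
                            averages = TRUE, seed = NULL) {
  fence_mode <- match.arg(fence_mode)
  interp_method <- match.arg(interp_method)
  chk <- function(v, name, lo) {
    if (length(v) != 1L || !is.finite(v) || v < lo)
      stop(sprintf("invalid `%s` (must be a single number >= %s)", name, lo))
  }
  chk(W, "W", 1); chk(k, "k", 1); chk(increment, "increment", 1)
  chk(fence_multiplier, "fence_multiplier", 0)
  chk(max_lag, "max_lag", 1); chk(min_overlap, "min_overlap", 1)
  chk(selection_strip_height, "selection_strip_height", 2)
  if (f_c <= 0 || f_c >= 0.5) stop("invalid `f_c` (must be in (0, 0.5))")
  structure(list(W = as.integer(W), k = as.integer(k),
                 increment = as.integer(increment),
                 increment_os = as.integer(increment) * as.integer(k),
                 f_c = f_c, fence = isTRUE(fence),
                 fence_multiplier = fence_multiplier,
                 fence_mode = fence_mode, interp_method = interp_method,
                 flip_sign = isTRUE(flip_sign),
                 max_lag = as.integer(max_lag),
                 min_overlap = as.integer(min_overlap),
                 selection_strip_height = as.integer(selection_strip_height),
                 averages = isTRUE(averages), seed = seed),
            class = "pipeline_config")
}

#' Write a provenance record
#'
#' JSON record of the configuration, seeds and any extra stage metadata,
#' sufficient to reproduce the artifact.
#'
#' @param path Output path.
#' @param config A `pipeline_config` (or any list).
#' @param ... Further named items (seeds, merit values, outlier counts...).
#' @export
write_provenance <- function(path, config, ...) {
  rec <- list(package = "lagbias",
              version = as.character(utils::packageVersion("lagbias")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = unclass(config), ...)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
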
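# The package's standard desk-scale simulation: the conditions under which
# the method is validated end to end.

#' Standard synthetic AO-SLO simulation
#'
#' Builds the package's reference validation scenario: a relaxed cone-mosaic
#' phantom of ~2450 cones in a 26-arcmin disc sampled at 5 px/arcmin
#' (256 x 256 px, ~1 arcmin cone spacing), raster-scanned into 96 x 96 px
#' frames of 33 ms each through a continuous self-avoiding-walk drift trace.
#'
#' The scenario's drift is calibrated to the vigorous end of fixational
#' motion (mean speed ~0.85 deg/s), so that every frame carries conspicuous
#' warp artifacts and the reference frame cannot be chosen free of motion --
#' the regime the lag-bias correction exists for.  The drift model's
#' defaults themselves remain at the textbook ~0.5 deg/s.
#'
#' @param seed Integer seed controlling both the phantom and the drift.
#' @param n_frames Number of frames in the series.
#' @return List with `phantom`, `scan`, `series`, and `f_c` (expected cone
#'   frequency in cycles/px for reference selection).
#' @export
standard_simulation <- function(seed, n_frames = 100L) {
  phantom <- build_phantom(seed = seed)
  scan <- scan_params()
  series <- simulate_series(phantom, scan, n_frames,
                            trace_params = list(step_rate = 1020),
                            seed = seed + 1L)
  list(phantom = phantom, scan = scan, series = series,
       f_c = expected_cone_frequency(phantom))
}

#' Restrict reference-strip lags to a subset of target frames
#'
#' Convenience for frame-count sufficiency analyses: keeps only the lags
#' measured against the given target frames, preserving the bookkeeping
#' attributes [estimate_bias()] needs.
#'
#' @param lags A `ref_strip_lags`.
#' @param frames Target frame indices to keep.
#' @return A `ref_strip_lags` restricted to those frames.
#' @export
subset_lag_frames <- function(lags, frames) {
  out <- lags[lags$frame %in% frames, , drop = FALSE]
  attr(out, "n_rows") <- attr(lags, "n_rows")
  attr(out, "W") <- attr(lags, "W")
  class(out) <- class(lags)
  out
}
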
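# Virtual raster scanner: samples a moving phantom line by line, producing
# the shear/compression/expansion warp characteristic of scanned ophthalmic
# imaging.

#' Raster scan parameters
#'
#' @param n_rows,n_cols Frame size in pixels (rows = slow scan, cols = fast
#'   scan).
#' @param line_rate Fast-scanner line rate in Hz.
#' @param px_per_um Lateral sampling in pixels per micrometer.
#' @param um_per_deg Retinal scale in micrometers per degree (300 by
#'   default, so 1 arcmin = 5 um).
#' @return An object of class `scan_params` with derived fields
#'   `frame_period` (s) and `px_per_arcmin`.
#' @export
scan_params <- function(n_rows = 96L, n_cols = 96L,
                        line_rate = n_rows / 0.033,
                        px_per_um = 1, um_per_deg = 300) {
  if (n_rows <= 0 || n_cols <= 0 || line_rate <= 0 || px_per_um <= 0 ||
      um_per_deg <= 0)
    stop("all scan parameters must be positive")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 line_rate = line_rate, px_per_um = px_per_um,
                 um_per_deg = um_per_deg,
                 frame_period = n_rows / line_rate,
                 px_per_arcmin = px_per_um * um_per_deg / 60),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat(sprintf(
    "<scan_params> %d x %d px, %.4g lines/s (frame %.3g ms), %.3g px/arcmin\n",
    x$n_rows, x$n_cols, x$line_rate, 1000 * x$frame_period, x$px_per_arcmin))
  invisible(x)
}

# Bilinear lookup of matrix P at fractional (ri, ci); caller guarantees
# coordinates lie within [1, nrow] x [1, ncol].
bilinear_at <- function(P, ri, ci) {
  i0 <- pmin(floor(ri), nrow(P) - 1L); fi <- ri - i0
  j0 <- pmin(floor(ci), ncol(P) - 1L); fj <- ci - j0
  P[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    P[cbind(i0 + 1L, j0)] * fi * (1 - fj) +
    P[cbind(i0, j0 + 1L)] * (1 - fi) * fj +
    P[cbind(i0 + 1L, j0 + 1L)] * fi * fj
}

crop_origin <- function(phantom, scan) {
  np <- dim(phantom$image)
  c(floor((np[1] - scan$n_rows) / 2), floor((np[2] - scan$n_cols) / 2))
}

#' Motion-free central crop of a phantom
#'
#' The `n_rows` x `n_cols` region of the phantom image that a zero-motion
#' raster scan would produce; the ground-truth "object" for validation.
#'
#' @param phantom A `mosaic_phantom`.
#' @param scan A `scan_params`.
#' @return Numeric matrix of size `n_rows` x `n_cols`.
#' @export
motion_free_crop <- function(phantom, scan) {
  o <- crop_origin(phantom, scan)
  if (any(o < 0)) stop("phantom image smaller than the scan window")
  phantom$image[o[1] + seq_len(scan$n_rows), o[2] + seq_len(scan$n_cols)]
}

#' Raster-scan a phantom through an eye trace
#'
#' Produces one motion-warped frame: output row `r` samples the phantom at
#' the central crop offset by the eye position at the acquisition time of
#' line `r` (whole rows share one offset -- per-line rigidity), using
#' bilinear interpolation.  Eye positions in arcmin are converted to pixels
#' with the scan's `px_per_arcmin`, which must match the phantom's sampling.
#'
#' @param phantom A `mosaic_phantom`.
#' @param trace An `eye_trace` with at least `n_rows` samples; sample `r` is
#'   used for output row `r`.
#' @param scan A `scan_params`.
#' @return Numeric matrix of size `n_rows` x `n_cols`.
#' @export
warp_frame <- function(phantom, trace, scan) {
  stopifnot(inherits(phantom, "mosaic_phantom"), inherits(scan, "scan_params"))
  if (abs(phantom$px_per_arcmin - scan$px_per_arcmin) > 1e-9)
    stop("phantom and scan sampling densities differ")
  R <- scan$n_rows; C <- scan$n_cols
  if (nrow(trace) < R) stop("trace shorter than one frame (", R, " lines)")
  o <- crop_origin(phantom, scan)
  if (any(o < 0)) stop("phantom image smaller than the scan window")
  dy <- trace$y[seq_len(R)] * scan$px_per_arcmin
  dx <- trace$x[seq_len(R)] * scan$px_per_arcmin
  ri <- matrix(o[1] + seq_len(R) + dy, R, C)
  ci <- outer(dx, o[2] + seq_len(C), "+")
  np <- dim(phantom$image)
  if (min(ri) < 1 || max(ri) > np[1] || min(ci) < 1 || max(ci) > np[2]) {
    need <- max(1 - min(ri), max(ri) - np[1], 1 - min(ci), max(ci) - np[2])
    stop(sprintf(
      "eye excursion exceeds phantom bounds; enlarge the phantom by >= %.1f px per side",
      need))
  }
  matrix(bilinear_at(phantom$image, as.vector(ri), as.vector(ci)), R, C)
}

#' Shear induced by eye motion along the fast scanner
#'
#' Instantaneous image shear, in pixels per line, produced by eye motion of
#' the given velocity: `velocity / line_rate * um_per_deg * px_per_um`.
#'
#' @param velocity Eye velocity in deg/s.
#' @param scan A `scan_params`.
#' @return Shear in pixels per line.
#' @export
shear_per_line <- function(velocity, scan) {
  stopifnot(inherits(scan, "scan_params"))
  velocity / scan$line_rate * scan$um_per_deg * scan$px_per_um
}

#' Simulate a motion-warped image series
#'
#' Generates one continuous drift trace spanning the whole acquisition
#' (`F * frame_period`), splits it per frame, and raster-scans the phantom
#' through each per-frame segment.  Consecutive frames therefore carry
#' similar but uncorrelated warp artifacts, and inter-frame (rigid) motion is
#' retained.
#'
#' @param phantom A `mosaic_phantom`.
#' @param scan A `scan_params`.
#' @param n_frames Number of frames `F >= 1`.
#' @param trace_params Named list of overrides passed to [simulate_drift()].
#' @param seed Optional integer seed (applies to the drift simulation).
#' @return An object of class `warped_series`: list with `frames` (list of
#'   matrices), `traces` (list of per-frame `eye_trace` segments with
#'   absolute positions), `trace` (the full trace), `phantom`, `scan`,
#'   `seed`.
#' @export
simulate_series <- function(phantom, scan, n_frames, trace_params = list(),
                            seed = NULL) {
  stopifnot(inherits(phantom, "mosaic_phantom"), inherits(scan, "scan_params"))
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  n_frames <- as.integer(n_frames)
  args <- c(list(duration = n_frames * scan$frame_period,
                 line_rate = scan$line_rate, seed = seed), trace_params)
  trace <- do.call(simulate_drift, args)
  R <- scan$n_rows
  frames <- vector("list", n_frames)
  traces <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    seg <- trace[((f - 1L) * R + 1L):(f * R), , drop = FALSE]
    class(seg) <- c("eye_trace", "data.frame")
    frames[[f]] <- warp_frame(phantom, seg, scan)
    traces[[f]] <- seg
  }
  structure(list(frames = frames, traces = traces, trace = trace,
                 phantom = phantom, scan = scan, seed = seed),
            class = "warped_series")
}

#' @export
print.warped_series <- function(x, ...) {
  cat(sprintf("<warped_series> %d frames of %d x %d px\n",
              length(x$frames), x$scan$n_rows, x$scan$n_cols))
  invisible(x)
}
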
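# Volumetric extension: synthetic two-band outer-retina volumes, en-face and
# fast-axis projections, axial lag-bias correction, baseline flattening
# methods and surface roughness.

#' Synthesize an outer-retina volume from a mosaic phantom
#'
#' Each lateral position carries Gaussian axial reflectance peaks, one per
#' band, at `band_depth + stagger`: the per-cone stagger (RMS
#' `stagger_rms`, assigned from the nearest cone) emulates the axial
#' staggering of reflectors among neighboring cells.  `axial_trace` is the
#' axial eye position per slow line; as with the lateral raster simulator,
#' a positive eye position offsets the sampling, so the imaged band appears
#' at `band_depth + stagger - axial_trace`.  The motion-free retinal
#' surfaces and the trace are stored in `attr(, "truth")`.
#'
#' @param phantom A `mosaic_phantom` providing lateral structure.
#' @param band_depths_um Axial band depths in micrometers (>= 1 band).
#' @param stagger_rms Per-cone axial stagger RMS in micrometers.
#' @param axial_trace Axial eye position per slow line, micrometers (length
#'   = lateral rows of the phantom image; `NULL` = no axial motion).
#' @param n_z Axial samples per A-scan.
#' @param z_um_per_px Axial pitch in micrometers per pixel.
#' @param band_sigma_um Axial width (sigma) of each band's reflectance peak.
#' @param seed Optional integer seed for the stagger draw.
#' @return A 3-D array of class `ao_volume`, dimensions (y slow, x fast, z
#'   axial), with attributes `z_um_per_px` and `truth` (list: `surfaces`,
#'   one motion-free `z(y, x)` matrix in um per band; `axial_trace`;
#'   `stagger_rms`).
#' @export
synth_volume <- function(phantom, band_depths_um = c(20, 45),
                         stagger_rms = 2.5, axial_trace = NULL,
                         n_z = 64L, z_um_per_px = 1, band_sigma_um = 2,
                         seed = NULL) {
  stopifnot(inherits(phantom, "mosaic_phantom"))
  if (length(band_depths_um) < 1) stop("need at least one band")
  if (any(band_depths_um <= 0 | band_depths_um >= n_z * z_um_per_px))
    stop("band depths outside the axial range")
  if (!is.null(seed)) set.seed(seed)
  A <- phantom$image
  ny <- nrow(A); nx <- ncol(A)
  if (is.null(axial_trace)) axial_trace <- numeric(ny)
  if (length(axial_trace) != ny)
    stop("`axial_trace` must have one value per slow line")
  ppa <- attr(A, "px_per_arcmin")
  ctr <- attr(A, "center")
  # nearest cone per lateral pixel (small fields only)
  px <- (rep(seq_len(nx), each = ny) - ctr[2]) / ppa
  py <- (rep(seq_len(ny), times = nx) - ctr[1]) / ppa
  nc <- length(phantom$field$x)
  nearest <- if (nc == 0) rep(1L, ny * nx) else {
    apply(outer(px, phantom$field$x, "-")^2 +
            outer(py, phantom$field$y, "-")^2, 1L, which.min)
  }
  z <- (seq_len(n_z) - 1) * z_um_per_px
  vol <- array(0, dim = c(ny, nx, n_z))
  surfaces <- vector("list", length(band_depths_um))
  for (b in seq_along(band_depths_um)) {
    stag <- rnorm(max(nc, 1L), 0, stagger_rms)
    retinal <- matrix(band_depths_um[b] + stag[nearest], ny, nx)
    surfaces[[b]] <- retinal
    zmap <- retinal - axial_trace  # apparent (imaged) depth
    for (iz in seq_len(n_z))
      vol[, , iz] <- vol[, , iz] +
        A * exp(-(z[iz] - zmap)^2 / (2 * band_sigma_um^2))
  }
  structure(vol, z_um_per_px = z_um_per_px,
            truth = list(surfaces = surfaces, axial_trace = axial_trace,
                         stagger_rms = stagger_rms),
            class = c("ao_volume", "array"))
}

#' En-face (axial) projection of a volume
#'
#' Mean intensity over an axial window, per lateral position.
#'
#' @param volume 3-D array (y, x, z).
#' @param z_range Axial index range `c(lo, hi)` (`NULL` = full depth).
#' @return Numeric matrix (y, x).
#' @export
en_face_project <- function(volume, z_range = NULL) {
  nz <- dim(volume)[3]
  if (is.null(z_range)) z_range <- c(1L, nz)
  if (z_range[1] < 1 || z_range[2] > nz || z_range[1] > z_range[2])
    stop("`z_range` outside the volume")
  sl <- volume[, , z_range[1]:z_range[2], drop = FALSE]
  apply(sl, c(1, 2), mean)
}

#' Fast-axis (lateral) projection of a volume
#'
#' Mean over the fast axis x, yielding a (z, y) image whose axial dimension
#' plays the role the fast scanner plays in en-face frames.
#'
#' @param volume 3-D array (y, x, z).
#' @return Numeric matrix (z, y).
#' @export
fast_axis_project <- function(volume) {
  t(apply(volume, c(1, 3), mean))
}

# Circular Fourier shift of each column of a matrix by a common delta
# (band-limited interpolation along the first dimension).
fourier_shift_cols <- function(M, delta) {
  n <- nrow(M)
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
  ph <- exp(-2i * pi * f * delta)
  if (n %% 2 == 0) ph[n / 2 + 1] <- Re(ph[n / 2 + 1])  # keep output real
  Re(mvfft(mvfft(M) * ph, inverse = TRUE)) / n
}

# Shift A-scan (y, x) of a volume along z. deltas: matrix (y, x) or
# per-y vector, in z pixels; positive moves content deeper.
shift_volume_z <- function(volume, deltas) {
  d <- dim(volume)
  out <- volume
  if (is.matrix(deltas)) {
    for (y in seq_len(d[1])) {
      M <- t(volume[y, , , drop = TRUE])  # z x x
      dy <- deltas[y, ]
      for (x in seq_len(d[2]))
        out[y, x, ] <- fourier_shift_cols(M[, x, drop = FALSE], dy[x])
    }
  } else {
    for (y in seq_len(d[1])) {
      M <- t(volume[y, , , drop = TRUE])
      out[y, , ] <- t(fourier_shift_cols(M, deltas[y]))
    }
  }
  attributes(out) <- attributes(volume)
  out
}

# Integer z-roll of one A-scan (exact, used by per-A-scan flattening).
roll_z <- function(v, s) {
  n <- length(v)
  s <- ((s %% n) + n) %% n
  if (s == 0) v else c(v[(n - s + 1):n], v[1:(n - s)])
}

#' Axial lag-bias correction of a volume series
#'
#' Runs the lag-bias machinery on fast-axis projections: the slow-axis
#' position is the strip axis and z is the displacement axis.  Reference
#' strips (bands of slow lines) are registered to each target's projection;
#' the per-slow-line averaged axial lags estimate the axial eye position
#' during the reference volume's acquisition, which is then removed by
#' shifting whole B-scans along z (band-limited interpolation).
#'
#' @param volumes List of `ao_volume` (or plain 3-D arrays), same shape.
#' @param reference_index Index of the volume to correct.
#' @param W Strip width in slow lines (7 is typical for OCT data).
#' @param k Oversampling factor for the projections.
#' @param increment Strip increment in slow lines.
#' @param max_lag Maximum displacement searched, in projection pixels.
#' @param fence Apply Tukey fencing to the lags?
#' @param min_overlap Minimum overlap in (oversampled) pixels.
#' @return List of class `axial_correction`: `corrected` (the corrected
#'   reference volume), `bias_um` (estimated axial trace per slow line, um),
#'   `bias` (the raw oversampled `bias_trace`), `lags`, `reference_index`.
#' @export
axial_lag_bias_correct <- function(volumes, reference_index = 1L, W = 7L,
                                   k = 3L, increment = 1L, max_lag = 20L,
                                   fence = TRUE, min_overlap = 50L) {
  if (length(volumes) < 2) stop("need at least two volumes")
  ref_vol <- volumes[[reference_index]]
  d <- dim(ref_vol)
  # projections as (slow y, z) so rows are strips and x-lags are axial
  projs <- lapply(volumes, function(v) {
    if (!identical(dim(v), d)) stop("volumes differ in shape")
    fourier_oversample(t(fast_axis_project(v)), k)
  })
  ref <- projs[[reference_index]]
  targets <- projs[-reference_index]
  lags <- register_reference_strips(ref, targets, W = as.integer(W * k),
                                    increment = as.integer(increment * k),
                                    max_lag = as.integer(max_lag * k),
                                    min_overlap = min_overlap)
  bias <- estimate_bias(lags, fence = fence)
  z_pitch <- attr(ref_vol, "z_um_per_px")
  if (is.null(z_pitch)) z_pitch <- 1
  # the z-lag of reference structure in the targets estimates the axial eye
  # position during the reference acquisition (content sits at -position,
  # exactly as in the lateral case); shifting content deeper by the
  # estimate removes the warp
  per_line <- bias_to_trace(bias, k, n_rows = d[1])
  bias_um <- per_line$x * z_pitch
  corrected <- shift_volume_z(ref_vol, per_line$x)
  structure(list(corrected = corrected, bias_um = bias_um, bias = bias,
                 lags = lags, reference_index = reference_index),
            class = "axial_correction")
}

band_window <- function(volume, band) {
  nz <- dim(volume)[3]
  z_pitch <- attr(volume, "z_um_per_px")
  if (is.null(z_pitch)) z_pitch <- 1
  if (is.null(band)) return(c(1L, nz))
  iz <- pmin(pmax(round(band / z_pitch) + 1L, 1L), nz)
  c(iz[1], iz[2])
}

#' Detect a band surface by per-A-scan peak position
#'
#' Axial position (um) of the intensity maximum of each A-scan within a band
#' window; `NA` for featureless A-scans.  Used both by [flatten_peak()] and
#' for measuring band roughness after a correction.
#'
#' @param volume An `ao_volume` or 3-D array.
#' @param band Axial window in micrometers `c(lo, hi)` (`NULL` = full
#'   depth).
#' @return Numeric matrix `z(y, x)` in micrometers.
#' @export
band_surface <- function(volume, band = NULL) {
  surface_from_peaks(volume, band)
}

surface_from_peaks <- function(volume, band = NULL) {
  w <- band_window(volume, band)
  d <- dim(volume)
  z_pitch <- attr(volume, "z_um_per_px")
  if (is.null(z_pitch)) z_pitch <- 1
  sub <- volume[, , w[1]:w[2], drop = FALSE]
  idx <- apply(sub, c(1, 2), function(v) {
    if (all(v == 0) || all(!is.finite(v))) NA_integer_ else which.max(v)
  })
  (idx + w[1] - 2L) * z_pitch  # 0-based z index times pitch
}

flatten_by_surface <- function(volume, z_px, label) {
  # integer per-A-scan shifts toward the median surface level
  flagged <- !is.finite(z_px)
  if (all(flagged)) stop("no usable A-scans for flattening")
  if (any(flagged)) z_px[flagged] <- median(z_px[!flagged])
  target <- round(median(z_px))
  shifts <- round(z_px) - target
  d <- dim(volume)
  out <- volume
  for (y in seq_len(d[1])) for (x in seq_len(d[2]))
    if (shifts[y, x] != 0)
      out[y, x, ] <- roll_z(volume[y, x, ], -shifts[y, x])
  attributes(out) <- attributes(volume)
  z_pitch <- attr(volume, "z_um_per_px")
  if (is.null(z_pitch)) z_pitch <- 1
  structure(list(volume = out, surface = z_px * z_pitch,
                 shifts = shifts, flagged = flagged, method = label),
            class = "flattening")
}

#' Baseline volume flattening methods
#'
#' Classical axial-alignment baselines: `flatten_center_of_mass` shifts
#' whole B-scans so their axial centers of mass align;
#' `flatten_gradient` shifts each A-scan by the position of its strongest
#' positive axial gradient; `flatten_peak` shifts each A-scan by the
#' position of its intensity peak within a band window.  Gradient and peak
#' shifts are integers, so peak flattening forces the flattened band's
#' surface exactly constant.  Featureless A-scans are filled from the
#' overall median and flagged.
#'
#' @param volume An `ao_volume` or 3-D array (y, x, z).
#' @param band Axial window in micrometers `c(lo, hi)` restricting the
#'   criterion (`NULL` = full depth).
#' @return A list of class `flattening`: `volume` (flattened), `surface`
#'   (the detected surface in um, pre-flattening), `shifts`, `flagged`,
#'   `method`.
#' @export
flatten_peak <- function(volume, band = NULL) {
  z_pitch <- attr(volume, "z_um_per_px")
  if (is.null(z_pitch)) z_pitch <- 1
  flatten_by_surface(volume, surface_from_peaks(volume, band) / z_pitch,
                     "peak")
}

#' @rdname flatten_peak
#' @export
flatten_gradient <- function(volume, band = NULL) {
  w <- band_window(volume, band)
  d <- dim(volume)
  z_pitch <- attr(volume, "z_um_per_px")
  if (is.null(z_pitch)) z_pitch <- 1
  sub <- volume[, , w[1]:w[2], drop = FALSE]
  idx <- apply(sub, c(1, 2), function(v) {
    g <- diff(v)
    if (all(g == 0)) NA_integer_ else which.max(g)
  })
  flatten_by_surface(volume, idx + w[1] - 1L, "gradient")
}

#' @rdname flatten_peak
#' @export
flatten_center_of_mass <- function(volume, band = NULL) {
  w <- band_window(volume, band)
  d <- dim(volume)
  z <- w[1]:w[2]
  com <- vapply(seq_len(d[1]), function(y) {
    p <- colMeans(volume[y, , z, drop = TRUE], na.rm = TRUE)
    if (sum(p) <= 0) NA_real_ else sum(z * p) / sum(p)
  }, numeric(1))
  flagged <- !is.finite(com)
  if (all(flagged)) stop("no usable B-scans for flattening")
  if (any(flagged)) com[flagged] <- median(com[!flagged])
  shifts <- com - median(com)
  out <- shift_volume_z(volume, -shifts)
  z_pitch <- attr(volume, "z_um_per_px")
  if (is.null(z_pitch)) z_pitch <- 1
  structure(list(volume = out,
                 surface = matrix(com * z_pitch, d[1], d[2]),
                 shifts = matrix(shifts, d[1], d[2]),
                 flagged = flagged, method = "center_of_mass"),
            class = "flattening")
}

#' Surface roughness (RMS about the mean)
#'
#' RMS deviation of a height map from its mean level; only the mean is
#' removed (no plane or curvature fit), so tilted surfaces report their tilt
#' as roughness.
#'
#' @param surface Numeric matrix of heights in micrometers (NAs ignored).
#' @return RMS roughness in micrometers.
#' @export
surface_roughness <- function(surface) {
  v <- surface[is.finite(surface)]
  if (length(v) == 0) stop("surface has no finite values")
  sqrt(mean((v - mean(v))^2))
}
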
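# Validation metrics: trace R^2, overlap-normalized whole-image
# cross-correlation, and power-spectrum shear detection.

r2_component <- function(true, est, align_offset) {
  if (length(true) != length(est)) stop("traces differ in length")
  if (align_offset) {
    true <- true - mean(true)
    est <- est - mean(est)
  }
  denom <- sum((true - mean(true))^2)
  if (denom == 0) stop("true trace has zero variance; R^2 undefined")
  1 - sum((true - est)^2) / denom
}

#' Coefficient of determination between true and estimated motion traces
#'
#' `R^2 = 1 - sum((x - xhat)^2) / sum((x - mean(x))^2)`, per axis.  Bias
#' traces are defined only up to a constant (the mean eye position over the
#' targets), so by default both traces are mean-centered first.
#'
#' @param true_trace Data.frame with columns `x`, `y` (the known per-line
#'   positions).
#' @param est Data.frame with columns `x`, `y`, same length and units (see
#'   [bias_to_trace()] for converting a `bias_trace`).
#' @param align_offset Subtract each trace's mean before comparing.
#' @return A list of class `fit_quality` with `r2_x`, `r2_y` (each <= 1; may
#'   be negative for fits worse than the mean).
#' @export
r_squared <- function(true_trace, est, align_offset = TRUE) {
  structure(list(r2_x = r2_component(true_trace$x, est$x, align_offset),
                 r2_y = r2_component(true_trace$y, est$y, align_offset)),
            class = "fit_quality")
}

#' @export
print.fit_quality <- function(x, ...) {
  cat(sprintf("<fit_quality> R^2 x = %.4f, y = %.4f\n", x$r2_x, x$r2_y))
  invisible(x)
}

#' Convert a bias trace to a physical per-line eye trace
#'
#' Divides the oversampled-pixel bias trace by the oversampling factor and
#' the sampling density, and resamples it from oversampled rows onto the
#' original scan lines (oversampled row `m` sits at original row
#' `1 + (m - 1) / k`).
#'
#' @param bias A `bias_trace` (oversampled rows/pixels).
#' @param k Oversampling factor used during registration.
#' @param px_per_arcmin Sampling density; 1 (default) reports pixels.
#' @param n_rows Number of original scan lines to resample onto.
#' @return Data.frame with columns `x`, `y` (arcmin if `px_per_arcmin` is
#'   supplied, original pixels otherwise), one row per scan line.
#' @export
bias_to_trace <- function(bias, k, px_per_arcmin = 1,
                          n_rows = floor((nrow(bias) - 1) / k) + 1) {
  pos <- 1 + (bias$row - 1) / k  # original-row coordinate
  rows <- seq_len(n_rows)
  data.frame(
    x = approx(pos, bias$xhat / (k * px_per_arcmin), xout = rows,
               rule = 2)$y,
    y = approx(pos, bias$yhat / (k * px_per_arcmin), xout = rows,
               rule = 2)$y)
}

#' Overlap-normalized whole-image cross-correlation
#'
#' Zero-mean correlation coefficient between two images at every integer
#' lag, computed over the overlapping region only, with a minimum-overlap
#' guard against spurious perfect correlations at extreme lags.  Lag (0, 0)
#' aligns the images' first pixels.
#'
#' @param a,b Numeric matrices (grayscale images).
#' @param min_overlap Minimum overlap in pixels for a lag to be admissible.
#' @param min_overlap_frac Minimum overlap as a fraction of the smaller
#'   image's area; without it, a tiny corner overlap can correlate almost
#'   perfectly by chance and displace the true peak.
#' @return An object of class `xcorr_result`: `surface` (correlation at each
#'   lag, `NA` where inadmissible), `peak`, `peak_lag` (`c(dx, dy)`), and
#'   the lag axes `dys`, `dxs`.
#' @export
whole_image_xcorr <- function(a, b, min_overlap = 100L,
                              min_overlap_frac = 0.25) {
  if (sd(as.vector(a)) == 0 || sd(as.vector(b)) == 0)
    stop("correlation undefined for a constant image")
  min_overlap <- max(min_overlap,
                     ceiling(min_overlap_frac * min(length(a), length(b))))
  dys <- as.integer((-(nrow(b) - 1L)):(nrow(a) - 1L))
  dxs <- as.integer((-(ncol(b) - 1L)):(ncol(a) - 1L))
  P1 <- ncc_pad_size(max(nrow(a), nrow(b)), max(abs(dys)))
  P2 <- ncc_pad_size(max(ncol(a), ncol(b)), max(abs(dxs)))
  pa <- ncc_prep_image(a, P1, P2)
  pt <- ncc_prep_template(b, 1L, 1L, P1, P2)
  ev <- ncc_eval(pa, pt, dys, dxs, min_overlap)
  m <- ncc_argmax(ev)
  if (!m$valid) stop("no admissible lags (overlap too small everywhere)")
  structure(list(surface = ev$rho, peak = m$peak,
                 peak_lag = c(dx = m$sx, dy = m$sy),
                 dys = dys, dxs = dxs),
            class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("<xcorr_result> peak %.4f at lag (dx = %d, dy = %d)\n",
              x$peak, x$peak_lag[1], x$peak_lag[2]))
  invisible(x)
}

#' Detect shear from the power spectrum of image strips
#'
#' For a quasi-hexagonal mosaic the power spectrum is an annulus; shear
#' compresses it into an ellipse.  Per horizontal strip: compute the power
#' spectrum, mask the DC bin and its 3x3 neighborhood, threshold at
#' `threshold_frac` of the mean power, record the y-coordinate of the
#' maximum in each surviving column, and report the R^2 of an ordinary
#' least-squares line through those points.  Circular (shear-free) spectra
#' give R^2 near 0; sheared, elliptical spectra give high R^2.
#'
#' @param image Numeric matrix.
#' @param strip_width Strip height in rows (consecutive, disjoint strips).
#' @param threshold_frac Threshold as a fraction of the mean masked power.
#' @return An object of class `shear_metric`: data.frame with columns
#'   `strip`, `row_start`, `r2`, `n_cols` (`r2` is `NA` when fewer than 3
#'   columns survive).
#' @export
shear_r2 <- function(image, strip_width = 50L, threshold_frac = 0.25) {
  R <- nrow(image)
  if (R < strip_width) stop("image shorter than one strip")
  starts <- seq(1L, R - strip_width + 1L, by = strip_width)
  res <- lapply(seq_along(starts), function(s) {
    strip <- image[starts[s]:(starts[s] + strip_width - 1L), , drop = FALSE]
    ps <- fftshift2(Mod(fft(strip - mean(strip)))^2)
    ci <- floor(nrow(ps) / 2) + 1L; cj <- floor(ncol(ps) / 2) + 1L
    ps[pmax(1L, ci - 1L):pmin(nrow(ps), ci + 1L),
       pmax(1L, cj - 1L):pmin(ncol(ps), cj + 1L)] <- 0
    thr <- threshold_frac * mean(ps)
    keep <- ps >= thr
    cols <- which(colSums(keep) > 0)
    if (length(cols) < 3)
      return(data.frame(strip = s, row_start = starts[s], r2 = NA_real_,
                        n_cols = length(cols)))
    ymax <- vapply(cols, function(j) {
      v <- ps[, j]
      v[!keep[, j]] <- -Inf
      which.max(v)
    }, integer(1))
    r2 <- if (stats::var(ymax) == 0 || stats::var(cols) == 0) 0 else
      suppressWarnings(stats::cor(cols, ymax)^2)
    if (!is.finite(r2)) r2 <- 0
    data.frame(strip = s, row_start = starts[s], r2 = r2,
               n_cols = length(cols))
  })
  structure(do.call(rbind, res), strip_width = strip_width,
            threshold_frac = threshold_frac,
            class = c("shear_metric", "data.frame"))
}
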
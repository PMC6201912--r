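# Strip-based registration: reference selection by spectral merit, strip
# windows, DFT-based registration of target strips to the reference, and
# sub-pixel-registered averaging with sum/counter bookkeeping.

#' Binary strip window
#'
#' Row mask of the strip centered on row `r`: rows `p` with
#' `|p - r| <= W / 2`, truncated at the image edges.  Rows are 1-based.
#'
#' @param r Strip center row (1 <= r <= n_rows).
#' @param W Strip width in rows (>= 1).
#' @param n_rows Number of image rows.
#' @return Logical vector of length `n_rows`.
#' @export
strip_window <- function(r, W, n_rows) {
  if (W < 1) stop("`W` must be >= 1")
  if (r < 1 || r > n_rows) stop("`r` out of range")
  p <- seq_len(n_rows)
  abs(p - r) <= W / 2
}

strip_rows <- function(r, W, n_rows) which(strip_window(r, W, n_rows))

#' Select a reference frame by cone-band spectral power
#'
#' Each frame is cut into strips of `strip_height` rows; each strip is
#' zero-padded to a square, DFT'd, and its squared modulus radially
#' averaged.  The per-strip spectra are averaged per frame and the total
#' power in the band `[0.95, 1.05] * f_c` is that frame's figure of merit.
#' The frame with the highest merit wins (ties: lowest index).
#'
#' @param frames List of equally sized numeric matrices.
#' @param f_c Expected cone spatial frequency in cycles/pixel (0 < f_c <
#'   0.5); see [expected_cone_frequency()].
#' @param strip_height Strip height in rows.
#' @param band Relative band limits around `f_c`.
#' @return An object of class `reference_selection`: list with `index`,
#'   `merit` (per-frame), `f_c`.
#' @export
select_reference <- function(frames, f_c, strip_height = 32L,
                             band = c(0.95, 1.05)) {
  if (length(frames) < 1) stop("need at least one frame")
  if (f_c <= 0 || f_c >= 0.5) stop("`f_c` must be in (0, 0.5) cycles/px")
  dims <- dim(frames[[1]])
  N <- nextn(max(strip_height, dims[2]), 2)
  # radial frequency of bin centers, cycles/px, for an N x N padded strip
  radii <- radial_average(matrix(0, N, N))$radius
  freq <- radii / N
  in_band <- freq >= band[1] * f_c & freq <= band[2] * f_c
  if (!any(in_band))
    stop("no spectral bins fall in the cone band at this resolution")
  merit <- vapply(frames, function(fr) {
    if (!identical(dim(fr), dims)) stop("frames differ in shape")
    starts <- seq(1L, dims[1] - strip_height + 1L, by = strip_height)
    spectra <- vapply(starts, function(s) {
      strip <- fr[s:(s + strip_height - 1L), ]
      pad <- matrix(0, N, N)
      # demean so edge leakage from the strip's DC does not enter the band
      pad[seq_len(strip_height), seq_len(dims[2])] <- strip - mean(strip)
      radial_average(fftshift2(Mod(fft(pad))^2))$power
    }, numeric(length(radii)))
    sum(rowMeans(spectra)[in_band])
  }, numeric(1))
  structure(list(index = which.max(merit), merit = merit, f_c = f_c),
            class = "reference_selection")
}

#' Register one target strip to the reference
#'
#' Zero-mean, overlap-normalized cross-correlation (computed with DFTs)
#' between the strip of `target` centered on row `r` and the whole
#' `reference`; the argmax gives the displacement of the strip from its
#' nominal position.  Ties are broken by the first maximum in row-major
#' order of the shift grid; an all-constant strip is flagged invalid.
#'
#' @param target,reference Numeric matrices of identical size (already
#'   oversampled, if oversampling is used).
#' @param r Strip center row in `target`.
#' @param W Strip width in rows.
#' @param max_lag Maximum displacement searched, in pixels of the supplied
#'   images (scalar, applied to both axes).
#' @param min_overlap Minimum admissible overlap, in pixels.
#' @return List with `sx`, `sy` (pixels), `peak` (correlation coefficient)
#'   and `valid`.
#' @export
register_strip <- function(target, r, W, reference, max_lag = 90L,
                           min_overlap = 100L) {
  stopifnot(identical(dim(target), dim(reference)))
  rows <- strip_rows(r, W, nrow(target))
  Tvals <- target[rows, , drop = FALSE]
  ncc_register(reference, Tvals, rows[1L], 1L, max_lag, max_lag, min_overlap)
}

#' Register every strip of a target frame to the reference
#'
#' Applies [register_strip()] for strip centers `r = 1, 1 + increment, ...`,
#' sharing the reference-side FFT across strips.
#'
#' @inheritParams register_strip
#' @param increment Row increment between strip centers (1 = densest).
#' @return A data.frame (class `lag_map` row block) with columns `r`, `sx`,
#'   `sy`, `peak`, `valid`.
#' @export
register_frame <- function(target, reference, W = 9L, increment = 1L,
                           max_lag = 90L, min_overlap = 100L) {
  stopifnot(identical(dim(target), dim(reference)))
  R <- nrow(target)
  P1 <- ncc_pad_size(R, max_lag)
  P2 <- ncc_pad_size(ncol(target), max_lag)
  pa <- ncc_prep_image(reference, P1, P2)
  dys <- as.integer((-max_lag):max_lag)
  centers <- seq(1L, R, by = as.integer(increment))
  out <- lapply(centers, function(r) {
    rows <- strip_rows(r, W, R)
    pt <- ncc_prep_template(target[rows, , drop = FALSE], rows[1L], 1L,
                            P1, P2)
    if (pt$constant)
      return(data.frame(r = r, sx = NA_real_, sy = NA_real_,
                        peak = NA_real_, valid = FALSE))
    res <- ncc_argmax(ncc_eval(pa, pt, dys, dys, min_overlap))
    data.frame(r = r, sx = res$sx, sy = res$sy, peak = res$peak,
               valid = res$valid)
  })
  do.call(rbind, out)
}

# Accumulate strips into an expanded sum/counter canvas.
accumulate_strips <- function(frames, lag_map, W, get_frame_rows) {
  ok <- lag_map$valid & is.finite(lag_map$sx) & is.finite(lag_map$sy)
  lm <- lag_map[ok, , drop = FALSE]
  if (nrow(lm) == 0) stop("lag map contains no valid entries")
  R <- nrow(frames[[1]]); C <- ncol(frames[[1]])
  sy <- round(lm$sy); sx <- round(lm$sx)
  row_off <- 1L - min(1L + min(sy), 1L)
  col_off <- 1L - min(1L + min(sx), 1L)
  nr <- R + row_off + max(max(sy), 0L)
  nc <- C + col_off + max(max(sx), 0L)
  sum_img <- matrix(0, nr, nc)
  counter <- matrix(0, nr, nc)
  for (i in seq_len(nrow(lm))) {
    fr <- frames[[lm$frame[i]]]
    rows <- get_frame_rows(lm$r[i], R)
    ri <- rows + sy[i] + row_off
    ci <- seq_len(C) + sx[i] + col_off
    sum_img[ri, ci] <- sum_img[ri, ci] + fr[rows, , drop = FALSE]
    counter[ri, ci] <- counter[ri, ci] + 1
  }
  structure(list(sum = sum_img, counter = counter,
                 average = sum_img / (counter + .Machine$double.eps),
                 offset = c(row = row_off, col = col_off)),
            class = "registered_average")
}

#' Build a sub-pixel-registered average from a lag map
#'
#' Places every valid strip at its registered position on a canvas expanded
#' to the extremes of the lag map, keeping a running sum image and a counter
#' image (number of contributing strips per pixel).  The average is the sum
#' divided by the counter plus machine epsilon.
#'
#' @param frames List of (oversampled) target frames.
#' @param lag_map Data.frame with columns `frame`, `r`, `sx`, `sy`, `valid`
#'   (as produced by [register_frame()] rows bound with a `frame` column).
#' @param W Strip width used during registration.
#' @return A `registered_average`: list with `sum`, `counter`, `average`,
#'   and `offset` (canvas origin relative to the reference origin).
#' @export
build_average <- function(frames, lag_map, W = 9L) {
  stopifnot(is.list(frames), all(c("frame", "r", "sx", "sy") %in%
                                   names(lag_map)))
  if (!"valid" %in% names(lag_map)) lag_map$valid <- TRUE
  accumulate_strips(frames, lag_map, W,
                    function(r, R) strip_rows(r, W, R))
}

#' Apply lags computed on one channel to a concurrently acquired channel
#'
#' Dual registration: strips of `channel_frames` are accumulated using the
#' lag map measured on the registration channel (e.g., lags from confocal
#' frames applied to split-detector or dark-field frames).
#'
#' @param channel_frames Frames congruent (same count and shape) with the
#'   frames that produced `lag_map`.
#' @inheritParams build_average
#' @return A `registered_average`.
#' @export
apply_lags_to_channel <- function(channel_frames, lag_map, W = 9L) {
  dims <- dim(channel_frames[[1]])
  if (!all(vapply(channel_frames, function(f) identical(dim(f), dims),
                  logical(1))))
    stop("channel frames differ in shape")
  if (max(lag_map$frame) > length(channel_frames))
    stop("lag map refers to frames beyond the channel series")
  build_average(channel_frames, lag_map, W)
}

#' @export
print.registered_average <- function(x, ...) {
  cat(sprintf("<registered_average> canvas %d x %d, max counter %d\n",
              nrow(x$sum), ncol(x$sum), max(x$counter)))
  invisible(x)
}
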
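# Lag-bias reconstruction of reference-frame intraframe motion: register
# reference strips against whole target frames, fence outliers, average the
# lags per reference row, and dewarp the reference onto motion-free
# coordinates.

#' Register reference strips to every target frame
#'
#' The inversion of ordinary strip registration: the reference is cut into
#' strips and each strip is registered, by zero-mean overlap-normalized
#' cross-correlation, against each whole target frame.  The matched position
#' of reference strip `r` in target `f`, relative to its nominal position,
#' is the lag `(sx(f, r), sy(f, r))`.
#'
#' Because eye motion is uncorrelated across targets, the per-row average of
#' these lags over frames estimates the eye position during acquisition of
#' that reference row (see [estimate_bias()]).
#'
#' @param reference Oversampled reference frame.
#' @param targets List of oversampled target frames, same size as
#'   `reference`.
#' @param W Strip width in (oversampled) rows.
#' @param increment Row increment between strip centers.
#' @param max_lag Maximum displacement searched, in oversampled pixels.
#' @param min_overlap Minimum admissible overlap in pixels.
#' @return An object of class `ref_strip_lags`: data.frame with columns
#'   `frame`, `r`, `sx`, `sy`, `peak`, `valid`, with `n_rows` (reference
#'   rows) in attributes.
#' @export
register_reference_strips <- function(reference, targets, W = 27L,
                                      increment = 1L, max_lag = 90L,
                                      min_overlap = 100L) {
  if (length(targets) < 1) stop("need at least one target frame")
  R <- nrow(reference)
  P1 <- ncc_pad_size(R, max_lag)
  P2 <- ncc_pad_size(ncol(reference), max_lag)
  centers <- seq(1L, R, by = as.integer(increment))
  preps <- lapply(centers, function(r) {
    rows <- strip_rows(r, W, R)
    ncc_prep_template(reference[rows, , drop = FALSE], rows[1L], 1L, P1, P2)
  })
  dys <- as.integer((-max_lag):max_lag)
  out <- vector("list", length(targets))
  for (f in seq_along(targets)) {
    if (!identical(dim(targets[[f]]), dim(reference)))
      stop("target ", f, " differs in shape from the reference")
    pa <- ncc_prep_image(targets[[f]], P1, P2)
    res <- lapply(seq_along(centers), function(i) {
      pt <- preps[[i]]
      if (pt$constant)
        return(data.frame(frame = f, r = centers[i], sx = NA_real_,
                          sy = NA_real_, peak = NA_real_, valid = FALSE))
      m <- ncc_argmax(ncc_eval(pa, pt, dys, dys, min_overlap))
      data.frame(frame = f, r = centers[i], sx = m$sx, sy = m$sy,
                 peak = m$peak, valid = m$valid)
    })
    out[[f]] <- do.call(rbind, res)
  }
  structure(do.call(rbind, out), n_rows = R, W = W,
            class = c("ref_strip_lags", "data.frame"))
}

#' Tukey's fences outlier mask
#'
#' Keeps values inside the closed interval
#' `[Q1 - multiplier * IQR, Q3 + multiplier * IQR]`, with quartiles computed
#' by linear interpolation of order statistics (`quantile(type = 6)`).
#' Fewer than 4 finite values: everything is kept.
#'
#' @param values Numeric vector.
#' @param multiplier Fence multiplier (1.5 = standard Tukey fences).
#' @return Logical keep mask, same length as `values` (`FALSE` for
#'   non-finite entries when fencing is active).
#' @export
tukey_filter <- function(values, multiplier = 1.5) {
  fin <- is.finite(values)
  if (sum(fin) < 4) return(rep(TRUE, length(values)))
  q <- quantile(values[fin], c(0.25, 0.75), type = 6, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- fin & values >= q[1] - multiplier * iqr &
    values <= q[2] + multiplier * iqr
  keep
}

#' Estimate reference intraframe motion from lag biases
#'
#' Averages the reference-strip lags over target frames, after outlier
#' removal, to obtain the bias trace: the estimated eye position (in
#' oversampled pixels) during acquisition of each reference row.  Fences are
#' applied per frame across strips (the distribution of matched locations
#' within one target), separately for x and y; `fence_mode = "strip"`
#' fences per strip across frames instead.  Rows whose lags are all
#' discarded are filled by linear interpolation from neighboring rows, and
#' the trace is linearly interpolated onto every reference row when strips
#' were spaced by more than one row.
#'
#' @param lags A `ref_strip_lags`.
#' @param fence Apply Tukey fencing?
#' @param fence_multiplier Fence multiplier.
#' @param fence_mode `"frame"` (default) or `"strip"`.
#' @return An object of class `bias_trace`: data.frame with columns `row`
#'   (1..R, oversampled), `xhat`, `yhat` (oversampled px), `n_valid_x`,
#'   `n_valid_y`.
#' @export
estimate_bias <- function(lags, fence = TRUE, fence_multiplier = 1.5,
                          fence_mode = c("frame", "strip")) {
  fence_mode <- match.arg(fence_mode)
  R <- attr(lags, "n_rows")
  df <- as.data.frame(lags)
  keep_x <- df$valid & is.finite(df$sx)
  keep_y <- df$valid & is.finite(df$sy)
  if (fence) {
    group <- if (fence_mode == "frame") df$frame else df$r
    for (g in unique(group)) {
      i <- which(group == g)
      keep_x[i] <- keep_x[i] & tukey_filter(df$sx[i], fence_multiplier)
      keep_y[i] <- keep_y[i] & tukey_filter(df$sy[i], fence_multiplier)
    }
  }
  if (!any(keep_x) || !any(keep_y))
    stop("all lags were discarded; cannot estimate bias")
  centers <- sort(unique(df$r))
  mean_by <- function(v, keep) {
    out <- rep(NA_real_, length(centers))
    n <- integer(length(centers))
    for (i in seq_along(centers)) {
      j <- df$r == centers[i] & keep
      n[i] <- sum(j)
      if (n[i] > 0) out[i] <- mean(v[j])
    }
    list(m = out, n = n)
  }
  mx <- mean_by(df$sx, keep_x)
  my <- mean_by(df$sy, keep_y)
  fill <- function(m) {
    if (all(is.na(m))) stop("all rows lost to fencing")
    if (anyNA(m)) {
      ok <- !is.na(m)
      m <- approx(centers[ok], m[ok], xout = centers, rule = 2)$y
    }
    m
  }
  rows <- seq_len(R)
  xhat <- approx(centers, fill(mx$m), xout = rows, rule = 2)$y
  yhat <- approx(centers, fill(my$m), xout = rows, rule = 2)$y
  structure(data.frame(row = rows, xhat = xhat, yhat = yhat,
                       n_valid_x = approx(centers, mx$n, xout = rows,
                                          method = "constant", rule = 2)$y,
                       n_valid_y = approx(centers, my$n, xout = rows,
                                          method = "constant", rule = 2)$y),
            class = c("bias_trace", "data.frame"),
            centers = centers)
}

#' Ideal and motion-displaced coordinate grids
#'
#' The ideal grid holds the uniformly spaced coordinates a motionless scan
#' would have imaged; the displaced grid holds the retinal coordinates at
#' which the pixels were actually acquired: every pixel of row `r` is
#' displaced by the bias `(xhat_r, yhat_r)`.
#'
#' @param R,C Grid size in rows and columns.
#' @param bias A `bias_trace` of length `R` (or any data.frame with `xhat`,
#'   `yhat`).
#' @param flip_sign Flip the sign convention (bias subtracted instead of
#'   added) for data sources with the opposite lag convention.
#' @return An object of class `coord_grid`: list with `R`, `C`, `dx`, `dy`
#'   (per-row displacements of the acquired coordinates).  Materialize the
#'   full point sets with [as.data.frame.coord_grid()].
#' @export
coordinate_grids <- function(R, C, bias, flip_sign = FALSE) {
  if (nrow(bias) != R) stop("bias length must equal R")
  s <- if (flip_sign) -1 else 1
  structure(list(R = as.integer(R), C = as.integer(C),
                 dx = s * bias$xhat, dy = s * bias$yhat),
            class = "coord_grid")
}

#' @rdname coordinate_grids
#' @param x A `coord_grid`.
#' @param ... Unused.
#' @export
as.data.frame.coord_grid <- function(x, ...) {
  X0 <- rep(seq_len(x$C), times = x$R)
  Y0 <- rep(seq_len(x$R), each = x$C)
  data.frame(X0 = X0, Y0 = Y0,
             X = X0 + rep(x$dx, each = x$C),
             Y = Y0 + rep(x$dy, each = x$C))
}

#' Dewarp a reference image onto motion-free coordinates
#'
#' Interpolates the intensities observed at the displaced coordinates onto
#' the ideal grid.  Because every row of the displaced grid is rigidly
#' shifted, the scattered interpolation reduces to an exact inverse mapping:
#' the row mapping `g(r) = r + dy_r` is inverted by 1-D interpolation and
#' the image is resampled bilinearly at `(g^{-1}(Y), X - dx)` (method
#' `"linear"`), or by nearest-neighbor lookup (`"nearest"`).  Border pixels
#' requiring extrapolation are filled from the nearest sample and flagged in
#' `attr(, "extrapolated")`.
#'
#' @param reference Numeric matrix (the oversampled reference frame).
#' @param grid A `coord_grid` from [coordinate_grids()] with `R` equal to
#'   `nrow(reference)`.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return The corrected image, same size as `reference`, with a logical
#'   `extrapolated` attribute.
#' @export
dewarp <- function(reference, grid, method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "coord_grid"))
  R <- nrow(reference); C <- ncol(reference)
  if (grid$R != R || grid$C != C)
    stop("grid size does not match the reference")
  g <- seq_len(R) + grid$dy
  if (any(duplicated(g)))
    g <- g + seq_len(R) * 1e-9  # break exact ties in the row mapping
  ord <- order(g)
  if (is.unsorted(g)) {
    # folded row mapping (compression beyond one line per line); use the
    # sorted branch, i.e. a first-preimage convention
    warning("row mapping is non-monotone; using sorted inversion")
  }
  rows_out <- seq_len(R)
  rstar <- approx(g[ord], ord, xout = rows_out, rule = 2, ties = "ordered")$y
  extrap_row <- rows_out < min(g) | rows_out > max(g)
  xsh <- approx(seq_len(R), grid$dx, xout = rstar, rule = 2)$y
  out <- matrix(0, R, C)
  extrap <- matrix(FALSE, R, C)
  cols <- seq_len(C)
  for (i in rows_out) {
    cq <- cols - xsh[i]
    ex <- extrap_row[i] | cq < 1 | cq > C
    cq <- pmin(pmax(cq, 1), C)
    if (method == "nearest") {
      out[i, ] <- reference[round(rstar[i]), round(cq)]
    } else {
      r0 <- min(floor(rstar[i]), R - 1L)
      fr <- rstar[i] - r0
      row_blend <- (1 - fr) * reference[r0, ] + fr * reference[r0 + 1L, ]
      j0 <- pmin(floor(cq), C - 1L)
      fj <- cq - j0
      out[i, ] <- (1 - fj) * row_blend[j0] + fj * row_blend[j0 + 1L]
    }
    extrap[i, ] <- ex
  }
  attr(out, "extrapolated") <- extrap
  out
}

#' Run the full lag-bias correction pipeline
#'
#' Selects a reference frame, oversamples the series, registers reference
#' strips to all targets, fences outliers, estimates the bias trace, dewarps
#' the reference, and re-registers the series to the corrected reference.
#'
#' @param frames List of original-resolution frames, or a `warped_series`.
#' @param config A [pipeline_config()].
#' @return A list of class `lagbias_result`: `selection`, `reference_index`,
#'   `lags`, `bias`, `reference` (oversampled, uncorrected),
#'   `corrected_reference`, `average_round1`, `average_round2` (both `NULL`
#'   unless `config$averages`), and `config`.
#' @export
run_pipeline <- function(frames, config = pipeline_config()) {
  if (inherits(frames, "warped_series")) frames <- frames$frames
  if (length(frames) < 2) stop("need at least two frames")
  cfg <- config
  sel <- select_reference(frames, f_c = cfg$f_c,
                          strip_height = cfg$selection_strip_height)
  os <- lapply(frames, fourier_oversample, k = cfg$k)
  ref <- os[[sel$index]]
  targets <- os[-sel$index]
  Wos <- cfg$W * cfg$k
  lagos <- cfg$max_lag * cfg$k
  avg1 <- avg2 <- NULL
  if (cfg$averages) {
    lm1 <- lag_map_series(targets, ref, Wos, cfg$increment_os, lagos,
                          cfg$min_overlap)
    avg1 <- build_average(targets, lm1, Wos)
  }
  lags <- register_reference_strips(ref, targets, W = Wos,
                                    increment = cfg$increment_os,
                                    max_lag = lagos,
                                    min_overlap = cfg$min_overlap)
  bias <- estimate_bias(lags, fence = cfg$fence,
                        fence_multiplier = cfg$fence_multiplier,
                        fence_mode = cfg$fence_mode)
  grid <- coordinate_grids(nrow(ref), ncol(ref), bias,
                           flip_sign = cfg$flip_sign)
  corrected <- dewarp(ref, grid, method = cfg$interp_method)
  if (cfg$averages) {
    lm2 <- lag_map_series(targets, corrected, Wos, cfg$increment_os, lagos,
                          cfg$min_overlap)
    avg2 <- build_average(targets, lm2, Wos)
  }
  structure(list(selection = sel, reference_index = sel$index, lags = lags,
                 bias = bias, reference = ref,
                 corrected_reference = corrected,
                 average_round1 = avg1, average_round2 = avg2,
                 config = cfg),
            class = "lagbias_result")
}

# register_frame over a series, binding a frame column.
lag_map_series <- function(targets, reference, W, increment, max_lag,
                           min_overlap) {
  out <- lapply(seq_along(targets), function(f) {
    lm <- register_frame(targets[[f]], reference, W = W,
                         increment = increment, max_lag = max_lag,
                         min_overlap = min_overlap)
    cbind(frame = f, lm)
  })
  do.call(rbind, out)
}

#' @export
print.lagbias_result <- function(x, ...) {
  cat(sprintf(
    "<lagbias_result> reference frame %d of %d, bias RMS (%.2f, %.2f) oversampled px\n",
    x$reference_index, length(x$selection$merit),
    sqrt(mean((x$bias$xhat - mean(x$bias$xhat))^2)),
    sqrt(mean((x$bias$yhat - mean(x$bias$yhat))^2))))
  invisible(x)
}
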
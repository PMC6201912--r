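# Core engine: zero-mean, overlap-normalized cross-correlation ("masked
# NCC") between an image and a rectangular template, evaluated over a grid
# of integer shifts.
#
# The raw cross-power term is computed with a single product of cached DFTs
# (one forward FFT per image, one per template) followed by one inverse FFT;
# all normalization terms (overlap sizes, local sums of the image, template
# sums clipped to the image) are evaluated exactly with integral images, so
# the per-pair cost is one inverse FFT plus O(#shifts) arithmetic.  Because
# correlation is circular, pad sizes must satisfy P >= extent + max |shift|;
# ncc_pad_size() takes care of that.

ii_pad <- function(A) {
  # integral image with a leading zero row/column
  cs <- A
  if (nrow(A) > 1L) cs <- apply(cs, 2L, cumsum)
  if (ncol(A) > 1L) cs <- t(apply(cs, 1L, cumsum))
  out <- matrix(0, nrow(A) + 1L, ncol(A) + 1L)
  out[-1L, -1L] <- cs
  out
}

ncc_pad_size <- function(extent, max_shift) {
  nextn(extent + max_shift + 1L, c(2L, 3L, 5L))
}

# Prepare the searched-over image: cached FFT + integral images.
ncc_prep_image <- function(A, P1, P2) {
  big <- matrix(0, P1, P2)
  big[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  list(FA = fft(big), ii = ii_pad(A), ii2 = ii_pad(A * A),
       n1 = nrow(A), n2 = ncol(A), P1 = P1, P2 = P2,
       ms2 = mean(A * A))
}

# Prepare a template whose pixel (1,1) sits at image position (row0, col0)
# at zero shift.
ncc_prep_template <- function(Tvals, row0, col0, P1, P2) {
  h <- nrow(Tvals); w <- ncol(Tvals)
  big <- matrix(0, P1, P2)
  big[row0:(row0 + h - 1L), col0:(col0 + w - 1L)] <- Tvals
  list(FT = fft(big), ii = ii_pad(Tvals), ii2 = ii_pad(Tvals * Tvals),
       h = h, w = w, row0 = as.integer(row0), col0 = as.integer(col0),
       constant = sd(as.vector(Tvals)) == 0)
}

# Inverse 2-D FFT restricted to a subset of output rows/columns: transform
# along dim 1, keep the needed rows, transform along dim 2.
ifft2_subset <- function(X, ridx, cidx) {
  B <- mvfft(X, inverse = TRUE)[ridx, , drop = FALSE]
  B <- t(mvfft(t(B), inverse = TRUE))[, cidx, drop = FALSE]
  Re(B) / (nrow(X) * ncol(X))
}

rect_sum <- function(ii, ylo, yhi, xlo, xhi) {
  # vectorized rectangle sums; ylo/yhi indexed over rows of the shift grid,
  # xlo/xhi over columns (all already clamped to valid integral-image range)
  ii[yhi + 1L, xhi + 1L, drop = FALSE] - ii[ylo, xhi + 1L, drop = FALSE] -
    ii[yhi + 1L, xlo, drop = FALSE] + ii[ylo, xlo, drop = FALSE]
}

# Evaluate the correlation-coefficient surface over shifts dys x dxs.
ncc_eval <- function(pa, pt, dys, dxs, min_overlap = 100L) {
  P1 <- pa$P1; P2 <- pa$P2
  raw <- ifft2_subset(pa$FA * Conj(pt$FT),
                      (dys %% P1) + 1L, (dxs %% P2) + 1L)
  # overlap geometry: template pixel (p, q) meets image pixel
  # (row0 + p - 1 + dy, col0 + q - 1 + dx)
  ylo <- pt$row0 + dys; yhi <- ylo + pt$h - 1L
  xlo <- pt$col0 + dxs; xhi <- xlo + pt$w - 1L
  ny <- pmax(0L, pmin(yhi, pa$n1) - pmax(ylo, 1L) + 1L)
  nx <- pmax(0L, pmin(xhi, pa$n2) - pmax(xlo, 1L) + 1L)
  n <- outer(ny, nx)
  clamp <- function(v, lim) pmin(pmax(v, 0L), lim)
  aylo <- clamp(pmax(ylo, 1L) - 1L, pa$n1) + 1L
  ayhi <- clamp(pmin(yhi, pa$n1), pa$n1)
  axlo <- clamp(pmax(xlo, 1L) - 1L, pa$n2) + 1L
  axhi <- clamp(pmin(xhi, pa$n2), pa$n2)
  sA  <- rect_sum(pa$ii,  aylo, ayhi, axlo, axhi)
  sA2 <- rect_sum(pa$ii2, aylo, ayhi, axlo, axhi)
  tylo <- clamp(pmax(1L, 2L - pt$row0 - dys) - 1L, pt$h) + 1L
  tyhi <- clamp(pmin(pt$h, pa$n1 - pt$row0 - dys + 1L), pt$h)
  txlo <- clamp(pmax(1L, 2L - pt$col0 - dxs) - 1L, pt$w) + 1L
  txhi <- clamp(pmin(pt$w, pa$n2 - pt$col0 - dxs + 1L), pt$w)
  sT  <- rect_sum(pt$ii,  tylo, tyhi, txlo, txhi)
  sT2 <- rect_sum(pt$ii2, tylo, tyhi, txlo, txhi)
  varA <- sA2 - sA * sA / n
  varT <- sT2 - sT * sT / n
  num <- raw - sA * sT / n
  tolA <- 1e-9 * pa$ms2
  bad <- n < min_overlap | varA <= tolA * n | varT <= 0
  denom <- sqrt(pmax(varA, 0) * pmax(varT, 0))
  rho <- num / denom
  rho[bad | !is.finite(rho)] <- NA_real_
  list(rho = rho, n = n, dys = dys, dxs = dxs)
}

# Peak of a correlation surface; ties broken by first occurrence in
# row-major order of the (dy, dx) grid.
ncc_argmax <- function(ev) {
  if (all(is.na(ev$rho)))
    return(list(sx = NA_real_, sy = NA_real_, peak = NA_real_,
                valid = FALSE))
  m <- max(ev$rho, na.rm = TRUE)
  hits <- which(ev$rho == m, arr.ind = TRUE)
  key <- (hits[, 1L] - 1L) * length(ev$dxs) + hits[, 2L]
  best <- hits[which.min(key), , drop = TRUE]
  list(sx = ev$dxs[best[2L]], sy = ev$dys[best[1L]], peak = m, valid = TRUE)
}

# One-shot registration of a template against an image.
ncc_register <- function(A, Tvals, row0, col0, max_dy, max_dx,
                         min_overlap = 100L, surface = FALSE) {
  ext1 <- max(nrow(A), row0 + nrow(Tvals) - 1L)
  ext2 <- max(ncol(A), col0 + ncol(Tvals) - 1L)
  P1 <- ncc_pad_size(ext1, max(abs(max_dy)))
  P2 <- ncc_pad_size(ext2, max(abs(max_dx)))
  pa <- ncc_prep_image(A, P1, P2)
  pt <- ncc_prep_template(Tvals, row0, col0, P1, P2)
  if (pt$constant)
    return(list(sx = NA_real_, sy = NA_real_, peak = NA_real_,
                valid = FALSE))
  dys <- if (length(max_dy) == 2L) max_dy[1]:max_dy[2] else (-max_dy):max_dy
  dxs <- if (length(max_dx) == 2L) max_dx[1]:max_dx[2] else (-max_dx):max_dx
  ev <- ncc_eval(pa, pt, as.integer(dys), as.integer(dxs), min_overlap)
  out <- ncc_argmax(ev)
  if (surface) out$surface <- ev
  out
}
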
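# DFT utilities: band-limited oversampling, spectrum shifting, radial
# averaging.

# Zero-pad a (complex) spectrum along one axis from n to k*n samples,
# preserving Hermitian symmetry: for even n the Nyquist bin is split in half
# between the +n/2 and -n/2 positions of the padded spectrum.
pad_spectrum_axis <- function(S, k, axis) {
  if (axis == 2) return(t(pad_spectrum_axis(t(S), k, 1)))
  n <- nrow(S); m <- ncol(S); N <- k * n
  out <- matrix(0 + 0i, N, m)
  if (n %% 2 == 1) {
    h <- (n - 1) / 2
    out[1:(h + 1), ] <- S[1:(h + 1), ]
    if (h > 0) out[(N - h + 1):N, ] <- S[(h + 2):n, ]
  } else {
    h <- n / 2
    out[1:h, ] <- S[1:h, ]
    nyq <- S[h + 1, ] / 2
    out[h + 1, ] <- nyq
    out[N - h + 1, ] <- nyq
    if (h > 1) out[(N - h + 2):N, ] <- S[(h + 2):n, ]
  }
  out
}

#' Fourier (band-limited) oversampling of an image
#'
#' Oversamples an image by an integer factor `k` per axis by zero-padding its
#' DFT spectrum and inverse transforming.  Hermitian symmetry is preserved
#' (Nyquist bins are split), so the output is real, and the image mean is
#' preserved.  Output pixel `m` (1-based) corresponds to input pixel
#' coordinate `1 + (m - 1) / k`.
#'
#' @param image Numeric matrix.
#' @param k Integer oversampling factor (>= 1).
#' @return Numeric matrix with `k` times the rows and columns.
#' @export
fourier_oversample <- function(image, k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  k <- as.integer(k)
  if (k == 1L) return(image)
  S <- fft(image)
  S <- pad_spectrum_axis(S, k, 1)
  S <- pad_spectrum_axis(S, k, 2)
  Re(fft(S, inverse = TRUE)) / (nrow(image) * ncol(image))
}

# Center the DC bin of a DFT power spectrum.
fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  i <- c((floor(n / 2) + 1):n, 1:floor(n / 2))
  j <- c((floor(m / 2) + 1):m, 1:floor(m / 2))
  x[i, j]
}

#' Radially average a centered 2-D power spectrum
#'
#' Mean power in annular bins of 1-pixel width about the spectrum center
#' (the DC bin after [fftshift2()]-style centering).
#'
#' @param power_spectrum Numeric matrix, DC at
#'   (`floor(nrow/2)+1`, `floor(ncol/2)+1`).
#' @return A data.frame with columns `radius` (px, bin center) and `power`.
#' @export
radial_average <- function(power_spectrum) {
  n <- nrow(power_spectrum); m <- ncol(power_spectrum)
  ci <- floor(n / 2) + 1; cj <- floor(m / 2) + 1
  r <- sqrt(outer((seq_len(n) - ci)^2, (seq_len(m) - cj)^2, "+"))
  bin <- as.integer(round(r)) + 1L
  tot <- rowsum(as.vector(power_spectrum), as.vector(bin))
  cnt <- tabulate(as.vector(bin), nbins = max(bin))
  keep <- as.integer(rownames(tot))
  data.frame(radius = keep - 1, power = tot[, 1] / cnt[keep])
}
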
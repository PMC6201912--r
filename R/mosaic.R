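# Cone-mosaic phantom: particle-system simulation of the photoreceptor
# mosaic used as a motion-free ground-truth object.

#' Seed a cone field with uniformly random positions in a disc
#'
#' Positions are drawn uniformly over a disc of the given radius, centered at
#' the origin.  Units throughout are arcmin of visual angle.
#'
#' @param n_cones Number of cones (non-negative integer).
#' @param radius Disc radius in arcmin (positive).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `cone_field`: a list with numeric vectors `x`,
#'   `y` (arcmin) and scalar `radius`.
#' @export
seed_cones <- function(n_cones, radius, seed = NULL) {
  if (length(n_cones) != 1L || is.na(n_cones) || n_cones < 0)
    stop("`n_cones` must be a single non-negative number")
  if (length(radius) != 1L || is.na(radius) || radius <= 0)
    stop("`radius` must be a single positive number")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_cones)
  rr <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  structure(list(x = rr * cos(th), y = rr * sin(th), radius = radius),
            class = "cone_field")
}

#' @export
print.cone_field <- function(x, ...) {
  cat(sprintf("<cone_field> %d cones in a disc of radius %.3g arcmin\n",
              length(x$x), x$radius))
  invisible(x)
}

# Expected inter-cone spacing for a hexagonal packing of n points in a disc.
expected_spacing <- function(n, radius) {
  if (n < 2) return(radius)
  sqrt(2 * pi * radius^2 / (sqrt(3) * n))
}

#' Relax a cone field into a quasi-hexagonal mosaic
#'
#' Iteratively moves every cone along the net of inverse-square repulsion
#' from all other cones and inverse-square attraction toward the field
#' center.  Updates are synchronous: all forces are evaluated, then all
#' points are moved, with the per-iteration displacement of any point capped
#' at one expected inter-cone spacing.  Iteration stops when the mean
#' per-iteration displacement falls below `motion_tol` or after `max_iter`
#' iterations.  Points are kept inside the seeded disc.
#'
#' Exactly coincident points contribute no pairwise force; if any are
#' detected the whole field is jittered by a tiny random amount before the
#' forces are recomputed, so no division by zero can occur.
#'
#' @param field A `cone_field`.
#' @param repulsion_gain,attraction_gain Non-negative gains of the repulsive
#'   and attractive inverse-square fields.  `attraction_gain = NULL` scales
#'   the attraction with the cone count (`repulsion_gain * n / 12`), tuned so
#'   the relaxed field shows a gentle monotone density decline with
#'   eccentricity and a central nearest-neighbor-spacing CV below 0.15.
#' @param soft Softening length (arcmin) of the central attraction
#'   (`d^2 -> d^2 + soft^2`), keeping the force finite at the origin;
#'   defaults to 15% of the field radius.
#' @param step Scale factor from net force to displacement per iteration.
#' @param motion_tol Convergence threshold on the mean per-iteration
#'   displacement, in arcmin.  `NULL` defaults to 0.2% of the expected
#'   inter-cone spacing.
#' @param max_iter Maximum number of iterations.
#' @return The relaxed `cone_field`, with the per-iteration mean displacement
#'   recorded in `attr(, "displacement_history")`.
#' @export
relax_mosaic <- function(field, repulsion_gain = 1, attraction_gain = NULL,
                         soft = NULL, step = 0.003, motion_tol = NULL,
                         max_iter = 100L) {
  stopifnot(inherits(field, "cone_field"))
  n <- length(field$x)
  if (is.null(attraction_gain)) attraction_gain <- repulsion_gain * n / 12
  if (is.null(soft)) soft <- 0.15 * field$radius
  if (repulsion_gain < 0 || attraction_gain < 0)
    stop("gains must be non-negative")
  if (n < 2) {
    attr(field, "displacement_history") <- numeric(0)
    return(field)
  }
  s_exp <- expected_spacing(n, field$radius)
  if (is.null(motion_tol)) motion_tol <- 0.002 * s_exp
  if (motion_tol <= 0) stop("`motion_tol` must be positive")
  x <- field$x; y <- field$y
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    f <- .mosaic_forces(x, y, repulsion_gain, attraction_gain, soft^2)
    while (f$n_coincident > 0) {
      jit <- 1e-6 * s_exp
      x <- x + runif(n, -jit, jit)
      y <- y + runif(n, -jit, jit)
      f <- .mosaic_forces(x, y, repulsion_gain, attraction_gain, soft^2)
    }
    dx <- step * f$fx
    dy <- step * f$fy
    dn <- sqrt(dx^2 + dy^2)
    over <- dn > s_exp
    if (any(over)) {
      sc <- s_exp / dn[over]
      dx[over] <- dx[over] * sc
      dy[over] <- dy[over] * sc
    }
    x <- x + dx
    y <- y + dy
    # project strays back onto the disc boundary
    rr <- sqrt(x^2 + y^2)
    out <- rr > field$radius
    if (any(out)) {
      sc <- field$radius / rr[out]
      x[out] <- x[out] * sc
      y[out] <- y[out] * sc
    }
    hist <- c(hist, mean(dn))
    if (hist[it] < motion_tol) break
  }
  field$x <- x
  field$y <- y
  attr(field, "displacement_history") <- hist
  field
}

#' Assign lognormal reflectance intensities to cones
#'
#' Cone reflectance in real AO images is positive and right-skewed; a
#' lognormal law with configurable log-mean and log-sd is used here.
#'
#' @param field A `cone_field`.
#' @param log_mean,log_sd Parameters of the lognormal on the log scale
#'   (`log_sd >= 0`; zero gives identical intensities `exp(log_mean)`).
#' @param seed Optional integer seed.
#' @return Numeric vector of positive intensities, one per cone.
#' @export
assign_intensities <- function(field, log_mean = 0, log_sd = 0.3,
                               seed = NULL) {
  stopifnot(inherits(field, "cone_field"))
  if (log_sd < 0) stop("`log_sd` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(field$x)
  if (n == 0) return(numeric(0))
  rlnorm(n, meanlog = log_mean, sdlog = log_sd)
}

# Bilinear splat of weighted points onto an n x m grid (1-based pixel
# centers).  Returns the accumulated image.
splat_bilinear <- function(i, j, w, n, m) {
  img <- numeric(n * m)
  i0 <- floor(i); j0 <- floor(j)
  fi <- i - i0;   fj <- j - j0
  add <- function(ii, jj, ww) {
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= m & ww > 0
    if (!any(ok)) return(invisible())
    li <- (jj[ok] - 1L) * n + ii[ok]
    agg <- rowsum(ww[ok], li)
    img[as.integer(rownames(agg))] <<- img[as.integer(rownames(agg))] + agg[, 1L]
    invisible()
  }
  add(i0,      j0,      w * (1 - fi) * (1 - fj))
  add(i0 + 1L, j0,      w * fi       * (1 - fj))
  add(i0,      j0 + 1L, w * (1 - fi) * fj)
  add(i0 + 1L, j0 + 1L, w * fi       * fj)
  matrix(img, n, m)
}

# FFT-based 2-D convolution with a centered kernel, zero boundary.
conv2_fft <- function(img, kernel) {
  n <- nrow(img); m <- ncol(img)
  kn <- nrow(kernel); km <- ncol(kernel)
  P1 <- nextn(n + kn, c(2, 3, 5)); P2 <- nextn(m + km, c(2, 3, 5))
  A <- matrix(0, P1, P2); A[1:n, 1:m] <- img
  K <- matrix(0, P1, P2); K[1:kn, 1:km] <- kernel
  out <- Re(fft(fft(A) * fft(K), inverse = TRUE)) / (P1 * P2)
  ci <- (kn + 1) %/% 2; cj <- (km + 1) %/% 2
  out[ci:(ci + n - 1), cj:(cj + m - 1)]
}

#' Render a cone field into an image
#'
#' Each cone deposits its intensity at its sub-pixel position by bilinear
#' splatting; the resulting delta image is convolved with a normalized 2-D
#' Gaussian point-spread function.  Total image energy therefore equals the
#' summed intensities up to boundary truncation.  The image center pixel
#' corresponds to field position (0, 0).
#'
#' @param field A `cone_field`.
#' @param intensities Per-cone intensities (recycled scalar allowed).
#' @param px_per_arcmin Sampling density in pixels per arcmin.
#' @param psf_sigma Gaussian PSF sigma in arcmin; `0` skips the blur.
#' @return Numeric matrix (non-negative), square, with attributes
#'   `px_per_arcmin` and `center` (row/col of the field origin).
#' @export
render_mosaic <- function(field, intensities, px_per_arcmin, psf_sigma) {
  stopifnot(inherits(field, "cone_field"))
  if (psf_sigma < 0) stop("`psf_sigma` must be non-negative")
  if (px_per_arcmin <= 0) stop("`px_per_arcmin` must be positive")
  n_c <- length(field$x)
  intensities <- rep_len(intensities, n_c)
  if (n_c > 0 && any(intensities < 0)) stop("intensities must be non-negative")
  s_exp <- expected_spacing(max(n_c, 2L), field$radius)
  if (s_exp * px_per_arcmin < 2)
    warning("sampling too coarse to separate cones (< 2 px per spacing)")
  half <- ceiling(field$radius * px_per_arcmin) + 2L
  n <- 2L * half + 1L
  ctr <- half + 1L
  img <- if (n_c == 0) matrix(0, n, n) else
    splat_bilinear(ctr + field$y * px_per_arcmin,
                   ctr + field$x * px_per_arcmin,
                   intensities, n, n)
  sig <- psf_sigma * px_per_arcmin
  if (sig > 0) {
    kh <- max(1L, ceiling(4 * sig))
    ax <- (-kh):kh
    g1 <- exp(-ax^2 / (2 * sig^2))
    kernel <- outer(g1, g1)
    kernel <- kernel / sum(kernel)
    img <- pmax(conv2_fft(img, kernel), 0)
  }
  structure(img, px_per_arcmin = px_per_arcmin, center = c(ctr, ctr))
}

#' Eccentricity-density curve of a cone field
#'
#' Counts cones in concentric annuli and divides by annulus area.
#'
#' @param field A `cone_field`.
#' @param bin_width Annulus width in arcmin.
#' @return A data.frame with columns `ecc` (bin midpoint, arcmin) and
#'   `density` (cones per arcmin^2); zero rows for an empty field.
#' @export
density_curve <- function(field, bin_width) {
  stopifnot(inherits(field, "cone_field"), bin_width > 0)
  if (length(field$x) == 0)
    return(data.frame(ecc = numeric(0), density = numeric(0)))
  r <- sqrt(field$x^2 + field$y^2)
  edges <- seq(0, field$radius + bin_width, by = bin_width)
  idx <- findInterval(r, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  area <- pi * diff(edges^2)
  data.frame(ecc = (edges[-length(edges)] + edges[-1]) / 2,
             density = counts / area)
}

#' Build a complete cone-mosaic phantom
#'
#' Convenience wrapper: seed, relax, assign intensities and render.  The
#' defaults give a ~256 x 256 px field with ~1 arcmin cone spacing at
#' 5 px/arcmin (the package's standard simulation scale: 300 um/deg and
#' 1 um/px).
#'
#' @param n_cones,radius,seed As in [seed_cones()].
#' @param px_per_arcmin,psf_sigma As in [render_mosaic()].
#' @param log_mean,log_sd As in [assign_intensities()].
#' @param ... Further arguments passed to [relax_mosaic()].
#' @return An object of class `mosaic_phantom`: list with elements `field`,
#'   `intensities`, `image`, `px_per_arcmin`, `psf_sigma`, `seed`.
#' @export
build_phantom <- function(n_cones = 2450, radius = 26, px_per_arcmin = 5,
                          psf_sigma = 0.2, log_mean = 0, log_sd = 0.3,
                          seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  field <- seed_cones(n_cones, radius)
  field <- relax_mosaic(field, ...)
  ints <- assign_intensities(field, log_mean, log_sd)
  img <- render_mosaic(field, ints, px_per_arcmin, psf_sigma)
  structure(list(field = field, intensities = ints, image = img,
                 px_per_arcmin = px_per_arcmin, psf_sigma = psf_sigma,
                 seed = seed),
            class = "mosaic_phantom")
}

#' @export
print.mosaic_phantom <- function(x, ...) {
  cat(sprintf(
    "<mosaic_phantom> %d cones, radius %.3g arcmin, image %d x %d px (%g px/arcmin)\n",
    length(x$field$x), x$field$radius, nrow(x$image), ncol(x$image),
    x$px_per_arcmin))
  invisible(x)
}

#' Expected cone spatial frequency of a phantom
#'
#' Modal spatial frequency of the quasi-hexagonal mosaic (the radius of the
#' annular concentration in its power spectrum), in cycles per pixel:
#' `2 / (sqrt(3) * spacing_px)`, with the spacing of an ideal hexagonal
#' packing at the field's mean density.
#'
#' @param phantom A `mosaic_phantom`.
#' @return Expected cone frequency in cycles/pixel.
#' @export
expected_cone_frequency <- function(phantom) {
  stopifnot(inherits(phantom, "mosaic_phantom"))
  s_px <- expected_spacing(length(phantom$field$x), phantom$field$radius) *
    phantom$px_per_arcmin
  2 / (sqrt(3) * s_px)
}
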
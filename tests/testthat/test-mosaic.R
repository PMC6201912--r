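test_that("seed_cones respects the disc and the seed", {
  expect_length(seed_cones(0, 10)$x, 0)
  f1 <- seed_cones(1, 10, seed = 1)
  expect_true(f1$x^2 + f1$y^2 <= 100)
  worst <- max(vapply(1:100, function(s) {
    f <- seed_cones(1000, 30, seed = s)
    max(sqrt(f$x^2 + f$y^2))
  }, numeric(1)))
  expect_lte(worst, 30)
  expect_identical(seed_cones(50, 5, seed = 9), seed_cones(50, 5, seed = 9))
  expect_error(seed_cones(-1, 10), "n_cones")
  expect_error(seed_cones(10, 0), "radius")
})

test_that("pairwise forces balance for the symmetric two-point case", {
  # repulsion a/(2d)^2 equals attraction b/d^2 exactly when a = 4b
  for (d in c(0.5, 1, 3)) {
    f <- lagbias:::.mosaic_forces(c(-d, d), c(0, 0),
                                  repulsion = 4, attraction = 1)
    expect_equal(f$fx, c(0, 0), tolerance = 1e-12)
    expect_equal(f$fy, c(0, 0), tolerance = 1e-12)
  }
})

test_that("relaxation is stationary for a single central point", {
  f <- structure(list(x = 0, y = 0, radius = 5), class = "cone_field")
  r <- relax_mosaic(f, max_iter = 20L)
  expect_identical(r$x, 0)
  expect_identical(r$y, 0)
})

test_that("relaxation conserves points, stays in the disc, and settles", {
  set.seed(3)
  f <- seed_cones(500, 12)
  r <- relax_mosaic(f)
  expect_length(r$x, 500)
  expect_true(all(sqrt(r$x^2 + r$y^2) <= 12 + 1e-9))
  h <- attr(r, "displacement_history")
  last10 <- tail(h, 10)
  # settled: the late displacement sequence no longer grows
  expect_true(all(diff(last10) <= 0.05 * last10[-length(last10)]))
  expect_lt(mean(last10), h[1])
})

test_that("relaxed mosaic is locally regular with declining density", {
  ph <- medium_phantom()
  f <- ph$field
  d2 <- outer(f$x, f$x, "-")^2 + outer(f$y, f$y, "-")^2
  diag(d2) <- Inf
  nn <- sqrt(apply(d2, 1, min))
  ctr <- sqrt(f$x^2 + f$y^2) < f$radius / 2
  expect_lt(sd(nn[ctr]) / mean(nn[ctr]), 0.15)
  dc <- density_curve(f, 1)
  expect_lt(cor(dc$ecc, dc$density, method = "spearman"), 0)
})

test_that("intensity assignment follows the lognormal law", {
  f <- seed_cones(10, 5, seed = 1)
  expect_equal(assign_intensities(f, log_mean = 0.5, log_sd = 0, seed = 1),
               rep(exp(0.5), 10))
  big <- seed_cones(1e4, 50, seed = 2)
  v <- assign_intensities(big, log_mean = 0, log_sd = 0.3, seed = 3)
  expect_true(all(v > 0))
  se <- 0.3 / sqrt(1e4)
  expect_lt(abs(mean(log(v))), 3 * se)
  empty <- seed_cones(0, 5)
  expect_length(assign_intensities(empty), 0)
})

test_that("rendering conserves energy and peaks at cone positions", {
  f <- structure(list(x = 0, y = 0, radius = 4), class = "cone_field")
  img <- render_mosaic(f, 1, px_per_arcmin = 5, psf_sigma = 0.3)
  expect_equal(sum(img), 1, tolerance = 1e-6)
  expect_true(all(img >= 0))

  f2 <- structure(list(x = c(-2, 2), y = c(0, 0), radius = 4),
                  class = "cone_field")
  img2 <- render_mosaic(f2, c(1, 1), 5, 0.3)
  ctr <- attr(img2, "center")
  for (xa in c(-2, 2)) {
    expected_col <- ctr[2] + xa * 5
    # local maximum within +-1 px of the cone position
    win <- img2[ctr[1] + (-3:3), expected_col + (-3:3)]
    peak <- which(win == max(win), arr.ind = TRUE)
    expect_lte(max(abs(peak - 4)), 1)
  }

  # zero-width PSF: rendering reduces to the splatted delta image
  f3 <- structure(list(x = 0.37, y = -0.23, radius = 2),
                  class = "cone_field")
  img3 <- render_mosaic(f3, 2, 5, 0)
  expect_equal(sum(img3), 2, tolerance = 1e-12)
  expect_equal(sum(img3 > 0), 4)  # bilinear splat: four corners
})

test_that("rendering warns when sampling cannot separate cones", {
  f <- seed_cones(500, 2, seed = 1)
  expect_warning(render_mosaic(f, 1, px_per_arcmin = 5, psf_sigma = 0.2),
                 "coarse")
})

test_that("density_curve recovers uniform density and handles edge cases", {
  set.seed(8)
  f <- seed_cones(20000, 20)
  dc <- density_curve(f, 2)
  inner <- dc$density[dc$ecc < 18]
  expect_lt(sd(inner) / mean(inner), 0.1)
  expect_equal(mean(inner), 20000 / (pi * 400), tolerance = 0.05)

  single <- structure(list(x = 3, y = 0, radius = 10), class = "cone_field")
  dcs <- density_curve(single, 2)
  expect_equal(sum(dcs$density > 0), 1)
  empty <- seed_cones(0, 5)
  expect_equal(nrow(density_curve(empty, 1)), 0)
})

test_that("rendering is reproducible and relaxed mosaics show Yellott's ring", {
  s1 <- build_phantom(n_cones = 120, radius = 5, seed = 7)
  s2 <- build_phantom(n_cones = 120, radius = 5, seed = 7)
  expect_identical(s1$image, s2$image)
  p1 <- medium_phantom()

  ring_prominence <- function(field, ints) {
    img <- render_mosaic(field, ints, 5, 0.1)
    ps <- lagbias:::fftshift2(Mod(fft(img - mean(img)))^2)
    ra <- radial_average(ps)
    fr <- ra$radius / nrow(img)
    band <- fr > 0.12 & fr < 0.45
    max(ra$power[band]) / mean(ra$power[band])
  }
  relaxed <- ring_prominence(p1$field, p1$intensities)
  set.seed(7)
  unrel <- seed_cones(1000, 16)
  unrelaxed <- ring_prominence(unrel, p1$intensities)
  expect_gt(relaxed, unrelaxed)
  # annular concentration: an interior local maximum exists
  img <- render_mosaic(p1$field, p1$intensities, 5, 0.1)
  ps <- lagbias:::fftshift2(Mod(fft(img - mean(img)))^2)
  ra <- radial_average(ps)
  fr <- ra$radius / nrow(img)
  band <- which(fr > 0.12 & fr < 0.45)
  pk <- band[which.max(ra$power[band])]
  expect_gt(ra$power[pk], ra$power[min(band) - 2])
  expect_gt(ra$power[pk], ra$power[max(band) + 2])
})
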
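test_that("strip windows truncate at edges as specified", {
  w <- strip_window(11, 9, 100)
  expect_identical(which(w), 7:15)          # |p - r| <= 4.5
  expect_true(all(strip_window(5, 300, 100)))
  expect_identical(which(strip_window(1, 9, 100)), 1:5)
  expect_error(strip_window(0, 9, 100), "out of range")
})

test_that("fourier_oversample is exact band-limited interpolation", {
  img <- matrix(rnorm(32 * 24), 32, 24)
  expect_identical(fourier_oversample(img, 1), img)
  expect_error(fourier_oversample(img, 0), "positive integer")

  # pure cosine: oversampling must match the analytic cosine on the fine grid
  n <- 24; k <- 3
  nu <- 5 / n  # cycles per px
  x <- outer(rep(1, n), seq_len(n))
  cosim <- cos(2 * pi * nu * (x - 1))
  big <- fourier_oversample(cosim, k)
  fine <- outer(rep(1, n * k), 1 + (seq_len(n * k) - 1) / k)
  expect_lt(max(abs(big - cos(2 * pi * nu * (fine - 1)))), 1e-6)

  expect_equal(mean(fourier_oversample(img, 2)), mean(img),
               tolerance = 1e-9)
})

test_that("reference selection favors the motion-free frame", {
  sc <- small_scan()
  hits <- 0
  for (s in 1:8) {
    ph <- build_phantom(n_cones = 250, radius = 8, psf_sigma = 0.2,
                        seed = 100 + s)
    ser <- simulate_series(ph, sc, 5,
                           trace_params = list(step_rate = 1800),
                           seed = 200 + s)
    frames <- c(list(motion_free_crop(ph, sc)), ser$frames)
    sel <- select_reference(frames, expected_cone_frequency(ph),
                            strip_height = 16)
    if (sel$index == 1) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("reference selection degenerate cases", {
  frames <- list(matrix(rnorm(64 * 64), 64, 64))
  sel <- select_reference(frames, 0.2, strip_height = 16)
  expect_identical(sel$index, 1L)

  flat <- select_reference(list(matrix(1, 64, 64), frames[[1]]), 0.2,
                           strip_height = 16)
  expect_equal(flat$merit[1], 0)
  expect_error(select_reference(frames, 0.6), "f_c")
})

test_that("register_strip: self-match, integer shifts, sub-pixel shifts", {
  ph <- small_phantom(); sc <- small_scan()
  ref <- fourier_oversample(motion_free_crop(ph, sc), 3)
  self <- register_strip(ref, r = 72, W = 27, ref, max_lag = 30)
  expect_equal(c(self$sx, self$sy), c(0, 0))
  expect_equal(self$peak, 1, tolerance = 1e-6)

  o <- lagbias:::crop_origin(ph, sc)
  shifted <- fourier_oversample(
    ph$image[o[1] + (1:48) + 4, o[2] + (1:48) - 2], 3)
  hit <- register_strip(shifted, 72, 27, ref, max_lag = 30)
  expect_equal(c(hit$sx, hit$sy), c(-6, 12))  # (-2, +4) px at k = 3

  # a 1/3-px physical shift appears as one oversampled pixel
  tr <- structure(data.frame(t = (0:47) / sc$line_rate, x = 1 / 15, y = 0),
                  class = c("eye_trace", "data.frame"))
  sub <- fourier_oversample(warp_frame(ph, tr, sc), 3)
  hit2 <- register_strip(sub, 72, 27, ref, max_lag = 10)
  expect_equal(c(hit2$sx, hit2$sy), c(1, 0))

  zero <- register_strip(matrix(0, 144, 144), 72, 27, ref, max_lag = 10)
  expect_false(zero$valid)
})

test_that("register_frame recovers rigid shifts and per-row motion", {
  ph <- small_phantom(); sc <- small_scan()
  ref <- fourier_oversample(motion_free_crop(ph, sc), 3)
  lm0 <- register_frame(ref, ref, W = 27, increment = 12, max_lag = 20)
  expect_true(all(lm0$sx == 0 & lm0$sy == 0))

  o <- lagbias:::crop_origin(ph, sc)
  shifted <- fourier_oversample(
    ph$image[o[1] + (1:48) - 3, o[2] + (1:48) + 1], 3)
  lm1 <- register_frame(shifted, ref, W = 27, increment = 12, max_lag = 30)
  expect_true(all(lm1$sx == 3) && all(lm1$sy == -9))

  # shift equivariance: lags of a shifted target differ by exactly delta
  lm2 <- register_frame(shifted, ref, W = 27, increment = 12, max_lag = 30)
  expect_equal(lm2$sx - lm1$sx, rep(0, nrow(lm1)))

  # warped frame with a known smooth trace: per-row lags track the
  # per-line eye positions
  rr <- seq_len(48)
  tr <- structure(data.frame(t = (rr - 1) / sc$line_rate,
                             x = 0.4 * sin(2 * pi * rr / 32),
                             y = 0.1 * cos(2 * pi * rr / 24)),
                  class = c("eye_trace", "data.frame"))
  tos <- fourier_oversample(warp_frame(ph, tr, sc), 3)
  lm3 <- register_frame(tos, ref, W = 27, increment = 3, max_lag = 45)
  interior <- lm3$r >= 15 & lm3$r <= 130
  true_x <- approx(rr, tr$x * 5 * 3,
                   xout = 1 + (lm3$r[interior] - 1) / 3, rule = 2)$y
  fit <- summary(lm(lm3$sx[interior] ~ true_x))
  expect_gt(fit$r.squared, 0.9)
})

test_that("build_average keeps sum/counter books straight", {
  ph <- small_phantom(); sc <- small_scan()
  ref <- fourier_oversample(motion_free_crop(ph, sc), 3)
  lm <- cbind(frame = 1,
              register_frame(ref, ref, W = 27, increment = 9, max_lag = 10))
  avg <- build_average(list(ref), lm, W = 27)
  expect_equal(avg$average, ref, tolerance = 1e-9, ignore_attr = TRUE)

  expected_px <- sum(vapply(lm$r, function(r)
    length(lagbias:::strip_rows(r, 27, 144)) * 144L, integer(1)))
  expect_identical(sum(avg$counter), as.double(expected_px))

  # averaging across frames beats any single frame against the truth
  ser <- small_series()
  os <- lapply(ser$frames, fourier_oversample, k = 3)
  lm_all <- lagbias:::lag_map_series(os, ref, 27, 6, 45, 100)
  avg2 <- build_average(os, lm_all, W = 27)
  expect_true(all(avg2$counter >= 0))
  interior <- avg2$average[avg2$offset[1] + (1:144),
                           avg2$offset[2] + (1:144)]
  rho_avg <- whole_image_xcorr(interior, ref)$peak
  rho_one <- whole_image_xcorr(os[[1]], ref)$peak
  expect_gt(rho_avg, rho_one)
})

test_that("borrowed lags align a second channel (dual registration)", {
  ph <- small_phantom(); sc <- small_scan()
  ref <- fourier_oversample(motion_free_crop(ph, sc), 3)
  ser <- small_series()
  os <- lapply(ser$frames, fourier_oversample, k = 3)
  lm <- lagbias:::lag_map_series(os, ref, 27, 6, 45, 100)
  a1 <- build_average(os, lm, W = 27)
  a2 <- apply_lags_to_channel(os, lm, W = 27)
  expect_identical(a1$average, a2$average)

  doubled <- apply_lags_to_channel(lapply(os, function(f) 2 * f), lm, W = 27)
  expect_equal(doubled$average, 2 * a1$average, tolerance = 1e-12)

  inv <- lapply(os, function(f) max(f) - f)
  ainv <- apply_lags_to_channel(inv, lm, W = 27)
  inv_truth <- max(ref) - ref
  interior <- ainv$average[ainv$offset[1] + (1:144),
                           ainv$offset[2] + (1:144)]
  rho_avg <- whole_image_xcorr(interior, inv_truth)$peak
  rho_one <- max(vapply(inv, function(f)
    whole_image_xcorr(f, inv_truth)$peak, numeric(1)))
  expect_gt(rho_avg, rho_one)

  bad <- lapply(os, function(f) f[1:100, ])
  expect_error(apply_lags_to_channel(c(bad, os[1]), lm, W = 27), "shape")
})

test_that("average pixels are convex combinations of contributing strips", {
  ser <- small_series()
  os <- lapply(ser$frames[1:3], fourier_oversample, k = 3)
  ref <- os[[1]]
  lm <- lagbias:::lag_map_series(os, ref, 27, 12, 45, 100)
  avg <- build_average(os, lm, W = 27)
  hi <- max(vapply(os, max, numeric(1)))
  lo <- min(vapply(os, min, numeric(1)))
  used <- avg$counter > 0
  expect_lte(max(avg$average[used]), hi + 1e-9)
  expect_gte(min(avg$average[used]), lo - 1e-9)
})
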
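test_that("reference strips match themselves and rigid shifts", {
  ph <- small_phantom(); sc <- small_scan()
  ref <- fourier_oversample(motion_free_crop(ph, sc), 3)
  lags <- register_reference_strips(ref, list(ref), W = 27, increment = 12,
                                    max_lag = 20)
  expect_true(all(lags$sx == 0 & lags$sy == 0))
  expect_true(all(abs(lags$peak - 1) < 1e-6))

  o <- lagbias:::crop_origin(ph, sc)
  shifted <- fourier_oversample(
    ph$image[o[1] + (1:48) + 2, o[2] + (1:48) + 3], 3)
  lags2 <- register_reference_strips(ref, list(shifted, shifted), W = 27,
                                     increment = 12, max_lag = 30)
  # targets show content from (+2, +3) px deeper in the phantom, so the
  # reference strips match at negative displacements
  expect_true(all(lags2$sx == -9 & lags2$sy == -6))
})

test_that("tukey_filter matches the hand-computed oracle", {
  expect_true(all(tukey_filter(rep(5, 10))))
  expect_true(all(tukey_filter(c(1, 2, 100))))  # < 4 values: keep all

  v <- c(1:9, 100)
  # type-6 quartiles: Q1 = 2.75, Q3 = 8.25, fences (-5.5, 16.5)
  keep <- tukey_filter(v)
  expect_identical(keep, c(rep(TRUE, 9), FALSE))

  # values exactly on a fence are kept (closed interval)
  w <- c(-1, 2, 2, 2, 4, 4, 4, 7)  # fences are exactly [-1, 7]
  q <- quantile(w, c(0.25, 0.75), type = 6, names = FALSE)
  expect_identical(c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q)), c(-1, 7))
  expect_true(all(tukey_filter(w)))
})

test_that("estimate_bias averages, cancels, and survives fencing", {
  mk <- function(frames, rs, sx, sy) {
    structure(data.frame(frame = frames, r = rs, sx = sx, sy = sy,
                         peak = 1, valid = TRUE),
              n_rows = max(rs), W = 9,
              class = c("ref_strip_lags", "data.frame"))
  }
  rs <- rep(1:20, 2)
  const <- mk(rep(1:2, each = 20), rs, 3, -2)
  b <- estimate_bias(const, fence = FALSE)
  expect_true(all(b$xhat == 3 & b$yhat == -2))

  anti <- mk(rep(1:2, each = 20), rs, rep(c(4, -4), each = 20),
             rep(c(-1, 1), each = 20))
  b2 <- estimate_bias(anti, fence = FALSE)
  expect_true(all(abs(b2$xhat) < 1e-12 & abs(b2$yhat) < 1e-12))

  # 5% wild mismatches (at most one strip per frame): fencing keeps the
  # bias close to the clean value
  set.seed(1)
  f <- rep(1:30, each = 20); r <- rep(1:20, 30)
  truth <- sin(seq(0, pi, length.out = 20)) * 4
  sx <- truth[r] + rnorm(600, 0, 0.3)
  out_idx <- (0:29) * 20 + sample(20, 30, replace = TRUE)
  sx_bad <- sx; sx_bad[out_idx] <- sx_bad[out_idx] + 60
  clean <- estimate_bias(mk(f, r, sx, 0), fence = FALSE)
  fenced <- estimate_bias(mk(f, r, sx_bad, 0), fence = TRUE)
  unfenced <- estimate_bias(mk(f, r, sx_bad, 0), fence = FALSE)
  rms <- function(a, b) sqrt(mean((a - b)^2))
  err_f <- rms(fenced$xhat, clean$xhat)
  err_u <- rms(unfenced$xhat, clean$xhat)
  expect_lt(err_f, 0.2 * sqrt(mean((clean$xhat - mean(clean$xhat))^2)))
  expect_gt(err_u, err_f)

  all_bad <- mk(1:10, rep(1, 10), NA_real_, NA_real_)
  all_bad$valid <- FALSE
  expect_error(estimate_bias(all_bad), "discarded")
})

test_that("coordinate grids displace rows by the bias", {
  bias <- data.frame(row = 1:5, xhat = rep(0, 5), yhat = rep(0, 5))
  g0 <- coordinate_grids(5, 4, bias)
  df0 <- as.data.frame(g0)
  expect_equal(df0$X, df0$X0, ignore_attr = TRUE)
  expect_equal(df0$Y, df0$Y0, ignore_attr = TRUE)
  expect_identical(nrow(df0), 20L)

  bias1 <- data.frame(row = 1:5, xhat = rep(1, 5), yhat = rep(0, 5))
  df1 <- as.data.frame(coordinate_grids(5, 4, bias1))
  expect_equal(df1$X, df1$X0 + 1)
  dfm <- as.data.frame(coordinate_grids(5, 4, bias1, flip_sign = TRUE))
  expect_equal(dfm$X, dfm$X0 - 1)
})

test_that("dewarp inverts known row displacements", {
  ph <- small_phantom(); sc <- small_scan()
  ref <- fourier_oversample(motion_free_crop(ph, sc), 3)
  R <- nrow(ref)

  zero <- coordinate_grids(R, R, data.frame(row = 1:R, xhat = 0, yhat = 0))
  out <- dewarp(ref, zero)
  expect_equal(out[2:(R - 1), 2:(R - 1)], ref[2:(R - 1), 2:(R - 1)],
               tolerance = 1e-12, ignore_attr = TRUE)

  # mean-offset invariance: constant added to the bias only shifts the image
  bias <- data.frame(row = 1:R, xhat = sin(1:R / 15) * 4, yhat = 0)
  a <- dewarp(ref, coordinate_grids(R, R, bias))
  bias_off <- bias; bias_off$xhat <- bias$xhat + 3
  b <- dewarp(ref, coordinate_grids(R, R, bias_off))
  expect_equal(a[, 10:(R - 13)], b[, 13:(R - 10)], tolerance = 1e-9,
               ignore_attr = TRUE)

  # dewarping with the true trace improves correspondence with the object
  ser <- small_series()
  w <- ser$frames[[2]]; tr <- ser$traces[[2]]
  wos <- fourier_oversample(w, 3)
  rows_os <- 1 + (seq_len(nrow(wos)) - 1) / 3
  true_bias <- data.frame(
    row = seq_len(nrow(wos)),
    xhat = approx(1:48, tr$x * 5, xout = rows_os, rule = 2)$y * 3,
    yhat = approx(1:48, tr$y * 5, xout = rows_os, rule = 2)$y * 3)
  fixed <- dewarp(wos, coordinate_grids(nrow(wos), ncol(wos), true_bias))
  obj <- fourier_oversample(motion_free_crop(ph, sc), 3)
  expect_gt(whole_image_xcorr(fixed, obj)$peak,
            whole_image_xcorr(wos, obj)$peak)

  # linear and nearest interpolation agree closely on smooth dewarps
  near <- dewarp(wos, coordinate_grids(nrow(wos), ncol(wos), true_bias),
                 method = "nearest")
  expect_gte(whole_image_xcorr(fixed, near)$peak, 0.99)
})

test_that("zero-motion series is a fixed point of the bias estimate", {
  ph <- small_phantom(); sc <- small_scan()
  crop <- motion_free_crop(ph, sc)
  os <- fourier_oversample(crop, 3)
  lags <- register_reference_strips(os, list(os, os, os), W = 27,
                                    increment = 6, max_lag = 20)
  bias <- estimate_bias(lags)
  expect_lt(sqrt(mean(bias$xhat^2)), 0.5)
  expect_lt(sqrt(mean(bias$yhat^2)), 0.5)
  grid <- coordinate_grids(nrow(os), ncol(os), bias)
  out <- dewarp(os, grid)
  inner <- 5:(nrow(os) - 5)
  expect_equal(out[inner, inner], os[inner, inner], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("run_pipeline is deterministic and improves both references", {
  ser <- small_series()
  cfg <- pipeline_config(W = 9, k = 3, increment = 4,
                         f_c = expected_cone_frequency(small_phantom()),
                         max_lag = 9, averages = FALSE)
  r1 <- run_pipeline(ser, cfg)
  r2 <- run_pipeline(ser, cfg)
  expect_identical(r1$corrected_reference, r2$corrected_reference)
  expect_identical(r1$bias, r2$bias)
  expect_error(run_pipeline(ser$frames[1], cfg), "at least two")
})
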
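make_series <- function(X, tr_s, sms = 1L) {
  # time x voxel matrix -> ts_image on a (v, 1, 1) grid
  d <- c(ncol(X), 1L, 1L, nrow(X))
  ts_image(array(t(X), d), tr_s = tr_s, sms_factor = sms)
}

test_that("downsampling keeps every Nth volume and rescales the TR", {
  set.seed(80)
  X <- matrix(rnorm(1240 * 3), 1240, 3)
  s <- make_series(X, 0.35, 8L)
  d8 <- downsample_series(s, 8)
  expect_equal(dim(d8$data)[4], 155L)                 # 1240 / 8
  expect_equal(d8$tr_s, 2.8)
  expect_equal(d8$data[1, 1, 1, ], X[seq(1, 1240, by = 8), 1])
  d8b <- downsample_series(s, 8, phase = 3)
  expect_equal(d8b$data[1, 1, 1, ], X[seq(4, 1240, by = 8), 1])
  expect_identical(downsample_series(s, 1)$data, s$data)  # N = 1 identity
  expect_error(downsample_series(s, 7), "divisible")
  expect_error(downsample_series(s, 8, phase = 8), "phase")
})

test_that("downsampling folds a 1 Hz tone to its predicted alias frequency", {
  t <- (0:1239) * 0.35
  x <- sin(2 * pi * 1.0 * t)
  s <- make_series(cbind(x), 0.35, 8L)
  d <- downsample_series(s, 8)
  pg <- smssense:::periodogram_mat(matrix(d$data[1, 1, 1, ], ncol = 1), 2.8)
  fs_new <- 1 / 2.8
  f_alias <- abs(1 - round(1 / fs_new) * fs_new)
  expect_equal(pg$freq[which.max(pg$power)], f_alias, tolerance = 0.01)
})

test_that("Butterworth decimation matches the closed-form magnitude response", {
  tr <- 0.35; n <- 1240
  t <- (0:(n - 1)) * tr
  spec <- decimation_spec(order = 6, cutoff_hz = 0.18)
  # constant series is unchanged (DC gain one)
  cst <- make_series(cbind(rep(5, n)), tr, 8L)
  f <- decimate_series(cst, spec, 8)
  expect_equal(f$data[1, 1, 1, ], rep(5, 155), tolerance = 1e-9)

  # zero-phase analog prototype |H|^2 = 1 / (1 + (f/fc)^(2 order))
  Hmag2 <- function(f) 1 / (1 + (f / 0.18)^12)
  probe <- function(freq) {
    x <- sin(2 * pi * freq * t)
    s <- make_series(cbind(x), tr, 8L)
    filt <- smssense:::butter_lowpass_mat(cbind(x), 6, 0.18, 1 / tr, TRUE)
    # amplitude ratio on the interior (transient-free) samples
    mid <- 200:1040
    sqrt(sum(filt[mid, 1]^2) / sum(x[mid]^2))
  }
  # 1 Hz tone: attenuated by more than 1e3 in amplitude
  expect_lt(probe(1.0), 1e-3)
  # 0.05 Hz passes within 2 percent, matching |H|^2 at 0.05 Hz
  expect_equal(probe(0.05), Hmag2(0.05), tolerance = 0.02)
  expect_gt(probe(0.05), 0.98)

  # cutoff at or above Nyquist is rejected
  s1 <- make_series(cbind(sin(t)), 2.8, 1L)
  expect_error(decimate_series(s1, spec, 1), "Nyquist")
})

test_that("decimated and downsampled series agree for an in-band signal", {
  tr <- 0.7; n <- 620
  t <- (0:(n - 1)) * tr
  x <- sin(2 * pi * 0.03 * t) + 0.5 * cos(2 * pi * 0.08 * t)
  s <- make_series(cbind(x), tr, 4L)
  down <- downsample_series(s, 4)
  dec <- decimate_series(s, decimation_spec(), 4)
  expect_equal(dec$data[1, 1, 1, ], down$data[1, 1, 1, ], tolerance = 0.02)
  expect_equal(dec$tr_s, down$tr_s)
  expect_equal(dim(dec$data), dim(down$data))
})

test_that("design matrix has the documented DCT convention and full rank", {
  sch <- tiny_schedule()
  X <- build_design_matrix(sch, 2.8, 155)
  # K = floor(2 T / 128) columns for T = 434 s
  expect_equal(sum(grepl("^dct", colnames(X))), floor(2 * 434 / 128))
  D <- X[, grepl("^dct", colnames(X))]
  expect_equal(crossprod(D), diag(ncol(D)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(qr(X)$rank, ncol(X))
  # contrasts orthogonal to the intercept direction
  ctr <- attr(X, "contrasts")
  expect_equal(ctr$scene_minus_object[colnames(X) == "intercept"], 0)
  # no events: intercept + DCT only
  sch0 <- sch
  sch0$blocks <- sch$blocks[sch$blocks$condition == "baseline", ]
  X0 <- build_design_matrix(sch0, 2.8, 155)
  expect_false(any(c("scene", "object") %in% colnames(X0)))
  expect_equal(ncol(X0), 1 + floor(2 * 434 / 128))
})

test_that("tSNR equals mean over residual sd and masks zero-variance voxels", {
  set.seed(90)
  n <- 155
  sch <- tiny_schedule()
  X <- build_design_matrix(sch, 2.8, n)
  # constant 100 + unit white noise: tSNR ~ 100
  Y <- matrix(100 + rnorm(n * 200), n, 200)
  s <- make_series(Y, 2.8)
  g <- fit_glm_ar1(s, X)
  ts <- compute_tsnr(s, g)
  expect_equal(mean(ts), 100, tolerance = 5)
  # zero-noise series: masked, not infinite
  Yc <- matrix(100, n, 3)
  sc <- make_series(Yc, 2.8)
  gc_ <- fit_glm_ar1(sc, X)
  tc <- compute_tsnr(sc, gc_)
  expect_true(all(is.na(tc)))
})

test_that("tSNR is invariant to task amplitude while t-scores increase with it", {
  set.seed(91)
  n <- 155
  sch <- tiny_schedule()
  X <- build_design_matrix(sch, 2.8, n)
  noise <- matrix(rnorm(n * 300), n, 300)
  make_y <- function(amp) 100 + amp * X[, "scene"] + noise
  g1 <- fit_glm_ar1(make_series(make_y(1), 2.8), X)
  g2 <- fit_glm_ar1(make_series(make_y(2), 2.8), X)
  t1 <- compute_tsnr(make_series(make_y(1), 2.8), g1)
  t2 <- compute_tsnr(make_series(make_y(2), 2.8), g2)
  expect_equal(mean(t2) / mean(t1), 1, tolerance = 0.01)
  expect_gt(mean(g2$t[, "task_vs_baseline"]), mean(g1$t[, "task_vs_baseline"]))
})

test_that("high-frequency content obeys the Parseval decomposition", {
  tr <- 0.35; n <- 1240
  t <- (0:(n - 1)) * tr
  # pure 1 Hz unit sinusoid: band sum ~ total power 1/2
  x <- sin(2 * pi * 1 * t)
  s <- make_series(cbind(x), tr, 8L)
  hf <- high_freq_content(s, 0.18)
  expect_equal(hf[1, 1, 1], 0.5, tolerance = 0.01)
  expect_false(attr(hf, "empty_band"))

  # band + complement = total (biased) variance for white noise
  set.seed(92)
  y <- rnorm(n)
  sy <- make_series(cbind(y), tr, 8L)
  hfy <- high_freq_content(sy, 0.18)
  pg <- smssense:::periodogram_mat(cbind(y), tr)
  expect_equal(sum(pg$power), mean((y - mean(y))^2), tolerance = 1e-10)
  lo <- sum(pg$power[pg$freq <= 0.18, 1])
  expect_equal(hfy[1, 1, 1] + lo, mean((y - mean(y))^2), tolerance = 1e-10)
  # expected band fraction for white noise ~ band width / full width
  expect_equal(hfy[1, 1, 1] / sum(pg$power), (1 / (2 * tr) - 0.18) / (1 / (2 * tr)),
               tolerance = 0.1)

  # SMS 1 rate: Nyquist 0.179 < 0.18, empty band -> zero map with flag
  s1 <- make_series(cbind(rnorm(155)), 2.8, 1L)
  h1 <- high_freq_content(s1, 0.18)
  expect_true(all(h1 == 0))
  expect_true(attr(h1, "empty_band"))
})

test_that("spectral power fraction is exact for pure tones and excludes DC", {
  n <- 4340
  t <- (seq_len(n) - 1) * 0.1
  f0 <- 22 / (n * 0.1)              # bin-centred tone, no leakage
  x <- sin(2 * pi * f0 * t)
  expect_equal(spectral_power_fraction(x, 0.1, c(0.02, 0.08)), 1,
               tolerance = 1e-9)
  expect_lt(spectral_power_fraction(x, 0.1, c(0.1, 1)), 1e-9)
  # adding a DC offset changes nothing
  expect_equal(spectral_power_fraction(x + 10, 0.1, c(0.02, 0.08)), 1,
               tolerance = 1e-9)
  # band entirely above the Nyquist frequency is empty
  expect_error(spectral_power_fraction(x, 0.1, c(5.0, 6.0)), "empty")
})

test_that("ROI definition finds the peak and matches a brute-force sphere count", {
  d <- c(11L, 11L, 7L)
  tm <- array(0, d)
  tm[6, 6, 4] <- 5
  tm[3, 3, 2] <- 3
  anat <- array(TRUE, d)
  gm <- array(TRUE, d)
  vox <- c(3, 3, 3)
  roi <- define_roi(tm, anat, gm, radius_mm = 5, voxel_size_mm = vox)
  expect_equal(roi$center, c(6L, 6L, 4L))
  # enumeration oracle for the sphere voxel count on a 3 mm grid
  cnt <- 0
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    if (sum(((c(i, j, k) - c(6, 6, 4)) * vox)^2) <= 25) cnt <- cnt + 1
  expect_equal(roi$n_voxels, cnt)
  # translation equivariance
  tm2 <- array(0, d); tm2[7, 5, 3] <- 5
  roi2 <- define_roi(tm2, anat, gm, radius_mm = 5, voxel_size_mm = vox)
  expect_equal(roi2$center, c(7L, 5L, 3L))
  # GM masking and empty-intersection error
  gm0 <- array(FALSE, d)
  expect_error(define_roi(tm, anat, gm0, 5, vox), "gray-matter")
  expect_error(define_roi(tm, array(FALSE, d), gm, 5, vox), "empty")
})

test_that("top-10% ROI mean uses the ceiling count convention", {
  d <- c(30L, 1L, 1L)
  tmap <- array(0, d)
  roi <- array(FALSE, d)
  # 10 voxels with t = 1..10: top-1 mean = 10
  roi[1:10] <- TRUE; tmap[1:10] <- 1:10
  expect_equal(roi_top10_mean(tmap, roi), 10)
  # all-equal map returns that value
  tmap[1:10] <- 7
  expect_equal(roi_top10_mean(tmap, roi), 7)
  # 23 voxels: ceiling(2.3) = 3 top values, against a sort-based oracle
  roi <- array(FALSE, d); roi[1:23] <- TRUE
  set.seed(93); vals <- rnorm(23); tmap[1:23] <- vals
  expect_equal(roi_top10_mean(tmap, roi),
               mean(sort(vals, decreasing = TRUE)[1:3]))
})

test_that("suprathreshold counting is a strict threshold on t", {
  d <- c(20L, 1L, 1L)
  tmap <- array(0, d); roi <- array(FALSE, d); roi[1:20] <- TRUE
  expect_equal(roi_count_significant(tmap, roi), 0)
  tmap[1:7] <- 4; tmap[8] <- 3.1  # boundary value not counted
  expect_equal(roi_count_significant(tmap, roi, 3.1), 7)
})

test_that("percent change matches its formula and rejects zero reference", {
  expect_equal(percent_change(110, 100), 10)
  expect_equal(percent_change(100, 100), 0)
  set.seed(94)
  v <- rnorm(20, 10); r <- rnorm(20, 10)
  expect_equal(percent_change(v, r), 100 * (v - r) / r)
  expect_error(percent_change(1, 0), "non-zero")
})
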
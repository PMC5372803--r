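test_that("SMS 1 kernels are the identity and reconstruct the input exactly", {
  p <- tiny_protocols()$sms1
  kern <- fit_slice_grappa(tiny_calib(p), p)
  # delta tap at zero offset on the matching coil
  wimg <- smssense:::kernel_image_weights(kern)
  nc <- kern$n_coils
  for (g in seq_along(wimg)) {
    wf <- array(wimg[[g]], c(prod(p$matrix), nc, nc))
    for (ci in seq_len(nc)) for (co in seq_len(nc)) {
      target <- if (ci == co) 1 else 0
      expect_equal(max(Mod(wf[, ci, co] - target)), 0, tolerance = 1e-12)
    }
  }
  run <- tiny_run(p)
  ksp <- one_volume_kspace(sms_encode(run, seed = 1))
  rec <- reconstruct_series(ksp, kern)
  gt <- combine_coils(tiny_ref_images(p), "rss")
  expect_equal(rec$data[, , , 1], gt, tolerance = 1e-10)
})

test_that("kernels reproduce each slice from synthetically collapsed calibration with disjoint coil support", {
  # two slices seen by disjoint coil subsets: exact unaliasing is possible
  # and the fitted kernels must find it (relative error < 1e-6)
  p <- acquisition_protocol(2, 1400, 76, 2, 310, n_slices = 2,
                            matrix = c(16L, 18L))
  nc <- 4L
  sens <- array(0i, c(16, 18, 2, nc))
  ph <- tiny_phantom()
  base <- ph$pd[, , 1:2] + 0.1
  set.seed(50)
  smooth_map <- function() {
    # full-spectrum random field with decaying coefficients: smooth but
    # well-conditioned for the kernel fit
    kx <- pmin(0:15, 16 - (0:15)); ky <- pmin(0:17, 18 - (0:17))
    decay <- exp(-outer(kx^2, ky^2, `+`) / 8)
    z <- matrix(complex(real = rnorm(288), imaginary = rnorm(288)), 16, 18) *
      decay
    smssense:::fft2(z)
  }
  for (c in 1:2) sens[, , 1, c] <- smooth_map()        # coils 1-2: slice 1
  for (c in 3:4) sens[, , 2, c] <- smooth_map()        # coils 3-4: slice 2
  img <- array(0i, c(16, 18, 2, nc))
  for (c in seq_len(nc)) img[, , , c] <- base * sens[, , , c]
  calib <- list(kspace = aperm(smssense:::fft2(img), c(1, 2, 4, 3)))
  for (lb in c(FALSE, TRUE)) {
    kern <- fit_slice_grappa(calib, p, leakblock = lb, ridge = 0)
    expect_lt(max(kern$fit_residual), 1e-6)
    ksp <- sms_encode(img, p, make_coil_array(nc, c(16L, 18L, 2L)), seed = 1)
    out <- apply_kernels(ksp, kern)
    expect_equal(out[, , , , 1], calib$kspace, tolerance = 1e-6)
  }
})

test_that("LeakBlock kernels leak strictly less across slices than standard kernels", {
  p <- small_protocols()$sms2
  calib <- small_calib(p)
  k_std <- fit_slice_grappa(calib, p, leakblock = FALSE)
  k_lb <- fit_slice_grappa(calib, p, leakblock = TRUE)
  grp <- k_std$groups; shifts <- k_std$shifts
  # energy recovered in slice B when only slice A carries signal
  leakage <- function(kern) {
    g <- 1
    sA <- grp[1, g]; total <- 0
    imgA <- array(0i, c(dim(calib$kspace)[1:2], p$n_slices,
                        dim(calib$kspace)[3]))
    imgA[, , sA, ] <- aperm(calib$images[, , , sA], c(1, 2, 3))
    ksp <- sms_encode(imgA, p, small_coils(), seed = 1)
    out <- apply_kernels(ksp, kern)
    sB <- grp[2, g]
    sum(Mod(out[, , , sB, 1])^2) / sum(Mod(out[, , , sA, 1])^2)
  }
  expect_lt(leakage(k_lb), leakage(k_std))
})

test_that("kernel application is linear and identity kernels pass input through", {
  p <- tiny_protocols()$sms2
  co <- tiny_coils()
  d <- c(tiny_grid, co$n_coils)
  set.seed(60)
  a <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  b <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  kern <- fit_slice_grappa(tiny_calib(p), p)
  ka <- apply_kernels(sms_encode(a, p, co, seed = 1), kern)
  kb <- apply_kernels(sms_encode(b, p, co, seed = 1), kern)
  kab <- apply_kernels(sms_encode(a + b, p, co, seed = 1), kern)
  expect_equal(kab, ka + kb, tolerance = 1e-9)

  # identity kernels on single-band data: output equals input per slice
  p1 <- tiny_protocols()$sms1
  kern1 <- fit_slice_grappa(tiny_calib(p1), p1)
  ksp1 <- one_volume_kspace(sms_encode(tiny_run(p1), seed = 1))
  out1 <- apply_kernels(ksp1, kern1)
  expect_equal(out1[, , , , 1], aperm(ksp1$data[, , , , 1], c(1, 2, 3, 4)),
               tolerance = 1e-10)
})

test_that("noiseless SMS reconstruction error is small and volume order is immaterial", {
  p <- small_protocols()$sms2
  kern <- fit_slice_grappa(small_calib(p), p)
  run <- small_run(p)
  ksp <- sms_encode(run, seed = 2)
  ksp$data <- ksp$data[, , , , 1:3, drop = FALSE]
  rec <- reconstruct_series(ksp, kern)
  gt <- combine_coils(small_ref_images(p), "rss")
  relerr <- sqrt(sum((rec$data[, , , 1] - gt)^2) / sum(gt^2))
  expect_lt(relerr, 0.01)

  # statelessness: permuting input volumes permutes the output identically
  perm <- c(3, 1, 2)
  ksp_p <- ksp; ksp_p$data <- ksp$data[, , , , perm, drop = FALSE]
  rec_p <- reconstruct_series(ksp_p, kern)
  expect_equal(rec_p$data, rec$data[, , , perm, drop = FALSE])
})

test_that("kernel fitting reports rank deficiency at ridge zero instead of regularizing", {
  p <- tiny_protocols()$sms2
  calib <- tiny_calib(p)
  calib$kspace[] <- 0i   # degenerate calibration
  expect_error(fit_slice_grappa(calib, p, ridge = 0), "rank-deficient")
})

test_that("coil combination methods behave as documented", {
  set.seed(70)
  d <- c(5L, 6L, 2L)
  ci <- array(complex(real = rnorm(60), imaginary = rnorm(60)), d)
  # single coil, unit sensitivity: |image|
  one <- array(ci[, , 1], c(5L, 6L, 1L))
  expect_equal(combine_coils(one, "rss"), Mod(ci[, , 1]))
  # rss invariant to per-coil global phase
  ci2 <- ci
  ci2[, , 1] <- ci[, , 1] * exp(1i * 0.7)
  ci2[, , 2] <- ci[, , 2] * exp(-1i * 1.3)
  expect_equal(combine_coils(ci, "rss"), combine_coils(ci2, "rss"))
  # cov_weighted with identity covariance equals rss (2-coil closed form:
  # sqrt(|a|^2 + |b|^2))
  a <- 3 + 4i; b <- 1 - 2i
  toy <- array(c(a, b), c(1L, 1L, 2L))
  expect_equal(as.vector(combine_coils(toy, "cov_weighted", diag(2))),
               sqrt(Mod(a)^2 + Mod(b)^2))
  expect_equal(combine_coils(ci, "cov_weighted", diag(2)),
               combine_coils(ci, "rss"))
  expect_error(combine_coils(ci, "unknown"))
  expect_error(combine_coils(ci, "cov_weighted"), "noise_cov")
})

test_that("mismatched kernels and k-space are rejected", {
  p2 <- tiny_protocols()$sms2
  p4 <- tiny_protocols()$sms4
  kern4 <- fit_slice_grappa(tiny_calib(p4), p4)
  ksp2 <- one_volume_kspace(sms_encode(tiny_run(p2), seed = 1))
  expect_error(apply_kernels(ksp2, kern4), "different protocol")
  expect_error(reconstruct_series(ksp2, NULL), "required")
})
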
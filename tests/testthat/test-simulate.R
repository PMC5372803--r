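test_that("zero activation and zero noise give a time-constant series", {
  run <- tiny_run(tiny_protocols()$sms1)
  s <- ground_truth_series(run, volumes = c(1, 50, 155))
  expect_equal(s[, , , 1], s[, , , 2])
  expect_equal(s[, , , 1], s[, , , 3])
  expect_equal(s[, , , 1], run$base)
})

test_that("activation outside the phantom regions is rejected", {
  expect_error(
    simulate_bold_run(tiny_phantom(), tiny_coils(), tiny_schedule(),
                      quiet_noise(), tiny_protocols()$sms1,
                      activation_spec = list(nowhere = c(scene = 1, object = 1))),
    "outside")
})

test_that("vessel voxels show their cardiac spectral peak when fully sampled", {
  p <- tiny_protocols()$tr350  # TR 0.35 s: 1 Hz fully sampled
  ns <- noise_spec(thermal_scale = 0,
                   physio = list(list(freq_hz = 1.0, amp = 0.05,
                                      region = "vessel")),
                   drift = list(amp = 0, period_s = 300))
  run <- simulate_bold_run(tiny_phantom(), tiny_coils(), tiny_schedule(),
                           ns, p, seed = 31)
  vi <- which(tiny_phantom()$vessel_mask)[1]
  idx <- arrayInd(vi, tiny_grid)
  x <- vapply(seq_len(256), function(v)
    smssense:::ground_truth_volume(run, v)[idx[1], idx[2], idx[3]],
    numeric(1))
  pg <- smssense:::periodogram_mat(matrix(x - mean(x), ncol = 1), 0.35)
  expect_equal(pg$freq[which.max(pg$power)], 1.0, tolerance = 0.02)
})

test_that("a 1 Hz component sampled at TR 2.8 s aliases to the folded frequency", {
  p <- tiny_protocols()$sms1
  ns <- noise_spec(thermal_scale = 0,
                   physio = list(list(freq_hz = 1.0, amp = 0.05,
                                      region = "vessel")),
                   drift = list(amp = 0, period_s = 300))
  run <- simulate_bold_run(tiny_phantom(), tiny_coils(), tiny_schedule(),
                           ns, p, seed = 32)
  vi <- which(tiny_phantom()$vessel_mask)[1]
  idx <- arrayInd(vi, tiny_grid)
  x <- vapply(seq_len(155), function(v)
    smssense:::ground_truth_volume(run, v)[idx[1], idx[2], idx[3]],
    numeric(1))
  pg <- smssense:::periodogram_mat(matrix(x - mean(x), ncol = 1), 2.8)
  # alias-frequency formula: |f - round(f/fs) fs| with fs = 1/2.8
  fs <- 1 / 2.8
  f_alias <- abs(1 - round(1 / fs) * fs)
  expect_equal(pg$freq[which.max(pg$power)], f_alias, tolerance = 0.01)
})

test_that("SMS 1 encoding is plain per-slice multi-coil k-space", {
  run <- tiny_run(tiny_protocols()$sms1)
  ksp <- sms_encode(run, seed = 1)
  expect_equal(dim(ksp$data)[4], 4L)      # one group per slice
  calib <- tiny_calib(tiny_protocols()$sms1)
  expect_equal(ksp$data[, , , , 1], aperm(calib$kspace, c(1, 2, 3, 4)),
               tolerance = 1e-12)
})

test_that("encoding is linear in its image input when noise is disabled", {
  p <- tiny_protocols()$sms2
  co <- tiny_coils()
  d <- c(tiny_grid, co$n_coils)
  set.seed(41)
  a <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  b <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  ka <- sms_encode(a, p, co, seed = 1)
  kb <- sms_encode(b, p, co, seed = 1)
  kab <- sms_encode(a + b, p, co, seed = 1)
  expect_equal(kab$data, ka$data + kb$data, tolerance = 1e-10)
})

test_that("a noiseless SMS 2 group shows the second slice displaced by FOV/2", {
  p <- tiny_protocols()$sms2
  co <- tiny_coils()
  ph <- tiny_phantom()
  # point object in slice of the second group member only
  grp <- smssense:::slice_groups(p)
  img <- array(0i, c(tiny_grid, co$n_coils))
  img[8, 9, grp[2, 1], ] <- 1
  ksp <- sms_encode(img, p, co, seed = 1)
  rec <- smssense:::ifft2(ksp$data[, , 1, 1, 1])
  peak <- arrayInd(which.max(Mod(rec)), dim(rec))[1, ]
  expect_equal(peak[1], 8)
  expect_equal(peak[2], ((9 - 1 + 9) %% 18) + 1)   # shifted by ny/2 = 9
})

test_that("encoding is reproducible from its seed", {
  run <- tiny_run(tiny_protocols()$sms2)
  ns <- noise_spec(thermal_scale = 0.01)
  run$noise <- ns
  k1 <- sms_encode(run, seed = 9)
  k2 <- sms_encode(run, seed = 9)
  k3 <- sms_encode(run, seed = 10)
  expect_identical(k1$data, k2$data)
  expect_false(identical(k1$data, k3$data))
})
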
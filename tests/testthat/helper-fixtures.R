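# Shared fixtures, built lazily in code and cached for the whole run.
# The "tiny" geometry (16 x 18 x 4, 4 coils) keeps unit tests fast; the
# "small" geometry (32 x 36 x 8, 8 coils) is used where the acceptance
# checks prescribe it.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fix)) assign(name, expr, envir = .fix)
  get(name, envir = .fix)
}

tiny_grid <- c(16L, 18L, 4L)
tiny_voxel <- c(192 / 16, 192 / 18, 60 / 4)

tiny_phantom <- function() fixture("tiny_phantom",
  make_phantom(tiny_grid, tiny_voxel, seed = 11))

tiny_coils <- function() fixture("tiny_coils",
  make_coil_array(4L, tiny_grid, seed = 12))

# only SMS 1/2/4 fit in 4 slices; a TR-350 ms variant stands in where the
# fastest sampling rate is needed
tiny_protocols <- function() fixture("tiny_protocols", list(
  sms1 = acquisition_protocol(1, 2800, 87, 0, 155, n_slices = 4L,
                              matrix = c(16L, 18L)),
  sms2 = acquisition_protocol(2, 1400, 76, 2, 310, n_slices = 4L,
                              matrix = c(16L, 18L)),
  sms4 = acquisition_protocol(4, 700, 60, 3, 620, n_slices = 4L,
                              matrix = c(16L, 18L)),
  tr350 = acquisition_protocol(4, 350, 45, 3, 1240, n_slices = 4L,
                               matrix = c(16L, 18L))))

tiny_schedule <- function() fixture("tiny_schedule",
  make_task_design(434, seed = 13))

quiet_noise <- function() smssense:::silent_noise()

# static noiseless run (no activation, no physio/drift)
tiny_run <- function(protocol = tiny_protocols()$sms2) {
  key <- paste0("tiny_run_sms", protocol$sms_factor)
  fixture(key, simulate_bold_run(tiny_phantom(), tiny_coils(),
                                 tiny_schedule(), quiet_noise(), protocol,
                                 seed = 14))
}

tiny_calib <- function(protocol = tiny_protocols()$sms2) {
  key <- paste0("tiny_calib_sms", protocol$sms_factor)
  fixture(key, singleband_calibration(tiny_run(protocol)))
}

tiny_ref_images <- function(protocol = tiny_protocols()$sms2) {
  aperm(tiny_calib(protocol)$images, c(1, 2, 4, 3))
}

small_grid <- c(32L, 36L, 8L)
small_voxel <- c(6, 192 / 36, 15)

small_phantom <- function() fixture("small_phantom",
  make_phantom(small_grid, small_voxel, seed = 21))

small_coils <- function() fixture("small_coils",
  make_coil_array(8L, small_grid, seed = 22))

small_protocols <- function() fixture("small_protocols",
  default_protocols(n_slices = 8L, matrix = c(32L, 36L)))

small_run <- function(protocol = small_protocols()$sms2) {
  key <- paste0("small_run_sms", protocol$sms_factor)
  fixture(key, simulate_bold_run(small_phantom(), small_coils(),
                                 fixture("small_schedule",
                                         make_task_design(434, seed = 23)),
                                 quiet_noise(), protocol, seed = 24))
}

small_calib <- function(protocol = small_protocols()$sms2) {
  key <- paste0("small_calib_sms", protocol$sms_factor)
  fixture(key, singleband_calibration(small_run(protocol)))
}

small_ref_images <- function(protocol = small_protocols()$sms2) {
  aperm(small_calib(protocol)$images, c(1, 2, 4, 3))
}

# single k-space volume helper
one_volume_kspace <- function(ksp) {
  ksp$data <- ksp$data[, , , , 1, drop = FALSE]
  ksp
}
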
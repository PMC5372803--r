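#' Noise specification for the synthetic scanner
#'
#' @param thermal_scale Per-coil, per-volume image-domain thermal noise
#'   standard deviation (signal units; the k-space noise injected by
#'   [sms_encode()] is scaled so that an unaccelerated reconstruction has
#'   this per-coil image noise level). 0 disables thermal noise.
#' @param physio List of components, each `list(freq_hz=, amp=, region=)`:
#'   a sinusoidal fractional signal modulation of amplitude `amp` at
#'   `freq_hz`, applied over `region` ("vessel", "gm", or "brain"). The
#'   defaults place ~1 Hz cardiac pulsation on the vessel hotspots and
#'   ~0.3 Hz respiration over the brain.
#' @param drift List `(amp=, period_s=)`: slow cosine drift as a fraction of
#'   baseline signal.
#' @param seed Seed for physiological phases (thermal noise is seeded
#'   separately at encode time).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(thermal_scale = 0.008,
                       physio = list(
                         list(freq_hz = 1.0, amp = 0.03, region = "vessel"),
                         list(freq_hz = 0.3, amp = 0.01, region = "brain")),
                       drift = list(amp = 0.005, period_s = 300),
                       seed = 1L) {
  if (thermal_scale < 0) stop("thermal_scale must be >= 0")
  for (p in physio) {
    if (p$freq_hz <= 0) stop("physiological frequencies must be positive")
    if (p$amp < 0) stop("physiological amplitudes must be >= 0")
  }
  structure(list(thermal_scale = thermal_scale, physio = physio,
                 drift = drift, seed = as.integer(seed)),
            class = "noise_spec")
}

silent_noise <- function() noise_spec(thermal_scale = 0, physio = list(),
                                      drift = list(amp = 0, period_s = 300))

resolve_region_map <- function(region, phantom) {
  if (is.array(region)) return(region * 1)
  switch(region,
         vessel = phantom$vessel_mask * 1,
         gm = phantom$gm_mask * 1,
         brain = phantom$support * 1,
         stop("unknown physiological noise region: ", region))
}

#' Simulate a noiseless-in-k-space BOLD ground-truth run
#'
#' Composes the voxelwise signal model
#' \deqn{s(x, t) = \rho(x)\, S_{ss}(x) \, [1 + BOLD(x,t) + physio(x,t) + drift(t)]}
#' where \eqn{\rho} is proton density, \eqn{S_{ss}} the spoiled steady-state
#' scaling from the protocol's (TR, flip) and the voxel T1, BOLD the
#' HRF-convolved task response scaled by the percent-signal-change
#' amplitudes in `activation_spec`, and physio/drift the sinusoidal
#' fractional modulations of `noise`. Thermal noise is *not* added here; it
#' enters in k-space during [sms_encode()].
#'
#' The series is stored in factored form (static baseline image plus a
#' small set of spatial modes with temporal modulators), so runs with many
#' volumes stay cheap; use [ground_truth_series()] or
#' [coil_slice_images()] to materialize volumes.
#'
#' @param phantom An `sms_phantom`.
#' @param coils A `coil_array` on the same grid.
#' @param schedule A `stim_schedule`.
#' @param noise A `noise_spec`.
#' @param protocol An `sms_protocol`.
#' @param activation_spec Named list over phantom region names; each entry a
#'   named numeric `c(scene=, object=)` of percent signal change.
#' @param seed Seed for physiological phases.
#' @return An object of class `sms_run`.
#' @export
simulate_bold_run <- function(phantom, coils, schedule, noise, protocol,
                              activation_spec = list(), seed = 1L) {
  stopifnot(inherits(phantom, "sms_phantom"), inherits(coils, "coil_array"),
            inherits(schedule, "stim_schedule"), inherits(noise, "noise_spec"),
            inherits(protocol, "sms_protocol"))
  if (!all(phantom$grid_shape == coils$grid_shape))
    stop("phantom and coil grids differ")
  if (protocol$n_slices != phantom$grid_shape[3])
    stop("protocol n_slices must equal the phantom slice count")
  for (nm in names(activation_spec))
    if (!nm %in% names(phantom$regions))
      stop("activation region outside phantom support: ", nm)

  tr_s <- protocol$tr_ms / 1000
  nvol <- protocol$n_volumes
  nvox <- prod(phantom$grid_shape)

  # static baseline: proton density x steady-state scaling (per-voxel T1)
  base <- phantom$pd
  e1 <- exp(-protocol$tr_ms / pmax(phantom$t1, 1))
  a <- protocol$flip_deg * pi / 180
  sss <- sin(a) * (1 - e1) / (1 - cos(a) * e1)
  sss[phantom$t1 <= 0] <- 0
  base <- base * sss

  # spatial modes (nvox x K) and temporal modulators (K x nvol)
  modes <- list(); mods <- list()

  if (length(activation_spec)) {
    reg <- sampled_regressors(schedule, tr_s = tr_s, n_volumes = nvol)$regressors
    amp_scene <- array(0, phantom$grid_shape)
    amp_object <- array(0, phantom$grid_shape)
    for (nm in names(activation_spec)) {
      amp_scene[phantom$regions[[nm]]] <- activation_spec[[nm]][["scene"]] / 100
      amp_object[phantom$regions[[nm]]] <- activation_spec[[nm]][["object"]] / 100
    }
    modes <- c(modes, list(as.vector(base * amp_scene),
                           as.vector(base * amp_object)))
    mods <- c(mods, list(reg[, "scene"], reg[, "object"]))
  }

  t_vol <- (seq_len(nvol) - 1) * tr_s
  phases <- with_seed(seed + noise$seed,
                      stats::runif(length(noise$physio) + 1, 0, 2 * pi))
  if (length(noise$physio)) {
    for (i in seq_along(noise$physio)) {
      p <- noise$physio[[i]]
      w <- resolve_region_map(p$region, phantom)
      modes <- c(modes, list(as.vector(base * p$amp * w)))
      mods <- c(mods, list(sin(2 * pi * p$freq_hz * t_vol + phases[i])))
    }
  }
  if (!is.null(noise$drift) && noise$drift$amp > 0) {
    modes <- c(modes, list(as.vector(base * noise$drift$amp * phantom$support)))
    mods <- c(mods, list(cos(2 * pi * t_vol / noise$drift$period_s +
                               phases[length(phases)])))
  }

  K <- length(modes)
  B <- if (K) matrix(unlist(modes), nvox, K) else matrix(0, nvox, 0)
  M <- if (K) do.call(rbind, mods) else matrix(0, 0, nvol)

  structure(list(base = base, modes = B, modulators = M,
                 phantom = phantom, coils = coils, schedule = schedule,
                 noise = noise, protocol = protocol,
                 activation_spec = activation_spec, seed = as.integer(seed)),
            class = "sms_run")
}

#' @export
print.sms_run <- function(x, ...) {
  cat(sprintf("simulated run: SMS %d, %d volumes, %d temporal modes\n",
              x$protocol$sms_factor, x$protocol$n_volumes, ncol(x$modes)))
  invisible(x)
}

# Single ground-truth magnitude volume (nx, ny, nz), 1-based volume index.
ground_truth_volume <- function(run, volume) {
  v <- as.vector(run$base)
  if (ncol(run$modes)) v <- v + run$modes %*% run$modulators[, volume]
  array(v, run$phantom$grid_shape)
}

#' Materialize the ground-truth magnitude time series
#'
#' @param run An `sms_run`.
#' @param volumes Optional volume indices (default all).
#' @return 4D array (nx, ny, nz, time).
#' @export
ground_truth_series <- function(run, volumes = NULL) {
  if (is.null(volumes)) volumes <- seq_len(run$protocol$n_volumes)
  d <- run$phantom$grid_shape
  out <- array(0, c(d, length(volumes)))
  for (i in seq_along(volumes))
    out[, , , i] <- ground_truth_volume(run, volumes[i])
  out
}

#' Per-coil complex slice images for one volume
#'
#' The pre-encoding multi-coil object: ground-truth volume multiplied by
#' the complex coil sensitivities.
#'
#' @param run An `sms_run`.
#' @param volume 1-based volume index.
#' @return Complex array (nx, ny, nz, n_coils).
#' @export
coil_slice_images <- function(run, volume = 1L) {
  img <- ground_truth_volume(run, volume)
  sw <- run$coils$sensitivity
  d <- dim(sw)
  array(as.vector(sw) * rep(as.vector(img), d[4]), d)
}

#' Blipped-CAIPI SMS k-space encoding
#'
#' Forward-simulates the SMS acquisition: slices are grouped with maximal
#' inter-slice spacing, each slice in a group receives its CAIPI in-plane
#' shift (an integer-pixel circular shift along phase encode, i.e. a linear
#' k-space phase ramp), coil-weighted slices are Fourier transformed and
#' summed within the group, and complex Gaussian thermal noise with the
#' coil covariance is added per k-space sample. With `sms_factor = 1` this
#' reduces to plain per-slice multi-coil k-space. The operator is linear in
#' its image input.
#'
#' @param x An `sms_run` (all volumes are encoded) or a complex array
#'   (nx, ny, nz, n_coils) of coil-weighted slice images for one volume.
#' @param protocol,coils,noise Acquisition protocol, coil array and noise
#'   spec; taken from `x` when it is an `sms_run` and these are missing.
#' @param seed Seed for the thermal noise stream.
#' @return An object of class `kspace_series`: `data` complex array
#'   (kx, ky, coil, slice_group, volume), `groups` (slice index matrix),
#'   `shifts` (per within-group position), `protocol`.
#' @export
sms_encode <- function(x, protocol = NULL, coils = NULL, noise = NULL,
                       seed = 1L) {
  if (inherits(x, "sms_run")) {
    protocol <- protocol %||% x$protocol
    coils <- coils %||% x$coils
    noise <- noise %||% x$noise
    vols <- seq_len(protocol$n_volumes)
    get_vol <- function(v) coil_slice_images(x, v)
  } else {
    if (is.null(protocol) || is.null(coils))
      stop("protocol and coils are required for plain image input")
    noise <- noise %||% silent_noise()
    stopifnot(length(dim(x)) == 4)
    vols <- 1L
    get_vol <- function(v) x
  }
  d <- c(protocol$matrix, protocol$n_slices, coils$n_coils)
  probe <- get_vol(1L)
  if (!all(dim(probe) == d))
    stop("image dimensions inconsistent with protocol/coils")

  grp <- slice_groups(protocol)
  shifts <- caipi_shifts(protocol)
  M <- nrow(grp); G <- ncol(grp)
  nx <- d[1]; ny <- d[2]; nc <- d[4]
  nk <- nx * ny

  sigma_k <- noise$thermal_scale * sqrt(nk)  # image-noise-sd parameterization
  psi <- coils$noise_cov

  data <- array(0i, c(nx, ny, nc, G, length(vols)))

  encode_one <- function(img) {
    out <- array(0i, c(nx, ny, nc, G))
    for (g in seq_len(G)) {
      acc <- array(0i, c(nx, ny, nc))
      for (j in seq_len(M)) {
        sl <- img[, , grp[j, g], , drop = FALSE]
        dim(sl) <- c(nx, ny, nc)
        acc <- acc + shift_phase(sl, shifts[j])
      }
      out[, , , g] <- fft2(acc)
    }
    out
  }

  if (sigma_k > 0) {
    with_seed(seed, {
      for (i in seq_along(vols)) {
        ks <- encode_one(get_vol(vols[i]))
        nzm <- rcnorm_cov(psi, nk * G) * sigma_k     # nc x (nk G)
        data[, , , , i] <- ks +
          aperm(array(nzm, c(nc, nx, ny, G)), c(2, 3, 1, 4))
      }
    })
  } else {
    for (i in seq_along(vols)) data[, , , , i] <- encode_one(get_vol(vols[i]))
  }

  structure(list(data = data, groups = grp, shifts = shifts,
                 protocol = protocol, n_coils = nc, seed = as.integer(seed)),
            class = "kspace_series")
}

#' @export
print.kspace_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("k-space series: %dx%d samples, %d coils, %d slice groups, %d volumes (SMS %d)\n",
              d[1], d[2], d[3], d[4], d[5], x$protocol$sms_factor))
  invisible(x)
}

#' Noiseless single-band calibration k-space
#'
#' Per-slice multi-coil k-space of the static baseline object (no task, no
#' physiological modulation, no thermal noise), mirroring the single-band
#' reference scans used to calibrate slice-GRAPPA kernels in practice. No
#' CAIPI ramps are applied here; [fit_slice_grappa()] applies them to match
#' the acquisition.
#'
#' @param run An `sms_run`.
#' @return List with `kspace` (nx, ny, n_coils, n_slices complex),
#'   `images` (same shape, image domain), and the protocol.
#' @export
singleband_calibration <- function(run) {
  d <- run$phantom$grid_shape
  nc <- run$coils$n_coils
  img <- array(as.vector(run$coils$sensitivity) *
                 rep(as.vector(run$base), nc), c(d, nc))
  img <- aperm(img, c(1, 2, 4, 3))            # (nx, ny, coil, slice)
  ks <- fft2(img)
  list(kspace = ks, images = img, protocol = run$protocol)
}
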
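#' Ernst angle for a spoiled gradient-echo acquisition
#'
#' The flip angle that maximizes the spoiled steady-state signal for a given
#' repetition time and longitudinal relaxation time:
#' \eqn{\alpha_E = \arccos(e^{-TR/T_1})}.
#'
#' The value is returned in (continuous) degrees; rounding to the nearest
#' integer degree, as done when programming a sequence protocol, is left to
#' the caller (e.g. `round(ernst_angle(2800, 1000))`).
#'
#' @param tr_ms Repetition time in milliseconds (> 0).
#' @param t1_ms Longitudinal relaxation time in milliseconds (> 0).
#' @return Flip angle in degrees.
#' @examples
#' round(ernst_angle(2800, 1000)) # 87
#' round(ernst_angle(350, 1000))  # 45
#' @export
ernst_angle <- function(tr_ms, t1_ms) {
  if (any(tr_ms <= 0) || any(t1_ms <= 0))
    stop("tr_ms and t1_ms must be positive")
  acos(exp(-tr_ms / t1_ms)) * 180 / pi
}

#' Relative spoiled steady-state signal
#'
#' Longitudinal steady-state magnetization available to a spoiled
#' gradient-echo readout, relative to full recovery:
#' \eqn{S = \sin\alpha \,(1 - E_1)/(1 - \cos\alpha \, E_1)} with
#' \eqn{E_1 = e^{-TR/T_1}}. Maximized over \eqn{\alpha} at the Ernst angle.
#'
#' @param flip_deg Flip angle in degrees, in (0, 90].
#' @inheritParams ernst_angle
#' @return Scalar in (0, 1].
#' @export
steady_state_signal <- function(flip_deg, tr_ms, t1_ms) {
  if (any(flip_deg <= 0) || any(flip_deg > 90))
    stop("flip_deg must be in (0, 90]")
  if (any(tr_ms <= 0) || any(t1_ms <= 0))
    stop("tr_ms and t1_ms must be positive")
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Temporal Nyquist frequency of a volume time series
#'
#' Half the volume sampling rate, `1000 / (2 * tr_ms)` Hz: the highest
#' temporal frequency fully sampled at that TR.
#'
#' @inheritParams ernst_angle
#' @return Frequency in Hz.
#' @export
nyquist_frequency <- function(tr_ms) {
  if (any(tr_ms <= 0)) stop("tr_ms must be positive")
  1000 / (2 * tr_ms)
}

#' Construct an SMS acquisition protocol
#'
#' Bundles the per-condition sequence parameters of a blipped-CAIPI SMS EPI
#' acquisition. `caipi_shift_denom` encodes the in-plane shift imposed
#' between simultaneously excited slices: 0 = no shift (single band),
#' 2 = FOV/2, 3 = FOV/3.
#'
#' @param sms_factor SMS (multiband) factor; must divide `n_slices`.
#' @param tr_ms Repetition time in ms.
#' @param flip_deg Excitation flip angle in degrees.
#' @param caipi_shift_denom Integer CAIPI shift denominator (0, 2 or 3).
#' @param n_volumes Number of volumes in the run.
#' @param n_slices Total number of slices.
#' @param matrix Integer pair, (read, phase) sample counts.
#' @param fov_mm In-plane field of view in mm.
#' @param slice_thickness_mm,slice_gap_fraction Slice geometry.
#' @param te_ms Echo time in ms (provenance only; unused by the simulator).
#' @return An object of class `sms_protocol`.
#' @export
acquisition_protocol <- function(sms_factor, tr_ms, flip_deg, caipi_shift_denom,
                                 n_volumes, n_slices = 40L,
                                 matrix = c(64L, 72L), fov_mm = 192,
                                 slice_thickness_mm = 2.5,
                                 slice_gap_fraction = 0.2, te_ms = 30.2) {
  stopifnot(sms_factor %in% c(1L, 2L, 4L, 8L), tr_ms > 0, flip_deg > 0,
            n_volumes >= 1, n_slices >= 1, length(matrix) == 2)
  if (n_slices %% sms_factor != 0)
    stop("n_slices must be divisible by sms_factor")
  if (!caipi_shift_denom %in% c(0L, 2L, 3L))
    stop("caipi_shift_denom must be 0, 2 or 3")
  if (sms_factor > 1 && caipi_shift_denom == 0)
    stop("SMS factors > 1 require a CAIPI shift denominator")
  structure(list(
    sms_factor = as.integer(sms_factor), tr_ms = tr_ms, flip_deg = flip_deg,
    caipi_shift_denom = as.integer(caipi_shift_denom),
    n_volumes = as.integer(n_volumes), n_slices = as.integer(n_slices),
    matrix = as.integer(matrix), fov_mm = fov_mm,
    slice_thickness_mm = slice_thickness_mm,
    slice_gap_fraction = slice_gap_fraction, te_ms = te_ms
  ), class = "sms_protocol")
}

#' Default protocol table across SMS factors 1/2/4/8
#'
#' The four matched-duration protocols used throughout the package: TR
#' halves as the SMS factor doubles (2800/1400/700/350 ms), flip angles are
#' the Ernst angles for a 1000 ms reference T1 rounded to integer degrees
#' (87/76/60/45 deg), CAIPI shifts are none, FOV/2, FOV/3, FOV/3, and the
#' volume counts 155/310/620/1240 keep the run duration at 434 s for all
#' four conditions.
#'
#' @param n_slices Total slice count (default 40).
#' @param matrix (read, phase) matrix size (default 64 x 72).
#' @param reference_t1_ms T1 used for the Ernst-angle flip angles.
#' @param sms Subset of SMS factors to build (default all four).
#' @return Named list of `sms_protocol` objects ("sms1", "sms2", "sms4", "sms8").
#' @export
default_protocols <- function(n_slices = 40L, matrix = c(64L, 72L),
                              reference_t1_ms = 1000,
                              sms = c(1L, 2L, 4L, 8L)) {
  tr_all <- c("1" = 2800, "2" = 1400, "4" = 700, "8" = 350)
  denom_all <- c("1" = 0L, "2" = 2L, "4" = 3L, "8" = 3L)
  vols_all <- c("1" = 155L, "2" = 310L, "4" = 620L, "8" = 1240L)
  sms <- as.integer(sms)
  stopifnot(all(sms %in% c(1L, 2L, 4L, 8L)))
  out <- lapply(sms, function(m) {
    key <- as.character(m)
    acquisition_protocol(m, tr_all[[key]],
                         round(ernst_angle(tr_all[[key]], reference_t1_ms)),
                         denom_all[[key]], vols_all[[key]],
                         n_slices = n_slices, matrix = matrix)
  })
  names(out) <- paste0("sms", sms)
  out
}

#' @export
print.sms_protocol <- function(x, ...) {
  cat(sprintf(
    "SMS %d protocol: TR %g ms, flip %g deg, CAIPI %s, %d volumes, %d slices, %dx%d matrix\n",
    x$sms_factor, x$tr_ms, x$flip_deg,
    if (x$caipi_shift_denom == 0) "none" else paste0("FOV/", x$caipi_shift_denom),
    x$n_volumes, x$n_slices, x$matrix[1], x$matrix[2]))
  invisible(x)
}

# Slice groups with maximal inter-slice spacing: group g (1..n_slices/M)
# contains slices g, g + G, ..., g + (M-1) G. Returns M x G integer matrix,
# one column per group.
slice_groups <- function(protocol) {
  M <- protocol$sms_factor
  G <- protocol$n_slices %/% M
  matrix(vapply(seq_len(G), function(g) g + G * (0:(M - 1)), integer(M)),
         nrow = M)
}

# CAIPI shift in phase-encode pixels for the j-th slice (1-based) within a
# group: (j-1) * ny / denom, cycling through the denom distinct positions.
caipi_shifts <- function(protocol) {
  M <- protocol$sms_factor
  ny <- protocol$matrix[2]
  if (protocol$caipi_shift_denom == 0) return(rep(0L, M))
  d <- protocol$caipi_shift_denom
  if (ny %% d != 0)
    stop("phase-encode matrix size must be divisible by the CAIPI denominator")
  as.integer(((seq_len(M) - 1) %% d) * (ny %/% d))
}
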
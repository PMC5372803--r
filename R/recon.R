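# Slice-GRAPPA / Split Slice-GRAPPA (LeakBlock) kernel fitting and
# application. All k-space neighbourhood operations use the periodic
# (circular) convention, which makes kernel application exactly equivalent
# to pointwise multiplication in the image domain (the representation used
# both for fast reconstruction and for the analytic g-factor).

# Extract index i of the 4th dim of a 4D array, keeping a 3D shape.
take_slice4 <- function(a, i) {
  d <- dim(a)
  out <- a[, , , i, drop = FALSE]
  dim(out) <- d[1:3]
  out
}

# Extract (g, v) of a 5D array, keeping a 3D shape.
take_slice5 <- function(a, g, v) {
  d <- dim(a)
  out <- a[, , , g, v, drop = FALSE]
  dim(out) <- d[1:3]
  out
}

kernel_offsets <- function(geom) {
  h <- (geom - 1) %/% 2
  if (any(geom %% 2 == 0)) stop("kernel geometry must be odd in both dims")
  expand.grid(dr = -h[1]:h[1], dp = -h[2]:h[2])
}

# Source matrix for LS fitting: columns over (coil, offset) of the circular
# k-space neighbourhood, column index (c-1)*kd + o.
source_matrix <- function(S, offsets) {
  nx <- dim(S)[1]; ny <- dim(S)[2]; nc <- dim(S)[3]
  kd <- nrow(offsets)
  A <- matrix(0i, nx * ny, nc * kd)
  for (c in seq_len(nc))
    for (o in seq_len(kd))
      A[, (c - 1) * kd + o] <-
        as.vector(circshift2(S[, , c], -offsets$dr[o], -offsets$dp[o]))
  A
}

#' Fit slice-GRAPPA or Split Slice-GRAPPA (LeakBlock) unaliasing kernels
#'
#' Calibrates, per slice group, the k-space kernels that map SMS-collapsed
#' multi-coil k-space to each constituent slice's (CAIPI-shifted) k-space.
#' In standard mode the kernels minimize
#' \eqn{\| K \circ (\sum_s C_s) - C_t \|^2} where the source is the
#' synthetically collapsed calibration; in LeakBlock mode they minimize
#' \eqn{\sum_s \| K \circ C_s - \delta_{s=t} C_s \|^2}, additionally
#' penalizing leakage of every other slice's signal into the target's
#' reconstruction. A ridge term \eqn{\lambda \,\mathrm{tr}(A^H A)/n_k \|K\|^2}
#' is added in both modes; with `ridge = 0` rank-deficient normal equations
#' are reported as an error rather than silently regularized.
#'
#' For `sms_factor = 1` the returned kernels are the exact identity (delta
#' tap at zero offset on the matching coil).
#'
#' @param calib Single-band calibration as returned by
#'   [singleband_calibration()] (or a list with element `kspace`,
#'   nx x ny x coil x slice complex, no CAIPI ramps applied).
#' @param protocol The `sms_protocol` to calibrate for.
#' @param kernel_geom Odd integer pair: k-space neighbourhood size
#'   (read, phase), default 5 x 5.
#' @param leakblock Logical: fit Split Slice-GRAPPA (LeakBlock) kernels.
#' @param ridge Trace-normalized ridge factor (default 1e-4; 0 allowed).
#' @return Object of class `slice_kernels`.
#' @export
fit_slice_grappa <- function(calib, protocol, kernel_geom = c(5L, 5L),
                             leakblock = TRUE, ridge = 1e-4) {
  ks <- calib$kspace
  d <- dim(ks)
  stopifnot(length(d) == 4)
  if (!all(d[1:2] == protocol$matrix) || d[4] != protocol$n_slices)
    stop("calibration dimensions inconsistent with protocol")
  nc <- d[3]
  grp <- slice_groups(protocol)
  shifts <- caipi_shifts(protocol)
  M <- nrow(grp); G <- ncol(grp)
  offsets <- kernel_offsets(as.integer(kernel_geom))
  kd <- nrow(offsets)
  p <- nc * kd

  weights <- vector("list", G)
  resid <- numeric(G)

  if (protocol$sms_factor == 1L) {
    W <- matrix(0i, p, nc)
    zero_o <- which(offsets$dr == 0 & offsets$dp == 0)
    for (c in seq_len(nc)) W[(c - 1) * kd + zero_o, c] <- 1
    for (g in seq_len(G)) weights[[g]] <- W
    return(structure(list(weights = weights, offsets = offsets,
                          geom = as.integer(kernel_geom), lambda = ridge,
                          leakblock = leakblock, groups = grp,
                          shifts = shifts, n_coils = nc, protocol = protocol,
                          fit_residual = resid),
                     class = "slice_kernels"))
  }

  for (g in seq_len(G)) {
    Sm <- lapply(seq_len(M), function(j)
      ramp_kspace(take_slice4(ks, grp[j, g]), shifts[j]))
    targets <- vapply(Sm, as.vector, complex(d[1] * d[2] * nc))
    dim(targets) <- c(d[1] * d[2], nc, M)

    if (!leakblock) {
      C <- Reduce(`+`, Sm)
      A <- source_matrix(C, offsets)
      Gm <- Conj(t(A)) %*% A
      rhs <- Conj(t(A)) %*% matrix(targets, d[1] * d[2], nc * M)
      Greg <- add_ridge(Gm, ridge)
      W <- solve(Greg, rhs)           # p x (M*nc), member outer, coil inner
      fitted <- A %*% W
      resid[g] <- sqrt(sum(Mod(fitted - matrix(targets, d[1] * d[2], nc * M))^2) /
                         sum(Mod(targets)^2))
      weights[[g]] <- W
    } else {
      As <- lapply(Sm, source_matrix, offsets = offsets)
      Gm <- Reduce(`+`, lapply(As, function(A) Conj(t(A)) %*% A))
      Greg <- add_ridge(Gm, ridge)
      Ginv <- solve(Greg)
      W <- matrix(0i, p, M * nc)
      rss <- 0; tss <- 0
      for (t in seq_len(M)) {
        rhs <- Conj(t(As[[t]])) %*% targets[, , t]
        Wt <- Ginv %*% rhs
        W[, (t - 1) * nc + seq_len(nc)] <- Wt
        for (s in seq_len(M)) {
          pred <- As[[s]] %*% Wt
          tgt <- if (s == t) targets[, , t] else 0
          rss <- rss + sum(Mod(pred - tgt)^2)
        }
        tss <- tss + sum(Mod(targets[, , t])^2)
      }
      resid[g] <- sqrt(rss / tss)
      weights[[g]] <- W
    }
  }

  structure(list(weights = weights, offsets = offsets,
                 geom = as.integer(kernel_geom), lambda = ridge,
                 leakblock = leakblock, groups = grp, shifts = shifts,
                 n_coils = nc, protocol = protocol, fit_residual = resid),
            class = "slice_kernels")
}

add_ridge <- function(Gm, ridge) {
  p <- ncol(Gm)
  if (ridge > 0) return(Gm + diag(ridge * Re(sum(diag(Gm))) / p, p))
  ev <- eigen(Gm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10)
    stop("rank-deficient normal equations with ridge = 0; set ridge > 0")
  Gm
}

#' @export
print.slice_kernels <- function(x, ...) {
  cat(sprintf("slice-GRAPPA kernels: SMS %d, %dx%d taps, %d coils, %s, ridge %g, max fit residual %.2e\n",
              x$protocol$sms_factor, x$geom[1], x$geom[2], x$n_coils,
              if (x$leakblock) "LeakBlock" else "standard", x$lambda,
              max(x$fit_residual)))
  invisible(x)
}

# Image-domain representation of the kernels: per group an array
# (nx, ny, nc_in, M*nc_out) such that unaliasing is pointwise
# o_col(x) = sum_c w[x, c, col] * i_coll_c(x) in the CAIPI-shifted frame.
kernel_image_weights <- function(kernels) {
  nx <- kernels$protocol$matrix[1]; ny <- kernels$protocol$matrix[2]
  nc <- kernels$n_coils
  kd <- nrow(kernels$offsets)
  lapply(kernels$weights, function(W) {
    ncol_out <- ncol(W)
    Z <- array(0i, c(nx, ny, nc, ncol_out))
    for (o in seq_len(kd)) {
      r <- (kernels$offsets$dr[o] %% nx) + 1
      p <- (kernels$offsets$dp[o] %% ny) + 1
      Z[r, p, , ] <- Z[r, p, , ] + W[(seq_len(nc) - 1) * kd + o, , drop = FALSE]
    }
    fft2(Z)   # w(x) = sum_delta K_delta exp(-2i pi delta.x / N)
  })
}

# Unalias one collapsed multi-coil image (nx, ny, nc) for group g; returns
# (nx, ny, nc_out, M) coil images still in the CAIPI-shifted frame.
unalias_group_image <- function(icoll, wimg_g, nc, M) {
  nk <- dim(icoll)[1] * dim(icoll)[2]
  iflat <- matrix(icoll, nk, nc)
  wflat <- array(wimg_g, c(nk, nc, nc * M))
  out <- matrix(0i, nk, nc * M)
  for (c in seq_len(nc))
    out <- out + wflat[, c, ] * iflat[, c]
  array(out, c(dim(icoll)[1], dim(icoll)[2], nc, M))
}

#' Apply fitted kernels to an SMS k-space series
#'
#' Linear, volume-wise stateless application of the slice-GRAPPA kernels:
#' for each volume and slice group the collapsed k-space is convolved
#' (circularly) with the kernels and the per-slice result is de-ramped
#' (CAIPI shift undone) back to the native slice position.
#'
#' @param kspace_series A `kspace_series` from [sms_encode()].
#' @param kernels A `slice_kernels` fitted on a matching protocol.
#' @return Complex array (kx, ky, coil, slice, volume) of per-slice
#'   multi-coil k-space.
#' @export
apply_kernels <- function(kspace_series, kernels) {
  check_kernel_match(kspace_series, kernels)
  pr <- kspace_series$protocol
  d <- dim(kspace_series$data)
  nx <- d[1]; ny <- d[2]; nc <- d[3]; G <- d[4]; nv <- d[5]
  M <- nrow(kernels$groups)
  wimg <- kernel_image_weights(kernels)
  out <- array(0i, c(nx, ny, nc, pr$n_slices, nv))
  for (v in seq_len(nv)) {
    for (g in seq_len(G)) {
      icoll <- ifft2(take_slice5(kspace_series$data, g, v))
      ua <- unalias_group_image(icoll, wimg[[g]], nc, M)
      for (j in seq_len(M)) {
        img <- shift_phase(take_slice4(ua, j), -kernels$shifts[j])
        out[, , , kernels$groups[j, g], v] <- fft2(img)
      }
    }
  }
  out
}

check_kernel_match <- function(kspace_series, kernels) {
  pk <- kspace_series$protocol; pg <- kernels$protocol
  if (pk$sms_factor != pg$sms_factor || !all(pk$matrix == pg$matrix) ||
      pk$n_slices != pg$n_slices ||
      pk$caipi_shift_denom != pg$caipi_shift_denom)
    stop("kernel set was fitted for a different protocol")
  if (dim(kspace_series$data)[3] != kernels$n_coils)
    stop("coil count mismatch between k-space series and kernels")
  invisible(TRUE)
}

#' Combine multi-coil images into a magnitude image
#'
#' `rss` is the root-sum-of-squares over coils; `cov_weighted` is the
#' noise-covariance-whitened quadrature combination
#' \eqn{\sqrt{i^H \Psi^{-1} i}} (equal to rss, up to scale, when
#' \eqn{\Psi = I}). Both are invariant to a global per-coil phase.
#'
#' @param coil_images Complex array with coils as the last dimension.
#' @param method "rss" or "cov_weighted".
#' @param noise_cov Coil noise covariance (required for "cov_weighted").
#' @return Real magnitude array with the coil dimension dropped.
#' @export
combine_coils <- function(coil_images, method = c("rss", "cov_weighted"),
                          noise_cov = NULL) {
  method <- match.arg(method)
  d <- dim(coil_images)
  nc <- d[length(d)]
  m <- matrix(coil_images, prod(d) / nc, nc)
  out <- switch(method,
    rss = sqrt(rowSums(Mod(m)^2)),
    cov_weighted = {
      if (is.null(noise_cov)) stop("cov_weighted combination requires noise_cov")
      sqrt(pmax(quad_form_rows(m, solve(noise_cov)), 0))
    })
  array(out, d[-length(d)])
}

#' Reconstruct a magnitude image series from SMS k-space
#'
#' Volume-by-volume kernel application, inverse Fourier transform and coil
#' combination. Volumes are processed independently (no temporal mixing).
#' For single-band data (`sms_factor = 1`) `kernels` may be `NULL`, in
#' which case the inverse FT is combined directly.
#'
#' @inheritParams apply_kernels
#' @param combine Coil combination method, see [combine_coils()].
#' @param noise_cov Coil noise covariance for `combine = "cov_weighted"`.
#' @return A [ts_image] with tag `"raw"`.
#' @export
reconstruct_series <- function(kspace_series, kernels = NULL,
                               combine = "rss", noise_cov = NULL) {
  pr <- kspace_series$protocol
  d <- dim(kspace_series$data)
  nx <- d[1]; ny <- d[2]; nc <- d[3]; G <- d[4]; nv <- d[5]
  if (is.null(kernels)) {
    if (pr$sms_factor != 1L)
      stop("kernels are required for SMS factors > 1")
    grp <- slice_groups(pr); shifts <- rep(0L, 1); M <- 1L
    wimg <- NULL
  } else {
    check_kernel_match(kspace_series, kernels)
    grp <- kernels$groups; shifts <- kernels$shifts; M <- nrow(grp)
    wimg <- kernel_image_weights(kernels)
  }
  out <- array(0, c(nx, ny, pr$n_slices, nv))
  for (v in seq_len(nv)) {
    coil_vol <- array(0i, c(nx, ny, pr$n_slices, nc))
    for (g in seq_len(G)) {
      icoll <- ifft2(take_slice5(kspace_series$data, g, v))
      ua <- if (is.null(wimg)) array(icoll, c(nx, ny, nc, 1))
            else unalias_group_image(icoll, wimg[[g]], nc, M)
      for (j in seq_len(M)) {
        img <- shift_phase(take_slice4(ua, j), -shifts[j])
        coil_vol[, , grp[j, g], ] <- img
      }
    }
    out[, , , v] <- combine_coils(coil_vol, combine, noise_cov)
  }
  ts_image(out, tr_s = pr$tr_ms / 1000, tag = "raw",
           sms_factor = pr$sms_factor,
           lineage = list(combine = combine,
                          leakblock = if (is.null(kernels)) NA else kernels$leakblock))
}
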
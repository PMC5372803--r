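# Voxelwise g-factor maps: noise amplification of the SMS reconstruction
# relative to a single-band reconstruction of the same object, propagated
# analytically through the kernel weights and coil noise covariance, and
# cross-checked by a pseudo-replica Monte-Carlo estimate.

# Per-voxel combination vectors (nvox x nc) in the *CAIPI-shifted frame*
# for one slice: rows are the linearized coil-combination weights at the
# signal operating point. For rss the noise-equivalent combination vector
# is the coil signal itself; cov_weighted whitens with the covariance.
combine_vectors <- function(ref_shifted, combine, noise_cov) {
  nk <- dim(ref_shifted)[1] * dim(ref_shifted)[2]
  nc <- dim(ref_shifted)[3]
  P <- matrix(ref_shifted, nk, nc)
  if (combine == "cov_weighted") P <- P %*% t(Conj(solve(noise_cov)))
  P
}

gfactor_support <- function(ref_images, combine, noise_cov, threshold = 0.05) {
  comb <- combine_coils(ref_images, combine,
                        noise_cov = if (combine == "cov_weighted") noise_cov)
  comb >= threshold * max(comb)
}

#' Analytic g-factor map from slice-GRAPPA weights and coil covariance
#'
#' Transforms the fitted k-space kernels to image-domain unaliasing weights
#' W(x) and computes, per voxel, the ratio of the noise standard deviation
#' of the combined SMS-reconstructed voxel to that of the same voxel
#' combined from a single-band reconstruction, both propagated through the
#' coil noise covariance \eqn{\Psi}:
#' \deqn{g(x) = \sqrt{\frac{p^H W \Psi W^H p}{p^H \Psi p}}}
#' with p the per-voxel coil combination vector linearized at the signal
#' operating point. No \eqn{\sqrt{R}} time penalty is applied: SMS does not
#' undersample in-plane k-space. Voxels whose combined reference signal is
#' below `support_threshold` of the maximum are masked (`NA`), and for
#' `sms_factor = 1` the map is identically 1 on support by the reference
#' convention.
#'
#' @param kernels A `slice_kernels`.
#' @param coils The `coil_array` (supplies the noise covariance).
#' @param protocol The matching `sms_protocol`.
#' @param reference_images Complex array (nx, ny, n_slices, n_coils) of
#'   noiseless single-band coil images of the imaged object (e.g.
#'   `singleband_calibration(run)$images` re-permuted, or
#'   [coil_slice_images()] of a static volume).
#' @param combine Combination method whose noise propagation is evaluated.
#' @param support_threshold Fraction of the maximum combined signal below
#'   which voxels are masked.
#' @return Object of class `gfactor_map`: `g` (nx, ny, n_slices with NA off
#'   support), `support`, `sms_factor`, `method = "analytic"`.
#' @export
analytic_gfactor <- function(kernels, coils, protocol, reference_images,
                             combine = "rss", support_threshold = 0.05) {
  d <- dim(reference_images)
  stopifnot(length(d) == 4, d[4] == coils$n_coils)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nc <- d[4]
  psi <- coils$noise_cov
  support <- gfactor_support(reference_images, combine, psi, support_threshold)
  g <- array(NA_real_, c(nx, ny, nz))

  if (protocol$sms_factor == 1L) {
    g[support] <- 1
    return(structure(list(g = g, support = support,
                          sms_factor = 1L, method = "analytic",
                          combine = combine), class = "gfactor_map"))
  }

  grp <- kernels$groups; shifts <- kernels$shifts
  M <- nrow(grp); G <- ncol(grp)
  wimg <- kernel_image_weights(kernels)
  nk <- nx * ny

  for (gi in seq_len(G)) {
    wf <- array(wimg[[gi]], c(nk, nc, nc, M))  # (vox, c_in, c_out, member)
    for (j in seq_len(M)) {
      s <- grp[j, gi]
      # reference coil images of slice s, shifted to the CAIPI frame
      ref_s <- reference_images[, , s, , drop = FALSE]
      dim(ref_s) <- c(nx, ny, nc)
      ref_sh <- shift_phase(ref_s, shifts[j])
      P <- combine_vectors(ref_sh, combine, psi)       # nvox x nc
      # q_cin(x) = sum_cout conj(W[x, cin, cout]) * p_cout(x)
      Q <- matrix(0i, nk, nc)
      for (co in seq_len(nc))
        Q <- Q + Conj(wf[, , co, j]) * P[, co]
      num <- quad_form_rows(Q, psi)
      den <- quad_form_rows(P, psi)
      gs <- sqrt(pmax(num, 0) / pmax(den, .Machine$double.eps))
      gmap <- shift_phase(matrix(gs, nx, ny), -shifts[j])
      g[, , s] <- Re(gmap)
    }
  }
  g[!support] <- NA_real_
  structure(list(g = g, support = support, sms_factor = protocol$sms_factor,
                 method = "analytic", combine = combine),
            class = "gfactor_map")
}

#' Pseudo-replica Monte-Carlo g-factor map
#'
#' Standard pseudo multiple-replica estimation: correlated complex Gaussian
#' noise with the coil covariance is injected in k-space, passed through
#' the same kernel-application chain as the image reconstruction, combined
#' with the per-voxel linearized combination vector, and the ratio of noise
#' standard deviations (SMS over single-band) is taken over replicas. The
#' same noise draw feeds both the collapsed and the single-band paths
#' (matched replicas), which sharply reduces the Monte-Carlo variance of
#' the ratio.
#'
#' @inheritParams analytic_gfactor
#' @param n_replicas Number of replicas (>= 100 recommended for maps; fewer
#'   triggers a warning).
#' @param seed RNG seed.
#' @return Object of class `gfactor_map` with `method = "pseudo_replica"`,
#'   `n_replicas`, `seed`.
#' @export
pseudo_replica_gfactor <- function(kernels, coils, protocol, reference_images,
                                   combine = "rss", n_replicas = 500,
                                   seed = 1L, support_threshold = 0.05) {
  d <- dim(reference_images)
  stopifnot(length(d) == 4, d[4] == coils$n_coils)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nc <- d[4]
  if (n_replicas < 100)
    warning("fewer than 100 replicas: g-factor confidence intervals are wide")
  psi <- coils$noise_cov
  support <- gfactor_support(reference_images, combine, psi, support_threshold)
  nk <- nx * ny

  if (protocol$sms_factor == 1L) {
    g <- array(NA_real_, c(nx, ny, nz)); g[support] <- 1
    return(structure(list(g = g, support = support, sms_factor = 1L,
                          method = "pseudo_replica", n_replicas = n_replicas,
                          seed = seed, combine = combine),
                     class = "gfactor_map"))
  }

  grp <- kernels$groups; shifts <- kernels$shifts
  M <- nrow(grp); G <- ncol(grp)
  wimg <- kernel_image_weights(kernels)
  g <- array(NA_real_, c(nx, ny, nz))

  with_seed(seed, {
    for (gi in seq_len(G)) {
      # per-voxel combination vectors for each member, shifted frame
      Ps <- lapply(seq_len(M), function(j) {
        ref_s <- reference_images[, , grp[j, gi], , drop = FALSE]
        dim(ref_s) <- c(nx, ny, nc)
        combine_vectors(shift_phase(ref_s, shifts[j]), combine, psi)
      })
      v_sms <- array(0i, c(nk, M, n_replicas))
      v_sb <- array(0i, c(nk, M, n_replicas))
      wf <- array(wimg[[gi]], c(nk, nc, nc * M))
      for (r in seq_len(n_replicas)) {
        nz_k <- rcnorm_cov(psi, nk)                   # nc x nk k-space draw
        nimg <- ifft2(array(t(nz_k), c(nx, ny, nc)))  # image-domain noise
        dim(nimg) <- c(nk, nc)
        ua <- matrix(0i, nk, nc * M)
        for (c in seq_len(nc))
          ua <- ua + wf[, c, ] * nimg[, c]
        ua <- array(ua, c(nk, nc, M))
        for (j in seq_len(M)) {
          v_sms[, j, r] <- rowSums(Conj(Ps[[j]]) * matrix(ua[, , j], nk, nc))
          v_sb[, j, r] <- rowSums(Conj(Ps[[j]]) * nimg)
        }
      }
      csd <- function(a) {
        m <- matrix(a, nk * M, n_replicas)
        mu <- rowMeans(m)
        matrix(sqrt(rowMeans(Mod(m - mu)^2)), nk, M)
      }
      sd_sms <- csd(v_sms); sd_sb <- csd(v_sb)
      for (j in seq_len(M)) {
        gs <- sd_sms[, j] / pmax(sd_sb[, j], .Machine$double.eps)
        g[, , grp[j, gi]] <- shift_phase(matrix(gs, nx, ny), -shifts[j])
      }
    }
  })
  g[!support] <- NA_real_
  structure(list(g = g, support = support, sms_factor = protocol$sms_factor,
                 method = "pseudo_replica", n_replicas = n_replicas,
                 seed = seed, combine = combine), class = "gfactor_map")
}

#' @export
print.gfactor_map <- function(x, ...) {
  cat(sprintf("g-factor map (%s, SMS %d): mean %.3f, max %.3f over %d support voxels\n",
              x$method, x$sms_factor, mean(x$g[x$support]),
              max(x$g[x$support]), sum(x$support)))
  invisible(x)
}

#' Summarize a g-factor map over regions of interest
#'
#' @param map A `gfactor_map`.
#' @param roi_masks Named list of logical arrays (or `roi_spec` objects)
#'   within the map support.
#' @return Data frame with mean and max g per ROI plus a `support` row for
#'   the whole support mask.
#' @export
summarize_gfactor <- function(map, roi_masks = list()) {
  masks <- lapply(roi_masks, function(m) if (inherits(m, "roi_spec")) m$mask else m)
  masks$support <- map$support
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]] & map$support
    if (!any(m)) stop("empty ROI mask: ", nm)
    vals <- map$g[m]
    data.frame(roi = nm, n_voxels = sum(m), mean_g = mean(vals),
               max_g = max(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
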
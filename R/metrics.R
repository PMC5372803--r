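#' Time-series image container
#'
#' Lightweight container for a 4D magnitude series with its effective TR
#' and processing provenance.
#'
#' @param data 4D array (x, y, z, time).
#' @param tr_s Effective repetition time in seconds.
#' @param tag Processing tag: "raw", "downsampled" or "decimated".
#' @param sms_factor SMS factor of the originating acquisition.
#' @param lineage List of processing parameters (filter, factor, phase...).
#' @return Object of class `ts_image`.
#' @export
ts_image <- function(data, tr_s, tag = "raw", sms_factor = 1L,
                     lineage = list()) {
  stopifnot(length(dim(data)) == 4, tr_s > 0,
            tag %in% c("raw", "downsampled", "decimated"))
  structure(list(data = data, tr_s = tr_s, tag = tag,
                 sms_factor = as.integer(sms_factor), lineage = lineage),
            class = "ts_image")
}

#' @export
print.ts_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ts_image [%s, SMS %d]: %dx%dx%d voxels, %d volumes, TR %.3f s\n",
              x$tag, x$sms_factor, d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

n_volumes <- function(series) dim(series$data)[4]

as_voxel_matrix <- function(series) {
  d <- dim(series$data)
  t(matrix(series$data, prod(d[1:3]), d[4]))  # time x voxel
}

#' Downsample a time series by keeping every Nth volume
#'
#' No anti-aliasing filter is applied: frequency content above the new
#' Nyquist folds into the retained band. The effective TR is multiplied
#' by N.
#'
#' @param series A [ts_image].
#' @param N Positive integer downsampling factor; must divide the series
#'   length.
#' @param phase Offset of the first kept volume, in `[0, N)`.
#' @return A [ts_image] tagged "downsampled".
#' @export
downsample_series <- function(series, N, phase = 0L) {
  N <- as.integer(N); phase <- as.integer(phase)
  if (N < 1) stop("N must be >= 1")
  if (phase < 0 || phase >= N) stop("phase must be in [0, N)")
  nv <- n_volumes(series)
  if (nv %% N != 0)
    stop(sprintf("series length %d not divisible by N = %d", nv, N))
  keep <- seq(phase + 1L, nv, by = N)
  ts_image(series$data[, , , keep, drop = FALSE], tr_s = series$tr_s * N,
           tag = "downsampled", sms_factor = series$sms_factor,
           lineage = c(series$lineage, list(downsample = N, phase = phase)))
}

#' Anti-alias decimation specification
#'
#' @param order Butterworth filter order (default 6).
#' @param cutoff_hz Low-pass cutoff in Hz (default 0.18).
#' @param zero_phase Apply the filter forward and backward (default TRUE),
#'   squaring the magnitude response and cancelling the phase so that the
#'   haemodynamic response is not delayed relative to the regressors.
#' @return Object of class `decimation_spec`.
#' @export
decimation_spec <- function(order = 6L, cutoff_hz = 0.18, zero_phase = TRUE) {
  if (order < 1) stop("order must be >= 1")
  if (cutoff_hz <= 0) stop("cutoff_hz must be positive")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 zero_phase = zero_phase), class = "decimation_spec")
}

# IIR direct-form filtering of the columns of X (time x voxel).
iir_filter_mat <- function(b, a, X) {
  n <- nrow(X)
  Y <- matrix(0, n, ncol(X))
  nb <- length(b); na <- length(a)
  for (t in seq_len(n)) {
    acc <- b[1] * X[t, ]
    if (nb > 1 && t > 1)
      for (i in 2:min(nb, t)) acc <- acc + b[i] * X[t - i + 1, ]
    if (na > 1 && t > 1)
      for (j in 2:min(na, t)) acc <- acc - a[j] * Y[t - j + 1, ]
    Y[t, ] <- acc / a[1]
  }
  Y
}

# Zero-phase (or causal) Butterworth low-pass on columns of X. The series
# mean is removed before filtering and restored afterwards (exact DC gain),
# and odd (rotation) reflection padding at both ends absorbs the filter
# transients, whose length scales with fs / cutoff.
butter_lowpass_mat <- function(X, order, cutoff_hz, fs_hz, zero_phase = TRUE) {
  wn <- cutoff_hz / (fs_hz / 2)
  if (wn >= 1) stop("cutoff_hz must be below the series Nyquist frequency")
  bf <- signal::butter(order, wn, type = "low")
  b <- bf$b; a <- bf$a
  n <- nrow(X)
  mu <- colMeans(X)
  X <- sweep(X, 2, mu)
  pad <- min(n - 1, max(50, ceiling(6 * fs_hz / cutoff_hz)))
  top <- 2 * matrix(X[1, ], pad, ncol(X), byrow = TRUE) -
    X[pad + 1 - seq_len(pad) + 1, , drop = FALSE]
  bot <- 2 * matrix(X[n, ], pad, ncol(X), byrow = TRUE) -
    X[n - seq_len(pad), , drop = FALSE]
  Xp <- rbind(top, X, bot)
  Y <- iir_filter_mat(b, a, Xp)
  if (zero_phase) {
    Y <- Y[nrow(Y):1, , drop = FALSE]
    Y <- iir_filter_mat(b, a, Y)
    Y <- Y[nrow(Y):1, , drop = FALSE]
  }
  sweep(Y[pad + seq_len(n), , drop = FALSE], 2, mu, `+`)
}

#' Decimate a time series: anti-alias filter, then downsample
#'
#' Applies the Butterworth low-pass of `spec` independently to every voxel
#' time course (zero-phase by default; endpoints handled by odd-reflection
#' padding) and then keeps every Nth volume as in [downsample_series()].
#'
#' @param series A [ts_image].
#' @param spec A [decimation_spec()].
#' @param N Downsampling factor.
#' @param phase Downsampling phase.
#' @return A [ts_image] tagged "decimated".
#' @export
decimate_series <- function(series, spec = decimation_spec(), N, phase = 0L) {
  stopifnot(inherits(spec, "decimation_spec"))
  fs <- 1 / series$tr_s
  if (spec$cutoff_hz >= fs / 2)
    stop("decimation cutoff must be below the input series Nyquist frequency")
  d <- dim(series$data)
  X <- as_voxel_matrix(series)
  Y <- butter_lowpass_mat(X, spec$order, spec$cutoff_hz, fs, spec$zero_phase)
  filt <- ts_image(array(t(Y), d), tr_s = series$tr_s, tag = "raw",
                   sms_factor = series$sms_factor,
                   lineage = c(series$lineage,
                               list(filter = unclass(spec))))
  out <- downsample_series(filt, N, phase)
  out$tag <- "decimated"
  out
}

# Discrete cosine high-pass basis: K = floor(2 T / cutoff) columns spanning
# fluctuations slower than 1/cutoff Hz, mutually orthogonal, DC excluded.
dct_basis <- function(n, tr_s, cutoff_s = 128) {
  T <- n * tr_s
  K <- floor(2 * T / cutoff_s)
  if (K < 1) return(matrix(0, n, 0))
  i <- seq_len(n) - 1
  sapply(seq_len(K), function(k)
    sqrt(2 / n) * cos(pi * k * (2 * i + 1) / (2 * n)))
}

#' Build a GLM design matrix for a block-design run
#'
#' HRF-convolved scene and object block regressors sampled at the volume
#' acquisition times, an intercept, and a discrete-cosine basis spanning
#' all periods of 128 s (or `hpf_cutoff_s`) and slower, so that low
#' frequency drift is absorbed by the model. Contrast vectors for
#' scene-minus-object and task-versus-baseline are attached.
#'
#' @param schedule A `stim_schedule`.
#' @param tr_s Effective TR of the series to model, seconds.
#' @param n_volumes Number of volumes.
#' @param hpf_cutoff_s High-pass cutoff period in seconds (default 128).
#' @return A numeric matrix with attributes `contrasts` (named list of
#'   vectors) and `task_cols`.
#' @export
build_design_matrix <- function(schedule, tr_s, n_volumes,
                                hpf_cutoff_s = 128) {
  reg <- sampled_regressors(schedule, tr_s = tr_s, n_volumes = n_volumes)
  task <- reg$regressors[, colSums(abs(reg$regressors)) > 0, drop = FALSE]
  X <- cbind(task, intercept = 1)
  D <- dct_basis(n_volumes, tr_s, hpf_cutoff_s)
  if (ncol(D)) colnames(D) <- paste0("dct", seq_len(ncol(D)))
  X <- cbind(X, D)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  p <- ncol(X)
  cvec <- function(w) {
    v <- numeric(p)
    v[match(names(w), colnames(X))] <- w
    v
  }
  contrasts <- list()
  if (all(c("scene", "object") %in% colnames(X)))
    contrasts <- list(
      scene_minus_object = cvec(c(scene = 1, object = -1)),
      task_vs_baseline = cvec(c(scene = 0.5, object = 0.5)))
  attr(X, "contrasts") <- contrasts
  attr(X, "task_cols") <- which(colnames(X) %in% c("scene", "object"))
  X
}

# Projection-bias-corrected pooled AR(1) estimate. The lag-one
# autocorrelation of OLS residuals is biased toward zero because the
# residual-forming projector R = I - H (in particular the low-frequency
# DCT columns) absorbs part of the autocorrelated power. Under an AR(1)
# model the expected residual statistic is
#   E[sum r_t r_{t-1}] / E[sum r_t^2] = tr(R V(rho) R L) / tr(R V(rho) R)
# with V the AR(1) correlation matrix and L the symmetrized lag-1
# operator; rho is recovered by matching this expectation to the observed
# pooled statistic.
debias_ar1 <- function(obs, X, XtXinv) {
  n <- nrow(X)
  H <- X %*% XtXinv %*% t(X)
  Rp <- diag(n) - H
  lag_idx <- cbind(2:n, 1:(n - 1))
  pred <- function(rho) {
    V <- rho^abs(outer(seq_len(n), seq_len(n), `-`))
    A <- Rp %*% V %*% Rp
    sum(A[lag_idx]) / sum(diag(A))
  }
  lo <- -0.9; hi <- 0.95
  f <- function(rho) pred(rho) - obs
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) return(obs)  # observed outside the attainable range
  stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
}

#' Fit a voxelwise GLM with AR(1) prewhitening
#'
#' Ordinary least squares is fitted first; a single AR(1) coefficient is
#' estimated from the pooled lag-one autocorrelation of the OLS residuals
#' over the analysis mask (SPM-style pooling), corrected for the bias
#' introduced by the residual-forming projection (see Details), both data
#' and design are prewhitened with the corresponding Cholesky transform,
#' and the GLM is re-fitted. t-statistics use the whitened residual
#' variance with `df = n - p`.
#'
#' @param series A [ts_image], or a time x voxel numeric matrix.
#' @param design Design matrix from [build_design_matrix()].
#' @param mask Optional logical array (or vector) selecting voxels.
#' @param pooled_rho Logical; `FALSE` estimates rho per voxel.
#' @param residual_space "whitened" (default) or "native": which residuals
#'   feed the residual standard deviation used by [compute_tsnr()].
#' @param keep_residuals Store the residual matrix (time x voxel).
#' @return Object of class `glm_result`: `beta`, `t` (one column per
#'   contrast), `se`, `sigma2`, `rho`, `df`, `resid_sd`, `mean_signal`,
#'   `mask`, `dims`.
#' @export
fit_glm_ar1 <- function(series, design, mask = NULL, pooled_rho = TRUE,
                        residual_space = c("whitened", "native"),
                        keep_residuals = FALSE) {
  residual_space <- match.arg(residual_space)
  if (inherits(series, "ts_image")) {
    dims <- dim(series$data)[1:3]
    Y <- as_voxel_matrix(series)
  } else {
    dims <- NULL
    Y <- as.matrix(series)
  }
  if (!is.null(mask)) Y <- Y[, as.vector(mask), drop = FALSE]
  n <- nrow(Y); p <- ncol(design)
  if (n != nrow(design)) stop("series length does not match design")
  bad <- !is.finite(colSums(Y))
  if (any(bad)) Y[, bad] <- 0

  X <- design
  XtXinv <- solve(crossprod(X))
  beta0 <- XtXinv %*% crossprod(X, Y)
  R <- Y - X %*% beta0

  num <- colSums(R[-1, , drop = FALSE] * R[-n, , drop = FALSE])
  den <- colSums(R^2)
  rho_vox <- ifelse(den > 0, num / den, 0)
  rho <- if (pooled_rho) {
    obs <- sum(num) / max(sum(den), .Machine$double.eps)
    debias_ar1(obs, X, XtXinv)
  } else rho_vox
  rho <- pmax(pmin(rho, 0.95), -0.95)

  whiten <- function(M, r) {
    W <- M
    W[1, ] <- sqrt(1 - r^2) * M[1, ]
    W[-1, ] <- M[-1, , drop = FALSE] - r * M[-n, , drop = FALSE]
    W
  }
  if (pooled_rho) {
    Xw <- whiten(X, rho); Yw <- whiten(Y, rho)
    XtXinv_w <- solve(crossprod(Xw))
    beta <- XtXinv_w %*% crossprod(Xw, Yw)
    Rw <- Yw - Xw %*% beta
  } else {
    beta <- matrix(0, p, ncol(Y)); Rw <- matrix(0, n, ncol(Y))
    XtXinv_w <- NULL
    for (v in seq_len(ncol(Y))) {
      Xw <- whiten(X, rho[v]); yw <- whiten(Y[, v, drop = FALSE], rho[v])
      bv <- solve(crossprod(Xw), crossprod(Xw, yw))
      beta[, v] <- bv
      Rw[, v] <- yw - Xw %*% bv
    }
  }
  df <- n - p
  sigma2 <- colSums(Rw^2) / df

  contrasts <- attr(design, "contrasts") %||%
    list(effect = c(1, rep(0, p - 1)))
  tmat <- matrix(NA_real_, ncol(Y), length(contrasts))
  semat <- matrix(NA_real_, ncol(Y), length(contrasts))
  colnames(tmat) <- names(contrasts)
  for (i in seq_along(contrasts)) {
    cv <- contrasts[[i]]
    if (pooled_rho) {
      cvar <- drop(t(cv) %*% XtXinv_w %*% cv)
      se <- sqrt(sigma2 * cvar)
    } else {
      se <- vapply(seq_len(ncol(Y)), function(v) {
        Xw <- whiten(X, rho[v])
        sqrt(sigma2[v] * drop(t(cv) %*% solve(crossprod(Xw)) %*% cv))
      }, numeric(1))
    }
    tmat[, i] <- drop(crossprod(beta, cv)) / se
    semat[, i] <- se
  }
  tmat[!is.finite(tmat)] <- NA_real_

  resid_sd <- if (residual_space == "whitened") sqrt(colSums(Rw^2) / df)
              else sqrt(colSums((Y - X %*% beta)^2) / df)
  resid_sd[bad] <- NA_real_

  structure(list(beta = beta, t = tmat, se = semat, sigma2 = sigma2,
                 rho = rho, df = df, resid_sd = resid_sd,
                 mean_signal = colMeans(Y), mask = mask, dims = dims,
                 residual_space = residual_space,
                 residuals = if (keep_residuals) Rw else NULL),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("GLM fit: %d voxels, df = %d, AR(1) rho = %s\n",
              length(x$sigma2), x$df,
              if (length(x$rho) == 1) sprintf("%.3f", x$rho) else "voxelwise"))
  invisible(x)
}

# Reassemble a voxel vector into the 3D grid of the fitted series.
glm_map <- function(glm_result, values) {
  if (is.null(glm_result$dims)) return(values)
  out <- array(NA_real_, glm_result$dims)
  if (is.null(glm_result$mask)) out[] <- values
  else out[as.vector(glm_result$mask)] <- values
  out
}

#' t-score map for a named contrast
#'
#' @param glm_result A `glm_result`.
#' @param contrast Contrast name (column of the fitted t matrix).
#' @return 3D array (or vector for matrix input).
#' @export
t_map <- function(glm_result, contrast = "task_vs_baseline") {
  if (!contrast %in% colnames(glm_result$t))
    stop("unknown contrast: ", contrast)
  glm_map(glm_result, glm_result$t[, contrast])
}

#' Temporal SNR from GLM residuals
#'
#' Voxelwise mean signal divided by the standard deviation over time of
#' the residual signal after the GLM fit (task-related variance and slow
#' drift are removed by the model). Voxels with (near-)zero residual
#' variance are masked `NA` rather than reported as infinite.
#'
#' @param series The [ts_image] that was fitted (used for the mean signal).
#' @param glm_result The corresponding `glm_result`.
#' @return 3D tSNR map (or vector for matrix input).
#' @export
compute_tsnr <- function(series, glm_result) {
  mu <- if (inherits(series, "ts_image")) {
    m <- colMeans(as_voxel_matrix(series))
    if (!is.null(glm_result$mask)) m <- m[as.vector(glm_result$mask)]
    m
  } else colMeans(as.matrix(series))
  sd <- glm_result$resid_sd
  tol <- 1e-12 * max(mu, 1)
  vals <- ifelse(is.finite(sd) & sd > tol, mu / sd, NA_real_)
  glm_map(glm_result, vals)
}

# One-sided periodogram of the columns of X (time x voxel), normalized so
# that the sum over all non-DC bins equals the (biased) temporal variance.
periodogram_mat <- function(X, tr_s) {
  n <- nrow(X)
  P <- Mod(stats::mvfft(X))^2 / n^2
  nfold <- floor(n / 2)
  freq <- (seq_len(nfold)) / (n * tr_s)
  pow <- P[1 + seq_len(nfold), , drop = FALSE]
  if (n %% 2 == 0) {
    if (nfold > 1)
      pow[seq_len(nfold - 1), ] <- pow[seq_len(nfold - 1), , drop = FALSE] +
        P[n + 1 - seq_len(nfold - 1), , drop = FALSE]
  } else {
    pow <- pow + P[n + 1 - seq_len(nfold), , drop = FALSE]
  }
  list(freq = freq, power = pow)
}

#' High-frequency content map
#'
#' Sums the one-sided periodogram of every voxel time course over the band
#' `f_lo < f <= Nyquist`. The normalization is such that the sum over all
#' non-DC bins equals the temporal variance (biased, 1/n), so band plus
#' complement always reconstruct the total variance; the band *sum* (not
#' mean) mirrors the fact that series with more volumes resolve the band
#' with more bins.
#'
#' @param series A [ts_image] at the original acquisition rate.
#' @param f_lo Lower band edge in Hz (default 0.18).
#' @return 3D map; attribute `empty_band` is TRUE when `f_lo` is at or
#'   above the series Nyquist frequency (the map is then all zero).
#' @export
high_freq_content <- function(series, f_lo = 0.18) {
  d <- dim(series$data)
  nyq <- 1 / (2 * series$tr_s)
  if (f_lo >= nyq) {
    out <- array(0, d[1:3])
    attr(out, "empty_band") <- TRUE
    return(out)
  }
  X <- as_voxel_matrix(series)
  pg <- periodogram_mat(X, series$tr_s)
  sel <- pg$freq > f_lo
  out <- array(colSums(pg$power[sel, , drop = FALSE]), d[1:3])
  attr(out, "empty_band") <- FALSE
  out
}

#' Fraction of spectral power inside a frequency band
#'
#' DC is excluded so that the mean level of a block design does not
#' dominate. The band is `band[1] < f <= band[2]` (upper edge `Inf` means
#' the Nyquist frequency).
#'
#' @param x Numeric regressor/time course, sampled at `dt_s`.
#' @param dt_s Sampling interval (<= 0.1 s recommended so the check itself
#'   does not alias).
#' @param band Numeric pair of band edges in Hz.
#' @return Fraction in `[0, 1]`.
#' @export
spectral_power_fraction <- function(x, dt_s, band) {
  stopifnot(length(band) == 2, band[1] < band[2])
  pg <- periodogram_mat(matrix(x, ncol = 1), dt_s)
  sel <- pg$freq > band[1] & pg$freq <= band[2]
  if (!any(sel)) stop("empty frequency band for this sampling rate")
  total <- sum(pg$power)
  if (total <= 0) stop("time course has no non-DC power")
  sum(pg$power[sel, 1]) / total
}

#' Define a spherical gray-matter-masked ROI at a t-score maximum
#'
#' Centers a sphere of `radius_mm` at the maximum of the (averaged) t map
#' within the anatomical search mask (ties broken toward the lowest linear
#' index) and intersects it with the gray-matter mask.
#'
#' @param t_map_avg 3D t-score map (averaged over the relevant conditions).
#' @param anatomy_mask Logical 3D search region.
#' @param gm_mask Logical 3D gray-matter mask.
#' @param radius_mm Sphere radius in mm (default 5, a "1 cm sphere").
#' @param voxel_size_mm Numeric triple of voxel dimensions.
#' @param label ROI label.
#' @return Object of class `roi_spec`: `center` (voxel index triple),
#'   `mask`, `radius_mm`, `label`, `n_voxels`.
#' @export
define_roi <- function(t_map_avg, anatomy_mask, gm_mask, radius_mm = 5,
                       voxel_size_mm = c(3, 3, 3), label = "roi") {
  stopifnot(all(dim(t_map_avg) == dim(anatomy_mask)))
  if (!any(anatomy_mask)) stop("anatomy mask is empty")
  vals <- t_map_avg
  vals[!anatomy_mask] <- -Inf
  vals[!is.finite(vals)] <- -Inf
  ctr <- arrayInd(which.max(vals), dim(vals))[1, ]
  d <- dim(t_map_avg)
  dx <- (slice.index(array(0, d), 1) - ctr[1]) * voxel_size_mm[1]
  dy <- (slice.index(array(0, d), 2) - ctr[2]) * voxel_size_mm[2]
  dz <- (slice.index(array(0, d), 3) - ctr[3]) * voxel_size_mm[3]
  sphere <- dx^2 + dy^2 + dz^2 <= radius_mm^2
  mask <- sphere & gm_mask
  if (!any(mask))
    stop("ROI sphere does not intersect the gray-matter mask")
  structure(list(center = ctr, mask = mask, radius_mm = radius_mm,
                 label = label, n_voxels = sum(mask)), class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("ROI '%s': center (%d,%d,%d), radius %g mm, %d voxels\n",
              x$label, x$center[1], x$center[2], x$center[3], x$radius_mm,
              x$n_voxels))
  invisible(x)
}

roi_values <- function(map, roi) {
  mask <- if (inherits(roi, "roi_spec")) roi$mask else roi
  v <- map[mask]
  v[is.finite(v)]
}

#' Mean of the highest 10% of t-scores within an ROI
#'
#' Averages the `ceiling(0.1 * n)` largest values.
#'
#' @param t_map 3D t map.
#' @param roi `roi_spec` or logical mask.
#' @param top_fraction Fraction of voxels to average (default 0.1).
#' @return Scalar.
#' @export
roi_top10_mean <- function(t_map, roi, top_fraction = 0.1) {
  v <- roi_values(t_map, roi)
  if (!length(v)) stop("ROI contains no finite t values")
  k <- ceiling(top_fraction * length(v))
  mean(sort(v, decreasing = TRUE)[seq_len(k)])
}

#' Count suprathreshold voxels within an ROI
#'
#' Strict count of voxels with `t > threshold` (default 3.1, the t-score
#' threshold corresponding to uncorrected p < 0.001 used throughout the
#' evaluation; stored as a constant, not recomputed from df).
#'
#' @inheritParams roi_top10_mean
#' @param threshold Significance threshold on t.
#' @return Integer count.
#' @export
roi_count_significant <- function(t_map, roi, threshold = 3.1) {
  sum(roi_values(t_map, roi) > threshold)
}

#' Percent change relative to a reference
#'
#' `100 * (value - reference) / reference`.
#'
#' @param value,reference Numeric (vectorized); `reference` must be
#'   non-zero.
#' @return Percent change.
#' @export
percent_change <- function(value, reference) {
  if (any(reference == 0)) stop("reference must be non-zero")
  100 * (value - reference) / reference
}
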
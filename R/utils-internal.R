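# Internal numerical helpers: batched 2D FFTs, circular shifts, seeded RNG,
# correlated complex Gaussian noise. All k-space operations in the package use
# the periodic (circular) convention on the discrete grid; see the methods
# vignette for why.

# 2D FFT over the first two dims of an array (nx, ny, ...), unnormalized.
fft2 <- function(a, inverse = FALSE) {
  d <- dim(a)
  if (is.null(d) || length(d) < 2) stop("fft2 needs an array with >= 2 dims")
  if (length(d) == 2) {
    out <- stats::fft(a, inverse = inverse)
    if (inverse) out <- out / (d[1] * d[2])
    return(out)
  }
  nx <- d[1]; ny <- d[2]; rest <- prod(d[-(1:2)])
  m <- stats::mvfft(matrix(a, nx, ny * rest), inverse = inverse)
  a2 <- aperm(array(m, c(nx, ny, rest)), c(2, 1, 3))
  m2 <- stats::mvfft(matrix(a2, ny, nx * rest), inverse = inverse)
  out <- aperm(array(m2, c(ny, nx, rest)), c(2, 1, 3))
  dim(out) <- d
  if (inverse) out <- out / (nx * ny)
  out
}

ifft2 <- function(a) fft2(a, inverse = TRUE)

# Circular shift of the first two dims: out[i, j, ..] = in[i - s1, j - s2, ..]
# (indices wrapped), i.e. content moves *forward* by (s1, s2).
circshift2 <- function(a, s1 = 0L, s2 = 0L) {
  d <- dim(a)
  if (is.null(d)) stop("circshift2 needs an array")
  s1 <- ((s1 %% d[1]) + d[1]) %% d[1]
  s2 <- ((s2 %% d[2]) + d[2]) %% d[2]
  if (s1 == 0 && s2 == 0) return(a)
  i1 <- ((seq_len(d[1]) - 1 - s1) %% d[1]) + 1
  i2 <- ((seq_len(d[2]) - 1 - s2) %% d[2]) + 1
  rest <- if (length(d) > 2) prod(d[-(1:2)]) else 1L
  m <- array(a, c(d[1], d[2], rest))
  out <- m[i1, i2, , drop = FALSE]
  dim(out) <- d
  out
}

# Shift along the phase-encode axis (dim 2) only.
shift_phase <- function(a, s) circshift2(a, 0L, s)

# Apply the linear k-space phase equivalent to an image-domain circular shift
# of `s` pixels along phase encode: K'(kx, ky) = K(kx, ky) * exp(-2i pi ky s/ny).
ramp_kspace <- function(k, s) {
  d <- dim(k)
  ky <- 0:(d[2] - 1)
  ph <- exp(-2i * pi * ky * s / d[2])
  sweep(k, 2, ph, `*`)
}

# Evaluate an expression with a local RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# n draws of a zero-mean circular complex Gaussian vector with covariance
# `cov` (Hermitian PSD, ncoil x ncoil): returns ncoil x n complex matrix.
rcnorm_cov <- function(cov, n) {
  nc <- nrow(cov)
  ev <- eigen(cov, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  L <- ev$vectors %*% diag(sqrt(lam), nc)
  z <- matrix(complex(real = stats::rnorm(nc * n), imaginary = stats::rnorm(nc * n)),
              nc, n) / sqrt(2)
  L %*% z
}

# v^H M v for each row v of complex matrix V (n x k), M k x k: real vector.
quad_form_rows <- function(V, M) {
  Re(rowSums(Conj(V) * (V %*% t(M))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
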
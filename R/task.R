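#' Canonical double-gamma haemodynamic response function
#'
#' The conventional double-gamma HRF (positive lobe peaking near 6 s, late
#' undershoot near 16 s, undershoot ratio 1/6), sampled on a regular grid
#' and normalized to unit peak.
#'
#' @param dt_s Sampling interval in seconds (> 0).
#' @param duration_s Kernel length in seconds.
#' @param peak_delay,under_delay Gamma shape parameters (s) of the main lobe
#'   and undershoot (unit dispersion).
#' @param ratio Undershoot-to-peak amplitude ratio before normalization.
#' @return Numeric kernel; attribute `times` holds the sample times.
#' @export
canonical_hrf <- function(dt_s, duration_s = 32, peak_delay = 6,
                          under_delay = 16, ratio = 1 / 6) {
  if (dt_s <= 0) stop("dt_s must be positive")
  t <- seq(0, duration_s, by = dt_s)
  h <- stats::dgamma(t, shape = peak_delay, scale = 1) -
    ratio * stats::dgamma(t, shape = under_delay, scale = 1)
  h <- h / max(h)
  attr(h, "times") <- t
  h
}

#' Generate a block-design scene/object/baseline stimulus schedule
#'
#' Fifteen scene and fifteen object blocks of 8 s (four 2 s images each,
#' 60 images per condition in total), alternating between the two stimulus
#' conditions so that the scene-minus-object contrast stays band-limited,
#' with 8 s baseline blocks evenly interleaved and inter-stimulus intervals
#' drawn uniformly from 2-4 s. The number of baseline blocks is the largest
#' count that fits the run duration given the drawn ISIs.
#'
#' @param run_duration_s Run length in seconds (default 434 s = 155 x 2.8 s).
#' @param seed RNG seed; the schedule is a deterministic function of
#'   (arguments, seed).
#' @param n_blocks_per_condition Stimulus blocks per condition (default 15).
#' @param block_s Block duration in seconds (default 8).
#' @param images_per_block Images per stimulus block (default 4).
#' @param isi_range ISI bounds in seconds (default c(2, 4)).
#' @return An object of class `stim_schedule`: `blocks` data frame (onset,
#'   duration, condition), `images` data frame, `isi` draws, counts, seed.
#' @export
make_task_design <- function(run_duration_s = 434, seed = 1L,
                             n_blocks_per_condition = 15L, block_s = 8,
                             images_per_block = 4L, isi_range = c(2, 4)) {
  nb <- as.integer(n_blocks_per_condition)
  n_stim <- 2L * nb
  min_total <- n_stim * block_s + (n_stim - 1) * isi_range[1]
  if (run_duration_s < min_total)
    stop(sprintf("run_duration_s = %g cannot fit %d stimulus blocks (needs >= %g s)",
                 run_duration_s, n_stim, min_total))

  out <- with_seed(seed, {
    first <- sample(c("scene", "object"), 1)
    cond <- rep(c(first, setdiff(c("scene", "object"), first)), nb)
    isi <- stats::runif(4L * nb + 64L, isi_range[1], isi_range[2])
    list(cond = cond, isi = isi)
  })
  isi <- out$isi

  # largest baseline count B such that all 2*nb + B blocks plus the ISIs
  # between them fit within the run
  fits <- function(B) {
    k <- n_stim + B
    k * block_s + sum(isi[seq_len(k - 1)]) <= run_duration_s
  }
  B <- 0L
  while (fits(B + 1L)) B <- B + 1L

  # interleave baselines evenly among the stimulus blocks
  types <- out$cond
  if (B > 0) {
    after <- unique(pmin(n_stim, ceiling(seq_len(B) * n_stim / (B + 1))))
    B <- length(after)
    seqs <- character(0)
    prev <- 0L
    for (i in seq_along(after)) {
      seqs <- c(seqs, types[(prev + 1):after[i]], "baseline")
      prev <- after[i]
    }
    if (prev < n_stim) seqs <- c(seqs, types[(prev + 1):n_stim])
    types <- seqs
  }

  onset <- numeric(length(types))
  t0 <- 0
  for (i in seq_along(types)) {
    onset[i] <- t0
    t0 <- t0 + block_s + isi[i]
  }
  blocks <- data.frame(onset = onset, duration = block_s, condition = types,
                       stringsAsFactors = FALSE)
  stopifnot(max(blocks$onset) + block_s <= run_duration_s)

  stim <- blocks[blocks$condition != "baseline", ]
  images <- data.frame(
    onset = rep(stim$onset, each = images_per_block) +
      rep(seq(0, by = block_s / images_per_block, length.out = images_per_block),
          nrow(stim)),
    duration = block_s / images_per_block,
    condition = rep(stim$condition, each = images_per_block),
    stringsAsFactors = FALSE)

  structure(list(blocks = blocks, images = images,
                 isi = isi[seq_len(length(types) - 1)],
                 run_duration_s = run_duration_s, block_s = block_s,
                 n_baseline = B, seed = as.integer(seed)),
            class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  tab <- table(x$blocks$condition)
  cat(sprintf("stimulus schedule, %g s run: %s\n", x$run_duration_s,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

# Condition boxcars convolved with the canonical HRF, evaluated on a fine
# grid (dt <= 0.1 s) and returned either at fine resolution or sampled at
# the volume acquisition times k * tr_s, k = 0 .. n_volumes-1.
sampled_regressors <- function(schedule, tr_s = NULL, n_volumes = NULL,
                               dt_s = 0.1, hrf = NULL) {
  fine_t <- seq(0, schedule$run_duration_s, by = dt_s)
  if (is.null(hrf)) hrf <- canonical_hrf(dt_s)
  conds <- c("scene", "object")
  fine <- sapply(conds, function(cn) {
    b <- schedule$blocks[schedule$blocks$condition == cn, ]
    box <- numeric(length(fine_t))
    for (i in seq_len(nrow(b)))
      box[fine_t >= b$onset[i] & fine_t < b$onset[i] + b$duration[i]] <- 1
    # normalized by the HRF area so a sustained block plateaus at ~1
    stats::convolve(box, rev(hrf), type = "open")[seq_along(box)] / sum(hrf)
  })
  if (is.null(tr_s)) {
    return(list(time = fine_t, regressors = fine))
  }
  vt <- (seq_len(n_volumes) - 1) * tr_s
  idx <- round(vt / dt_s) + 1
  idx[idx > length(fine_t)] <- length(fine_t)
  list(time = vt, regressors = fine[idx, , drop = FALSE])
}
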
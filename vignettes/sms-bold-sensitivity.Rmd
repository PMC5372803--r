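---
title: "Evaluating BOLD sensitivity of SMS-EPI acquisitions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating BOLD sensitivity of SMS-EPI acquisitions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Simultaneous multi-slice (SMS) EPI accelerates fMRI by exciting and reading
out several slices at once; the repetition time TR shrinks in proportion to
the SMS factor. Faster sampling brings two benefits — more samples per unit
time and a higher temporal Nyquist frequency, which lets physiological
signals near 0.3 Hz (respiration) and 1 Hz (cardiac pulsation) be sampled
and removed instead of aliasing into the BOLD band — but it costs image SNR
twice over: less longitudinal magnetization recovers at short TR, and
unaliasing simultaneously acquired slices amplifies thermal noise by the
voxelwise g-factor. Which effect wins is spatially non-uniform, so the best
SMS factor depends on where in the brain you look.

`smssense` implements a complete, self-contained framework for quantifying
this trade-off: a synthetic multi-coil scanner, slice-GRAPPA
reconstruction with analytic g-factor mapping, and a 4 x 2 factorial
evaluation (SMS factor 1/2/4/8 crossed with two processing routes) using
temporal SNR, high-frequency content and ROI t-score metrics.

# Acquisition model

## Protocols

The four default protocols keep the run duration fixed at 434 s while TR
halves with each doubling of the SMS factor:

| SMS | TR (ms) | flip | CAIPI shift | Nyquist (Hz) | volumes |
|----:|--------:|-----:|------------:|-------------:|--------:|
| 1   | 2800    | 87   | none        | 0.18         | 155     |
| 2   | 1400    | 76   | FOV/2       | 0.36         | 310     |
| 4   | 700     | 60   | FOV/3       | 0.71         | 620     |
| 8   | 350     | 45   | FOV/3       | 1.43         | 1240    |

Flip angles are Ernst angles, `acos(exp(-TR/T1))`, for the 1000 ms gray
matter reference T1, rounded to integer degrees. The per-voxel signal scale
is the spoiled steady state `sin(a) (1 - E1) / (1 - cos(a) E1)`,
`E1 = exp(-TR/T1)`, evaluated with each tissue's T1 — this is how the
shorter TRs pay their magnetization-saturation cost in the simulator.

## Phantom and coil array

The phantom is analytic (nested ellipsoids): a gray-matter shell around a
white-matter core, CSF ventricles, and three vessel-like hotspots that
carry localized cardiac noise. Three gray-matter regions are labelled to
mirror the reconstruction regimes of interest — `v1_like` on the posterior
rim (close to coil elements, well-conditioned), `ppa_like` in the posterior
interior band, and `vmpfc_like` in the anterior interior band, which is the
worst-conditioned regime because the coil layout has an anterior face
opening. Geometry is deterministic; the seed only drives a +/-2%
proton-density texture.

Coil sensitivities are localized loop-like profiles (Lorentzian falloff)
on up to four rings along the slice axis, azimuthally staggered, with a
60 degree anterior gap and a through-slice phase slope that is graded
across rings. The rings and graded phase are what make slices within an
SMS group distinguishable; the localization and the anterior gap are what
make the g-factor low at the posterior periphery and high in the
anterior-central region, the spatial pattern the metrics are designed to
expose. On the reduced default fixture (32 x 36 x 8 grid, 16 channels)
the analytic g-factor support means are about 1.01 / 1.19 / 2.3 at
SMS 2 / 4 / 8 — the regime reported for 32-channel arrays at these
accelerations. The coil noise covariance is `correlation^|j-k|`
(Hermitian, positive definite), default neighbour correlation 0.2.

## Task, BOLD and noise

The block design presents 15 scene and 15 object blocks of 8 s (four 2 s
images each, 60 images per condition), alternating between the two
conditions, with 8 s baseline blocks evenly interleaved — the baseline
count is the largest that fits the run given the inter-stimulus intervals,
drawn uniformly from 2-4 s. Alternation is deliberate: it concentrates the
scene-minus-object contrast near 1/22 Hz so that, after convolution with
the canonical double-gamma HRF (peak near 5 s, undershoot near 16 s,
ratio 1/6, unit peak), more than 99.9% of its non-DC spectral power lies
above the 1/128 Hz high-pass cutoff and more than 99.9% below the 0.18 Hz
single-band Nyquist frequency. A fully randomized block order would not be
band-limited at the low end. The secondary task-versus-baseline contrast
is slightly less band-limited (99.5% / 99.8%); the spectral checks use the
scene-minus-object contrast.

The voxel signal model is

```
s(x, t) = pd(x) * sss(x) * [1 + bold(x, t) + physio(x, t) + drift(t)]
```

with BOLD percent-signal-change amplitudes per labelled region (defaults
0.4-2%, the usual 3T block-design range), sinusoidal physiological
components (1 Hz at 3% of signal on the vessel hotspots, 0.3 Hz at 1%
brain-wide) with seeded random phases, and a 0.5% slow cosine drift.
Physiological signals are injected in image space, thermal noise in
k-space with the coil covariance — each where its physics lives. The
thermal scale is parameterized as the per-coil image-domain noise standard
deviation (default 0.008 signal units), which puts coil-combined gray
matter tSNR at SMS 1 in the tens, the thermal-dominated regime of 3 mm
EPI.

## Blipped-CAIPI encoding

Slices are grouped with maximal spacing (slice i joins i + nz/M, ...);
slice j within a group receives an in-plane shift of `(j-1) mod d` times
FOV/d along phase encode (d the CAIPI denominator), implemented as an
integer-pixel circular shift, i.e. an exact linear phase ramp in k-space.
Group k-space is the sum of the shifted, coil-weighted slices' 2D FFTs,
plus complex Gaussian noise with the coil covariance added once per
acquired (collapsed) k-sample — SMS acquires 1/M as many samples but the
per-sample noise is unchanged, which is why no sqrt(R) factor appears
anywhere.

# Reconstruction

Slice-GRAPPA kernels (default 5 x 5 k-space neighbourhood, all coils) are
fitted per group on noiseless single-band calibration of the same object,
with the CAIPI ramps applied to match acquisition. Standard mode solves
`min || A(sum_s C_s) K - C_t ||^2`; LeakBlock (Split Slice-GRAPPA) mode
solves `min sum_s || A(C_s) K - delta(s=t) C_s ||^2`, explicitly
penalizing the leakage of every other slice's signal into the target's
output. Both add a trace-normalized ridge (default 1e-4); with ridge 0 a
rank-deficient system is an error, never a silent regularization.

All k-space neighbourhood operations use the periodic (circular)
convention on the discrete grid. This is a deliberate design choice:
circular convolution by a k-space kernel is *exactly* pointwise
multiplication in the image domain, so (i) kernel application costs one
FFT pair per volume plus per-voxel multiplies, and (ii) the analytic
g-factor below is exact rather than a boundary approximation. Boundary
behaviour is therefore periodic wrap, not zero padding, and is bit-exactly
reproducible.

Coil combination is root-sum-of-squares by default; the
covariance-whitened quadrature combination `sqrt(i^H Psi^-1 i)` is
available and is what the analytic g-factor uses when selected.

# g-factor

With image-domain unaliasing weights `W(x)` (the FFT of the kernel taps)
and per-voxel combination vector `p(x)` (the coil signal vector for rss,
linearized at the operating point; `Psi^-1 s` for the whitened
combination), the analytic map is

```
g(x) = sqrt( p^H W Psi W^H p / p^H Psi p )
```

— the SMS-reconstructed voxel's noise standard deviation over its
single-band value, both propagated through the coil covariance. Voxels
below 5% of the maximum combined reference signal are masked (`NA`), since
near-zero signal corrupts the ratio; no spatial smoothing is applied. For
SMS 1 the map is 1 on support by the reference convention.

Because the magnitude-rss combination is only linearized, the binding
definition of correctness is the pseudo multiple-replica oracle:
correlated k-space noise draws pushed through the same kernel-application
code path, with the *same* draw feeding the collapsed and the single-band
paths (matched replicas — this makes the ratio estimator tight). Analytic
and pseudo-replica maps agree to a few percent median relative deviation
at 300-500 replicas on the test fixtures; that equivalence, not the
analytic formula, is what the test suite enforces.

# The 4 x 2 evaluation

Two processing routes return every acquisition to 155 volumes at an
effective TR of 2.8 s, removing the degrees-of-freedom confound:

* **Downsampled** — keep every Nth volume (N = SMS factor), no filter:
  high-frequency content aliases into the retained band.
* **Decimated** — 6th-order Butterworth low-pass at 0.18 Hz, then the same
  downsampling. The filter runs zero-phase (forward-backward, squaring the
  magnitude response) so the haemodynamic response is not delayed relative
  to the regressors; a causal mode exists. The series mean is removed and
  restored around filtering (exact DC gain) and edges use odd-reflection
  padding with length scaling as 6 fs / cutoff. For SMS 1 the 0.18 Hz
  cutoff sits above the 0.179 Hz Nyquist, where a digital low-pass is
  undefined; the runner therefore defines Decimated(SMS 1) as
  Downsampled(SMS 1), the two being equivalent there up to filter
  roll-off.

The GLM design holds the HRF-convolved scene and object block regressors,
an intercept, and a discrete-cosine basis with `floor(2 T / 128)` columns
(6 for T = 434 s), spanning all fluctuations slower than 1/128 Hz.
Temporal autocorrelation is handled by AR(1) prewhitening with a single
pooled coefficient (SPM-style pooling; voxelwise mode available). The
pooled estimate corrects the residual-autocorrelation bias: OLS residuals
under-state the autocorrelation because the residual-forming projector —
especially the low-frequency DCT columns — absorbs autocorrelated power,
so the estimator matches the observed pooled lag-1 statistic to its
model-implied expectation `tr(R V R L) / tr(R V R)` and solves for rho by
root finding. On simulated AR(1) data with rho = 0.4 at n = 155 this
recovers rho to within a few thousandths where the raw residual statistic
is biased low by ~0.08, and it keeps the empirical type-I error at
p < 0.001 within its binomial band on white-noise nulls.

Outcome metrics:

* **tSNR** — voxel mean signal over the temporal standard deviation of
  the GLM residuals (whitened residuals by default; native-space mode
  available). Task variance and slow drift are removed by the model, so
  tSNR is invariant to the injected activation amplitude.
* **High-frequency content** — one-sided periodogram summed over
  0.18 Hz < f <= Nyquist on the full-rate series, normalized so all
  non-DC bins sum to the (biased) temporal variance; the *sum* (not mean)
  is used, so longer series resolve the band with more bins. At SMS 1 the
  band is empty and the map is zero with a flag.
* **ROI t-metrics** — ROIs are spheres (1 cm at full scale; 12 mm in the
  reduced configuration, whose 6 mm voxels would otherwise leave a single
  voxel) centred at the peak of the averaged Decimated t-maps within each
  anatomical region, masked by gray matter. The contrast per region is
  scene-minus-object for `ppa_like` and task-versus-baseline for the
  others. Reported are the mean of the top `ceiling(0.1 n)` t values and
  the strict count of t > 3.1 (the t threshold for uncorrected p < 0.001,
  stored as a constant by design).

`run_factorial()` assembles the three comparisons — Relative Image SNR
(Downsampled across SMS), High-Frequency Noise Removal (Decimated vs
Downsampled per SMS), Combined Effects (Decimated across SMS) — and is
byte-deterministic given the configuration seeds.
`validate_full_vs_decimated()` additionally fits the full-rate series with
AR(1) prewhitening and checks that its ROI t-metrics rank the conditions
like the Decimated chain, the theoretically equivalent route.

# Problem sizes and numerical choices

The default configuration runs the full protocol table (matched 434 s
runs, up to 1240 volumes) on a 32 x 36 x 8 grid with 16 coils — a complete
factorial takes a few minutes on one CPU; the full-scale 64 x 72 x 40,
32-channel geometry is a configuration change. Unit tests use a 16 x 18 x 4
grid with 4 coils; the g-factor oracle comparison runs at 32 x 36 with
8 channels and 500 replicas. Other conventions: downsampling keeps index 0
first; ROI peak ties break toward the lowest linear index; DC is excluded
from spectral power fractions so block-design means cannot dominate;
kernel ridge is trace-normalized so its meaning is invariant to signal
scale.

```{r example}
library(smssense)
cfg <- default_config(seed = 1)
report <- run_factorial(cfg, verbose = TRUE)
report$tables$combined
```

# What the synthetic data does and does not show

The generator reproduces the *mechanisms* — steady-state saturation,
g-factor noise amplification with a realistic spatial pattern,
physiological noise aliasing and its removal by decimation — under known
ground truth, which is exactly what is needed to verify the pipeline's
statistics and the analytic g-factor. It does not emulate subject motion,
EPI distortion or dropout, T2* decay, partial Fourier, in-plane
acceleration, slice-timing offsets, spatially varying B1+, or the
covariance structure of real physiological noise; no spatial
preprocessing (realignment, normalization) is modelled, and spatial
smoothing is off by default for synthetic data. Passing tests therefore
certify the analysis machinery and the qualitative acceleration
trade-offs, not quantitative predictions for any particular scanner. The
absolute tSNR percent changes here are more filter-dominated than in real
data, whose noise floor contains more non-removable physiological
variance; the spatial orderings across regions and SMS factors are the
transportable result.
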
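# smssense

**BOLD sensitivity analysis of simultaneous multi-slice (SMS) EPI
acquisitions.**

Simultaneous multi-slice EPI shortens the fMRI repetition time in
proportion to the number of slices excited together. The shorter TR buys
more samples per unit time and a temporal Nyquist frequency high enough to
sample — and then filter out — physiological fluctuations near 0.3 Hz
(respiration) and 1 Hz (cardiac pulsation) that otherwise alias into the
BOLD band. It costs image SNR twice: less longitudinal magnetization
recovers per TR (the spoiled steady state
`sin(a)(1-E1)/(1-cos(a)E1)`, `E1 = exp(-TR/T1)`, with the flip angle at the
Ernst angle `acos(E1)`), and unaliasing simultaneously acquired slices
amplifies thermal noise by the voxelwise g-factor

```
g(x) = sqrt( p^H W Psi W^H p / p^H Psi p ),
```

the noise of the SMS-reconstructed, coil-combined voxel relative to its
single-band reference, propagated through the slice-GRAPPA image-domain
weights `W(x)` and the coil noise covariance `Psi`. Which effect wins is
spatially non-uniform, so the optimal SMS factor is region dependent.

`smssense` is a self-contained framework for quantifying this trade-off.
It provides, for researchers planning or evaluating SMS-fMRI protocols:

* a **synthetic multi-coil scanner**: tissue phantom with labelled regions
  and vessel hotspots, localized complex coil sensitivities with a coil
  noise covariance, a scenes/objects block-design task, physiological
  noise and drift, and blipped-CAIPI SMS k-space encoding at SMS factors
  1/2/4/8 with matched 434 s runs (155/310/620/1240 volumes);
* **slice-GRAPPA and Split Slice-GRAPPA (LeakBlock)** kernel fitting and
  reconstruction, with an **analytic g-factor** map verified against a
  matched-replica **pseudo-replica Monte-Carlo** oracle;
* the **4 x 2 factorial evaluation**: Downsampled (every Nth volume, no
  anti-alias filter) and Decimated (6th-order 0.18 Hz Butterworth, then
  downsampling) processing of every acquisition back to 155 volumes at an
  effective TR of 2.8 s, GLM with discrete-cosine 128 s high-pass and
  pooled AR(1) prewhitening, and tSNR / high-frequency-content / ROI
  t-score metrics assembled into the three comparisons: Relative Image
  SNR, High-Frequency Noise Removal, and Combined Effects.

## Worked example

```r
library(smssense)

cfg <- default_config(seed = 1)   # reduced 32x36x8 grid, 16 coils,
                                  # full matched-duration protocol table
report <- run_factorial(cfg)
report$tables$combined
```

which prints (Decimated data across SMS factors, percent changes against
SMS 1):

```
        roi sms mean_tsnr tsnr_pct_change  top10_t top10_t_pct_change n_sig
   ppa_like   1  30.09130        0.000000 2.137255           0.000000     0
   ppa_like   2  35.95743       19.494435 3.891829          82.094786     1
   ppa_like   4  28.68403       -4.676680 3.399778          59.072175     3
   ppa_like   8  19.04900      -36.695989 2.857300          33.690182     1
    v1_like   1  40.28109        0.000000 5.487289           0.000000     6
    v1_like   2  49.30687       22.406991 5.790553           5.526662     7
    v1_like   4  47.31695       17.466927 5.806835           5.823392     6
    v1_like   8  27.66039      -31.331581 3.221515         -41.291316     2
 vmpfc_like   1  29.50174        0.000000 2.722362           0.000000     0
 vmpfc_like   2  35.84097       21.487668 2.046030         -24.843553     0
 vmpfc_like   4  31.34366        6.243429 3.296409          21.086370     1
 vmpfc_like   8  11.46442      -61.139856 1.906885         -29.954764     0
```

Read it as: moderate acceleration helps everywhere (+19 to +22% tSNR at
SMS 2); at SMS 4 the peripheral `v1_like` region still gains (+17%) while
the central regions are flat-to-negative; at SMS 8 every region loses
tSNR, and the anterior-central `vmpfc_like` region — where the g-factor is
highest — loses by far the most (-61% vs -31% in `v1_like`). The
corresponding analytic g-factor support means are 1.01 / 1.19 / 2.33 at
SMS 2 / 4 / 8. The companion tables `report$tables$relative_snr`
(Downsampled across SMS: pure image-SNR effect, tSNR falling to -75 to
-87% at SMS 8) and `report$tables$hf_removal` (Decimated vs Downsampled:
the filtering gain, growing from ~+46% at SMS 2 to ~+185% at SMS 8) isolate
the two opposing mechanisms that the combined table nets out.

`validate_full_vs_decimated(cfg)` additionally checks that analysing the
full-rate series with AR(1) prewhitening ranks the conditions the same way
as the Decimated chain.

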
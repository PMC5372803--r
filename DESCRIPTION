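Package: smssense
Title: BOLD Sensitivity Analysis of Simultaneous Multi-Slice EPI Acquisitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation framework for quantifying how
    simultaneous multi-slice (SMS) EPI acceleration affects BOLD sensitivity
    in task fMRI. Provides a synthetic multi-coil scanner (tissue phantom,
    complex coil sensitivities with a coil noise covariance, block-design
    task, physiological noise, blipped-CAIPI SMS k-space encoding),
    slice-GRAPPA and Split Slice-GRAPPA (LeakBlock) reconstruction, analytic
    and pseudo-replica g-factor mapping, and a 4 x 2 factorial evaluation
    pipeline (SMS factor by Downsampled/Decimated processing) with GLM/AR(1)
    statistics, temporal SNR, high-frequency content, and ROI t-score
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
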
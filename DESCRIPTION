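Package: cineflow
Title: Cardio-Cerebral Haemodynamics from Cardiac-Gated Cine Phase-Contrast MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cardiac-gated cine phase-contrast MRI of the
    intracranial arteries (basilar trunk, internal carotids) and venous sinuses
    (superior sagittal, straight): vessel lumen segmentation by background-noise
    thresholding, voxelwise velocity decoding and per-frame flow computation,
    normalization of partially-covered flow waveforms onto a canonical 32-step
    cardiac-cycle grid, waveform feature extraction (peak timing, dicrotic
    notch, systolic upslope, pulsatility and resistive indices), per-cycle
    blood volumes, perfusion and cerebral blood flow, arterio-venous volume
    balance under the Monro-Kellie constraint (correction factor, oscillating
    volume, flow-flow hysteresis loop), and nonparametric group statistics.
    Includes a calibrated synthetic-cohort generator emulating young and old
    marmoset acquisitions so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
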
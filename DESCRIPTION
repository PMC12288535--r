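Package: freecmr
Title: Free-Running 4D Cardiac MRI Simulation, Self-Gating, Reconstruction
    and Automated Biomarker Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale pipeline for free-breathing, free-running cardiac
    magnetic resonance imaging (CMR). Simulates multi-coil Cartesian
    k-space acquisitions of a dynamic digital heart phantom (continuous
    cine and pulse-oximeter-gated multi-inversion-time delayed
    enhancement), extracts cardiac and respiratory self-gating signals by
    principal component analysis with spectral band classification,
    detects heartbeats with Savitzky-Golay smoothing and rejects
    arrhythmic RR intervals, bins readouts into 30 cardiac frames and a
    mode respiratory phase, reconstructs motion-resolved volumes with
    region-optimized virtual coils, slice-wise SENSE compressed sensing
    with temporal total variation and locally-low-rank denoising,
    generates magnitude and phase-sensitive inversion-recovery contrasts
    with per-voxel null-point detection, and computes whole-heart
    biomarkers (volumes, ejection fractions, cardiac output, mass,
    fractional area change, scar burden), cardiac landmarks, standard
    view planes, and agreement statistics (intraclass correlation,
    Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    signal,
    pracma,
    rhdf5,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
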
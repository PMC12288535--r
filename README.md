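# freecmr

Desk-scale, end-to-end **free-running cardiac MRI** in R: a dynamic
digital heart phantom and multi-coil k-space simulator, self-gated
motion extraction, motion-resolved compressed-sensing reconstruction,
phase-sensitive delayed-enhancement (PSIR) contrast generation, and an
automated whole-heart biomarker / view-prescription engine.

## The problem

Conventional cardiac MR needs ECG gating, repeated breath-holds and an
expert technologist planning patient-specific 2D views. Free-running
protocols instead acquire 3D isotropic data continuously while the
patient breathes freely, then sort the data retrospectively:
*self-gating* lines through the k-space center — acquired after every
10th imaging line during cine, once per heartbeat during
delayed-enhancement (DE) — carry the cardiac and respiratory motion,
so the whole exam becomes push-button. The cost is moved into the
algorithms: navigator extraction, beat detection, arrhythmia rejection,
binning into 30 cardiac frames and a mode respiratory phase, heavily
undersampled reconstruction, and automated analysis of the resulting
4D volumes. `freecmr` implements that entire chain against a seeded
synthetic phantom, so every stage can be developed and verified on one
CPU with known ground truth.

## The core models

* **Self-gating**: SG readouts are stacked channel-wise and separated
  by PCA; a component is respiratory if its spectral energy is
  dominantly below 0.6 Hz and cardiac if dominantly above. The cardiac
  navigator is Savitzky–Golay smoothed before peak detection; RR
  intervals farther than two standard deviations from the mean are
  rejected, and each accepted peak-to-peak interval is stretched
  linearly onto 30 cardiac frames. Heart rate is
  `60000 / mean(accepted RR in ms)`.
* **Reconstruction**: region-optimized virtual coils (generalized
  eigenproblem `A w = λ B w` over heart/interference signal Gram
  matrices), then slice-wise SENSE compressed sensing
  `min ½‖MFSx − y‖² + λ Σ_t |x_{t+1} − x_t|` with cyclic temporal total
  variation, then multi-block locally-low-rank denoising.
* **DE / PSIR**: lines sorted into overlapping 80 ms TI windows
  centered 80–340 ms; the inversion-recovery signal
  `M(TI) = M0 (1 − 2 e^{−TI/T1})` nulls at `TI = T1 ln 2`, so per-voxel
  null-point detection (parabolic refinement of the magnitude minimum)
  yields both a polarity-restored PSIR contrast and a T1 estimate.
* **Biomarkers**: `EF = 100 (EDV − ESV)/EDV`, `CO = SV × HR`,
  `LVM = myocardial volume × 1.05 g/mL`, atrial
  `EF = 100 (V_LVES − V_LVED)/V_LVES`, `FAC = 100 (Amax − Amin)/Amax`,
  valve-plane landmarks from label interfaces, and 2CH/4CH/SAX view
  planes from the landmark geometry. Agreement statistics: two-way
  mixed consistency ICC (fixed raters) and Bland–Altman.

See the methods vignette (`vignettes/freecmr-methods.Rmd`) for the
phantom physics, numerical choices and known limitations.

## Worked example

Simulate two minutes of free-running cine at desk scale (32³ grid,
160 mm FOV, 4 coils, SNR 20), run the self-gating chain, and compute
the biomarker report from the phantom's ground-truth label maps:

```r
library(freecmr)

phantom  <- default_heart_phantom()        # 60 bpm, 0.22 Hz breathing
protocol <- cine_protocol(fov_mm = 160, matrix_size = 32, tr_ms = 5,
                          duration_s = 120, seed = 42)
raw    <- simulate_acquisition(phantom, protocol, n_coils = 4, snr = 20)
gating <- self_gate(raw)
gating
#> <gating_result> 119 peaks, HR 60.1 bpm, 113/118 RR accepted
#>   readouts: 20500 assigned / 1319 rejected (cardiac), 18% in respiratory window

compare_to_reference(gating, raw$trigger_times_ms)$n_matched
#> [1] 119     # of 120 simulated beats

labels <- array(0L, c(32, 32, 32, 30))
for (f in 1:30)
  labels[, , , f] <- make_cardiac_phantom(phantom, 32, (f - 0.5) / 30,
                                          160)$labels
biomarker_report(labels, 160 / 32, gating$heart_rate_bpm,
                 compute_areas = FALSE)
#> <biomarker_report> LVEF 59.4%  RVEF 60.0%  HR 60 bpm
#>   LV EDV/ESV 50.5/20.5 mL, CO 1.80 L/min, LVM 57 g

analytic_ef(phantom)                       # configured ground truth
#> [1] 59.5
```

The detected heart rate (60.1 bpm) matches the simulated 1 Hz rhythm,
119 of 120 beats are found (the last beat has no closing peak), and the
measured LVEF reproduces the phantom's configured 59.5% to rasterization
accuracy. The small volumes reflect the deliberately small desk-scale
phantom heart. On the tissue side:

```r
ti <- de_protocol()$ti_centers_ms          # 80, 90, ..., 340 ms
np <- detect_null_point(abs(ir_signal(ti, 250)), ti)
c(null = np$null_ti_ms, t1 = np$t1_ms)
#>     null       t1
#> 172.6    249.0    # analytic null: 250 * ln 2 = 173.3 ms
```

`run_pipeline()` (or the `inst/cli/freecmr` script) chains
simulate → gate → reconstruct → analyze → report and writes raw HDF5,
gating JSON, NIfTI volumes, the text/JSON summary and a checksum
manifest into an output directory.

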
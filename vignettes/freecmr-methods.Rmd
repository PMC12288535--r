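---
title: "Free-running cardiac MRI at desk scale: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-running cardiac MRI at desk scale: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freecmr)
```

`freecmr` implements a complete free-breathing, free-running cardiac MRI
(CMR) pipeline at desk scale: a dynamic digital heart phantom and
k-space simulator, self-gated motion extraction and binning,
motion-resolved compressed-sensing reconstruction with phase-sensitive
delayed-enhancement (DE) contrasts, and an automated whole-heart
biomarker, landmark and view-prescription engine. This vignette is the
package's account of the underlying science: the models it assumes, the
parameters that matter, and the choices made where the design was
genuinely open.

## The acquisition being emulated

The simulated exam has two acquisitions, both spoiled-gradient-echo,
Cartesian, with a fully sampled readout axis and Gaussian-random
sampling of the two phase-encode axes (`ky`, `kz`):

* **Cine**: 3D isotropic data acquired continuously (the published
  protocol runs 10 minutes at 1.6 mm / 307 mm FOV). A self-gating (SG)
  line through the k-space center is inserted after every 10th imaging
  line; cardiac and respiratory motion are recovered retrospectively
  from those SG lines, so no ECG or breath-holds are needed.
* **Delayed enhancement**: pulse-oximeter-triggered inversion recovery,
  900 heartbeats. Each beat: trigger, a 100 ms trigger delay, a
  non-selective inversion, then 400 ms of imaging lines whose inversion
  time (TI) is their time since the inversion; one SG line per
  heartbeat. Sorting lines into overlapping 80 ms TI windows centered
  80--340 ms (10 ms apart) yields 27 reconstructed TI contrasts.

`cine_protocol()` and `de_protocol()` encode these numbers;
`acq_protocol()` exposes every timing and geometry field. At desk scale
the same protocols are run with a 160 mm FOV and 32--64 voxel grids so
that the full pipeline executes in seconds to minutes on one CPU; the
test suite uses 32^3 grids, 60--120 s cine durations and 40--60
simulated heartbeats throughout.

## The digital phantom

`phantom_state()` describes an analytic thorax stand-in: ellipsoidal LV
blood pool, LV myocardium (an epicardial shell minus the instantaneous
cavity, open above a basal plane like a real ventricle), RV, LA, RA,
ascending aorta, and an optional scar patch confined to the lateral
wall. Two motion processes are modeled, chosen as the simplest physics
with the frequency structure the gating algorithm assumes:

* **Cardiac**: radial scaling of the chamber ellipsoids. Ventricles are
  largest at phase 0 (end-diastole) and scale by
  `1 - contraction_amplitude * (1 - cos(2*pi*phase)) / 2`; atria move in
  counter-phase, so atrial volume peaks at ventricular systole and the
  printed atrial-EF formula returns positive values. Because volume
  scales with the cube of the factor, the configured ejection fraction
  is `100 * (1 - (1 - contraction_amplitude)^3)` (`analytic_ef()`); the
  default amplitude 0.26 gives EF ~= 59.5%.
* **Respiratory**: rigid translation along the readout
  (superior-inferior) axis, amplitude `resp_amp_mm` (default 8 mm). The
  translation must project onto the readout because the SG line — the
  k-space center along `kx` — integrates over the phase-encode plane
  and is blind to in-plane shifts.

Chambers are tangent or slightly overlapping where valves sit; voxels
contested between structures go to the earlier-listed structure, which
keeps label maps disjoint while leaving the voxel-adjacent interfaces
the valve-plane detector needs. Gross overlap (more than 25% of a
structure) is a configuration error.

Two deliberate frequency choices deserve note. The default respiratory
rate is 0.22 Hz (~13 breaths/min), not a round 0.25 Hz: 0.25 Hz is
exactly commensurate with the 1 Hz default heart rate, and a rational
ratio phase-locks the mode-respiratory acceptance window to a fixed
subset of cardiac phases, leaving some cine frames systematically
empty — an artifact of perfectly periodic synthetic motion that real,
jittery physiology does not produce. Conversely, the phantom *keeps*
two realistic nuisance features: atrial counter-motion puts a secondary
bump inside each cardiac cycle of the navigator, and rigid respiratory
translation couples nonlinearly into the SG channels so that
respiratory *harmonics* (2x, 3x the breathing rate) appear above the
0.6 Hz classification boundary. Both shaped the gating design below.

What the generator does **not** emulate: realistic torso anatomy, B0/B1
inhomogeneity, flow and susceptibility effects, heart-rate variability,
bulk motion, and through-plane valve motion. Passing tests therefore
demonstrate algorithmic correctness under controlled motion and
relaxation physics, not robustness to every clinical confounder.

The k-space simulator (`simulate_acquisition()`) samples each line from
the phantom at its timestamp's motion state. Motion is quantized to
`n_card_states` x `n_resp_states` cached states (defaults 24 x 7) so
runtime scales with distinct states, not lines; for DE, linearity of
the Fourier transform lets each line be assembled from per-structure
FFTs weighted by the inversion-recovery signal at that line's TI. The
IR model is the standard perfect-inversion form
`M(TI) = M0 * (1 - 2 * eff * exp(-TI / T1))` with the efficiency `eff`
exposed (default 1); the signal nulls at `TI = T1 * log(2 * eff)`. All
randomness derives from `protocol$seed`: identical seeds give
bit-identical k-space. Noise is additive complex Gaussian calibrated so
`snr` is the mean phantom magnitude over the image-domain noise SD.

## Self-gating

`self_gate()` chains five steps, each exposed individually:

1. **`extract_sg_matrix()`** stacks the central 16 readout samples of
   every coil's SG lines, real and imaginary parts as separate
   channels, mean-removed. Optional per-coil weights let a heart ROI
   emphasize cardiac-proximal coils.
2. **`decompose_and_classify()`** resamples the channels to a uniform
   grid (linear interpolation at the median SG spacing), computes
   principal components, and classifies each by its spectral energy
   split at 0.6 Hz: dominantly (>= 60%) below is respiratory,
   dominantly above is cardiac; energy exactly at 0.6 Hz counts as
   respiratory. Among cardiac candidates the component with the most
   power *outside* narrow bands around the respiratory harmonics
   (k x f_resp +/- 6% of f_resp) is preferred, because the nonlinear
   respiratory coupling described above can push a harmonic component
   above 0.6 Hz with more variance than the true cardiac signal. When
   every candidate is harmonic (e.g. exactly commensurate rhythms) the
   plain highest-variance rule is used. A band with no dominant
   component raises an error naming the band — the analogue of a failed
   automated self-gating exam.
3. **`detect_peaks()`** applies a Savitzky-Golay filter (window 9,
   polyorder 3, both exposed) and finds maxima with a minimum
   separation of 0.6 x a naive RR estimate taken from the dominant
   spectral peak. The 0.6 factor (rather than a looser 0.4) is what
   rejects the atrial-counter-motion bump riding inside each beat;
   genuinely short arrhythmic intervals are then handled by the RR
   rejection rule rather than the peak picker. PCA sign is arbitrary,
   so both polarities are tried and the one with the lower RR
   coefficient of variation wins.
4. **`reject_arrhythmic()`** accepts interval *i* iff
   `|RR_i - mean(RR)| <= 2 * sd(RR)`, with mean and SD computed once
   over all intervals (single pass; the rule is not re-applied to the
   accepted subset).
5. **`assign_cardiac_bins()`** stretches each accepted peak-to-peak
   interval linearly onto 30 cardiac frames
   (`bin = floor(30 * (t - p_k) / (p_k+1 - p_k))`); readouts in
   rejected intervals or outside the peak span are flagged rejected.
   **`respiratory_mode_window()`** builds a 10-bin amplitude histogram
   of the respiratory navigator at the readout times and accepts
   readouts in the modal bin (typically end-expiration). Histogram bin
   count and retention (one modal bin) are package choices; a constant
   navigator accepts everything.

Heart rate is `60000 / mean(accepted RR)`. `compare_to_reference()`
pairs detected beats with reference triggers by nearest neighbor within
half the median reference RR.

## Reconstruction

`average_image()` grids all cine lines (averaging repeated cells),
inverse transforms, and combines coils by root-sum-of-squares; it feeds
`heart_roi()` (threshold + largest connected component, or ground-truth
labels) whose ROI/interference masks drive `rovir_basis()`: Gram
matrices of the coil signal over the ROI (A) and interference (B)
voxels, generalized eigenproblem `A w = lambda B w` solved by whitening
with `B^(-1/2)`, eigenvalues sorted descending, enough eigenvectors
kept for 95% of ROI energy (or an explicit count), weights
orthonormalized. A near-singular B receives a ridge
(`eps * trace(B)/N * I`) with a logged message.

`cs_reconstruct()` solves, slice by slice along the fully sampled
readout after a 1D inverse FFT,

  minimize 0.5 * || M F S x - y ||^2 + lambda * sum_t | x_(t+1) - x_t |

with `M` the per-frame ky-kz sampling mask, `F` the centered unitary 2D
FFT, `S` coil-sensitivity multiplication, and the temporal difference
cyclic over the frames (heartbeat periodicity for cine; for DE the
frame axis is the TI axis). Numerical choices: the TV is applied
anisotropically to real and imaginary parts; its proximal operator is
evaluated per voxel in the dual by projected gradient (step 1/4, 40
iterations); the outer loop is a Jacobi-preconditioned proximal
gradient (preconditioner `1 / sum_c |s_c|^2`, which solves the fully
sampled lambda = 0 case exactly in one step) with objective-based
backtracking, so the logged objective trace is non-increasing by
construction. `lambda_tv = NULL` defaults to 1% of the peak adjoint
image magnitude, per slice, and is exposed. Sensitivities default to
the ground-truth analytic maps; the FFT convention (forward = image to
k-space with negative exponent, DC at 0-based index `n %/% 2` after
shifting) is fixed package-wide.

`llr_denoise()` implements multi-scale locally-low-rank denoising:
non-overlapping cubic blocks per scale, block-by-frame Casorati
matrices, singular-value soft-thresholding, averaging across scales
(defaults: blocks of 4 and 8, threshold 0.05). It is a deliberate
simplification of full multi-scale low-rank decomposition: scales are
averaged rather than jointly decomposed.

For DE, `bin_de_by_ti()` applies respiratory acceptance and assigns
each line to *every* overlapping TI window containing its TI — with 80
ms windows spaced 10 ms apart this overlap is the only reading
consistent with both printed numbers. `detect_null_point()` finds the
per-voxel magnitude minimum over TI, refines it with 3-point parabolic
interpolation (ties toward the lower TI), flags boundary minima as
out-of-range, and converts `T1 = null / log(2 * eff)`. `make_psir()`
restores polarity (`-|m|` below the null, `+|m|` at or above it;
out-of-range voxels take their longest-TI trend sign) and normalizes
each TI volume to [-1, 1] — plain per-volume scaling, since no
surface-coil correction exists at desk scale. Respiratory handling for
DE is rejection-only; no translation correction is applied.

`resolve_resolution()` mirrors the physical resolution-phantom readout:
Fourier-upsampled line profiles through each 3x3 post grid, modulation
`(max - min) / (max + min)`, a grid resolved at modulation >= 0.5.
`acquire_static()` band-limits a finely rasterized phantom to the
acquisition resolution with a symmetric-inclusive band (the positive
Nyquist edge folded onto its negative partner), the discretization
under which a bar grid at exactly the acquisition pitch keeps its full
fundamental — matching the claim that features at the acquisition
resolution remain resolvable.

## Biomarkers, landmarks and views

`chamber_volumes()` is voxel count x voxel volume in mL per structure
per frame. `find_ed_es()` takes LVED = argmax and LVES = argmin of the
LV volume curve (ties to the lower frame). Ventricular EDV/ESV are read
at those frames for both ventricles; `EF = 100 (EDV - ESV)/EDV`,
`CO = (EDV - ESV) x HR / 1000`, `LVM` = myocardial volume at LVED x
1.05 g/mL (the standard myocardial density; a package choice). Atrial
EF uses exactly the printed formula on the LVES/LVED frames —
`100 (V_LVES - V_LVED)/V_LVES` — while max/min atrial volumes over all
30 frames are reported separately. CO is stroke volume x heart rate
because volumes are all the biomarker engine sees; no flow-derived
quantity exists in this pipeline.

`detect_landmarks()` derives valve planes from label adjacency: the
mitral plane is the least-squares plane through LV-blood voxels
6-adjacent to LA voxels (aortic: LV/aorta; tricuspid: RV/RA), and the
apex maximizes projection onto the direction from the mitral center
through the LV center of mass. `prescribe_views()`: the 4CH plane
passes through apex, mitral and tricuspid centers; the SAX stack is
normal to the long axis from the mitral plane to the apex at 8 mm
spacing (mirroring the clinical 2D protocol; the spacing is a package
choice); the 2CH plane contains the long axis and is orthogonal to the
4CH plane — the construction is not prescribed anywhere, and this
choice reproduces the usual clinical relationship between the two
long-axis views. Angular comparisons use the sign-invariant
`acos(|n1 . n2|)`. Atrial areas come from nearest-neighbor resampling
of the label map on a 1 mm in-plane 4CH grid;
`FAC = 100 (Amax - Amin)/Amax`.

`scar_percent()` offers label arithmetic
(`100 * scar / (scar + myocardium)`) and a mean + 5 SD threshold over a
remote-myocardium region on PSIR intensities — a deliberately simple
stand-in for full expectation-maximization scar segmentation, adequate
at phantom contrast-to-noise. `icc_fixed_raters()` is the two-way
mixed, single-measure, consistency ICC ((MS_rows - MS_err)/(MS_rows +
MS_err) for two raters), insensitive to a fixed rater offset;
`bland_altman()` reports bias +/- 1.96 sample SD. `generate_summary()`
tabulates every metric with units, reference range and LOW/NORMAL/HIGH
flag in a fixed order; the shipped YAML range table contains generic
adult placeholders meant to be edited, not clinical claims.

## The pipeline and its interfaces

`run_pipeline()` chains simulate, gate, reconstruct, analyze and report
and writes every intermediate: raw k-space as HDF5 (paired real/imag
datasets, per-line timestamps, type flags, encode indices, TI, and a
JSON header), gating as JSON, volumes as NIfTI-1 (complex data as
real/imag pairs so round trips are bit-exact), the report as JSON +
fixed-layout text, and a manifest of MD5 checksums. Configuration is
YAML with unknown keys rejected by path and a mandatory explicit seed;
identical configuration gives byte-identical JSON outputs. Ground-truth
label maps rasterized at the 30 frame centers stand in for the
segmentation-network interface, which is outside this package's scope.
A thin command-line wrapper (`inst/cli/freecmr`) exposes
`simulate`, `gate`, `analyze` and `run` subcommands.

## Known limitations

* Perfectly periodic motion makes commensurate cardiac/respiratory
  rates a degenerate corner (empty cine frames, ambiguous harmonic
  classification); the defaults avoid it and the classifier degrades
  gracefully, but strongly locked rhythms remain ambiguous in
  principle.
* TI bins average the IR signal across an 80 ms window, biasing
  recovered T1 by a few ms at short T1 — visible as ~1--2% error in
  end-to-end tests versus ~0.4% for the pure analytic curve.
* The threshold scar mode needs a user-supplied remote region and high
  contrast-to-noise; it is not an EM-based scar algorithm.
* DE respiratory handling is rejection-only; cine reconstruction keeps
  a single (mode) respiratory state rather than resolving several.
* Reconstruction quality at high acceleration depends on `lambda_tv`;
  the 1%-of-adjoint default is a reasonable origin, not an optimum.
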
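---
title: "Joint shot-group reconstruction for 3D multi-shot EPI: model, simulator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint shot-group reconstruction for 3D multi-shot EPI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segcaipi)
```

## The problem

3D multi-shot EPI acquires one kx–ky plane per excitation ("shot") and
encodes kz across shots, so a whole image volume is assembled from data
spread over seconds. At 7T, respiration modulates B0 and hence the image
phase on a ~4 s cycle; shots acquired in different respiratory states are
mutually inconsistent, and combining them in k-space produces ghosting
along kz and, across a time series, a loss of temporal SNR (tSNR =
voxelwise temporal mean / temporal standard deviation). This is exactly the
regime where 3D EPI should beat 2D simultaneous-multi-slice imaging on
thermal-noise grounds but often does not, because physiological noise
dominates.

This package implements a navigator-free answer with two coupled parts:

1. **seg-CAIPI sampling** — a ky–kz shot schedule with *interleaved*
   ordering along kz. `width` is the kz offset between consecutive shots
   with identical trajectories (also the kz span of one shot); an
   interleave of `Nz/width` consecutive shots forms a *shot group* whose
   own sampling pattern is a near-uniform `Ry × width` CAIPI lattice. The
   number of groups is `width/Rz`. The blip size `dkz` may exceed `Rz`
   thanks to the wider per-shot band. The combined mask is identical to the
   standard blipped-CAIPI mask with blip `dkz mod Rz`, so nothing is lost
   relative to a conventional acquisition.
2. **Joint low-rank reconstruction** — instead of one shot-combined image,
   one image *per shot group* is reconstructed jointly, assuming all groups
   share a magnitude and differ only by a smooth phase. Group images are
   then sum-of-squares combined, which is immune to phase cancellation.

## The model

Let `X` be the stack of per-shot-group (virtual single-coil) k-space
planes, `Y` the measured multi-coil per-group k-space, `S` the coil
sensitivities, `F` the centered unitary 2D Fourier transform, `M` the
per-group sampling masks, and `E = M·F·S·F⁻¹` the SENSE forward operator.
The reconstruction solves

$$\hat X = \arg\min_X \tfrac12\lVert EX - Y\rVert_2^2
          + \lambda \lVert \mathcal H X\rVert_*$$

where `ℋ` lifts `X` to a block-Hankel matrix: a `k1 × k2` sliding window
(valid positions only, no wrap-around) walks over each group's plane, each
window is vectorized into a row, and the `G` group blocks are concatenated
side by side. Smooth inter-group phase differences make the blocks nearly
linearly dependent, so the lifted matrix is rank-deficient and the nuclear
norm `‖·‖*` is an effective convex surrogate.

ADMM on the split `Z = ℋX` alternates:

* **X-update**: conjugate gradients on
  `(EᴴE + ρ ℋᴴℋ) X = EᴴY + ρ ℋᴴ(Z − U)`. `ℋᴴℋ` is diagonal — the
  patch-coverage counts, `k1·k2` in the grid interior — so the Hankel term
  is free inside CG.
* **Z-update**: singular-value thresholding of `ℋX + U`. Hard thresholding
  (keep `σᵢ ≥ τ·σ₁`) is the default, which trades a little output tSNR for
  markedly better image quality in low-SNR regimes; soft thresholding
  (`σᵢ ← max(σᵢ − λ/ρ, 0)`), the exact proximal operator of the nuclear
  norm, is available via `threshold_mode = "soft"`.
* **U-update**: `U ← U + ℋX − Z`.

Each volume of a time series is reconstructed independently
(`reconstruct_timeseries()`), preserving the full temporal degrees of
freedom; results are bit-identical under any reordering of input volumes.

### On the rank-deficiency premise

For a 2-group lift of a 48×48 phantom with a smooth second-order-harmonic
inter-group phase, a single 6×6 Hankel block already has ≈ `k1·k2 = 36`
significant singular values — that is the complexity of the image itself.
What the smooth-phase premise buys is that appending the *second* group
block adds almost no rank: the spectrum collapses immediately after index
36 (`σ₃₇/σ₁ < 0.05` on the packaged phantom, with an incoherent-control
counter-check in the test suite). Formulations that expect the collapse at
a small fixed index (e.g. index 7) hold only for images that are sums of a
handful of point sources, not for structured phantoms or brains.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `lam` | 3e-3 | nuclear-norm weight after data normalization; the simulation operating point (in-vivo regimes used 3e-4–6e-4) |
| `rho` | `1/(k1·k2)` | ADMM penalty; see below |
| `admm_iters` | 10 | fixed outer iteration count |
| `cg_iters` | 10 | inner CG iterations, warm-started |
| `threshold_param` | 0.05 | hard-threshold cut relative to σ₁ |
| `kernel_ky`, `kernel_kz` | 6, 6 | Hankel window size |
| `normalize` | TRUE | divide `Y` by the 99th-percentile magnitude of the initialization image |

**Why `rho = 1/(k1·k2)` and not 1.** With unitary transforms and
RSS-normalized coil maps, `‖EᴴE‖ ≤ 1`, while `ℋᴴℋ` has diagonal entries up
to `k1·k2 = 36`. With `ρ = 1` the X-update is consensus-dominated and the
data term propagates too slowly for a fixed budget of 10 iterations;
dividing by the interior coverage balances the two quadratic terms. This
was chosen from objective/data-residual traces on the noiseless
phase-recovery fixture; `rho` remains a config field.

**Normalization rule.** "Normalize the data before reconstruction" is
realized as division by the 99th-percentile magnitude of the shot-combined,
coil-combined initialization image (robust to hot pixels, invariant to
coil scaling). The exact percentile is this package's choice.

**Initialization.** `X₀` is the shot-combined (exact superposition —
per-group masks are disjoint), coil-combined single-coil k-space replicated
into every group slot; `Z₀ = ℋX₀`, `U₀ = 0`.

**λ = 0.** The solver skips the Z/U updates entirely and reduces to plain
CG-SENSE per shot group — useful as a baseline and exercised by the
exact-recovery tests.

**Combined image.** `sqrt(mean_g |image_g|²)` — the sum-of-squares combine
scaled by `1/√G` so it estimates the common magnitude (and equals the
phantom exactly in the noiseless fully-sampled limit).

## The simulator's stated world

`simulate_timeseries()` emulates the published simulation design on one
ky–kz plane:

* **Ground truth**: a hard-edged ellipse phantom (canonical head-phantom
  style; magnitude ≤ 1, support strictly inside the grid, optional
  low-order baseline phase). Hard edges keep the thresholded support mask
  identical to the analytic ellipse support; optional k-space Gaussian
  apodization is available via `smooth`.
* **Coil maps**: Gaussian lobes on a ring outside the object with mild
  linear phase ramps, RSS-normalized to 1 — so noise propagates with unit
  gain through coil combination.
* **Phase fluctuations**: `φ(u,v,t) = trace(t)·Σ aₖBₖ(u,v)` on the 6 real
  second-order 2D harmonic/polynomial maps
  `{1, u, v, uv, u²−v², u²+v²}` over `[−1,1)²` (the published fits used a
  second-order spherical-harmonic basis over a 2D sagittal slice; real
  polynomial harmonics are the 2D analogue). The trace is a 0.25 Hz
  respiratory sinusoid plus slow drift and optional deterministic jitter.
  Default amplitudes give ≈ 1.4 rad peak-to-peak at the object edge —
  plausible for 7T respiration; the magnitude is a free knob, not a
  literature value. Time advances continuously across volumes
  (`t = global shot index × shot_TR`, default 55 ms), never re-zeroed, so
  inter-volume fluctuation statistics are realistic.
* **Phase sampling**: `per_shot` (default) evaluates the phase at every
  shot's own timestamp; `per_group` evaluates it once per shot group at
  the group's mean shot time. The phase-recovery fixture uses `per_group` —
  "distinct smooth group phases" is exactly the reconstruction's model —
  while the tSNR study uses `per_shot`, so intra-group incoherence is
  present there as it would be in vivo.
* **Noise**: i.i.d. complex Gaussian on acquired samples only, with `sd`
  the complex-sample standard deviation. `snr_calibrate()` is closed-form
  (`sd = mean|phantom|_support / target`) because the unitary transforms
  and unit-RSS maps give unit noise gain; the published operating points
  97/65/43 are the defaults of the study. The paired reference series uses
  a zero-amplitude phase model and the *same* noise stream (same seed), so
  corrupted and reference series differ by phase modulation alone.

**What a green test does not establish.** The simulator has no cardiac
pulsation, no motion, no T2* decay along the EPI train, no slice profile,
no trajectory errors, and its coil maps are exact (no calibration error).
Orderings and recovery tolerances demonstrated here say nothing about
absolute in-vivo tSNR values, which depend on scanner hardware and
physiology; the in-vivo numbers in the source work require 7T data that is
not reproducible at desk scale.

## Sampling-generator conventions

* Indices are 0-based; the first sampled ky line is 0 (configurable via
  `ky_offset`).
* Intra-shot blips follow `kz = origin + ((n·dkz) mod width)` for line
  `n` — the wrap-within-band rule, the single place to change if a
  different blip/rewind convention is needed.
* kz indices are taken modulo `Nz`: bands of edge shots wrap circularly.
  This is required for the seg-CAIPI/standard combined-mask identity and
  is verified against every protocol-table pairing.
* `Nz` must be divisible by `Rz` and `width` (hard errors); `Ny` need not
  be divisible by `Ry` — shots acquire `ceiling(Ny/Ry)` lines, as real
  protocols (e.g. a 140-point ky grid at `Ry = 3`) require.
* Acquisition timestamps are interleave-major (all shots of interleave 0
  first), making each shot group a set of consecutively acquired shots.
* `suggest_dkz()` implements the "minimize the largest gap to the nearest
  sample" rule by brute force over `dkz ∈ [1, width)` on the group
  lattice; it is advisory only, and the distance metric (torus distance
  with ky scaled by `width/Ry`) is a documented package choice.

## Numerical choices

* Centered unitary FFTs throughout; on even grids the centering is a
  checkerboard sign modulation (algebraically identical, cheaper).
* CG tolerance 1e-6 relative residual; divergence (residual growth over 5
  consecutive iterations) is a hard error with diagnostics, as is any NaN.
* SVDs are dense LAPACK on the lifted matrix (≈ 1800 × 100 at the target
  sizes); no randomized SVD is needed.
* Coil-combination denominator floored at `1e-12·max|S|²`; voxels with
  vanishing coil support map to 0.
* All generators are deterministic under fixed seeds, and seeded helpers
  restore the caller's RNG state.

## Known limitations

* Only the 2D ky–kz plane problem is implemented; a 3D readout axis is
  handled by looping the decoupled planes after an inverse transform along
  the fully sampled readout axis (the standard decomposition, since
  shot-to-shot inconsistencies do not occur along the readout); that loop
  is the caller's responsibility in the real-data path.
* HDF5/NIfTI external formats are not supported in this build (no suitable
  R packages in the target environment); schedules serialize to JSON and
  the CLI scripts write TSV/CSV.
* The hard-threshold level of the reference implementation is unpublished;
  the relative-to-σ₁ default (0.05) is this package's choice, as is the
  within-ADMM constancy of the threshold.
* Partial-Fourier / virtual-conjugate-shot lifting, motion modeling, and
  multi-volume joint reconstruction are out of scope.
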
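# segcaipi

Segmented CAIPI sampling and Hankel-structured low-rank reconstruction for
3D multi-shot EPI fMRI.

## What problem this solves

3D multi-shot EPI offers an SNR advantage over 2D multi-slice imaging for
high-resolution fMRI, but each image volume is assembled from shots spread
over seconds of acquisition. Respiration-induced B0/phase modulations make
those shots mutually inconsistent, producing kz ghosting and a large loss
of temporal SNR (tSNR) at 7T. This package is for MRI physicists and
reconstruction researchers who want a navigator-free, desk-scale
implementation of the two-part remedy:

* **seg-CAIPI sampling** (`trajectory_config()`, `build_schedule()`):
  interleaved kz ordering combined with CAIPI blips, described by
  `(width, Δkz)`. Shots of one interleave form a *shot group* whose own
  sampling is a near-uniform `Ry × width` lattice; there are `width/Rz`
  groups and the combined mask is exactly the standard blipped-CAIPI mask.
* **Joint shot-group reconstruction** (`admm_solve()`,
  `reconstruct_timeseries()`): one k-space `X_g` per shot group is
  recovered jointly by solving

  ```
  argmin_X  1/2 ||E X - Y||^2 + lambda ||H X||_*
  ```

  with `E = M·F·S·F⁻¹` the SENSE operator and `H` the block-Hankel lifting
  whose low rank encodes "all groups share a magnitude and differ by a
  smooth phase". ADMM alternates a CG data-consistency update, singular-
  value (hard, by default) thresholding, and a dual update; group images
  are sum-of-squares combined. Volumes are reconstructed independently, so
  the temporal degrees of freedom of an fMRI series are untouched.

A full simulation framework (`make_phantom()`, `make_coil_maps()`,
`phase_model()`, `simulate_timeseries()`, `snr_calibrate()`) and evaluation
metrics (`tsnr_map()`, `mean_tsnr()`, `mean_power_spectrum()`) reproduce
the structure of the published validation study. See the vignette
(`vignettes/seg-caipi-reconstruction.Rmd`) for the model, assumptions, and
every numerical choice.

## Worked example

Simulate a 12-volume, 48×48, 8-coil series with respiratory phase
fluctuations at mean SNR 65, then compare reconstructions:

```r
library(segcaipi)

ph    <- make_phantom(48, 48)
maps  <- make_coil_maps(8, c(48, 48), seed = 2)
sched <- build_schedule(trajectory_config(48, 48, Ry = 1, Rz = 1,
                                          scheme = "seg_caipi",
                                          width = 2, dkz = 1))
noise <- snr_calibrate(65, ph, seed = 1)
sim   <- simulate_timeseries(ph, maps, sched, phase_model(), noise, 12)
ref   <- simulate_timeseries(ph, maps, sched, phase_model(), noise, 12,
                             reference = TRUE)

conv <- reconstruct_timeseries(sim, maps, method = "sense")
prop <- reconstruct_timeseries(sim, maps, recon_config(), "proposed")
upper <- reconstruct_timeseries(ref, maps, method = "sense")

supp <- support_mask(Mod(ph))
round(c(reference    = mean_tsnr(tsnr_map(upper), supp),
        conventional = mean_tsnr(tsnr_map(conv),  supp),
        proposed     = mean_tsnr(tsnr_map(prop),  supp)), 2)
#>    reference conventional     proposed
#>        98.05        76.07        86.87
```

The reference series (same thermal noise, no phase corruption) bounds what
any reconstruction can achieve; the conventional shot-combined SENSE recon
loses ~22 tSNR units to physiological phase inconsistency, and the joint
low-rank reconstruction recovers roughly half of that loss on this short
series — on the 40-volume study of the acceptance suite the ordering
`reference > proposed > conventional` holds at every noise level
(SNR 97/65/43) and seed, with the gap shrinking as thermal noise grows.
The same study is scripted in `inst/cli/simulate_recon.R`:

```sh
Rscript inst/cli/simulate_recon.R --snr 65 --volumes 40 --seed 1 --out study
```

Shot schedules for published protocols come straight from the generator:

```r
build_schedule(trajectory_config(116, 96, Ry = 2, Rz = 2,
                                 scheme = "seg_caipi", width = 8, dkz = 3))
#> <trajectory_config> seg-CAIPI(8,3)  grid 116x96  R=2x2  4 interleave(s)
#>   48 shots, 4 shot group(s), 12 shots/group, 58 lines/shot
```

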
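# bispeckle

Single-shot imaging through thin scattering media by truncated-bispectrum
phase retrieval, in R.

When a small incoherent object is viewed through a thin diffuser, the camera
records a seemingly random speckle pattern. Within the optical memory effect
the system is shift-invariant, so the frame is a convolution `I = O ⊗ S` of
the object `O` with a speckle point-spread function `S`. Classical speckle
autocorrelation imaging recovers the object's Fourier **amplitude** from a
single frame — `I ⋆ I = O ⋆ O + C` and, by the Wiener–Khinchin theorem,
`|FT(O)|² = FT(I ⋆ I) − C` — but the Fourier **phase** must then come from an
iterative Fienup-type algorithm whose random initialization leaves the
result's position and orientation undetermined.

`bispeckle` implements the deterministic alternative: the phase is read off
the **bispectrum** (triple-correlation spectrum)

```
B(f1, f2) = X(f1) X(f2) X*(f1 + f2)
```

whose phase obeys the closure relation
`φ_B(f1,f2) = φ(f1) + φ(f2) − φ(f1+f2)` and is blind to translation and to
the (real) speckle transfer term. The single camera frame is cropped into
sub-speckle tiles — a spatial ensemble replacing the multi-frame temporal
averages of astronomical speckle interferometry — each tile is
Gaussian-apodized and Radon-projected onto 1D signals at 18 equally spaced
angles, and the tile-averaged 1D bispectra yield each angle's radial phase by
recursion from the seeds `φ(0) = φ(1) = 0`. Because only the low-frequency
box `f ≤ (1−C)·M` of each bispectrum is retained (**truncation factor** `C`;
at `C = 0.7` more than 80 % of the elements are discarded), the quartic cost
of bispectrum analysis collapses while the reconstruction survives. The
projection-slice theorem places the per-angle phases on Fourier-domain rays;
phasor interpolation fills the Cartesian grid; and the inverse transform of
`amplitude · exp(i·phase)` is the object.

The package contains the full chain plus everything needed to exercise it:

* `speckle_sim` — Fourier-optics forward model (random phase screen ×
  circular aperture → speckle PSF), glyph objects, memory-effect FOV
  (`Δx = uλ/πl`) and diffraction-limit (`δ = 1.22 λ d / D`) calculators;
* `autocorrelate()` / `window_autocorrelation()` / `fourier_amplitude()` —
  the Wiener–Khinchin amplitude route;
* `crop_subspeckles()` / `apodize()` / `radon_project()` — the sub-speckle
  sinogram front-end;
* `truncation_scheme()` / `truncated_bispectrum()` / `speckle_bispectrum()` /
  `recover_phase_recursive()` — the truncated bispectrum engine with
  phase-closure recursion;
* `assemble_phase_2d()` + `combine_and_invert()` — 2D phase assembly and the
  final reconstruction;
* `fienup_retrieve()` — an ER/HIO baseline for comparison;
* `snr_db()`, `ncc_aligned()`, `sweep_truncation()` — quality metrics and
  the truncation-factor sweep;
* a CLI (`inst/cli/bispeckle.R`) with `simulate`, `reconstruct` and `sweep`
  commands.

## Worked example

```r
library(bispeckle)

cfg <- preset_config("fast", seed = 1)   # 512x512 sensor, 632.8 nm
sim <- simulate_speckle(cfg)             # glyph '5' behind a random screen
print(sim$frame)
#> <speckle_frame> 512 x 512, simulated, mean 0.001347

rep <- reconstruct_bispectrum(sim$frame, K = 128, stride = 16, C = 0.7,
                              reference = sim$object)
print(rep)
#> <recon_report> method bispectrum, 129 x 129 image, C = 0.70
#>   (91.0% data reduction, 625 tiles), SNR 3.17 dB, NCC 0.720

print(truncation_scheme(0.7, 256))
#> <truncation_scheme> C = 0.70, M = 256, f_max = 76:
#>   retain 5929 of 65536 elements (91.0% reduction)
```

The report says: from one 512×512 speckle frame, 625 overlapping 128×128
sub-speckles were projected at 18 angles; at truncation factor 0.7 only
5 929 of the 65 536 bispectrum elements per angle (9 %) were computed; the
reconstruction matches the hidden glyph with normalized cross-correlation
0.72 and is deterministic — rerunning the call reproduces it bit for bit,
with the correct (un-flipped) orientation. `plot(rep)` displays the image.

From a shell, the same run is

```sh
Rscript inst/cli/bispeckle.R reconstruct --preset fast --seed 1 --C 0.7 --out out/
```

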
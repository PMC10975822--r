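---
title: "Single-shot speckle imaging with truncated bispectra: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-shot speckle imaging with truncated bispectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bispeckle)
```

## The imaging model

An incoherent, narrow-band source illuminates a small object a distance $u$
in front of a thin diffuser; a camera a distance $d$ behind the diffuser
records the scattered intensity. Within the optical memory effect the system
is shift-invariant, so the frame is a convolution of the object with a
speckle point-spread function,

$$ I = O \otimes S. $$

Two classical facts make the object recoverable from one frame:

1. **Amplitude.** $I \star I = (O \star O) \otimes (S \star S)$, and the PSF
   autocorrelation $S \star S$ is sharply peaked, so
   $I \star I \approx O \star O + C$ with a background pedestal $C$. By the
   Wiener–Khinchin theorem the windowed autocorrelation gives
   $|\widehat O|^2$.
2. **Phase.** The bispectrum
   $B(f_1,f_2) = \widehat I(f_1)\,\widehat I(f_2)\,\widehat I^*(f_1{+}f_2)$
   averaged over an ensemble of speckle realizations factors into the object
   bispectrum times a *real* transfer term, so its phase obeys the closure
   relation $\varphi_B = \varphi(f_1) + \varphi(f_2) - \varphi(f_1{+}f_2)$,
   from which $\varphi$ follows recursively — with no random initialization,
   hence a deterministic position/orientation, unlike ER/HIO phase
   retrieval.

A single frame supplies the ensemble spatially: the frame is cropped into
$N$ sub-speckle tiles whose bispectra are averaged. Because a 2D bispectrum
is 4D data ($P^4$ elements for a $P\times P$ image; `full_bispectrum_count(256)`
is about $4\times10^9$), each tile is first Radon-projected onto 1D signals
at 18 equally spaced angles in $[0^\circ, 180^\circ)$, and each 1D
bispectrum is **truncated** to the index box
$f \le (1-C)\,M$ with truncation factor $C\in[0,1)$. The per-angle radial
phases are placed on Fourier-domain rays (projection-slice theorem),
interpolated to the Cartesian grid of the recovered amplitude, and
$\mathrm{amplitude}\cdot e^{i\,\mathrm{phase}}$ is inverse-transformed.

## The synthetic forward model

`make_incoherent_psf()` uses the single-FFT Fourier-optics model: the PSF is
the squared modulus of the FT of a circular aperture times the unit-modulus
phasor of a uniform i.i.d. random phase screen. This is the idealized
fully-developed-speckle limit of a thin diffuser. `render_speckle()`
convolves circularly, which makes memory-effect shift invariance *exact* and
keeps the Wiener–Khinchin algebra free of boundary terms; objects are small
and centered so wrap-around is negligible. Optional Poisson shot noise with
a fixed expected photon budget is the only noise source.

What the simulator does **not** emulate: finite memory-effect range (shift
invariance never decays), finite spectral bandwidth, detector read noise,
and — importantly — the near-field "lens-like" character of real ground
glass, whose sub-regions act as random lenslets and partially self-image the
object. Simulated tiles are therefore *harder* for bispectrum statistics
than bench tiles: projections of idealized far-field speckle are close to
Gaussian, and a Gaussian process carries a vanishing mean bispectrum. A
passing test suite here demonstrates the estimators' correctness and the
pipeline's determinism, not that every physical diffuser will reach the same
quality at the same ensemble size (see *Limitations*).

### Presets

* `fig1`: 632.8 nm, 2048×2048 sensor, 2.4 µm pitch, 2.5 mm iris — the
  reference simulation geometry, speckle grain ≈ 2 px.
* `fast`: 512×512 sensor, 0.15 mm iris, everything else shared. The iris is
  chosen so the speckle grain spans ~8 px. Rationale: the ensemble
  signal-to-noise of the averaged bispectrum scales like $\sqrt{N/n}$ in the
  total grain count $N$ and the grains per tile $n$; at 1/16 the reference
  frame area, keeping $n$ low (~$16^2$ per tile) preserves that ratio, while
  the ~8 px diffraction limit stays a factor 4 below the default 32 px
  object support (`support = min(sensor)/16`).

## Estimator choices that matter

**Tile apodization order.** `apodize()` removes each tile's mean *before*
multiplying by the centered Gaussian (σ = `sigma_fraction`·K, default
0.125·K), then re-centers. Windowing the raw nonnegative tile instead leaves
a deterministic term — the local mean times (Gaussian − its mean) — that is
identical across tiles; its bispectrum has phases locked to 0 or π and does
not average away, biasing exactly the low closure frequencies the recursion
is seeded from. Removing the pedestal first eliminates that term.

**Radon operator.** A pixel-driven operator splats each pixel's mass
linearly between the two nearest ρ-bins (assembled once per geometry as a
sparse matrix). Mass is conserved exactly at every angle, the 0° projection
equals column sums exactly, and with `M = K` the slice identity against the
2D FFT is exact at the axis angles. `M` defaults to the next power of two
above $K\sqrt2$ so all angles share one bispectrum geometry.

**Closure recursion.** `recover_phase_recursive()` seeds
$\varphi(0)=\varphi(1)=0$ (structure, not position, is wanted) and estimates
each $\varphi(f)$ as the argument of a *phasor* sum over retained pairs
$f_1+f_2=f$, $1\le f_1\le f_2$ — wrap-safe, unlike averaging raw angles. By
default each pair is weighted by $|B(f_1,f_2)|$: under speckle noise the
closure elements are strongly heteroskedastic, and on clean signals the
weights cancel exactly (the unweighted estimator is available as
`weights = "none"`). Phases beyond
$f_\mathrm{reach} = \min(2 f_{\max}, M/2)$ are set to zero rather than
extrapolated; the windowed amplitude is negligible there.

**Ray gauge alignment.** Fixing $\varphi(1)=0$ per angle re-centers each
projection independently; with noisy data the implied centerings disagree
across angles and misregister the Fourier rays. `align_ray_gauges()`
removes each ray's amplitude-weighted best-fit linear ramp (estimated from
phase increments in phasor space). This is the centroid gauge: a
projection's centroid at angle θ is the object centroid projected onto θ,
so zeroing every ray's ramp is consistent with one global shift. It is part
of the default pipeline (`gauge_align = TRUE`).

**Phase assembly.** Rays at θ and θ+180° share one line through conjugate
symmetry; Cartesian points take inverse-distance phasor-interpolated values
from the two nearest rays and radii — interpolating $e^{i\varphi}$, never
raw radians. Hermitian antisymmetry $\varphi(-k) = -\varphi(k)$ is enforced
exactly by constructing the upper half-plane and mirroring; DC is 0.

**Amplitude route.** `autocorrelate()` subtracts the frame mean before
transforming — the background constant of the autocorrelation identity has
no separate estimator, and mean removal deletes its DC pedestal — and
residual negative power-spectrum values are clamped before the square root
(their fraction is reported as a diagnostic). The default window taper is a
radial Tukey (flat center, cosine edge, α = 0.3): it leaves the central
object autocorrelation untouched while suppressing the noisy rim;
Gaussian/Hann/rectangular are available. The window is odd-sized
(2·`half_width`+1) so DC is an exact grid point.

**Sub-speckle stride.** `crop_subspeckles()` defaults to non-overlapping
tiles (`stride = K`). The pipeline preset uses `stride = 16` on the fast
geometry: with windows of σ ≈ 16 px the effective support of each apodized
tile is much smaller than K, so densely strided tiles are nearly independent
ensemble members, and the $\sqrt N$ averaging gain is what the spatial
ensemble exists for.

**Fienup baseline.** HIO (β = 0.9, 200 iterations) then ER (50), best of
`n_restarts` by relative Fourier residual, loose centered-box support of
half the grid, nonnegativity. These are the classic defaults; the baseline
exists to exhibit the translation/flip ambiguity that the bispectrum path
removes.

## Numerical conventions

Centered grids put the origin at index `floor(n/2)+1`; `ft2c()`/`ift2c()`
wrap `fft()` with the corresponding shifts. Frequency indexing is 0-based on
the length-M periodic DFT grid; $-f_1-f_2$ is handled as the conjugate at
$f_1+f_2$ (mod M). The assembly grid radius is converted to 1D frequency
units by $M/W$ for a window of side $W$. Degenerate tiles (windowed energy
below $10^{-6}$ of the median) are dropped with a warning; a zero-magnitude
phasor sum in the recursion yields phase 0 with a warning rather than an
error. The bispectrum path contains no randomness: identical inputs give
bit-identical reconstructions.

## Problem sizes

The default test and acceptance runs use the fast preset (512² frames,
128² tiles, 18 angles, window 129², M = 256, 625 tiles at stride 16); one
reconstruction takes a few seconds, a 10-point truncation sweep under a
minute, and the whole acceptance script about a minute on one CPU. The
`fig1` geometry (2048²) runs in tens of seconds per frame and is exercised
once in the test suite.

## Limitations

* **Ensemble size at desk scale.** A 512² frame holds a 16× smaller tile
  ensemble than the reference 3072×2048 bench frame. Under the idealized
  far-field phase-screen PSF the projected sub-speckles are near-Gaussian,
  so closure phases converge slowly; at this scale the end-to-end NCC
  against the hidden glyph levels off just below ~0.7 (the acceptance
  script reports the measured values), with the single-frame amplitude
  estimate and 18-ray phase interpolation contributing comparable error.
  Real diffusers, whose tiles carry partially self-imaged structure, are
  statistically more favorable than this synthetic worst case.
* **Truncation sweep shape.** The reconstruction quality is flat in the
  truncation factor up to C = 0.7 (the sweep's plateau). A sharp collapse
  at C = 0.9 additionally requires the informative band — bounded by the
  aperture MTF — to extend beyond the truncated reach 0.2·W; with ~8 px
  grains the band is narrower than that, so the sweep stays flat through
  C = 0.9 at this preset. Collapse appears only with finer grains, which in
  turn lower the closure SNR: the two effects trade off through the same
  iris diameter.
* The SNR-in-dB score (peak-normalized, shift-aligned residual energy) is
  this package's own formula; absolute dB values are not comparable across
  different definitions, only the shape of trends is.
* No thick-medium or multiple-scattering model, no partial coherence, no
  iterative refinement of the assembled phase against the measured
  amplitude.
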
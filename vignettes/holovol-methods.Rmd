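---
title: "Methods: 3D holographic reconstruction by volumetric deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D holographic reconstruction by volumetric deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holovol)
```

## The imaging problem

A lens-free digital in-line holographic microscope (DIHM) records, on a bare
CMOS sensor, the interference between a quasi-planar illumination wave and
the light scattered by a thin sample placed a few hundred micrometres above
the sensor. Because source and sensor are far apart (80 mm here) and sample
and sensor are close, the geometry is Gabor's: unit magnification, and a
field of view equal to the whole sensor area — 29.85 mm² for a
3872 × 2764-pixel, 1.67 µm-pitch device. The price of this simplicity is
threefold:

1. **Undersampling.** The detector pitch (1.67 µm) limits resolution.
2. **Phase loss.** Only intensity is recorded; reconstructing a single
   hologram overlays every object with its defocused conjugate — the *twin
   image*.
3. **Out-of-focus haze.** A z-stack of back-propagated planes spreads each
   object's diffraction pattern over the whole stack, obscuring 3D
   structure.

`holovol` implements the corresponding three-stage remedy: pixel
super-resolution (PSR) from sub-pixel-shifted frames, multi-height
iterative phase recovery, and 3D volumetric deconvolution of the
back-propagation stack against a simulated point-spread-function (PSF)
volume.

## Wave propagation

All stages share one physics kernel, angular-spectrum free-space
propagation: the field's 2D FFT is multiplied by

$$H(f_x, f_y; z) = \exp\!\Big(i 2 \pi z \sqrt{1/\lambda^2 - f_x^2 - f_y^2}\Big),
\qquad f_x^2 + f_y^2 \le 1/\lambda^2,$$

and zero beyond the cutoff. The hard evanescent cutoff is essential for
back-propagation (negative $z$), where evanescent components would grow
exponentially. On the propagating band $|H| = 1$, so propagation is unitary
— the test suite asserts energy conservation, invertibility and the group
property $P_{z_1+z_2} = P_{z_2} P_{z_1}$ at $10^{-10}$ relative tolerance.
Frequencies are sampled on the unpadded FFT grid by default; `propagate()`
accepts a zero-padding factor to trade wraparound suppression against 4×
computation. Lengths are micrometres everywhere inside the package.

The magnification is fixed at one (plane-wave illumination); the
source-to-sample distance is retained in `optical_config()` as metadata
only.

## Pixel super-resolution

The stage shifts the sample over a $k \times k$ grid with spacing
$p/k$ ($p$ = 1.67 µm, $k$ = 6, so 0.278 µm and 36 frames per height).
Because the shifts are known from the stage, no registration is performed:
`synthesize_highres()` splats each coarse frame onto the $k$-times-finer
grid at its shift offset (bilinear splatting of sub-node residuals),
normalizes by per-pixel coverage, and optionally removes the detector
pixel-aperture blur. For a full grid the splat output equals the true
fine-pitch image cross-correlated with the $k \times k$ box kernel
*exactly*, which is how it is tested.

The aperture deblur divides by the box OTF with a Wiener regularizer
(default $10^{-3}$). The box OTF has nulls starting at $1/(k p_{hi})$
cycles/µm; content beyond the first null cannot be restored by any
regularized inverse, so the deblur contract (5% relative error) is stated
for images band-limited below that null. Intensity, not amplitude, is
super-resolved; the square root is taken at the start of phase recovery.

## Autofocus and the sharpness metric

Reconstruction distances are refined by maximizing a Sobel sharpness score
with a golden-section search. The score is the *root-mean-square* Sobel
gradient magnitude over the image interior. The quadratic mean matters: the
arithmetic mean of $|g|$ is, on our simulations of both bar targets and
bead fields, *minimized* at focus, because a defocused hologram spreads
moderate gradients over every pixel while a focused image concentrates
large gradients on few edge pixels. The RMS form rewards that
concentration (it is the square root of the classical Tenengrad energy),
while keeping two useful exact properties: a constant image scores 0 and
the score is linear in edge height.

The sharpness response over a wide z-interval is multi-peaked (twin-image
side lobes), so golden-section alone is unreliable. `autofocus()` first
runs an 11-point coarse scan, re-scanning the winning bracket until it is
narrow (≤ 20 × tolerance), warns if the response is visibly multi-modal,
and only then applies golden-section. On a synthetic 3 µm bar target at
800 µm the result lands within 1 µm of a 0.5 µm brute-force scan.

## Multi-height phase recovery

Holograms are acquired at several sample-to-sensor distances (default six,
20 µm apart; spacings under 2 µm are rejected because the inter-plane
intensity change becomes too small to constrain the phase). The recovery
sweep is:

* initialize at the closest height with measured amplitude
  $\sqrt{I_1}$ and zero phase;
* propagate to each subsequent height, replace the amplitude by the
  arithmetic mean of calculated and measured amplitude, keep the phase;
* sweep back down to the first height the same way;
* one forward + backward sweep is one iteration; stop when the relative L2
  change of the first-plane field drops below `tol` (default $10^{-4}$,
  50 iterations maximum).

Zero-phase initialization makes the whole pipeline deterministic; a seeded
random initialization is available via `init = "random"` for comparing
initializations. Convergence is reported (`RecoveryReport`-style list) with
the full residual history. On noiseless synthetic bead scenes the recovery
reduces the background twin-image artifact energy of the refocused image by
roughly an order of magnitude relative to the single-height zero-phase
baseline; the acceptance suite asserts the factor-2 bound.

A caveat the synthetic tests make visible: background artifact energy is
only a *twin-image* measure when every object sits in the refocus plane.
In multi-plane scenes the background also contains the genuine defocused
diffraction of objects on other planes — a perfectly recovered field
actually scores *worse* there than a blurred one. The twin-suppression
metric is therefore always evaluated on single-plane scenes.

## Back-propagation stacking and the measured volume

`build_measured_volume()` stacks back-propagations of the recovered
hologram on a uniform z-grid. For deconvolution the volume is built with
`background = "mean"`: the plane-wave background survives back-propagation
as each plane's DC component, and the linear model below holds for the
*scattered* wave only. Subtracting the per-plane complex mean before taking
magnitudes yields a nonnegative volume that is ≈ 0 in empty space and
bright at scatterers, matching the background-subtracted PSF construction.
Deconvolving the raw background-laden stack instead makes the min/max
matching of Gold's method stretch the nearly flat re-blurred volume's
texture to the full data range and the iteration diverges — which is why
the background choice is explicit in the API.

## The PSF volume and deconvolution

The stacking operator blurs a point object into a double cone: sharp at its
own plane, rings everywhere else. Writing the measured stack as
$M = O \otimes \mathrm{PSF}$, the object $O$ is recovered by 3D
deconvolution. The PSF volume is simulated, not measured: a single-voxel
perturbation (point scatterer, or point blocker — they differ only in
sign) on a unit background at the central plane is propagated to the
detector, the unperturbed background field is subtracted, and the scattered
wave is back-propagated to every plane of the target grid, recentered, and
normalized. Normalization scales the *summed voxel magnitude* to one so
that convolution with the PSF preserves constants — the property the
convolution tests pin down.

Two deconvolvers operate on matching grids (circular FFT convolution by
default, optional zero-padding for linear convolution):

**Regularized Wiener inverse.**
$O = \mathrm{FT}^{-1}\!\big[\mathrm{FT}[M]\,\overline{\mathrm{FT}[\mathrm{PSF}]}
/ (|\mathrm{FT}[\mathrm{PSF}]|^2 + \beta)\big]$ with $\beta = 0.001$ as the
operating point. It is exact in the noiseless small-$\beta$ limit (tested
to $10^{-6}$ on a well-conditioned kernel) but on the holographic PSF —
whose spectrum is small at most frequencies — a practical $\beta$
degenerates it toward a matched filter with little axial confinement.

**Gold's multiplicative iteration.** Starting from $O^{(0)} = M$:
$M^{(k)} = O^{(k-1)} \otimes \mathrm{PSF}$, then the magnitude of $M^{(k)}$
is affinely rescaled so its minimum and maximum match those of $M$
(`match_minmax()`, idempotent, phase-preserving; kept as one function so
the convention can be swapped), then
$O^{(k)} = O^{(k-1)} \, M \, \overline{M^{(k)}} / (|M^{(k)}|^2 + \beta)$.
The update is nonnegativity-preserving in amplitude mode — the default
mode, since magnitudes are where the method is well-behaved; a complex
mode preserves per-voxel phase through the rescale. Default 20 iterations,
$\beta = 0.001$; counts above 200 trigger an over-fitting warning, and the
per-iteration data-fidelity residuals are returned so late-stage
non-monotonicity is observable.

On the synthetic two-bead scene (beads at 700 and 760 µm, 25-plane stack),
Gold deconvolution cuts the axial FWHM through each bead from ~18–29 µm to
~8 µm and concentrates the axial energy into the focal neighbourhood; the
acceptance suite asserts both inequalities.

## The simulator: what it emulates, what it does not

`make_beads()` / `make_bar_target()` build thin transmissive scenes
(opaque or phase-shifting disks with 5-diameter minimum separation,
round-robin over z-planes; 1:1 duty-cycle three-bar groups). Bead centers
snap to the pixel-corner lattice so a 1 µm bead covers exactly 4 high-res
pixels across at 0.278 µm pitch. `render_hologram()` is a multi-slice
forward model: unit plane wave, transmission per plane, angular-spectrum
propagation between planes and to the detector. `acquire_lowres_stack()`
shifts the fine intensity in the Fourier domain (exact for the band-limited
fields the forward model produces), box-integrates $k \times k$ blocks, and
optionally adds seeded Gaussian intensity noise. Every generator is
deterministic under its seed.

Not emulated: partial coherence (the 10 nm source bandwidth), sensor
quantization, dark current, fill factor < 1, refraction at the cover
glass, or realistic cell morphology. Passing tests therefore demonstrate
the *algorithmic* claims (resolution gain, twin-image suppression, axial
confinement) under an idealized but physically consistent forward model,
not instrument-level performance on tissue.

## Problem sizes and numerical choices

The shipped test and acceptance workloads use 252 × 252 high-resolution
grids (the nearest multiple of the 6× factor below 256) with six heights
and 25-plane volumes — large enough for the twin image and the double-cone
PSF to be fully developed, small enough that the whole suite runs in well
under a minute per experiment on one core. Other conventions:

* FFT grids are unshifted; the PSF's center voxel is defined as
  `floor(n/2)+1` on every axis and moved to the origin before convolution.
* `fwhm()` interpolates half-crossings linearly around the global peak and
  returns `NA` when a profile never falls to half height on one side.
* Degenerate inputs fail loudly: non-uniform z-grids, mismatched volume
  shapes, sub-2 µm height spacing, non-divisible acquisition dims (the
  error names the required crop), over-packed bead demands (the error
  names the achievable count).
* Shifts outside `[0, pitch)` are folded back with a warning rather than
  rejected, since they are physically equivalent.

## Known limitations

The first Born reading of $M = O \otimes \mathrm{PSF}$ ignores multiple
scattering and the cross-terms between scatterers; for dense scenes the
deconvolution sharpens but does not quantify. Wiener deconvolution with
the paper-style $\beta$ should be treated as a fast preview, not a
confinement method. Autofocus assumes the sharpness response has a
dominant peak in the search window; heavily phase-shifting extended
samples may need a narrower window around the nominal distance.
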
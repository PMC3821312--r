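---
title: "Modelling orientation-dependent birefringence contrast with polarized light"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling orientation-dependent birefringence contrast with polarized light}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polbiref)
```

## The problem

Cross-polarized confocal microscopy images birefringent tissue structures —
hair cortex, collagen, muscle — by detecting only the light whose polarization
changed inside the sample. With *linearly* polarized illumination the detected
signal depends strongly on the angle between the polarization and the optical
axis of the structure: a fiber aligned at 0° or 90° to the polarization
returns almost nothing, while the same fiber at 45° returns the full
birefringent signal. For wavy structures with no preferred orientation this
produces a systematic underestimation of birefringence content. Circularly
and radially polarized illumination have no preferred transverse direction,
so their contrast is orientation-independent.

`polbiref` implements the full computation chain needed to study this
quantitatively in simulation: Mueller/Stokes algebra, a model of the
segmented half-wave retarder that generates radially polarized light, a
rotating circular-polarizer imaging Stokes polarimeter with a realistic 8-bit
averaging camera, a cross-polarized confocal forward model of a birefringent
fiber, and the ratio-contrast statistic

$$R \;=\; \frac{I_B^{P1}/I_N^{P1}}{I_B^{P2}/I_N^{P2}},$$

where $I_B$ and $I_N$ are mean intensities measured in regions of interest on
the birefringent fiber and the non-birefringent background, and $P1$, $P2$
are two incident-polarization orientations 45° apart. $R = 1$ means the
contrast does not depend on orientation.

## Conventions

All public angles are in degrees, counter-clockwise from horizontal, viewed
against the propagation direction; retardances are radians; lengths are
micrometres. Circular handedness: $s_3 > 0$ is labelled right circular, and a
quarter-wave plate at +45° turns horizontal linear light into $(1,0,0,+1)$.
The source instrument papers in this area rarely fix these conventions, so
they are package choices, applied consistently; no test depends on the
absolute sign of $s_3$, only on consistency under a global flip.

Only intensity (Mueller) calculus is used. Every observable modelled here is
an intensity of incoherently summed contributions, so field-level (Jones)
coherence is not needed; this is also why the radial beam is modelled as an
incoherent pupil average (below) rather than a focused vector field.

## The segmented retarder

The radial-polarization converter is a circular aperture tiled by eight
half-wave-plate sectors. A sector centred at azimuth $\varphi_k$ carries its
fast axis at $(\varphi_k + \theta_{in})/2$, so a half-wave plate maps linear
input at $\theta_{in}$ onto linear output along $\varphi_k$ — the local
radial direction. Sector $k$ spans $[\,k\cdot45° - 22.5°,\ k\cdot45° +
22.5°)$; this symmetric layout is a package choice (no published layout
exists for the physical device). Light in the air gaps between sectors passes
unmodified, which reproduces the gap-noise mechanism qualitatively;
edge diffraction is deliberately not modelled. An optional per-sector
fast-axis jitter (`axis_jitter_sd`) emulates cutting/mounting inaccuracy for
robustness studies; it defaults to 0.

Two structural facts are asserted exactly in the tests: half-wave sectors are
lossless ($s_0$ conserved) and cannot create circularity ($s_3 = 0$ for
linear input).

## The imaging polarimeter

The analyzer is a rigid quarter-wave plate + polarizer unit with axes 45°
apart. With the wave plate facing the light it is a circular analyzer,
$I = \tfrac12(S_0 \pm S_3)$, independent of unit rotation; flipped by 180° it
acts as a linear analyzer at the polarizer axis,
$I = \tfrac12(S_0 + S_1\cos 2\varphi + S_2\sin 2\varphi)$. The default
protocol — flipped at $\{0°, 45°, 90°, 135°\}$ plus one normal setting — is
the minimal full-rank design; the published instrument description does not
list its angles, so the protocol is configurable and checked for rank before
use, with a diagnostic naming what is missing.

The camera model quantizes each frame to 8 bits after adding read noise
(default sd 1 count) and shot noise. Shot noise uses the Gaussian
approximation with variance equal to the mean count — at the ~200-count
working level set by the auto-exposure this is indistinguishable from Poisson
counting and keeps large frame-stack simulations fast. Exposure is set so the
brightest ideal pixel sits at 90% of full scale, avoiding saturation (the
instrument's exposure strategy is unpublished). 256 frames are averaged per
setting, as in the modelled instrument.

Reconstruction is per-pixel ordinary least squares over all settings
(homoscedastic averaged noise justifies no weighting), followed by a minimal
physicality projection: if the recovered polarized part exceeds $S_0$ the
vector $(s_1,s_2,s_3)$ is radially clipped, preserving direction. "Accuracy"
for a component $i$ is defined as
$100\,(1 - \overline{|\Delta S_i|}/S_{0,\mathrm{ref}})$ — the instrument
literature quotes "98%" without a formula, so the package fixes the simplest
per-point metric and also reports the worst pixel.

## The confocal fiber model

A cylindrical fiber of diameter 80 μm (typical scalp hair; configurable) lies
in the image plane at angle $\psi$. The cortex is a linear retarder with fast
axis along the fiber; its birefringence is $\delta = n_e - n_o = 1.548 -
1.541 = 0.007$, and the retardance after optical path $x$ is $d = 2\pi\delta
x/\lambda$ with $\lambda = 0.83$ μm. The per-pixel path is the chord of the
circular cross-section from the entry surface down to the focal plane
(single-pass by default; `pass_factor = 2` gives the double-pass reading, as
the detected geometry is ambiguous in reflection instruments).

Depolarization from multiple scattering is carried phenomenologically by
$p(x) = e^{-x/\ell_p}$ with default $\ell_p = 100$ μm; only the *trend*
(polarization → 0 with path) is physically established, so $\ell_p$ is an
explicit free parameter.

The detected intensity is the Mueller chain: input state → partial
depolarizer → fiber retarder → crossed analyzer matched to the illumination
(orthogonal linear, opposite circular, or per-azimuth crossed linear for
radial light). The depolarized fraction represents multiply-scattered light
that the confocal pinhole rejects, so the analyzer's unpolarized throughput
$\tfrac12(1-p)I_0$ is removed from the detected signal. With that detection
model the chain reduces exactly to

* linear: $I = I_0\, p\, \sin^2\!\big(2(\theta-\psi)\big)\sin^2(d/2) + b$,
* circular: $I = I_0\, p\, \sin^2(d/2) + b$,
* radial: $I = \tfrac12 I_0\, p\, \sin^2(d/2) + b$,

which the test suite verifies to $10^{-10}$ on 1,000 random parameter tuples
against independently coded closed forms. The radial $\tfrac12$ falls out of
the pupil average of $\sin^2$ and mirrors the lower focal intensity of radial
beams. A convenient exact fact: the equally spaced average of $\sin^2$ equals
$\tfrac12$ for any $n \ge 3$ azimuths, so the 8-sector device average and the
continuous ideal coincide analytically — the 8-sector radial response is
orientation-independent *exactly*, not approximately.

Radial illumination is an incoherent average over the pupil's local linear
polarizations. This is a modelling decision: the instrument detects
intensities only, and the physical argument for orientation independence
("no preferential direction") is precisely this average. Focused vector-field
structure (longitudinal fields, side lobes) is out of scope.

## Orientation, P1/P2, and why noise-free R is exactly 1

The two measurement orientations are realized by rotating the *incident
polarization frame* by 0° and 45° with the fiber geometry fixed in the image,
matching the experimental procedure the model emulates (the polarization is
rotated relative to the hair axis). By frame invariance — verified in the
tests by jointly rotating fiber and polarization — this is physically
equivalent to rotating the fiber, but it avoids re-rasterizing the fiber
footprint, so for circular and radial illumination the two orientations are
*identical* computations and the noise-free $R$ equals 1 to machine
precision rather than up to pixelation error.

ROI handling follows the same logic: three 25 × 25 μm² regions (35 × 30
pixels at the default 450 × 400 μm / 630 × 480 px imaging scale) are placed
uniformly at random, rejection-sampled to stay inside their mask without
overlap. Placements are matched between P1 and P2 (same seed) so geometric
sampling cancels in the ratio, and re-drawn per depth with a seed offset.
The reported uncertainty is first-order propagation of the standard errors
of the four ROI means — the source plots show error bars without defining
them, so the delta method is the package's choice. By convention the curve
reports both the raw ratio and an oriented $R \ge 1$ (P1 taken as the
higher-contrast orientation), making "contrast variation is high for linear
polarization" a one-sided comparison.

## What the generator emulates — and what it does not

The synthetic scenarios cover the chain end to end: homogeneous calibration
beams (linear at −45°, circular), the segmented-retarder output, and fiber
scenes in air (background $10^{-3} I_0$, a floor that keeps ratios finite
over "zero" backgrounds) and on skin (level $0.05\,I_0$ with log-normal
multiplicative speckle, σ = 0.3 — any positive heterogeneous field suffices
for ratio statistics; real skin texture is not parameterized). Everything is
deterministic given a seed, to the byte on disk.

Passing tests therefore demonstrate internal consistency of the optics chain
and the statistics under this noise model — not fidelity to a particular
camera's noise spectrum, real hair-surface scattering, Fresnel interface
reflectance (ignored by design), melanin absorption, or focused-field
vector effects. Those are stated limitations, not approximation errors.

## Numerical choices

* Degenerate inputs are refused loudly: rank-deficient analyzer protocols
  (with the missing settings named), non-physical Stokes vectors,
  depolarization fractions outside $[0,1]$, non-positive intensities in the
  ratio, infeasible ROI placements.
* Reconstruction uses one normal-equation factorization for the whole image;
  the noise-free forward/inverse roundtrip is exact to $10^{-10}$ with the
  idealized continuous detector (`bit_depth = Inf`).
* On-disk maps use 16-bit fixed-point TIFF planes with affine scaling in a
  JSON sidecar; this grid is exactly idempotent under write/read, so a
  re-write of a read map is byte-identical. Confocal images use the deeper
  32-bit mode (~2 × 10⁻¹⁰ of range). Frame stacks store the exact integer
  frame-sum in 16-bit TIFFs.
* Problem sizes used by the shipped checks: 256 × 256 polarimeter maps with
  256-frame averaging over 20 seeds for the accuracy study, and full
  630 × 480 confocal frames for the contrast study — the scales of the
  modelled instrument.

## Known limitations

The depolarization length, skin speckle parameters and fiber diameter are
plausible defaults, not measured values; conclusions that depend on their
absolute scale (e.g. the depth at which linear and circular contrast
converge) should be read as qualitative. The SVR model omits edge
diffraction, so gap noise appears as clean pass-through light rather than
the diffuse halo a camera would record. The polarimeter model omits
wave-plate retardance errors and dark/flat-field structure.
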
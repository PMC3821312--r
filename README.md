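# polbiref

Simulation and analysis of orientation-dependent birefringence contrast in
cross-polarized confocal imaging, in Mueller/Stokes calculus.

## The problem

Cross-polarized confocal microscopy detects light whose polarization changed
inside the sample, which makes birefringent structures (hair cortex,
collagen) stand out against non-birefringent background. With **linearly**
polarized illumination the detected signal scales as
`sin²(2(θ−ψ)) · sin²(d/2)`, where `θ−ψ` is the angle between the
polarization and the fiber's optical axis and `d = 2πδx/λ` is the phase
retardation accumulated over path `x` in a medium of birefringence
`δ = n_e − n_o` (hair cortex: `n_o = 1.541`, `n_e = 1.548`, `δ = 0.007`).
A fiber at 0° or 90° to the polarization is nearly invisible; at 45° it is
maximally bright. **Circular** and **radial** illumination have no preferred
transverse direction, so their contrast is orientation-independent — which
matters for wavy structures that cannot be oriented to the examiner's
preference.

The orientation dependence is quantified by the ratio contrast

```
R = (I_B^P1 / I_N^P1) / (I_B^P2 / I_N^P2)
```

with `I_B`, `I_N` mean ROI intensities on the birefringent fiber and the
background, and `P1`, `P2` two incident-polarization orientations 45° apart;
`R = 1` means orientation-independent contrast.

The package provides, as testable simulation components:

* **Mueller/Stokes algebra** — rotators, retarders, polarizers, partial
  depolarizers, degree of polarization;
* **a segmented half-wave retarder** (8 sectors, with optional inter-sector
  gaps and axis jitter) that converts a linear beam into a nearly radially
  polarized beam, plus the continuous ideal map and per-component agreement
  metrics;
* **an imaging Stokes polarimeter** — a rotating quarter-wave-plate +
  polarizer analyzer (rotated and flipped), an 8-bit averaging CCD model
  with shot/read noise, and per-pixel least-squares Stokes reconstruction;
* **a cross-polarized confocal forward model** of a birefringent fiber under
  linear, circular and radial illumination, with chord-path retardation and
  exponential depth depolarization;
* **the ratio-contrast analysis** — random non-overlapping 25 × 25 μm ROIs,
  power normalization, `R` with delta-method uncertainties, depth profiles;
* **a synthetic-fixture generator** for every scenario above, byte-stable
  given a seed, with TIFF + JSON serialization throughout.

## Worked example

Render a hair fiber on skin at 20 μm focal depth under the three
illumination modes, at two incident-polarization orientations 45° apart, and
evaluate `R`:

```r
library(polbiref)

scene <- fiber_scene(background = "skin")   # 80 um hair, delta = 0.007
ins   <- instrument_config()                # 450 x 400 um FOV, 630 x 480 px

series <- function(ill) lapply(c(0, 45), function(o)
  render_image(scene, ill, ins, depth = 20, orientation = o, seed = 1))

fm <- fiber_mask(scene, ins, erode_um = 5)
bm <- background_mask(scene, ins)
R_of <- function(pair) contrast_depth_curve(pair[1], pair[2], fm, bm,
                                            depths = 20, seed = 7)

rbind(linear   = unlist(R_of(series(illumination_linear(0)))[1, c("R", "R_raw", "R_sd")]),
      circular = unlist(R_of(series(illumination_circular(1)))[1, c("R", "R_raw", "R_sd")]),
      radial   = unlist(R_of(series(illumination_radial(8)))[1, c("R", "R_raw", "R_sd")]))
#>                 R  R_raw   R_sd
#> linear   157.6424 0.0063 1.5985
#> circular   1.0000 1.0000 0.0120
#> radial     1.0000 1.0000 0.0120
```

Linear illumination: the fiber is ~158× more contrasted at 45° than
along-axis (`R` is the oriented ratio ≥ 1; `R_raw` keeps the P1/P2 order as
given). Circular and radial illumination are orientation-independent,
`R = 1` exactly in the noise-free model.

Polarimeter calibration: simulate a homogeneous circular beam through the
8-bit, 256-frame-averaged camera and reconstruct it pixel by pixel:

```r
fx  <- make_polarimeter_fixture(fixture_spec("homogeneous_circular",
                                             grid_shape = c(128, 128), seed = 1))
acc <- accuracy_report(reconstruct_stokes(fx$stack), fx$truth)
round(acc, 3)
#>     S0     S1     S2     S3
#> 99.767 99.671 99.669 99.431
```

Every Stokes component is recovered with better than 98% mean accuracy
(`attr(acc, "worst")` additionally reports the worst single pixel).

## Documentation

The methods vignette (`vignettes/polarized-contrast.Rmd`) describes the
model and its assumptions, the angle/handedness conventions, the noise and
depolarization models, the ROI and P1/P2 design choices, and what the
synthetic scenarios do and do not emulate.
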
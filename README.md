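# polarLD

Quantitative fluorescence-detected linear dichroism (LD) imaging in R.

Fluorophores whose orientation is constrained — dyes in lipid membranes,
lipidated fluorescent proteins, labels on cytoskeletal filaments — are
excited more efficiently when the excitation polarization aligns with
their transition dipole moment (∝ cos²ψ for one-photon, ∝ cos⁴ψ for
two-photon excitation). Polarization-resolved microscopy therefore
encodes molecular orientation in the *dichroic ratio* r = F_h/F_v of
fluorescence excited with horizontally vs vertically polarized light.
polarLD turns such images into physical statements about the
orientational distribution of the fluorophore.

The package provides, end to end:

- **Forward model** — wrapped-Gaussian distributions of TDM tilt angles
  (mean tilt α₀, width σ, free rotation about the membrane normal or
  filament axis) mapped to dichroic observables: absorption moments
  m₂ = ⟨cos²α⟩, m₄ = ⟨cos⁴α⟩, the shape parameters
  b₁P = (3m₂ − 1)/(m₂ + 1) and (b₂P, c₂P), and ideal log₂ r(θ) curves;
  plus a brute-force Monte-Carlo oracle and a precomputed (α₀, σ) lookup
  table.
- **Image processing** — de-interleaving of pixel-alternating
  mixed-polarization frames, background/bleed-through/gain corrections,
  per-pixel dichroic-ratio maps, exact closed-form cos² fits of
  multi-polarization stacks (r_max and molecular azimuth per pixel),
  photobleaching correction, and hue/brightness renders with azimuth
  overlays and matching color bars.
- **Geometry** — Hough circle detection of vesicle cross-sections,
  Otsu/mask segmentation with eraser support, spline outlines with dense
  tangents, and nearest-point assignment of the feature orientation θ to
  every analyzed pixel.
- **Inference** — weighted multi-start fits of the 1P/2P parametric LD
  curves, log₂(r_max), goodness-of-fit heat maps over the (α₀, σ) grid
  (r², RMSD, χ²), combination of 1P and 2P data sets, bootstrap
  confidence regions (resampling whole objects), two-Gaussian mixture
  searches with an entropy tie-break, and orientation sets consistent
  with observed r_max values.
- **Synthetic scenes** — a ground-truth generator rendering vesicle rings
  and filaments through the same forward model with Poisson noise,
  background, bleed-through and bleaching, used as the package's test
  surface.

## Worked example

Simulate a DiI-like vesicle (TDM in the membrane plane: α₀ = 90°,
σ = 10°), image it as a 1P and a 2P polarization pair, and recover the
tilt distribution:

```r
library(polarLD)

analyze <- function(modality, seed) {
  scene <- sceneSpec(distribution = tiltDistribution(90, 10),
                     modality = modality, photons = 1e4, seed = seed)
  img   <- renderScene(scene)$data
  pair  <- correctPair(img, backgroundH = 0, backgroundV = 0)
  map   <- dichroicRatioMap(pair, minIntensity = 50)
  mask  <- segmentOutline(map@intensity, "circle", radii = 40:80, band = 2)
  assignTheta(map, fitSpline(mask, closed = TRUE), "membrane",
              modality = modality)
}

s1 <- analyze("1P", seed = 3)
s2 <- analyze("2P", seed = 1003)

fit1P(s1)
#> Fit1PResult: A = 0.0007, B1P = 0.8881, phi = (0.0, 0.0) deg
#>   log2(rmax) = 4.0778, r2 = 0.9993, RMSD = 0.0655, n = 2232

goodnessMap(list(s1, s2))
#> GoodnessMap (combined): 91 x 90 cells, best (alpha0, sigma) = (89, 10) deg
```

The 1P fit says the dichroic ratio swings over 2^4.08 ≈ 17-fold around
the ring (its maximum at θ = 0, polarization parallel to the membrane),
with amplitude B₁P ≈ 0.888 — the fingerprint of an in-plane fluorophore.
The combined 1P+2P goodness map localizes the generating distribution to
within a degree: (89°, 10°) against the simulated truth (90°, 10°).
1P data alone constrain only one shape parameter (a whole (α₀, σ) band
fits equally well); adding 2P data is what pins both parameters — see the
vignette for the model and its caveats.

A thin command-line interface over the same functions ships in
`inst/cli/polarLD.R` (subcommands `simulate`, `process-pair`,
`process-stack`, `segment`, `quantify`, `pool`, `heatmap`, `bootstrap`,
`mixture`, `rmax2orient`, `forward`, `colorbar`; every run writes its
effective configuration as JSON next to its outputs).

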
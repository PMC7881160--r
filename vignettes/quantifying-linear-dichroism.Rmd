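---
title: "Quantifying fluorescence-detected linear dichroism with polarLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescence-detected linear dichroism with polarLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarLD)
```

## The measurement and the model

Fluorescence excited by linearly polarized light depends on the angle
between the excitation polarization and the transition dipole moment
(TDM) of the fluorophore: the excitation probability scales as
cos² of that angle for one-photon (1P) excitation and, under the vector
approximation, as cos⁴ for two-photon (2P) excitation. When fluorophores
are orientationally constrained — dyes in a lipid bilayer, fluorescent
proteins tethered to a membrane, labels on actin filaments — images taken
at different excitation polarizations therefore differ, and the
*dichroic ratio* `r = F_h / F_v` (fluorescence under horizontally vs
vertically polarized excitation) carries quantitative information about
molecular orientation.

polarLD models the orientation of the TDM relative to a local symmetry
axis — the membrane normal for membrane-bound fluorophores, the filament
axis for filaments — by a **wrapped Gaussian distribution of tilt
angles**: mean tilt `alpha0` in [0°, 90°], width `sigma` > 0, with free
rotation `rho` about the axis. Two-component mixtures of such Gaussians
are supported for heterogeneous populations (for example, a protein in
two conformational states).

### Tilt density

The tilt angle is an axis (alpha and 180° − alpha are the same physical
orientation), so the Gaussian is mirrored about 0°, wrapped with period
180°, and reduced to [0°, 90°]. Because the TDM rotates freely about the
symmetry axis, tilt angle alpha occupies a cone with solid angle
proportional to sin(alpha); the density used everywhere in the package is
therefore

p(alpha) ∝ [ Σ_k N(alpha; ±alpha0 + 180k, sigma) ] · sin(alpha),

renormalized on [0°, 90°]. The sin(alpha) factor is what makes the
wide-sigma limit genuinely isotropic: as sigma grows, p(alpha) tends to
the uniform axis distribution with ⟨cos²alpha⟩ = 1/3, ⟨cos⁴alpha⟩ = 1/5,
and all dichroism vanishes. Without it, a "flat" tilt-angle density would
retain a spurious residual dichroism (⟨cos²alpha⟩ = 1/2), which
contradicts both the physics and the behavior expected of the model. The
wrap is truncated adaptively (|k| grows with sigma) so that the flat
limit is reached even for extremely wide distributions. Mirror-folding
the wrapped density about 90° reproduces the same family of Gaussian
means, so it amounts to a normalization constant and is not applied
explicitly.

Degenerate widths: below sigma = 0.01° the moments switch to the delta
shortcut (cos²alpha0, cos⁴alpha0); inside the density, sigma is clamped
at 0.01° to avoid division by zero.

### From the density to observables

Averaging the excitation probability over `rho` leaves only two
sufficient statistics of p(alpha), the absorption moments
`m2 = ⟨cos²alpha⟩` and `m4 = ⟨cos⁴alpha⟩` (`computeMoments()`, trapezoid
quadrature at 0.05° steps — far below any experimental error; mixtures
are weight-linear). With beta the angle between the excitation
polarization and the symmetry axis,

- 1P: `F1P(beta) ∝ m2 cos²beta + ((1 − m2)/2) sin²beta`
- 2P: `F2P(beta) ∝ m4 cos⁴beta + 3(m2 − m4) cos²beta sin²beta +
  (3/8)(1 − 2 m2 + m4) sin⁴beta`

Normalizing the Fourier expansion by the DC term gives the **dichroic
shape parameters** (`momentsToShapeParams()`):

- `b1p = (3 m2 − 1)/(m2 + 1)`, so `F1P ∝ 1 + b1p cos 2beta`
- `b2p`, `c2p`, so `F2P ∝ 1 + b2p cos 2beta + c2p cos 4beta`

Useful anchors: isotropy gives (0, 0, 0); a delta at the pole gives
(1, 4/3, 1/3); a sigma→0 distribution at the 1P magic angle
(cos²alpha0 = 1/3, alpha0 ≈ 54.74°) has `b1p = 0`. These reductions are
verified in the test suite against a brute-force Monte-Carlo oracle
(`sampleOrientationsMC()`) that samples TDM vectors directly and averages
`(mu·e)²` and `(mu·e)⁴`.

### Angle conventions

Image coordinates are pixel-centered, 0-based, x right / y down; angles
are measured in degrees from +x toward +y and reduced mod 180°. `theta`
is the angle between the horizontal excitation polarization and the local
feature tangent; `theta = 0` when they are parallel, so in-plane membrane
probes (DiI-like) peak at `theta = 0`. Geometry maps `theta` to `beta`:
membrane `beta = 90° − theta` (axis = normal), filament `beta = theta`
(axis = tangent). The predicted ideal curve is
`log2 r(theta) = log2 F(beta) − log2 F(beta + 90°)` (`predictLog2r()`),
which is antisymmetric under `theta → theta + 90°`; the implementation
canonicalizes `theta` to [0°, 90°) and negates on the other half-period
so the antisymmetry is exact in floating point. Where the orthogonal
channel is fully extinguished (a perfectly polarized limit) the curve
returns a signed infinity, flagged in an attribute; the fitting routines
never produce it because their amplitude bounds keep both intensity
polynomials positive.

## Image processing

1PPM/2PPM frames interleave the two polarizations between adjacent
pixels or rows. `deinterleave()` splits the frame by the declared scheme
and phase (which polarization comes first is explicit configuration —
acquisitions differ) and re-grids each channel to every pixel center by
linear interpolation along the modulation axis. `correctPair()` subtracts
per-channel background (defaulting to each channel's 1st percentile, a
batch-friendly choice), unmixes linear bleed-through with the symmetric
inverse `(fh − k fv)/(1 − k²)`, and applies a relative gain to fv.
Bleed-through is treated as linear unmixing rather than per-channel
scaling: it models polarization leakage as a fixed fractional
cross-coupling, which is exactly invertible.

`dichroicRatioMap()` yields per-pixel `r = fh/fv` with an intensity
threshold mask instead of errors. For stacks acquired at uniformly
incremented polarizations, `fitStackPerPixel()` uses closed-form harmonic
regression (`a0`, `a2`, `b2` sums), which *is* the least-squares fit of
`F = A + B cos²(theta − C)` when the angles tile the half-circle evenly,
is exact on noiseless data of that form, and is deterministic; nonuniform
angle sets fall back to explicit least squares on the same basis. The
azimuth is undefined at the zero-modulation tie and reported `NA` there.
`correctBleaching()` fits a single exponential to the frame means by
log-linear regression and divides it out — a deliberately simple model
for the monotone intensity loss across a stack; it preserves the
polarization modulation because the modulation averages out of the frame
means when angles tile the half-circle.

Rendering (`renderLDImage()`, `renderAzimuthOverlay()`, `ldColorbar()`)
encodes log2(r) (clipped to ±2 by default, recorded in the call) or the
azimuth as hue and intensity (normalized to its 99th percentile) as
brightness. Renders are pure functions; the color bar reproduces the
exact ramp pixel-for-pixel, and a spacing-1, length-1 azimuth overlay
degenerates to the per-pixel azimuth coloring.

## Geometry

`detectCircle()` is a Hough transform: for each candidate radius the mean
intensity along the circle perimeter is accumulated by ring-kernel
convolution; the best (center, radius) wins, with deterministic
tie-breaks (row-major smaller center, then smaller radius).
`segmentOutline()` offers the circle band, Otsu thresholding, or an
external mask; an eraser mask reproduces manual exclusion of irregular
membrane sections, and a curvature threshold in `assignTheta()` can
exclude high-turn outline stretches automatically.

`fitSpline()` approximates closed outlines by a periodic cubic spline of
the radius about the anchor centroid whenever the anchors are star-shaped
— this representation is exact on circles, where a chord-parametrized
interpolating cubic through 4 anchors would deviate by almost 3% of the
radius — falling back to a chord-length parametric periodic cubic for
non-star-shaped outlines; open outlines use a natural parametric cubic
(an interpolating, not smoothing, spline: anchor positions are trusted).
The outline is densely resampled at ≤ 0.5 px arc spacing with analytic
tangents. `assignTheta()` associates every valid pixel with its nearest
dense outline point (default cut-off 3 px, about the ring thickness/PSF)
and records (theta, log2 r, intensity weight) per object.

## Inference

`fit1P()`/`fit2P()` fit the measured `(theta, log2 r)` samples by the
parametric curves

log2 r = A1P + log2[(1 + B1P cos 2(θ−φ1)) / (1 − B1P cos 2(θ−φ2))]

log2 r = A2P + log2[(1 + B2P cos 2(θ−φ1) + C2P cos 4(θ−φ1)) /
(1 − B2P cos 2(θ−φ2) + C2P cos 4(θ−φ2))]

by weighted Levenberg-Marquardt with multi-start over phase and
amplitude; equal-SSE ties resolve to the smaller amplitude (parsimony).
The 2P fit is parameterized in the symmetry-axis (beta) convention, keeps
both intensity polynomials positive (soft penalty plus a final
projection), and carries a tiny amplitude ridge during the multi-start —
at `B = 0` the curve is independent of `C`, so the ridge keeps the
unidentifiable direction at zero for near-isotropic data — followed by an
unridged polish from the selected optimum, so noiseless curves are
recovered to better than 1e-6. `log2rmax` is the signed extremum of the
fitted curve with the largest magnitude (ties resolve toward theta = 0);
note that a small negative offset can legitimately hand the larger lobe
to theta = 90°, flipping the sign but not the magnitude.

Goodness of fit reports r² (flagged `NA` for zero-variance data), RMSD,
and chi-squared. Chi-squared needs per-point variances, which the
measurement does not define; the default estimates them from the local
scatter of log2 r in 18 theta bins (bins with fewer than 3 points fall
back to the global scatter).

### Goodness maps, combination, confidence

`goodnessMap()` compares the data with the ideal curve of every
(alpha0, sigma) cell of a precomputed lookup table (`buildLookupTable()`,
default 1° grid — the grid spacing is a resolution/speed compromise;
bilinear interpolation reproduces direct computation to ~1e-4 on b1p).
Offsets are profiled out per cell by weighted least squares (phases are
fixed at zero by the theta convention), which keeps the whole map a few
matrix products over 0.5°-binned samples. 1P data constrain only `b1p`,
so the 1P map has a one-parameter family of equally good cells; 2P data
determine both shape parameters and in principle pick a single cell.
Combining modalities (`poolAndFit()`, a shared (alpha0, sigma) with
independent per-modality offsets) sharpens the map further and also
yields the 1P curve predicted from the 2P best fit.

A practical caveat the synthetic experiments make explicit: the forward
map (alpha0, sigma) → (b1p, b2p, c2p) has a *diagonal near-degeneracy* —
narrow distributions at smaller tilt and wider distributions at larger
tilt (for example (78°, 1°) vs (90°, 10°)) generate 1P and 2P curves
differing by well under a tenth of the signal's RMS. Cells along this
valley remain within Δr² ≈ 0.005 of the optimum even for noiseless data,
so "the set of near-optimal cells" collapses to a point only relative to
a noise-scaled threshold, not relative to a fixed Δr². The best-fit cell
itself is nevertheless recovered accurately (the acceptance checks
demand the truth within ±3°/±5° median).

`bootstrapConfidence()` resamples whole objects — pixels within one
vesicle/cell are strongly correlated, so the object is the exchangeable
unit — refits the best cell per replicate, and returns the smallest cell
set holding the requested mass of bootstrap best-fits (always including
the full-data best cell). Everything is deterministic given the seed.

`mixtureSearch()` addresses two-population samples: an exhaustive grid
over two components and the mixing fraction (defaults: alpha0 step 5°,
sigma ∈ {5°,…,45°}, f step 0.1 — chosen to keep the full search around a
CPU-minute; mixture moments are weight-linear, so the search is fully
vectorized), scored by r² against the three target shape parameters.
Near-ties are re-ranked by the differential entropy of the mixture tilt
density (trapezoid on the 0.05° grid, reported in bits) — the entropy
criterion prefers the least committal distribution consistent with the
data; note it may prefer a broad two-component mixture over the widest
single Gaussian, since such mixtures can approach the uniform axis
distribution even more closely. Mixture fits are intrinsically degenerate
(many pairs fit almost equally well); the search reports a ranked
candidate list, not a unique answer. `rmaxToOrientation()` is the
coarser inverse: all cells whose predicted log2(r_max) matches the
observed value(s) within tolerance.

## The synthetic-scene generator

`renderScene()` renders vesicle equatorial rings or filament polylines
with a Gaussian radial intensity profile (default width 3 px at a
notional 100 nm pixel spacing — only ratios matter), drives every pixel's
polarization response through the same forward model via the analytic
local tangent, scales to an expected peak photon count, applies
bleed-through mixing, background, per-frame bleaching in acquisition
order, and Poisson noise, and emits the matching pair / interleaved
frame / stack containers plus a ground-truth record (distribution,
tangent map, noise-free channels). Default conditions used throughout
the tests: 256² images, ring radius 60 px, peak 1e4 photons — bright,
GUV-like objects.

What the generator does *not* emulate: optical point-spread blurring
beyond the radial profile, high-NA polarization mixing, out-of-plane
membrane tilt (only approximable as extra sigma), membrane ruffling, or
sample movement. Passing the end-to-end recovery tests therefore
demonstrates correctness of the algorithms under the stated image model,
not robustness to every artifact of real microscopy.

## Problem sizes and numerical choices

The default lookup grid is 91 × 90 cells; goodness maps aggregate samples
into 0.5° theta bins (approximation error far below sample noise);
acceptance-level checks use 20 pipeline seeds, 20 bootstrap ensembles of
20 objects at 200 replicates, and Monte-Carlo cross-checks at 1e6–1e7
draws. Moment quadrature uses the trapezoid rule at 0.05°; lookup tables
serialize to CSV with an FNV-1a content hash. All randomness flows
through explicit integer seeds, and RNG state is restored on exit from
every stochastic function.

## Known limitations

- The vector (cos⁴) approximation for 2P absorption, and a single TDM
  orienting both 1P and 2P absorption; full 2P absorptivity tensors are
  out of scope.
- The (alpha0, sigma) diagonal near-degeneracy discussed above limits how
  sharply any method can localize both parameters from LD curves alone.
- Labels with an extra internal rotational degree of freedom between the
  fluorophore and the feature violate the single wrapped-Gaussian model;
  such data show up as systematically low r² against the whole map.
- Mixture searches are reported as ranked candidate lists because of
  intrinsic non-uniqueness; interpreting a single "best" pair is rarely
  justified.
- No image registration: multi-frame inputs are assumed pre-aligned.
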
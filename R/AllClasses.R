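## S4 class definitions for polarLD.
##
## Angle conventions (used everywhere in the package):
##  - image coordinates are pixel-centered, 0-based, x to the right and y
##    downwards; angles are measured in degrees from +x towards +y;
##  - theta is the angle between the horizontal excitation polarization and
##    the local feature tangent, reduced mod 180 deg;
##  - beta is the angle between the excitation polarization and the symmetry
##    axis of the orientational distribution (membrane normal or filament
##    axis): membrane beta = 90 - theta, filament beta = theta.

#' TiltDistribution: wrapped-Gaussian distribution of fluorophore tilt angles
#'
#' Describes the orientational distribution of transition dipole moments
#' (TDMs) around a local symmetry axis: the membrane normal for
#' membrane-bound fluorophores, or the filament axis for labeled filaments.
#' The tilt angle alpha of the TDM from the axis follows a wrapped,
#' mirror-folded Gaussian on \[0, 90\] degrees with mean tilt `alpha0` and
#' width `sigma`; rotation about the axis (angle rho) is free and is
#' integrated out analytically by the moment computation. One or two
#' components (a mixture) are supported.
#'
#' @slot components numeric matrix with columns `alpha0`, `sigma`, `weight`
#'   (degrees, degrees, fraction); one row per mixture component (1 or 2).
#' @slot geometry `"membrane"` or `"filament"`; decides how the in-image
#'   feature tangent maps onto the symmetry axis.
#' @seealso [tiltDistribution()], [computeMoments()], [predictLog2r()]
#' @export
setClass("TiltDistribution",
  representation(components = "matrix", geometry = "character"))

setValidity("TiltDistribution", function(object) {
  cmp <- object@components
  msg <- character()
  if (!is.numeric(cmp) || ncol(cmp) != 3L)
    return("components must be a numeric matrix with columns alpha0, sigma, weight")
  if (!identical(colnames(cmp), c("alpha0", "sigma", "weight")))
    msg <- c(msg, "components columns must be named alpha0, sigma, weight")
  if (nrow(cmp) < 1L || nrow(cmp) > 2L)
    msg <- c(msg, "1 or 2 mixture components only")
  if (any(!is.finite(cmp)))
    msg <- c(msg, "components must be finite")
  else {
    if (any(cmp[, "alpha0"] < 0 | cmp[, "alpha0"] > 90))
      msg <- c(msg, "alpha0 must lie in [0, 90] degrees")
    if (any(cmp[, "sigma"] <= 0))
      msg <- c(msg, "sigma must be > 0")
    if (any(cmp[, "weight"] <= 0 | cmp[, "weight"] > 1))
      msg <- c(msg, "weights must lie in (0, 1]")
    if (abs(sum(cmp[, "weight"]) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1 (within 1e-9)")
  }
  if (length(object@geometry) != 1L ||
      !object@geometry %in% c("membrane", "filament"))
    msg <- c(msg, "geometry must be 'membrane' or 'filament'")
  if (length(msg)) msg else TRUE
})

#' AbsorptionMoments: sufficient statistics of a tilt distribution
#'
#' The second and fourth moments of cos(alpha) over the tilt density,
#' `m2 = <cos^2 alpha>` and `m4 = <cos^4 alpha>`. Together with free
#' rotation about the axis these determine all dichroic observables for
#' one- and two-photon excitation.
#'
#' @slot m2 numeric in \[0, 1\].
#' @slot m4 numeric in \[0, 1\], with `m4 <= m2` and `m4 >= m2^2`.
#' @export
setClass("AbsorptionMoments", representation(m2 = "numeric", m4 = "numeric"))

setValidity("AbsorptionMoments", function(object) {
  m2 <- object@m2; m4 <- object@m4
  tol <- 1e-8
  if (length(m2) != 1L || length(m4) != 1L || !is.finite(m2) || !is.finite(m4))
    return("m2 and m4 must be finite scalars")
  if (m2 < -tol || m2 > 1 + tol) return("m2 must lie in [0, 1]")
  if (m4 < -tol || m4 > m2 + tol) return("m4 must lie in [0, m2]")
  if (m4 < m2^2 - 1e-6) return("m4 must be >= m2^2 (Cauchy-Schwarz)")
  TRUE
})

#' DichroicShapeParams: Fourier shape coefficients of the excitation curves
#'
#' Fourier-normalized coefficients of the rho-averaged excitation
#' probability as a function of beta, the angle between the excitation
#' polarization and the symmetry axis:
#' 1P: `F(beta) = 1 + b1p cos(2 beta)`;
#' 2P: `F(beta) = 1 + b2p cos(2 beta) + c2p cos(4 beta)`.
#'
#' @slot b1p numeric in \[-1, 1\] (non-negativity of the 1P curve).
#' @slot b2p,c2p numerics; the 2P polynomial must be >= 0 for all beta.
#' @export
setClass("DichroicShapeParams",
  representation(b1p = "numeric", b2p = "numeric", c2p = "numeric"))

setValidity("DichroicShapeParams", function(object) {
  tol <- 1e-6
  v <- c(object@b1p, object@b2p, object@c2p)
  if (length(v) != 3L || any(!is.finite(v)))
    return("b1p, b2p, c2p must be finite scalars")
  if (abs(object@b1p) > 1 + tol)
    return("b1p must lie in [-1, 1]")
  beta <- seq(0, 180, by = 0.5) * pi / 180
  f2 <- 1 + object@b2p * cos(2 * beta) + object@c2p * cos(4 * beta)
  if (min(f2) < -tol)
    return("2P intensity polynomial 1 + b2p cos2b + c2p cos4b must be >= 0")
  TRUE
})

#' LDLookupTable: precomputed dichroic shape parameters on an (alpha0, sigma) grid
#'
#' Tabulated `b1p`, `b2p`, `c2p` for every combination of mean tilt angle
#' and distribution width, used by the inverse inference (goodness maps,
#' restricted 2P fits, mixture searches).
#'
#' @slot alpha0 strictly increasing grid of mean tilt angles (degrees).
#' @slot sigma strictly increasing grid of widths (degrees).
#' @slot b1p,b2p,c2p numeric matrices of dim `length(alpha0) x length(sigma)`.
#' @seealso [buildLookupTable()]
#' @export
setClass("LDLookupTable",
  representation(alpha0 = "numeric", sigma = "numeric",
                 b1p = "matrix", b2p = "matrix", c2p = "matrix"))

setValidity("LDLookupTable", function(object) {
  msg <- character()
  if (length(object@alpha0) < 1L || is.unsorted(object@alpha0, strictly = TRUE))
    msg <- c(msg, "alpha0 grid must be non-empty and strictly increasing")
  if (length(object@sigma) < 1L || is.unsorted(object@sigma, strictly = TRUE))
    msg <- c(msg, "sigma grid must be non-empty and strictly increasing")
  dims <- c(length(object@alpha0), length(object@sigma))
  for (s in c("b1p", "b2p", "c2p"))
    if (!identical(dim(slot(object, s)), as.integer(dims)))
      msg <- c(msg, sprintf("%s matrix must be %d x %d", s, dims[1], dims[2]))
  if (length(msg)) msg else TRUE
})

#' MixedPolarizationImage: single frame with interleaved polarizations
#'
#' In 1PPM/2PPM the excitation polarization alternates between adjacent
#' pixels (or rows) within one frame; this class holds such a frame plus
#' the modulation scheme.
#'
#' @slot pixels nonnegative intensity matrix.
#' @slot scheme `"per_pixel_column"` (alternation across columns),
#'   `"per_pixel_row"` or `"per_row"` (alternation across rows).
#' @slot phase `"h_first"` or `"v_first"`: polarization of the first
#'   column/row along the modulation axis.
#' @export
setClass("MixedPolarizationImage",
  representation(pixels = "matrix", scheme = "character", phase = "character"))

setValidity("MixedPolarizationImage", function(object) {
  msg <- character()
  if (!object@scheme %in% c("per_pixel_column", "per_pixel_row", "per_row"))
    msg <- c(msg, "unknown modulation scheme")
  if (!object@phase %in% c("h_first", "v_first"))
    msg <- c(msg, "phase must be 'h_first' or 'v_first'")
  px <- object@pixels
  if (any(!is.finite(px)) || any(px < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  n <- if (identical(object@scheme, "per_pixel_column")) ncol(px) else nrow(px)
  if (n %% 2L != 0L)
    msg <- c(msg, "extent along the modulation axis must be even")
  if (length(msg)) msg else TRUE
})

#' PolarizationPair: co-registered images at two orthogonal polarizations
#'
#' @slot fh,fv intensity matrices for horizontally and vertically polarized
#'   excitation, same dimensions.
#' @slot modality `"1P"` or `"2P"`.
#' @slot calibration list with elements `backgroundH`, `backgroundV`
#'   (intensity offsets; `NULL` means estimate from the 1st percentile),
#'   `bleedK` (bleed-through fraction in \[0, 1)), `gainG` (relative gain
#'   applied to the corrected fv).
#' @export
setClass("PolarizationPair",
  representation(fh = "matrix", fv = "matrix", modality = "character",
                 calibration = "list"))

setValidity("PolarizationPair", function(object) {
  msg <- character()
  if (!identical(dim(object@fh), dim(object@fv)))
    msg <- c(msg, "fh and fv must have the same dimensions")
  if (!object@modality %in% c("1P", "2P"))
    msg <- c(msg, "modality must be '1P' or '2P'")
  cal <- object@calibration
  num <- unlist(cal[c("bleedK", "gainG")], use.names = FALSE)
  if (any(!is.finite(num)))
    msg <- c(msg, "calibration values must be finite")
  if (length(msg)) msg else TRUE
})

#' PolarizationStack: frames acquired at uniformly incremented polarizations
#'
#' @slot frames numeric array of dim `nrow x ncol x nframes`.
#' @slot angles polarization angles in degrees, strictly increasing with a
#'   uniform step; at least 4 frames covering >= 165 degrees of unique
#'   polarization directions mod 180.
#' @slot modality `"1P"` or `"2P"`.
#' @export
setClass("PolarizationStack",
  representation(frames = "array", angles = "numeric", modality = "character"))

setValidity("PolarizationStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("frames must be a 3-D array (rows x cols x frames)")
  ang <- object@angles
  if (d[3] != length(ang))
    msg <- c(msg, "number of frames must match number of angles")
  if (length(ang) < 4L)
    msg <- c(msg, "at least 4 frames are required")
  if (length(ang) >= 2L) {
    st <- diff(ang)
    if (any(st <= 0)) msg <- c(msg, "angles must be strictly increasing")
    if (diff(range(st)) > 1e-6) msg <- c(msg, "angle step must be uniform")
    span <- min((length(ang) - 1) * st[1], 180 - st[1])
    if ((length(ang) - 1) * st[1] < 165 - 1e-6 && span < 165 - 1e-6)
      msg <- c(msg, "angles must span >= 165 degrees of unique directions mod 180")
  }
  if (!object@modality %in% c("1P", "2P"))
    msg <- c(msg, "modality must be '1P' or '2P'")
  if (length(msg)) msg else TRUE
})

#' PixelLDMap: per-pixel linear dichroism results
#'
#' Produced by [dichroicRatioMap()] (pair mode: `ld` holds the dichroic
#' ratio r = Fh/Fv) or [fitStackPerPixel()] (stack mode: `ld` holds
#' r_max = Fmax/Fmin from the per-pixel cos^2 fit and `azimuth` the
#' polarization direction of maximal fluorescence).
#'
#' @slot intensity total-intensity matrix.
#' @slot ld dichroic-ratio matrix (r or r_max); `NA` where invalid.
#' @slot azimuth azimuth matrix in degrees mod 180 (stack mode; all-`NA` in
#'   pair mode).
#' @slot valid logical matrix of analyzable pixels.
#' @slot fitParams list with matrices `a`, `b`, `c` of the per-pixel
#'   `F = A + B cos^2(theta - C)` fit (stack mode; empty otherwise).
#' @slot mode `"pair"` or `"stack"`.
#' @export
setClass("PixelLDMap",
  representation(intensity = "matrix", ld = "matrix", azimuth = "matrix",
                 valid = "matrix", fitParams = "list", mode = "character"))

setValidity("PixelLDMap", function(object) {
  msg <- character()
  d <- dim(object@intensity)
  for (s in c("ld", "azimuth", "valid"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, sprintf("%s must match intensity dimensions", s))
  if (!object@mode %in% c("pair", "stack"))
    msg <- c(msg, "mode must be 'pair' or 'stack'")
  ldv <- object@ld[object@valid]
  if (length(ldv) && any(ldv < 0, na.rm = TRUE))
    msg <- c(msg, "ld must be >= 0 wherever valid")
  azv <- object@azimuth[!is.na(object@azimuth)]
  if (length(azv) && (any(azv < 0) || any(azv >= 180)))
    msg <- c(msg, "azimuth must lie in [0, 180)")
  if (length(msg)) msg else TRUE
})

#' SplineOutline: smooth approximation of a feature outline
#'
#' A cubic-spline approximation of a segmented feature (vesicle outline,
#' filament), densely resampled with local tangent angles, used to assign
#' an orientation theta to nearby pixels.
#'
#' @slot anchors matrix of anchor points (columns `x`, `y`, 0-based pixel
#'   coordinates).
#' @slot closed logical; closed outlines wrap around.
#' @slot samples data.frame with columns `x`, `y`, `tangent` (degrees mod
#'   180) at <= 0.5 px arc spacing.
#' @export
setClass("SplineOutline",
  representation(anchors = "matrix", closed = "logical", samples = "data.frame"))

setValidity("SplineOutline", function(object) {
  msg <- character()
  if (!all(c("x", "y", "tangent") %in% names(object@samples)))
    msg <- c(msg, "samples must have columns x, y, tangent")
  tg <- object@samples$tangent
  if (length(tg)) {
    if (any(tg < 0 | tg >= 180)) msg <- c(msg, "tangents must lie in [0, 180)")
    dd <- abs(diff(tg)); dd <- pmin(dd, 180 - dd)
    if (any(dd > 30)) msg <- c(msg, "adjacent tangent angles must differ < 30 degrees")
  }
  if (length(msg)) msg else TRUE
})

#' ThetaSamples: the quantitation currency
#'
#' Pairs of feature orientation theta and log2 dichroic ratio extracted
#' from the analyzed pixels of one object, with intensity-derived weights.
#'
#' @slot samples data.frame with columns `theta` (degrees in \[0, 180)),
#'   `log2r` (finite), `weight` (nonnegative).
#' @slot modality `"1P"` or `"2P"`.
#' @slot geometry `"membrane"` or `"filament"`.
#' @slot objectId character identifier of the source object.
#' @export
setClass("ThetaSamples",
  representation(samples = "data.frame", modality = "character",
                 geometry = "character", objectId = "character"))

setValidity("ThetaSamples", function(object) {
  msg <- character()
  s <- object@samples
  if (!all(c("theta", "log2r", "weight") %in% names(s)))
    return("samples must have columns theta, log2r, weight")
  if (nrow(s)) {
    if (any(s$theta < 0 | s$theta >= 180)) msg <- c(msg, "theta must lie in [0, 180)")
    if (any(!is.finite(s$log2r))) msg <- c(msg, "log2r must be finite")
    if (any(s$weight < 0)) msg <- c(msg, "weights must be >= 0")
  }
  if (!object@modality %in% c("1P", "2P")) msg <- c(msg, "bad modality")
  if (!object@geometry %in% c("membrane", "filament")) msg <- c(msg, "bad geometry")
  if (length(msg)) msg else TRUE
})

#' Fit1PResult: parametric fit of a 1P dichroic-ratio curve
#'
#' Parameters of the single-photon LD curve
#' `log2 r(theta) = A1P + log2((1 + B1P cos 2(theta - phi1)) /
#' (1 - B1P cos 2(theta - phi2)))`.
#'
#' @slot a1p offset in log2 units.
#' @slot b1pFit amplitude parameter in \[0, 1).
#' @slot phi1,phi2 phase angles (degrees).
#' @slot log2rmax signed extremum of the fitted curve with largest
#'   magnitude (log2 of r_max).
#' @slot r2,rmsd,chi2 goodness of fit (r2 is `NA` for zero-variance data).
#' @slot n number of samples fitted.
#' @export
setClass("Fit1PResult",
  representation(a1p = "numeric", b1pFit = "numeric", phi1 = "numeric",
                 phi2 = "numeric", log2rmax = "numeric", r2 = "numeric",
                 rmsd = "numeric", chi2 = "numeric", n = "integer"))

#' Fit2PResult: parametric fit of a 2P dichroic-ratio curve
#'
#' Parameters of the two-photon LD curve
#' `log2 r(theta) = A2P + log2((1 + B2P cos 2(theta - phi1) +
#' C2P cos 4(theta - phi1)) / (1 - B2P cos 2(theta - phi2) +
#' C2P cos 4(theta - phi2)))`. In restricted mode the shape parameters
#' (B2P, C2P) are constrained to those generated by a wrapped-Gaussian tilt
#' distribution, and the best (alpha0, sigma) is reported.
#'
#' @slot a2p offset in log2 units.
#' @slot b2pFit,c2pFit shape parameters in the symmetry-axis convention
#'   (`F(beta) = 1 + b2p cos 2 beta + c2p cos 4 beta`); for membrane
#'   geometry the theta-space cos-2 coefficient has the opposite sign.
#' @slot phi1,phi2 phase angles (degrees).
#' @slot restricted logical.
#' @slot alpha0,sigma best wrapped-Gaussian parameters (restricted mode;
#'   `NA` otherwise).
#' @slot log2rmax,r2,rmsd,chi2,n as in [Fit1PResult-class].
#' @export
setClass("Fit2PResult",
  representation(a2p = "numeric", b2pFit = "numeric", c2pFit = "numeric",
                 phi1 = "numeric", phi2 = "numeric", restricted = "logical",
                 alpha0 = "numeric", sigma = "numeric", log2rmax = "numeric",
                 r2 = "numeric", rmsd = "numeric", chi2 = "numeric",
                 n = "integer"))

#' GoodnessMap: agreement between LD data and tilt distributions
#'
#' Goodness of fit (r2, RMSD, chi-squared) between observed (theta, log2 r)
#' data and the ideal curves of every wrapped-Gaussian tilt distribution on
#' an (alpha0, sigma) grid, with per-cell offsets profiled out. Displayed
#' as heat maps; the best-fitting cell and (optionally) a bootstrap
#' confidence mask are recorded.
#'
#' @slot alpha0,sigma parameter grids (degrees).
#' @slot r2,rmsd,chi2 goodness matrices (`length(alpha0) x length(sigma)`).
#' @slot best numeric vector `c(alpha0, sigma)` of the best cell.
#' @slot confidence logical matrix (bootstrap confidence mask; all-`FALSE`
#'   until filled by [bootstrapConfidence()]).
#' @slot modality `"1P"`, `"2P"` or `"combined"`.
#' @export
setClass("GoodnessMap",
  representation(alpha0 = "numeric", sigma = "numeric", r2 = "matrix",
                 rmsd = "matrix", chi2 = "matrix", best = "numeric",
                 confidence = "matrix", modality = "character"))

setValidity("GoodnessMap", function(object) {
  msg <- character()
  dims <- c(length(object@alpha0), length(object@sigma))
  for (s in c("r2", "rmsd", "chi2", "confidence"))
    if (!identical(dim(slot(object, s)), as.integer(dims)))
      msg <- c(msg, sprintf("%s matrix must be %d x %d", s, dims[1], dims[2]))
  if (length(object@best) != 2L)
    msg <- c(msg, "best must be c(alpha0, sigma)")
  if (any(object@confidence) && length(object@best) == 2L) {
    i <- which.min(abs(object@alpha0 - object@best[1]))
    j <- which.min(abs(object@sigma - object@best[2]))
    if (!object@confidence[i, j])
      msg <- c(msg, "confidence mask must contain the best cell")
  }
  if (length(msg)) msg else TRUE
})

#' SceneSpec: specification of a synthetic polarization-microscopy scene
#'
#' Ground-truth generator input: a bright object (vesicle equatorial ring
#' or filament segment) carrying fluorophores with a known tilt
#' distribution, imaged as a polarization pair, a mixed-polarization frame,
#' or a multi-angle stack, with photon noise, background, bleed-through and
#' bleaching.
#'
#' @slot object list: `type` (`"ring"` or `"segment"`), plus `center`,
#'   `radius`, `width` (ring) or `anchors`, `width` (segment); pixels.
#' @slot distribution a [TiltDistribution-class].
#' @slot modality `"1P"` or `"2P"`.
#' @slot acquisition list: `mode` (`"pair"`, `"mixed"`, `"stack"`), plus
#'   `angles` (stack) or `scheme`/`phase` (mixed).
#' @slot photons expected peak photon count per pixel per polarization.
#' @slot background expected background counts per pixel.
#' @slot bleedK bleed-through fraction mixed between channels.
#' @slot bleach per-frame intensity retention factor (stacks; 1 = none).
#' @slot size image size `c(nrow, ncol)`.
#' @slot seed integer seed for the photon noise.
#' @export
setClass("SceneSpec",
  representation(object = "list", distribution = "TiltDistribution",
                 modality = "character", acquisition = "list",
                 photons = "numeric", background = "numeric",
                 bleedK = "numeric", bleach = "numeric", size = "integer",
                 seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  ob <- object@object
  if (!ob$type %in% c("ring", "segment")) msg <- c(msg, "object type must be ring or segment")
  if (identical(ob$type, "ring")) {
    if (ob$radius < 5) msg <- c(msg, "ring radius must be >= 5 px")
    if (ob$radius > max(object@size)) msg <- c(msg, "ring radius exceeds image size")
  }
  if (object@photons < 0) msg <- c(msg, "photons must be >= 0")
  if (!object@acquisition$mode %in% c("pair", "mixed", "stack"))
    msg <- c(msg, "acquisition mode must be pair, mixed or stack")
  if (length(msg)) msg else TRUE
})
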
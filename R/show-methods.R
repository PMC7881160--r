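## show() methods and accessors.

#' @rdname TiltDistribution-class
#' @param object,x the object.
#' @export
setMethod("show", "TiltDistribution", function(object) {
  cmp <- object@components
  cat(sprintf("TiltDistribution (%s), %d component(s)\n", object@geometry,
              nrow(cmp)))
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  alpha0 = %6.2f deg  sigma = %6.2f deg  weight = %.3f\n",
                cmp[i, "alpha0"], cmp[i, "sigma"], cmp[i, "weight"]))
  invisible(NULL)
})

#' @rdname TiltDistribution-class
#' @export
tiltComponents <- function(x) x@components

#' @rdname TiltDistribution-class
#' @export
tiltGeometry <- function(x) x@geometry

#' @rdname AbsorptionMoments-class
#' @export
setMethod("show", "AbsorptionMoments", function(object) {
  cat(sprintf("AbsorptionMoments: m2 = %.6f, m4 = %.6f\n",
              object@m2, object@m4))
  invisible(NULL)
})

#' @rdname AbsorptionMoments-class
#' @param x an `AbsorptionMoments`.
#' @export
absorptionMoments <- function(x) c(m2 = x@m2, m4 = x@m4)

#' @rdname DichroicShapeParams-class
#' @export
setMethod("show", "DichroicShapeParams", function(object) {
  cat(sprintf("DichroicShapeParams: b1p = %.5f, b2p = %.5f, c2p = %.5f\n",
              object@b1p, object@b2p, object@c2p))
  invisible(NULL)
})

#' @rdname DichroicShapeParams-class
#' @param x a `DichroicShapeParams`.
#' @export
dichroicParams <- function(x) c(b1p = x@b1p, b2p = x@b2p, c2p = x@c2p)

#' @rdname LDLookupTable-class
#' @export
setMethod("show", "LDLookupTable", function(object) {
  cat(sprintf("LDLookupTable: %d alpha0 x %d sigma cells (alpha0 %g..%g, sigma %g..%g deg)\n",
              length(object@alpha0), length(object@sigma),
              min(object@alpha0), max(object@alpha0),
              min(object@sigma), max(object@sigma)))
  invisible(NULL)
})

#' @rdname PolarizationPair-class
#' @export
setMethod("show", "PolarizationPair", function(object) {
  cat(sprintf("PolarizationPair (%s): %d x %d px, <fh> = %.1f, <fv> = %.1f\n",
              object@modality, nrow(object@fh), ncol(object@fh),
              mean(object@fh), mean(object@fv)))
  invisible(NULL)
})

#' @rdname PolarizationStack-class
#' @export
setMethod("show", "PolarizationStack", function(object) {
  cat(sprintf("PolarizationStack (%s): %d frames of %d x %d px, angles %g..%g deg (step %g)\n",
              object@modality, dim(object@frames)[3], dim(object@frames)[1],
              dim(object@frames)[2], min(object@angles), max(object@angles),
              diff(object@angles)[1]))
  invisible(NULL)
})

#' @rdname PixelLDMap-class
#' @export
setMethod("show", "PixelLDMap", function(object) {
  nv <- sum(object@valid)
  cat(sprintf("PixelLDMap (%s mode): %d x %d px, %d valid (%.1f%%)\n",
              object@mode, nrow(object@intensity), ncol(object@intensity),
              nv, 100 * nv / length(object@valid)))
  if (nv) {
    l2 <- log2(object@ld[object@valid])
    cat(sprintf("  log2(r): median %.3f, IQR [%.3f, %.3f]\n",
                stats::median(l2, na.rm = TRUE),
                stats::quantile(l2, 0.25, na.rm = TRUE, names = FALSE),
                stats::quantile(l2, 0.75, na.rm = TRUE, names = FALSE)))
  }
  invisible(NULL)
})

#' @rdname PixelLDMap-class
#' @param x a `PixelLDMap`.
#' @export
ldValues <- function(x) x@ld

#' @rdname PixelLDMap-class
#' @export
azimuthValues <- function(x) x@azimuth

#' @rdname PixelLDMap-class
#' @export
validMask <- function(x) x@valid

#' @rdname SplineOutline-class
#' @export
setMethod("show", "SplineOutline", function(object) {
  cat(sprintf("SplineOutline (%s): %d anchors, %d dense samples\n",
              if (object@closed) "closed" else "open", nrow(object@anchors),
              nrow(object@samples)))
  invisible(NULL)
})

#' @rdname SplineOutline-class
#' @param x a `SplineOutline`.
#' @export
outlineSamples <- function(x) x@samples

#' @rdname ThetaSamples-class
#' @export
setMethod("show", "ThetaSamples", function(object) {
  cat(sprintf("ThetaSamples '%s' (%s, %s): %d samples, theta span %.1f deg\n",
              object@objectId, object@modality, object@geometry,
              nrow(object@samples), .thetaSpan(object@samples$theta)))
  invisible(NULL)
})

#' @rdname ThetaSamples-class
#' @param x a `ThetaSamples`.
#' @export
thetaSamplesData <- function(x) x@samples

#' @rdname Fit1PResult-class
#' @export
setMethod("show", "Fit1PResult", function(object) {
  cat(sprintf(paste0("Fit1PResult: A = %.4f, B1P = %.4f, phi = (%.1f, %.1f) deg\n",
                     "  log2(rmax) = %.4f, r2 = %.4f, RMSD = %.4f, n = %d\n"),
              object@a1p, object@b1pFit, object@phi1, object@phi2,
              object@log2rmax, object@r2, object@rmsd, object@n))
  invisible(NULL)
})

#' @rdname Fit2PResult-class
#' @export
setMethod("show", "Fit2PResult", function(object) {
  cat(sprintf("Fit2PResult (%s): A = %.4f, B2P = %.4f, C2P = %.4f, phi = (%.1f, %.1f) deg\n",
              if (object@restricted) "restricted" else "unrestricted",
              object@a2p, object@b2pFit, object@c2pFit, object@phi1,
              object@phi2))
  if (object@restricted)
    cat(sprintf("  best alpha0 = %g deg, sigma = %g deg\n", object@alpha0,
                object@sigma))
  cat(sprintf("  log2(rmax) = %.4f, r2 = %.4f, RMSD = %.4f, n = %d\n",
              object@log2rmax, object@r2, object@rmsd, object@n))
  invisible(NULL)
})

#' @rdname GoodnessMap-class
#' @export
setMethod("show", "GoodnessMap", function(object) {
  cat(sprintf("GoodnessMap (%s): %d x %d cells, best (alpha0, sigma) = (%g, %g) deg\n",
              object@modality, length(object@alpha0), length(object@sigma),
              object@best[1], object@best[2]))
  if (any(object@confidence))
    cat(sprintf("  confidence mask: %d cells\n", sum(object@confidence)))
  invisible(NULL)
})

#' @rdname GoodnessMap-class
#' @param x a `GoodnessMap`.
#' @export
bestCell <- function(x) x@best

#' @rdname GoodnessMap-class
#' @export
r2Slice <- function(x) x@r2

#' @rdname GoodnessMap-class
#' @export
confidenceMask <- function(x) x@confidence

#' @rdname SceneSpec-class
#' @export
setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %s, %s, %s acquisition, %g peak photons, %d x %d px\n",
              object@object$type, object@modality, object@acquisition$mode,
              object@photons, object@size[1], object@size[2]))
  invisible(NULL)
})
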
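#' @include AllClasses.R
NULL

#' Compute absorption moments of a tilt distribution
#'
#' Integrates `cos^2(alpha)` and `cos^4(alpha)` over the tilt density
#' `p(alpha)` on \[0, 90\] degrees. Mixtures are weight-linear in the
#' moments.
#'
#' @param dist a [TiltDistribution-class].
#' @param ... further arguments passed to methods.
#' @return an [AbsorptionMoments-class].
#' @export
setGeneric("computeMoments", function(dist, ...) standardGeneric("computeMoments"))

#' Predict the ideal log2 dichroic-ratio curve
#'
#' Evaluates `log2(F(beta) / F(beta + 90))` for the requested excitation
#' modality, where beta is derived from theta by the geometry convention
#' (membrane: `beta = 90 - theta`; filament: `beta = theta`). This is the
#' ideal (offset-free, in-phase) form of the 1P/2P dichroic-ratio curves.
#'
#' @param object a [TiltDistribution-class] or [DichroicShapeParams-class].
#' @param thetas angles theta in degrees.
#' @param modality `"1P"` or `"2P"`.
#' @param ... further arguments passed to methods; for shape-parameter
#'   input, `geometry` (`"membrane"` or `"filament"`) must be given.
#' @return numeric vector of log2 r values; pixels where the denominator
#'   vanishes yield signed `Inf` sentinels (an attribute `"infinite"` marks
#'   them).
#' @export
setGeneric("predictLog2r",
  function(object, thetas, modality = c("1P", "2P"), ...)
    standardGeneric("predictLog2r"))
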
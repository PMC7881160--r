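## Photoselection forward model: wrapped-Gaussian tilt distributions ->
## absorption moments -> dichroic shape parameters -> ideal log2 r(theta)
## curves, plus the precomputed lookup table and the Monte-Carlo oracle.

.DEG <- pi / 180
## quadrature grid for moments: trapezoid at 0.05 deg on [0, 90]
.ALPHA_GRID <- seq(0, 90, by = 0.05)
.WRAP_K <- -4:4

.polarLDCache <- new.env(parent = emptyenv())

#' Construct a tilt distribution
#'
#' @param alpha0 mean tilt angle(s) in degrees, in \[0, 90\]; length 1 or 2.
#' @param sigma distribution width(s) in degrees, > 0; same length.
#' @param weight component weights summing to 1; default equal weights.
#' @param geometry `"membrane"` or `"filament"`.
#' @return a [TiltDistribution-class].
#' @examples
#' d <- tiltDistribution(90, 10)
#' computeMoments(d)
#' @export
tiltDistribution <- function(alpha0, sigma, weight = NULL,
                             geometry = c("membrane", "filament")) {
  geometry <- match.arg(geometry)
  if (is.null(weight)) weight <- rep(1 / length(alpha0), length(alpha0))
  if (length(sigma) != length(alpha0) || length(weight) != length(alpha0))
    stop("alpha0, sigma and weight must have equal lengths")
  cmp <- cbind(alpha0 = alpha0, sigma = sigma, weight = weight)
  methods::new("TiltDistribution", components = cmp, geometry = geometry)
}

## Unnormalized tilt density of one Gaussian component on a grid in [0, 90]:
## wrapped sum over periods (|k| <= 4), mirrored about 0 (alpha is an axis)
## and folded about 90, times the solid-angle factor sin(alpha).
.tiltDensityRaw <- function(alpha0, sigma, alpha = .ALPHA_GRID) {
  sigma <- max(sigma, 0.01)
  ## wrapped, mirrored (alpha is an axis) Gaussian; folding about 90 merely
  ## doubles this mean family (fold(-a0 + 180k) = a0 + 180(1 - k)), so the
  ## means are not duplicated explicitly. The wrap truncation widens with
  ## sigma so very broad distributions stay flat (|k| <= 5 covers the
  ## default range up to sigma ~ 90 deg).
  kmax <- max(5, ceiling((8 * sigma + 90) / 180) + 1)
  mu <- c(outer(180 * (-kmax:kmax), c(alpha0, -alpha0), "+"))
  mu <- mu[mu > -8 * sigma - 1 & mu < 90 + 8 * sigma + 1]
  g <- numeric(length(alpha))
  for (m in mu) g <- g + exp(-((alpha - m)^2) / (2 * sigma^2))
  g * sin(alpha * .DEG)
}

#' Tilt-angle density of a distribution
#'
#' Normalized density of the TDM tilt angle alpha on \[0, 90\] degrees,
#' including the solid-angle factor sin(alpha) implied by free rotation
#' about the symmetry axis.
#'
#' @param dist a [TiltDistribution-class].
#' @param alpha evaluation grid in degrees (uniformly spaced).
#' @return numeric density values (integrates to 1 over `alpha`).
#' @export
tiltDensity <- function(dist, alpha = .ALPHA_GRID) {
  methods::validObject(dist)
  cmp <- dist@components
  p <- numeric(length(alpha))
  for (i in seq_len(nrow(cmp))) {
    pi0 <- .tiltDensityRaw(cmp[i, "alpha0"], cmp[i, "sigma"], alpha)
    p <- p + cmp[i, "weight"] * pi0 / pracma::trapz(alpha, pi0)
  }
  p
}

.momentsOfComponent <- function(alpha0, sigma) {
  if (sigma < 0.01) {                    # delta shortcut
    ca <- cos(alpha0 * .DEG)
    return(c(m2 = ca^2, m4 = ca^4))
  }
  p <- .tiltDensityRaw(alpha0, sigma)
  ca2 <- cos(.ALPHA_GRID * .DEG)^2
  z <- pracma::trapz(.ALPHA_GRID, p)
  c(m2 = pracma::trapz(.ALPHA_GRID, p * ca2) / z,
    m4 = pracma::trapz(.ALPHA_GRID, p * ca2^2) / z)
}

#' @describeIn computeMoments trapezoidal quadrature at 0.05 degree step
#'   (delta shortcut below sigma = 0.01 degrees).
#' @export
setMethod("computeMoments", "TiltDistribution", function(dist, ...) {
  methods::validObject(dist)
  cmp <- dist@components
  mm <- c(0, 0)
  for (i in seq_len(nrow(cmp)))
    mm <- mm + cmp[i, "weight"] *
      .momentsOfComponent(cmp[i, "alpha0"], cmp[i, "sigma"])
  methods::new("AbsorptionMoments", m2 = unname(mm[1]), m4 = unname(mm[2]))
})

#' Convert absorption moments to dichroic shape parameters
#'
#' With beta the angle between the excitation polarization and the symmetry
#' axis, averaging the 1P and 2P excitation probabilities over the free
#' rotation rho gives
#' `F1P(beta) = m2 cos^2 b + ((1 - m2)/2) sin^2 b` and
#' `F2P(beta) = m4 cos^4 b + 3 (m2 - m4) cos^2 b sin^2 b +
#'  (3/8) (1 - 2 m2 + m4) sin^4 b`.
#' This returns their Fourier coefficients normalized by the DC term:
#' `b1p = (3 m2 - 1) / (m2 + 1)`, and `b2p`, `c2p` the cos(2 beta) and
#' cos(4 beta) coefficients of F2P divided by its DC coefficient.
#'
#' @param moments an [AbsorptionMoments-class], or a numeric m2 when `m4`
#'   is given separately.
#' @param m4 optional numeric m4 (when `moments` is numeric m2).
#' @return a [DichroicShapeParams-class].
#' @examples
#' momentsToShapeParams(1/3, 1/5)   # isotropy: no LD
#' @export
momentsToShapeParams <- function(moments, m4 = NULL) {
  if (methods::is(moments, "AbsorptionMoments")) {
    m2 <- moments@m2; m4 <- moments@m4
  } else {
    m2 <- moments
    if (is.null(m4)) stop("m4 must be supplied when moments is numeric")
  }
  P <- m4
  Q <- 3 * (m2 - m4)
  R <- (3 / 8) * (1 - 2 * m2 + m4)
  dc <- 3 * P / 8 + Q / 8 + 3 * R / 8
  methods::new("DichroicShapeParams",
    b1p = (3 * m2 - 1) / (m2 + 1),
    b2p = (P / 2 - R / 2) / dc,
    c2p = (P / 8 - Q / 8 + R / 8) / dc)
}

#' Shape parameters of a tilt distribution
#'
#' Convenience composition of [computeMoments()] and
#' [momentsToShapeParams()].
#'
#' @param dist a [TiltDistribution-class].
#' @return a [DichroicShapeParams-class].
#' @export
shapeParams <- function(dist) momentsToShapeParams(computeMoments(dist))

.thetaToBeta <- function(thetas, geometry) {
  switch(geometry, membrane = 90 - thetas, filament = thetas,
         stop("geometry must be 'membrane' or 'filament'"))
}

.predictFromParams <- function(params, thetas, modality, geometry) {
  stopifnot(all(is.finite(thetas)))
  ## canonicalize theta to [0, 90) and negate on the other half-period, so
  ## the antisymmetry log2 r(theta + 90) = -log2 r(theta) holds exactly
  eta <- thetas %% 180
  flip <- eta >= 90
  eta[flip] <- eta[flip] - 90
  beta <- .thetaToBeta(eta, geometry) * .DEG
  c2 <- cos(2 * beta)
  if (identical(modality, "1P")) {
    num <- 1 + params@b1p * c2
    den <- 1 - params@b1p * c2
  } else {
    c4 <- cos(4 * beta)
    num <- 1 + params@b2p * c2 + params@c2p * c4
    den <- 1 - params@b2p * c2 + params@c2p * c4
  }
  num <- pmax(num, 0)
  den <- pmax(den, 0)
  out <- log2(num) - log2(den)
  out[num == 0 & den == 0] <- 0
  out[flip] <- -out[flip]
  attr(out, "infinite") <- !is.finite(out)
  out
}

#' @describeIn predictLog2r from precomputed shape parameters; `geometry`
#'   is required.
#' @param geometry `"membrane"` or `"filament"` (shape-parameter method).
#' @export
setMethod("predictLog2r", "DichroicShapeParams",
  function(object, thetas, modality = c("1P", "2P"),
           geometry = c("membrane", "filament"), ...) {
    .predictFromParams(object, thetas, match.arg(modality),
                       match.arg(geometry))
  })

#' @describeIn predictLog2r from a tilt distribution; geometry is taken
#'   from the distribution.
#' @export
setMethod("predictLog2r", "TiltDistribution",
  function(object, thetas, modality = c("1P", "2P"), ...) {
    .predictFromParams(shapeParams(object), thetas, match.arg(modality),
                       object@geometry)
  })

#' Precompute dichroic shape parameters over an (alpha0, sigma) grid
#'
#' Tabulates `b1p`, `b2p`, `c2p` for every combination of mean tilt angle
#' and width, for use by the inverse inference. Deterministic; the table
#' can be cached to a CSV sidecar with [writeLookupTable()].
#'
#' @param alpha0Grid mean tilt angles in degrees, default `0:90`.
#' @param sigmaGrid widths in degrees, default `1:90`.
#' @return an [LDLookupTable-class].
#' @export
buildLookupTable <- function(alpha0Grid = 0:90, sigmaGrid = 1:90) {
  if (!length(alpha0Grid) || !length(sigmaGrid))
    stop("lookup grids must be non-empty")
  if (any(alpha0Grid < 0 | alpha0Grid > 90))
    stop("alpha0 grid must lie in [0, 90] degrees")
  if (any(sigmaGrid <= 0))
    stop("sigma grid must be positive")
  for (g in list(alpha0Grid, sigmaGrid))
    if (length(g) > 1 && min(diff(g)) < 0.1 - 1e-12)
      stop("grid step must be >= 0.1 degrees")
  na <- length(alpha0Grid); ns <- length(sigmaGrid)
  b1p <- b2p <- c2p <- matrix(NA_real_, na, ns)
  ca2 <- cos(.ALPHA_GRID * .DEG)^2
  ca4 <- ca2^2
  for (j in seq_len(ns)) for (i in seq_len(na)) {
    p <- .tiltDensityRaw(alpha0Grid[i], sigmaGrid[j])
    z <- pracma::trapz(.ALPHA_GRID, p)
    sp <- momentsToShapeParams(pracma::trapz(.ALPHA_GRID, p * ca2) / z,
                               pracma::trapz(.ALPHA_GRID, p * ca4) / z)
    b1p[i, j] <- sp@b1p; b2p[i, j] <- sp@b2p; c2p[i, j] <- sp@c2p
  }
  methods::new("LDLookupTable", alpha0 = as.numeric(alpha0Grid),
               sigma = as.numeric(sigmaGrid), b1p = b1p, b2p = b2p, c2p = c2p)
}

#' Default lookup table (1 degree grid), cached per session
#'
#' @return the [LDLookupTable-class] on the default `0:90` x `1:90` grid.
#' @export
defaultLookupTable <- function() {
  if (is.null(.polarLDCache$defaultTable))
    .polarLDCache$defaultTable <- buildLookupTable()
  .polarLDCache$defaultTable
}

#' Interpolate shape parameters from a lookup table
#'
#' Bilinear interpolation of `b1p`, `b2p`, `c2p` at an (alpha0, sigma)
#' point inside the table grid.
#'
#' @param table an [LDLookupTable-class].
#' @param alpha0,sigma query point (degrees).
#' @return a [DichroicShapeParams-class].
#' @export
lookupShapeParams <- function(table, alpha0, sigma) {
  bil <- function(m) {
    i <- findInterval(alpha0, table@alpha0, all.inside = TRUE)
    j <- findInterval(sigma, table@sigma, all.inside = TRUE)
    x1 <- table@alpha0[i]; x2 <- table@alpha0[i + 1]
    y1 <- table@sigma[j];  y2 <- table@sigma[j + 1]
    tx <- if (x2 > x1) (alpha0 - x1) / (x2 - x1) else 0
    ty <- if (y2 > y1) (sigma - y1) / (y2 - y1) else 0
    (1 - tx) * (1 - ty) * m[i, j] + tx * (1 - ty) * m[i + 1, j] +
      (1 - tx) * ty * m[i, j + 1] + tx * ty * m[i + 1, j + 1]
  }
  if (alpha0 < min(table@alpha0) || alpha0 > max(table@alpha0) ||
      sigma < min(table@sigma) || sigma > max(table@sigma))
    stop("query point outside the lookup grid")
  methods::new("DichroicShapeParams",
               b1p = bil(table@b1p), b2p = bil(table@b2p), c2p = bil(table@c2p))
}

#' Monte-Carlo oracle: sample TDM orientations and average excitation terms
#'
#' Draws tilt angles alpha from the tilt density by inverse-CDF lookup on a
#' dense grid and the rotation rho uniformly, builds unit TDM vectors, and
#' averages `(mu . e)^2` and `(mu . e)^4` directly. Serves as the
#' brute-force reference for the quadrature moments and the predicted
#' curves; it shares no code path with [computeMoments()].
#'
#' @param dist a [TiltDistribution-class].
#' @param n number of draws (>= 1).
#' @param seed integer seed; the global RNG state is restored on exit.
#' @param betas optional polarization angles beta (degrees, from the
#'   symmetry axis) at which to average the excitation terms.
#' @return list with `m2`, `m4`, their standard errors `se2`, `se4`, the
#'   moments as an [AbsorptionMoments-class] (`moments`), and, when `betas`
#'   is given, a data.frame `beta` with columns `beta`, `f1p`, `se1p`,
#'   `f2p`, `se2p`.
#' @export
sampleOrientationsMC <- function(dist, n, seed = 1L, betas = NULL) {
  stopifnot(n >= 1)
  methods::validObject(dist)
  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  cmp <- dist@components
  comp <- if (nrow(cmp) == 1L) rep(1L, n) else
    sample.int(nrow(cmp), n, replace = TRUE, prob = cmp[, "weight"])
  alpha <- numeric(n)
  for (i in seq_len(nrow(cmp))) {
    idx <- which(comp == i)
    if (!length(idx)) next
    if (cmp[i, "sigma"] < 0.01) {
      alpha[idx] <- cmp[i, "alpha0"]
    } else {
      p <- .tiltDensityRaw(cmp[i, "alpha0"], cmp[i, "sigma"])
      np <- length(p)
      cdf <- c(0, cumsum((p[-1] + p[-np]) / 2))   # mass up to each grid point
      cdf <- cdf / cdf[np]
      alpha[idx] <- stats::approx(cdf, .ALPHA_GRID, runif(length(idx)),
                                  ties = "ordered", rule = 2)$y
    }
  }
  ca <- cos(alpha * .DEG)
  c2 <- ca^2; c4 <- c2^2
  out <- list(m2 = mean(c2), m4 = mean(c4),
              se2 = stats::sd(c2) / sqrt(n), se4 = stats::sd(c4) / sqrt(n))
  out$moments <- methods::new("AbsorptionMoments",
                              m2 = min(max(out$m2, 0), 1),
                              m4 = min(max(out$m4, out$m2^2), out$m2))
  if (!is.null(betas)) {
    rho <- runif(n, 0, 2 * pi)
    sa <- sin(alpha * .DEG)
    bt <- lapply(betas, function(b) {
      d <- cos(b * .DEG) * ca + sin(b * .DEG) * sa * cos(rho)
      d2 <- d^2; d4 <- d2^2
      c(f1p = mean(d2), se1p = stats::sd(d2) / sqrt(n),
        f2p = mean(d4), se2p = stats::sd(d4) / sqrt(n))
    })
    out$beta <- data.frame(beta = betas, do.call(rbind, bt))
  }
  out
}
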
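## Ground-truth scene generator: renders vesicle equatorial rings and
## filament segments as polarization pairs, mixed-polarization frames or
## multi-angle stacks, from a known tilt distribution, with photon noise,
## background, bleed-through and bleaching. The forward model of the
## orientation module drives every per-pixel intensity, so processing a
## rendered scene and recovering the distribution is a true round trip.

#' Construct a synthetic scene specification
#'
#' @param object list describing the bright object:
#'   `list(type = "ring", center = c(x, y), radius, width)` (a vesicle
#'   equatorial cross-section with a Gaussian radial profile of standard
#'   deviation `width` px) or `list(type = "segment", anchors, width)`
#'   (a filament polyline through the `n x 2` anchor matrix).
#' @param distribution a [TiltDistribution-class] (its geometry decides
#'   how tangents map to the symmetry axis).
#' @param modality `"1P"` or `"2P"`.
#' @param acquisition `list(mode = "pair")`,
#'   `list(mode = "mixed", scheme, phase)`, or
#'   `list(mode = "stack", angles)`.
#' @param photons expected peak photon count per pixel (at profile maximum
#'   and the polarization of maximal excitation).
#' @param background expected background counts per pixel.
#' @param bleedK bleed-through fraction mixed between the channels.
#' @param bleach per-frame retention factor for stacks (1 = no bleaching).
#' @param size image size `c(nrow, ncol)`.
#' @param seed integer seed for the photon noise.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(object = list(type = "ring", center = c(127.5, 127.5),
                                    radius = 60, width = 3),
                      distribution = tiltDistribution(90, 10),
                      modality = c("1P", "2P"),
                      acquisition = list(mode = "pair"),
                      photons = 1e4, background = 0, bleedK = 0,
                      bleach = 1, size = c(256L, 256L), seed = 1L) {
  methods::new("SceneSpec", object = object, distribution = distribution,
               modality = match.arg(modality), acquisition = acquisition,
               photons = photons, background = background, bleedK = bleedK,
               bleach = bleach, size = as.integer(size),
               seed = as.integer(seed))
}

## distance to the object midline and local tangent angle, per pixel
.sceneGeometry <- function(object, size) {
  x <- matrix(rep(seq_len(size[2]) - 1, each = size[1]), size[1])
  y <- matrix(rep(seq_len(size[1]) - 1, size[2]), size[1])
  if (identical(object$type, "ring")) {
    dx <- x - object$center[1]; dy <- y - object$center[2]
    rr <- sqrt(dx^2 + dy^2)
    list(dist = abs(rr - object$radius),
         tangent = ((atan2(dy, dx) / .DEG) + 90) %% 180)
  } else {
    a <- object$anchors
    dist <- matrix(Inf, size[1], size[2])
    tang <- matrix(0, size[1], size[2])
    for (i in seq_len(nrow(a) - 1)) {
      p <- a[i, ]; q <- a[i + 1, ]
      vx <- q[1] - p[1]; vy <- q[2] - p[2]
      len2 <- vx^2 + vy^2
      t <- pmin(pmax(((x - p[1]) * vx + (y - p[2]) * vy) / len2, 0), 1)
      d <- sqrt((x - (p[1] + t * vx))^2 + (y - (p[2] + t * vy))^2)
      upd <- d < dist
      dist[upd] <- d[upd]
      tang[upd] <- (atan2(vy, vx) / .DEG) %% 180
    }
    list(dist = dist, tangent = tang)
  }
}

## expected (noise-free) intensity at polarization angle chi (degrees)
.sceneExpected <- function(geo, object, params, modality, geometry,
                           photons, chi) {
  beta <- switch(geometry,
                 membrane = (chi - (geo$tangent + 90)) * .DEG,
                 filament = (chi - geo$tangent) * .DEG)
  f <- if (identical(modality, "1P")) {
    1 + params@b1p * cos(2 * beta)
  } else {
    1 + params@b2p * cos(2 * beta) + params@c2p * cos(4 * beta)
  }
  bg <- seq(0, 179, by = 1) * .DEG
  fmax <- if (identical(modality, "1P")) max(1 + params@b1p * cos(2 * bg))
    else max(1 + params@b2p * cos(2 * bg) + params@c2p * cos(4 * bg))
  profile <- exp(-geo$dist^2 / (2 * object$width^2))
  photons * profile * pmax(f, 0) / fmax
}

#' Render a synthetic scene with known ground truth
#'
#' Computes the analytic tangent of the object at every pixel, evaluates
#' the forward-model excitation probability for each acquisition
#' polarization, scales to photons, applies bleed-through mixing,
#' background, per-frame bleaching (stacks, in acquisition order) and
#' Poisson noise.
#'
#' @param scene a [SceneSpec-class].
#' @return list with `data` (a [PolarizationPair-class],
#'   [MixedPolarizationImage-class] or [PolarizationStack-class] according
#'   to the acquisition mode) and `truth` (list: `distribution`, `tangent`
#'   matrix, `noiseFree` channel list, `scene`).
#' @export
renderScene <- function(scene) {
  methods::validObject(scene)
  if (identical(scene@object$type, "ring") &&
      scene@object$radius > min(scene@size))
    stop("ring radius exceeds the image")
  geo <- .sceneGeometry(scene@object, scene@size)
  params <- shapeParams(scene@distribution)
  geometry <- scene@distribution@geometry
  expectedAt <- function(chi)
    .sceneExpected(geo, scene@object, params, scene@modality, geometry,
                   scene@photons, chi)
  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(scene@seed)
  mode <- scene@acquisition$mode
  noisy <- function(lam) {
    out <- matrix(stats::rpois(length(lam), lam + scene@background),
                  nrow(lam), ncol(lam))
    storage.mode(out) <- "double"
    out
  }
  if (mode %in% c("pair", "mixed")) {
    lamH <- expectedAt(0); lamV <- expectedAt(90)
    k <- scene@bleedK
    obsH <- noisy(lamH + k * lamV)
    obsV <- noisy(lamV + k * lamH)
    pair <- polarizationPair(obsH, obsV, scene@modality,
                             .defaultCalibration(NULL, NULL, k, 1))
    truth <- list(distribution = scene@distribution, tangent = geo$tangent,
                  noiseFree = list(fh = lamH, fv = lamV), scene = scene)
    if (identical(mode, "pair")) return(list(data = pair, truth = truth))
    mixed <- interleave(pair,
                        scheme = scene@acquisition$scheme %||% "per_pixel_column",
                        phase = scene@acquisition$phase %||% "h_first")
    return(list(data = mixed, truth = truth))
  }
  angles <- scene@acquisition$angles
  frames <- array(0, dim = c(scene@size, length(angles)))
  lam0 <- lapply(angles, expectedAt)
  for (i in seq_along(angles))
    frames[, , i] <- noisy(lam0[[i]] * scene@bleach^(i - 1))
  list(data = polarizationStack(frames, angles, scene@modality),
       truth = list(distribution = scene@distribution, tangent = geo$tangent,
                    noiseFree = lam0, scene = scene))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interleave a polarization pair into a mixed-polarization frame
#'
#' Samples each channel on its sub-grid according to the modulation scheme
#' and phase; the exact inverse of [deinterleave()] at the sampled
#' positions.
#'
#' @param pair a [PolarizationPair-class].
#' @param scheme,phase as in [MixedPolarizationImage-class].
#' @return a [MixedPolarizationImage-class].
#' @export
interleave <- function(pair, scheme = c("per_pixel_column", "per_pixel_row",
                                        "per_row"),
                       phase = c("h_first", "v_first")) {
  scheme <- match.arg(scheme)
  phase <- match.arg(phase)
  methods::validObject(pair)
  byCol <- identical(scheme, "per_pixel_column")
  fh <- if (byCol) pair@fh else t(pair@fh)
  fv <- if (byCol) pair@fv else t(pair@fv)
  n <- ncol(fh)
  if (n %% 2L != 0L) stop("extent along the modulation axis must be even")
  odd <- seq(1L, n, by = 2L); even <- seq(2L, n, by = 2L)
  mixed <- fh
  if (identical(phase, "h_first")) mixed[, even] <- fv[, even]
  else { mixed <- fv; mixed[, even] <- fh[, even] }
  if (!byCol) mixed <- t(mixed)
  mixedPolarizationImage(mixed, scheme, phase)
}
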
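## Object geometry: circle detection, segmentation, spline outlines and
## assignment of a local tangent angle theta to analyzed pixels.
##
## Coordinates are pixel-centered, 0-based, x to the right (columns) and
## y down (rows); angles in degrees from +x towards +y, reduced mod 180.

#' Detect the best-scoring circle by a Hough transform
#'
#' Accumulates, for every candidate radius, the mean image intensity along
#' the circle perimeter centered at each pixel (ring-kernel convolution)
#' and returns the highest-scoring (center, radius). Deterministic: score
#' ties are broken by the smaller center in row-major order, then by the
#' smaller radius.
#'
#' @param img intensity matrix with a bright ring.
#' @param radii candidate radii in pixels (rounded to integers).
#' @param scoreThreshold minimal accumulator score (mean perimeter
#'   intensity); default `0.1 * max(img)`. No peak above it is an error.
#' @return list with `center` (`c(x, y)`, 0-based), `radius`, `score`.
#' @export
detectCircle <- function(img, radii = 5:(min(dim(img)) %/% 2),
                         scoreThreshold = NULL) {
  stopifnot(all(is.finite(img)))
  if (is.null(scoreThreshold)) scoreThreshold <- 0.1 * max(img)
  radii <- sort(unique(pmax(round(radii), 1L)))
  best <- list(score = -Inf, center = c(NA, NA), radius = NA)
  for (r in radii) {
    sz <- 2L * r + 1L
    off <- seq_len(sz) - r - 1L
    dd <- sqrt(outer(off^2, off^2, "+"))
    kern <- (abs(dd - r) < 0.5) * 1
    kern <- kern / sum(kern)
    acc <- EBImage::filter2(img, kern, boundary = 0)
    sc <- max(acc)
    if (sc < best$score - 1e-12) next
    hits <- which(acc >= sc - 1e-12, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    cand <- list(score = sc,
                 center = c(hits[1, 2] - 1, hits[1, 1] - 1),  # (x, y)
                 radius = r)
    take <- sc > best$score + 1e-12 ||
      (abs(sc - best$score) <= 1e-12 &&
         (cand$center[2] < best$center[2] ||
            (cand$center[2] == best$center[2] &&
               cand$center[1] < best$center[1])))
    if (take) best <- cand
  }
  if (!is.finite(best$score) || best$score <= scoreThreshold)
    stop("no circle: no accumulator peak above threshold")
  best
}

#' Segment the analyzable outline of an object
#'
#' Builds a boolean mask of pixels to analyze, by one of three methods:
#' a band around a detected (or supplied) circle, Otsu thresholding, or an
#' externally supplied mask file/matrix (the reproducible stand-in for
#' manual segmentation). An optional eraser mask subtracts regions, which
#' reproduces manual exclusion of irregular membrane sections.
#'
#' @param img intensity matrix.
#' @param method `"circle"`, `"threshold"` or `"mask"`.
#' @param radii candidate radii for circle detection.
#' @param circle optional precomputed circle (list with `center`, `radius`)
#'   to skip detection.
#' @param band half-width of the circular band in pixels.
#' @param mask logical matrix for `method = "mask"`.
#' @param eraser optional logical matrix; `TRUE` pixels are excluded.
#' @return logical matrix mask.
#' @export
segmentOutline <- function(img, method = c("circle", "threshold", "mask"),
                           radii = 5:(min(dim(img)) %/% 2), circle = NULL,
                           band = 2, mask = NULL, eraser = NULL) {
  method <- match.arg(method)
  out <- switch(method,
    circle = {
      if (is.null(circle)) circle <- detectCircle(img, radii)
      x <- matrix(rep(seq_len(ncol(img)) - 1, each = nrow(img)), nrow(img))
      y <- matrix(rep(seq_len(nrow(img)) - 1, ncol(img)), nrow(img))
      dd <- sqrt((x - circle$center[1])^2 + (y - circle$center[2])^2)
      abs(dd - circle$radius) <= band
    },
    threshold = {
      mx <- max(img)
      if (mx <= 0) stop("empty result mask: image has no signal")
      th <- EBImage::otsu(EBImage::Image(img / mx), range = c(0, 1))
      img / mx > th
    },
    mask = {
      if (is.null(mask)) stop("method 'mask' requires a mask")
      mask
    })
  if (!is.null(eraser)) out <- out & !eraser
  if (!any(out)) stop("empty result mask")
  out
}

## pairwise segment-crossing check for anchor polylines (warning only)
.selfIntersects <- function(a, closed) {
  n <- nrow(a)
  segs <- cbind(seq_len(n - 1), seq(2, n))
  if (closed) segs <- rbind(segs, c(n, 1))
  cross <- function(o, p, q)
    (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  m <- nrow(segs)
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    s1 <- segs[i, ]; s2 <- segs[j, ]
    if (length(intersect(s1, s2))) next   # shared endpoint
    p1 <- a[s1[1], ]; p2 <- a[s1[2], ]; q1 <- a[s2[1], ]; q2 <- a[s2[2], ]
    d1 <- cross(p1, p2, q1); d2 <- cross(p1, p2, q2)
    d3 <- cross(q1, q2, p1); d4 <- cross(q1, q2, p2)
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  }
  FALSE
}

.anchorsFromMask <- function(mask, nAnchors = 16L) {
  rc <- which(mask, arr.ind = TRUE)
  x <- rc[, 2] - 1; y <- rc[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  phi <- atan2(y - cy, x - cx)
  bins <- cut(phi, breaks = seq(-pi, pi, length.out = nAnchors + 1),
              include.lowest = TRUE)
  ax <- tapply(x, bins, mean); ay <- tapply(y, bins, mean)
  keep <- !is.na(ax)
  cbind(x = as.numeric(ax[keep]), y = as.numeric(ay[keep]))
}

.resampleArc <- function(x, y, tangent, spacing = 0.4) {
  arc <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  s <- seq(0, arc[length(arc)], by = spacing)
  ## unwrap the mod-180 tangent for interpolation, then wrap back
  tw <- tangent
  for (i in seq_along(tw)[-1]) {
    d <- tw[i] - tw[i - 1]
    tw[i] <- tw[i] - 180 * round(d / 180)
  }
  data.frame(x = stats::approx(arc, x, s, ties = "ordered")$y,
             y = stats::approx(arc, y, s, ties = "ordered")$y,
             tangent = stats::approx(arc, tw, s, ties = "ordered")$y %% 180)
}

#' Fit a spline outline through a mask or anchor points
#'
#' Closed outlines (vesicle/cell cross-sections) are approximated by a
#' periodic cubic spline of the radius about the anchor centroid when the
#' anchors are star-shaped (exact on circles), falling back to a
#' chord-length parametric periodic cubic otherwise. Open outlines
#' (filaments) use a natural parametric cubic. The outline is densely
#' resampled at <= 0.5 px arc spacing with analytic tangent angles.
#'
#' @param x logical mask matrix, or an `n x 2` matrix of anchor points
#'   (columns x, y; 0-based pixel coordinates).
#' @param closed logical; closed outlines need >= 4 anchors, open >= 2.
#' @param nAnchors anchors extracted from a mask (mask input only).
#' @return a [SplineOutline-class].
#' @export
fitSpline <- function(x, closed = TRUE, nAnchors = 16L) {
  a <- if (is.logical(x)) .anchorsFromMask(x, nAnchors) else
    cbind(x = x[, 1], y = x[, 2])
  ## deduplicate consecutive (and wrap-around) duplicates
  if (nrow(a) > 1) {
    keep <- c(TRUE, rowSums(abs(diff(a))) > 1e-9)
    a <- a[keep, , drop = FALSE]
    if (closed && nrow(a) > 1 && sum(abs(a[1, ] - a[nrow(a), ])) < 1e-9)
      a <- a[-nrow(a), , drop = FALSE]
  }
  if (closed && nrow(a) < 4) stop("closed outlines need >= 4 anchors")
  if (!closed && nrow(a) < 2) stop("open outlines need >= 2 anchors")
  if (nrow(a) > 3 && .selfIntersects(a, closed))
    warning("anchor ordering self-intersects; spline may be degenerate")
  if (closed) {
    cx <- mean(a[, 1]); cy <- mean(a[, 2])
    phi <- atan2(a[, 2] - cy, a[, 1] - cx)
    o <- order(phi)
    starShaped <- all(diff(phi[o]) > 1e-9)
    if (starShaped) {
      rr <- sqrt((a[o, 1] - cx)^2 + (a[o, 2] - cy)^2)
      ph <- c(phi[o], phi[o][1] + 2 * pi)
      fr <- stats::splinefun(ph, c(rr, rr[1]), method = "periodic")
      nd <- max(360L, ceiling(2 * pi * max(rr) / 0.2))
      pg <- seq(phi[o][1], phi[o][1] + 2 * pi, length.out = nd + 1)
      r <- fr(pg); dr <- fr(pg, deriv = 1)
      xx <- cx + r * cos(pg); yy <- cy + r * sin(pg)
      tx <- dr * cos(pg) - r * sin(pg)
      ty <- dr * sin(pg) + r * cos(pg)
    } else {
      t0 <- c(0, cumsum(sqrt(rowSums(diff(rbind(a[o, ], a[o, ][1, ]))^2))))
      fx <- stats::splinefun(t0, c(a[o, 1], a[o, 1][1]), method = "periodic")
      fy <- stats::splinefun(t0, c(a[o, 2], a[o, 2][1]), method = "periodic")
      nd <- max(360L, ceiling(t0[length(t0)] / 0.2))
      tg <- seq(0, t0[length(t0)], length.out = nd + 1)
      xx <- fx(tg); yy <- fy(tg)
      tx <- fx(tg, deriv = 1); ty <- fy(tg, deriv = 1)
    }
  } else {
    t0 <- c(0, cumsum(sqrt(rowSums(diff(a)^2))))
    fx <- stats::splinefun(t0, a[, 1], method = "natural")
    fy <- stats::splinefun(t0, a[, 2], method = "natural")
    nd <- max(16L, ceiling(t0[length(t0)] / 0.2))
    tg <- seq(0, t0[length(t0)], length.out = nd + 1)
    xx <- fx(tg); yy <- fy(tg)
    tx <- fx(tg, deriv = 1); ty <- fy(tg, deriv = 1)
  }
  tangent <- (atan2(ty, tx) / .DEG) %% 180
  samples <- .resampleArc(xx, yy, tangent)
  methods::new("SplineOutline", anchors = a, closed = closed,
               samples = samples)
}

#' Assign a feature-tangent angle theta to every analyzable pixel
#'
#' Associates each valid pixel of an LD map with the nearest point of the
#' dense spline outline (Euclidean distance) and records the outline
#' tangent there as theta, together with the pixel's log2 dichroic ratio
#' and an intensity weight. Pixels farther than `maxDistance` from the
#' outline are dropped; dense outline points whose local tangent turn rate
#' exceeds `maxTurn` (degrees per pixel of arc) are excluded, emulating
#' manual exclusion of high-curvature irregularities.
#'
#' @param map a [PixelLDMap-class].
#' @param outline a [SplineOutline-class].
#' @param geometry `"membrane"` or `"filament"` (carried into the samples).
#' @param maxDistance maximal pixel-to-outline distance in px (default 3,
#'   about the ring thickness/PSF).
#' @param maxTurn curvature exclusion threshold in degrees per pixel
#'   (default `Inf` = no exclusion).
#' @param modality `"1P"` or `"2P"` tag.
#' @param objectId identifier recorded in the output.
#' @param mask optional logical matrix restricting the analyzed pixels.
#' @return a [ThetaSamples-class].
#' @export
assignTheta <- function(map, outline, geometry = c("membrane", "filament"),
                        maxDistance = 3, maxTurn = Inf,
                        modality = c("1P", "2P"), objectId = "object",
                        mask = NULL) {
  geometry <- match.arg(geometry)
  modality <- match.arg(modality)
  methods::validObject(map); methods::validObject(outline)
  sel <- map@valid & is.finite(map@ld) & map@ld > 0
  if (!is.null(mask)) sel <- sel & mask
  rc <- which(sel, arr.ind = TRUE)
  if (!nrow(rc)) stop("no valid pixels to assign")
  px <- rc[, 2] - 1; py <- rc[, 1] - 1
  sm <- outline@samples
  if (is.finite(maxTurn) && nrow(sm) > 2) {
    arcStep <- mean(sqrt(diff(sm$x)^2 + diff(sm$y)^2))
    dtan <- abs(diff(sm$tangent)); dtan <- pmin(dtan, 180 - dtan)
    turn <- c(dtan[1], (dtan[-1] + dtan[-length(dtan)]) / 2,
              dtan[length(dtan)]) / arcStep
    sm <- sm[turn <= maxTurn, , drop = FALSE]
    if (!nrow(sm)) stop("no outline points below the curvature threshold")
  }
  n <- length(px)
  nearest <- integer(n); ndist <- numeric(n)
  chunk <- 2000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(px[s:e], sm$x, "-")^2 + outer(py[s:e], sm$y, "-")^2
    nearest[s:e] <- max.col(-d2, ties.method = "first")
    ndist[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), nearest[s:e])])
  }
  keep <- ndist <= maxDistance
  if (!any(keep)) stop("no pixels within maxDistance of the outline")
  df <- data.frame(theta = sm$tangent[nearest[keep]] %% 180,
                   log2r = log2(map@ld[sel][keep]),
                   weight = map@intensity[sel][keep])
  df <- df[is.finite(df$log2r), , drop = FALSE]
  methods::new("ThetaSamples", samples = df, modality = modality,
               geometry = geometry, objectId = objectId)
}
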
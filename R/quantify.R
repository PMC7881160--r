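## Fitting of (theta, log2 r) data by the 1P and 2P parametric LD curves,
## pooling across experiments, wrapped-Gaussian inference with goodness
## maps, bootstrap confidence regions, and two-Gaussian mixture search.

## Eq-style parametric curves (theta, phases in degrees, output log2 units)
.eq1Curve <- function(theta, A, B, p1, p2) {
  A + log2(1 + B * cos(2 * (theta - p1) * .DEG)) -
    log2(1 - B * cos(2 * (theta - p2) * .DEG))
}

.eq2Curve <- function(theta, A, B, C, p1, p2) {
  A + log2(1 + B * cos(2 * (theta - p1) * .DEG) +
             C * cos(4 * (theta - p1) * .DEG)) -
    log2(1 - B * cos(2 * (theta - p2) * .DEG) +
           C * cos(4 * (theta - p2) * .DEG))
}

## angular span of theta values mod 180 (180 minus the largest gap)
.thetaSpan <- function(theta) {
  u <- sort(unique(theta %% 180))
  if (length(u) < 2) return(0)
  gaps <- c(diff(u), 180 - (u[length(u)] - u[1]))
  180 - max(gaps)
}

.log2rmaxFromCurve <- function(thetaGrid, v) {
  ## signed extremum of largest magnitude; ties resolved towards theta = 0
  dist0 <- pmin(thetaGrid %% 180, 180 - thetaGrid %% 180)
  i <- which(abs(v) >= max(abs(v)) - 1e-6)
  v[i[which.min(dist0[i])]]
}

## per-point sigma estimates from local scatter in 18 theta bins
.binSigmas <- function(theta, y, nbins = 18L) {
  b <- pmin(floor(theta / (180 / nbins)) + 1L, nbins)
  sds <- tapply(y, b, stats::sd)
  ns <- tapply(y, b, length)
  fallback <- stats::sd(y)
  if (!is.finite(fallback) || fallback <= 0) fallback <- 1
  sds[!is.finite(sds) | sds <= 0 | ns < 3] <- fallback
  as.numeric(sds[as.character(b)])
}

.fitMetrics <- function(theta, y, w, fitted) {
  res <- y - fitted
  sw <- sum(w)
  ybar <- sum(w * y) / sw
  sst <- sum(w * (y - ybar)^2)
  ssr <- sum(w * res^2)
  r2 <- if (sst <= 1e-12 * max(1, sum(w * y^2))) NA_real_ else 1 - ssr / sst
  sig <- .binSigmas(theta, y)
  list(r2 = r2, rmsd = sqrt(ssr / sw), chi2 = sum((res / sig)^2))
}

.checkSamples <- function(ts) {
  methods::validObject(ts)
  s <- ts@samples
  if (nrow(s) < 8) stop("need >= 8 samples, got ", nrow(s))
  span <- .thetaSpan(s$theta)
  if (span < 60)
    stop(sprintf("theta span %.1f degrees is below the required 60", span))
  s
}

#' Fit 1P dichroic-ratio data by the parametric LD curve
#'
#' Weighted nonlinear least squares of `log2 r(theta)` by
#' `A1P + log2((1 + B1P cos 2(theta - phi1)) / (1 - B1P cos 2(theta -
#' phi2)))`, multi-started over phase (0, 45, 90, 135 degrees) and
#' amplitude (0.1, 0.5, 0.9); equal-SSE starts resolve to the smaller
#' amplitude. `log2rmax` is the signed extremum of the fitted curve with
#' the largest magnitude.
#'
#' @param samples a [ThetaSamples-class] with >= 8 points spanning >= 60
#'   degrees of theta.
#' @param maxPhiDelta sanity bound on `|phi1 - phi2|` (degrees); exceeding
#'   it warns.
#' @return a [Fit1PResult-class].
#' @export
fit1P <- function(samples, maxPhiDelta = 20) {
  s <- .checkSamples(samples)
  th <- s$theta; y <- s$log2r
  w <- s$weight; if (sum(w) <= 0) w <- rep(1, length(y))
  sw <- sqrt(w)
  a0 <- sum(w * y) / sum(w)
  best <- NULL
  for (phi0 in c(0, 45, 90, 135)) for (b0 in c(0.1, 0.5, 0.9)) {
    fit <- try(minpack.lm::nls.lm(
      par = c(A = a0, B = b0, p1 = phi0, p2 = phi0),
      lower = c(-Inf, 0, phi0 - 45, phi0 - 45),
      upper = c(Inf, 0.999, phi0 + 45, phi0 + 45),
      fn = function(p) sw * (y - .eq1Curve(th, p[1], p[2], p[3], p[4])),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (sse < best$sse + 1e-12 && fit$par[2] < best$par[2]))
      best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best)) stop("1P fit failed to converge from any start")
  p <- best$par
  if (abs(p[3] - p[4]) > maxPhiDelta)
    warning(sprintf("|phi1 - phi2| = %.1f exceeds the sanity bound %.1f",
                    abs(p[3] - p[4]), maxPhiDelta))
  grid <- seq(0, 179.75, by = 0.25)
  met <- .fitMetrics(th, y, w, .eq1Curve(th, p[1], p[2], p[3], p[4]))
  methods::new("Fit1PResult",
    a1p = unname(p[1]), b1pFit = unname(p[2]), phi1 = unname(p[3]),
    phi2 = unname(p[4]),
    log2rmax = .log2rmaxFromCurve(grid, .eq1Curve(grid, p[1], p[2], p[3], p[4])),
    r2 = met$r2, rmsd = met$rmsd, chi2 = met$chi2, n = nrow(s))
}

## positivity of the Eq.(2) numerator/denominator polynomials over beta
.eq2MinPoly <- function(B, C) {
  bg <- seq(0, 180, by = 1) * .DEG
  min(1 + B * cos(2 * bg) + C * cos(4 * bg),
      1 - B * cos(2 * bg) + C * cos(4 * bg))
}

## 2P curve in the symmetry-axis (beta) convention with independent phases
## and clamped polynomials (finite for any parameter values)
.fm2PCurve <- function(th, A, B, C, p1, p2, geometry) {
  bn <- .thetaToBeta(th - p1, geometry) * .DEG
  bd <- .thetaToBeta(th - p2, geometry) * .DEG
  num <- 1 + B * cos(2 * bn) + C * cos(4 * bn)
  den <- 1 - B * cos(2 * bd) + C * cos(4 * bd)
  A + log2(pmax(num, 1e-12)) - log2(pmax(den, 1e-12))
}

#' Fit 2P dichroic-ratio data by the parametric LD curve
#'
#' Weighted nonlinear least squares of `log2 r(theta)` by the two-photon
#' curve with parameters (A2P, B2P, C2P, phi1, phi2), under the constraint
#' that both intensity polynomials stay positive. In restricted mode the
#' shape parameters are constrained to those generated by wrapped-Gaussian
#' tilt distributions (via the lookup table), and the best (alpha0, sigma)
#' is returned with offset and phase profiled out.
#'
#' @param samples a [ThetaSamples-class] (same preconditions as [fit1P()]).
#' @param restricted logical; restrict (B2P, C2P) to the Gaussian family.
#' @param table lookup table for restricted mode (default
#'   [defaultLookupTable()]).
#' @param maxPhiDelta sanity bound on `|phi1 - phi2|`.
#' @return a [Fit2PResult-class].
#' @export
fit2P <- function(samples, restricted = FALSE, table = NULL,
                  maxPhiDelta = 20) {
  s <- .checkSamples(samples)
  th <- s$theta; y <- s$log2r
  w <- s$weight; if (sum(w) <= 0) w <- rep(1, length(y))
  sw <- sqrt(w)
  a0 <- sum(w * y) / sum(w)
  geometry <- samples@geometry
  if (restricted) {
    if (is.null(table)) table <- defaultLookupTable()
    b2 <- as.vector(table@b2p); c2 <- as.vector(table@c2p)
    nc <- length(b2)
    bestSse <- Inf; bestCell <- 1L; bestPhi <- 0
    for (phi in seq(-20, 20, by = 2.5)) {
      beta <- .thetaToBeta(th - phi, geometry) * .DEG
      C2 <- cos(2 * beta); C4 <- cos(4 * beta)
      ## curves for all cells at once: ncells x n
      G <- log2(1 + outer(b2, C2) + outer(c2, C4)) -
        log2(1 - outer(b2, C2) + outer(c2, C4))
      ## profile the offset per cell (weighted):
      ## sse_c = S(wy^2) - 2 G(wy) + G^2 w - (S(wy) - Gw)^2 / Sw
      Sw <- sum(w); Sy <- sum(w * y)
      GW <- as.vector(G %*% w)
      sse <- sum(w * y^2) - 2 * as.vector(G %*% (w * y)) +
        as.vector((G * G) %*% w) - (Sy - GW)^2 / Sw
      i <- which.min(sse)
      if (sse[i] < bestSse) { bestSse <- sse[i]; bestCell <- i; bestPhi <- phi }
    }
    na <- length(table@alpha0)
    ia <- (bestCell - 1L) %% na + 1L
    is <- (bestCell - 1L) %/% na + 1L
    B <- table@b2p[ia, is]; C <- table@c2p[ia, is]
    ## refine phase and offset at the chosen cell
    cellSse <- function(phi) {
      g <- .fm2PCurve(th, 0, B, C, phi, phi, geometry)
      aa <- sum(w * (y - g)) / sum(w)
      sum(w * (y - aa - g)^2)
    }
    phi <- stats::optimize(cellSse, c(bestPhi - 5, bestPhi + 5))$minimum
    g <- .fm2PCurve(th, 0, B, C, phi, phi, geometry)
    A <- sum(w * (y - g)) / sum(w)
    met <- .fitMetrics(th, y, w, A + g)
    grid <- seq(0, 179.75, by = 0.25)
    return(methods::new("Fit2PResult",
      a2p = A, b2pFit = B, c2pFit = C, phi1 = phi, phi2 = phi,
      restricted = TRUE, alpha0 = table@alpha0[ia], sigma = table@sigma[is],
      log2rmax = .log2rmaxFromCurve(grid,
        .fm2PCurve(grid, A, B, C, phi, phi, geometry)),
      r2 = met$r2, rmsd = met$rmsd, chi2 = met$chi2, n = nrow(s)))
  }
  obj <- function(p) {
    pen <- max(0, 1e-4 - .eq2MinPoly(p[2], p[3]))
    ## the tiny ridge keeps C identifiable when B ~ 0 (at B = 0 the curve
    ## is independent of C); its bias is orders below the fit tolerance
    sum(w * (y - .fm2PCurve(th, p[1], p[2], p[3], p[4], p[5], geometry))^2) +
      1e6 * length(y) * pen^2 + 1e-4 * length(y) * (p[2]^2 + p[3]^2)
  }
  best <- NULL
  for (b0 in c(-1.3, -0.6, 0.3, 0.8, 1.3)) for (c0 in c(0.1, 0.35)) {
    fit <- try(stats::optim(c(a0, b0, c0, 0, 0), obj, method = "L-BFGS-B",
                            lower = c(-Inf, -2, -1, -45, -45),
                            upper = c(Inf, 2, 1, 45, 45),
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (fit$value < best$value + 1e-12 && abs(fit$par[2]) < abs(best$par[2])))
      best <- fit
  }
  if (is.null(best)) stop("2P fit failed to converge from any start")
  ## polish without the ridge from the selected optimum: removes the small
  ## parsimony bias while staying in the basin the ridge selected
  resPlain <- function(p) c(
    sw * (y - .fm2PCurve(th, p[1], p[2], p[3], p[4], p[5], geometry)),
    sqrt(1e6 * length(y)) * max(0, 1e-4 - .eq2MinPoly(p[2], p[3])))
  pol <- try(minpack.lm::nls.lm(
    par = best$par, fn = resPlain,
    lower = c(-Inf, -2, -1, -45, -45), upper = c(Inf, 2, 1, 45, 45),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (!inherits(pol, "try-error") &&
      sum(pol$fvec^2) <= sum(resPlain(best$par)^2))
    best <- pol
  p <- best$par
  while (.eq2MinPoly(p[2], p[3]) <= 1e-9 && (abs(p[2]) > 1e-9 ||
                                             abs(p[3]) > 1e-9)) {
    p[2] <- p[2] * 0.98; p[3] <- p[3] * 0.98
  }
  if (abs(p[4] - p[5]) > maxPhiDelta)
    warning(sprintf("|phi1 - phi2| = %.1f exceeds the sanity bound %.1f",
                    abs(p[4] - p[5]), maxPhiDelta))
  grid <- seq(0, 179.75, by = 0.25)
  met <- .fitMetrics(th, y, w,
                     .fm2PCurve(th, p[1], p[2], p[3], p[4], p[5], geometry))
  methods::new("Fit2PResult",
    a2p = unname(p[1]), b2pFit = unname(p[2]), c2pFit = unname(p[3]),
    phi1 = unname(p[4]), phi2 = unname(p[5]), restricted = FALSE,
    alpha0 = NA_real_, sigma = NA_real_,
    log2rmax = .log2rmaxFromCurve(grid,
      .fm2PCurve(grid, p[1], p[2], p[3], p[4], p[5], geometry)),
    r2 = met$r2, rmsd = met$rmsd, chi2 = met$chi2, n = nrow(s))
}

## ---- binned machinery behind goodness maps and the bootstrap ----

.binTheta <- function(ts, binWidth = 0.5) {
  s <- ts@samples
  nb <- as.integer(round(180 / binWidth))
  b <- pmin(floor(s$theta / binWidth) + 1L, nb)
  agg <- function(v) {
    out <- numeric(nb)
    t <- tapply(v, b, sum)
    out[as.integer(names(t))] <- t
    out
  }
  w <- s$weight
  if (sum(w) <= 0) w <- rep(1, nrow(s))
  list(centers = (seq_len(nb) - 0.5) * binWidth,
       W = agg(w), Y = agg(w * s$log2r), Y2 = agg(w * s$log2r^2),
       N = agg(rep(1, nrow(s))), U = agg(s$log2r), U2 = agg(s$log2r^2))
}

.addBins <- function(a, b) {
  for (f in c("W", "Y", "Y2", "N", "U", "U2")) a[[f]] <- a[[f]] + b[[f]]
  a
}

## ideal curves of every lookup cell at the given thetas: ncells x ntheta
.cellCurveMatrix <- function(table, modality, geometry, thetas) {
  beta <- .thetaToBeta(thetas, geometry) * .DEG
  C2 <- cos(2 * beta)
  if (identical(modality, "1P")) {
    b1 <- as.vector(table@b1p)
    log2(1 + outer(b1, C2)) - log2(1 - outer(b1, C2))
  } else {
    C4 <- cos(4 * beta)
    b2 <- as.vector(table@b2p); c2 <- as.vector(table@c2p)
    log2(1 + outer(b2, C2) + outer(c2, C4)) -
      log2(1 - outer(b2, C2) + outer(c2, C4))
  }
}

## weighted residual sum per cell with the offset profiled out
.ssresPerCell <- function(G, bins) {
  W <- bins$W; Y <- bins$Y
  Sw <- sum(W); Sy <- sum(Y); SY2 <- sum(bins$Y2)
  GW <- as.vector(G %*% W)
  GY <- as.vector(G %*% Y)
  G2W <- as.vector((G * G) %*% W)
  ssres <- SY2 - 2 * GY + G2W - (Sy - GW)^2 / Sw
  list(ssres = pmax(ssres, 0), offset = (Sy - GW) / Sw,
       sstot = SY2 - Sy^2 / Sw, sw = Sw)
}

## chi-squared per cell using 18-bin scatter variances (unweighted counts)
.chi2PerCell <- function(G, bins, offsets) {
  nb <- length(bins$centers)
  coarse <- pmin(floor(bins$centers / 10) + 1L, 18L)
  N18 <- tapply(bins$N, coarse, sum)
  U18 <- tapply(bins$U, coarse, sum)
  U218 <- tapply(bins$U2, coarse, sum)
  var18 <- pmax((U218 - U18^2 / pmax(N18, 1)) / pmax(N18 - 1, 1), 1e-12)
  glob <- sum(bins$U2) - sum(bins$U)^2 / max(sum(bins$N), 1)
  glob <- max(glob / max(sum(bins$N) - 1, 1), 1e-12)
  var18[N18 < 3] <- glob
  vb <- as.numeric(var18[coarse])           # variance per fine bin
  chi <- as.vector((G * G) %*% (bins$N / vb)) +
    as.vector(G %*% (-2 * bins$U / vb)) + sum(bins$U2 / vb)
  ## add the offset terms: sum_b N_b (a^2 + 2 a g_b - 2 a ybar_b) / v_b
  chi + offsets^2 * sum(bins$N / vb) +
    2 * offsets * as.vector(G %*% (bins$N / vb)) -
    2 * offsets * sum(bins$U / vb)
}

.splitByModality <- function(x) {
  if (methods::is(x, "ThetaSamples")) x <- list(x)
  mods <- vapply(x, function(t) t@modality, character(1))
  geos <- unique(vapply(x, function(t) t@geometry, character(1)))
  if (length(geos) != 1) stop("all sample sets must share one geometry")
  list(sets = split(x, mods), geometry = geos)
}

#' Goodness-of-fit map over the (alpha0, sigma) grid
#'
#' For every wrapped-Gaussian tilt distribution in the lookup table,
#' compares its ideal log2 r(theta) curve(s) with the observed samples,
#' with a per-modality offset profiled out by weighted least squares, and
#' records r2, RMSD and chi-squared heat-map slices plus the best cell.
#' Pass a list of [ThetaSamples-class] mixing 1P and 2P data for a
#' combined map (shared (alpha0, sigma), independent offsets).
#'
#' @param x a [ThetaSamples-class] or list of them (pooled).
#' @param table an [LDLookupTable-class]; default [defaultLookupTable()].
#' @param binWidth aggregation bin width in degrees (default 0.5).
#' @return a [GoodnessMap-class].
#' @export
goodnessMap <- function(x, table = NULL, binWidth = 0.5) {
  if (is.null(table)) table <- defaultLookupTable()
  sp <- .splitByModality(x)
  ssres <- 0; sstot <- 0; sw <- 0; chi2 <- 0
  anyVar <- FALSE
  for (mod in names(sp$sets)) {
    bins <- Reduce(.addBins, lapply(sp$sets[[mod]], .binTheta,
                                    binWidth = binWidth))
    G <- .cellCurveMatrix(table, mod, sp$geometry, bins$centers)
    pc <- .ssresPerCell(G, bins)
    ssres <- ssres + pc$ssres
    chi2 <- chi2 + .chi2PerCell(G, bins, pc$offset)
    sstot <- sstot + pc$sstot
    sw <- sw + pc$sw
    if (pc$sstot > 1e-12) anyVar <- TRUE
  }
  na <- length(table@alpha0); ns <- length(table@sigma)
  r2 <- if (anyVar) matrix(1 - ssres / sstot, na, ns) else
    matrix(NA_real_, na, ns)
  i <- which.min(ssres)
  ia <- (i - 1L) %% na + 1L; is <- (i - 1L) %/% na + 1L
  mod <- if (length(sp$sets) > 1) "combined" else names(sp$sets)
  methods::new("GoodnessMap", alpha0 = table@alpha0, sigma = table@sigma,
    r2 = r2, rmsd = matrix(sqrt(ssres / sw), na, ns),
    chi2 = matrix(chi2, na, ns),
    best = c(table@alpha0[ia], table@sigma[is]),
    confidence = matrix(FALSE, na, ns), modality = mod)
}

#' Pool sample sets and fit per modality and combined
#'
#' Concatenates (theta, log2 r) sets across objects, fits the 1P data by
#' the 1P curve, the 2P data by the 2P curve, and infers the shared
#' wrapped-Gaussian (alpha0, sigma) from the combined data (independent
#' offsets per modality). Also emits the 1P curve predicted from the
#' 2P-only best distribution (two-photon data determine both shape
#' parameters, hence predict the single-photon curve).
#'
#' @param sampleList list of [ThetaSamples-class].
#' @param table lookup table; default [defaultLookupTable()].
#' @return list with elements `fit1p` ([Fit1PResult-class] or `NULL`),
#'   `fit2p` ([Fit2PResult-class] or `NULL`), `map1p`, `map2p` (per-
#'   modality [GoodnessMap-class]s or `NULL`), `combined` (combined
#'   [GoodnessMap-class] or `NULL`), and `predicted1PFrom2P` (data.frame
#'   `theta`, `log2r`).
#' @export
poolAndFit <- function(sampleList, table = NULL) {
  if (is.null(table)) table <- defaultLookupTable()
  sp <- .splitByModality(sampleList)
  pool <- function(sets) {
    df <- do.call(rbind, lapply(sets, methods::slot, "samples"))
    methods::new("ThetaSamples", samples = df, modality = sets[[1]]@modality,
                 geometry = sets[[1]]@geometry, objectId = "pooled")
  }
  out <- list(fit1p = NULL, fit2p = NULL, map1p = NULL, map2p = NULL,
              combined = NULL, predicted1PFrom2P = NULL)
  if (!is.null(sp$sets[["1P"]])) {
    p1 <- pool(sp$sets[["1P"]])
    out$fit1p <- fit1P(p1)
    out$map1p <- goodnessMap(p1, table)
  } else message("no 1P sample sets supplied")
  if (!is.null(sp$sets[["2P"]])) {
    p2 <- pool(sp$sets[["2P"]])
    out$fit2p <- fit2P(p2, restricted = FALSE)
    out$map2p <- goodnessMap(p2, table)
    grid <- seq(0, 179.5, by = 0.5)
    sp2 <- lookupShapeParams(table, out$map2p@best[1], out$map2p@best[2])
    out$predicted1PFrom2P <- data.frame(theta = grid,
      log2r = as.numeric(predictLog2r(sp2, grid, "1P",
                                      geometry = sp$geometry)))
  } else message("no 2P sample sets supplied")
  if (length(sp$sets) > 1) out$combined <- goodnessMap(sampleList, table)
  out
}

#' Bootstrap confidence region on the (alpha0, sigma) grid
#'
#' Resamples whole objects (cells/vesicles) with replacement — pixels
#' within an object are correlated, so the object is the exchangeable unit
#' — refits the best (alpha0, sigma) for each replicate, and returns the
#' smallest set of grid cells containing at least `level` of the bootstrap
#' best-fits (always including the full-data best cell).
#'
#' @param sampleList list of [ThetaSamples-class] (>= 2 distinct objects).
#' @param table lookup table; default [defaultLookupTable()].
#' @param nBoot number of bootstrap replicates (warns below 50).
#' @param seed integer seed (RNG state restored on exit).
#' @param level confidence level, default 0.95.
#' @param binWidth aggregation bin width in degrees.
#' @return the full-data [GoodnessMap-class] with its `confidence` mask
#'   filled; attribute `"bootBest"` holds the replicate best cells.
#' @export
bootstrapConfidence <- function(sampleList, table = NULL, nBoot = 200L,
                                seed = 1L, level = 0.95, binWidth = 0.5) {
  if (is.null(table)) table <- defaultLookupTable()
  if (nBoot < 50) warning("nBoot < 50 gives unstable confidence masks")
  ids <- vapply(sampleList, function(t) t@objectId, character(1))
  if (length(unique(ids)) < 2) stop("bootstrap needs >= 2 distinct objects")
  sp <- .splitByModality(sampleList)
  geometry <- sp$geometry
  mods <- names(sp$sets)
  ## per-object binned stats and cell-curve matrices per modality
  perObj <- lapply(sp$sets, function(sets) lapply(sets, .binTheta,
                                                  binWidth = binWidth))
  centers <- (seq_len(round(180 / binWidth)) - 0.5) * binWidth
  Gs <- lapply(mods, function(m) .cellCurveMatrix(table, m, geometry, centers))
  names(Gs) <- mods
  G2s <- lapply(Gs, function(G) G * G)
  objIds <- lapply(sp$sets, function(sets)
    vapply(sets, function(t) t@objectId, character(1)))
  uids <- unique(ids)
  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  na <- length(table@alpha0)
  bestCells <- integer(nBoot)
  for (r in seq_len(nBoot)) {
    pick <- sample(uids, length(uids), replace = TRUE)
    ssres <- 0
    for (m in mods) {
      take <- unlist(lapply(pick, function(u) which(objIds[[m]] == u)))
      if (!length(take)) next
      W <- Y <- Y2 <- 0
      for (i in take) {
        W <- W + perObj[[m]][[i]]$W
        Y <- Y + perObj[[m]][[i]]$Y
        Y2 <- Y2 + perObj[[m]][[i]]$Y2
      }
      Sw <- sum(W); Sy <- sum(Y)
      GW <- as.vector(Gs[[m]] %*% W)
      GY <- as.vector(Gs[[m]] %*% Y)
      G2W <- as.vector(G2s[[m]] %*% W)
      ssres <- ssres + (sum(Y2) - 2 * GY + G2W - (Sy - GW)^2 / Sw)
    }
    bestCells[r] <- which.min(ssres)
  }
  full <- goodnessMap(sampleList, table, binWidth)
  tab <- table(bestCells)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  cells <- as.integer(names(tab))[ord]
  counts <- as.integer(tab)[ord]
  need <- ceiling(level * nBoot)
  k <- which(cumsum(counts) >= need)[1]
  if (is.na(k)) k <- length(cells)
  conf <- matrix(FALSE, na, length(table@sigma))
  conf[cells[seq_len(k)]] <- TRUE
  ib <- which.min(abs(table@alpha0 - full@best[1]))
  jb <- which.min(abs(table@sigma - full@best[2]))
  conf[ib, jb] <- TRUE
  full@confidence <- conf
  attr(full, "bootBest") <- data.frame(
    alpha0 = table@alpha0[(bestCells - 1L) %% na + 1L],
    sigma = table@sigma[(bestCells - 1L) %/% na + 1L])
  full
}

#' Search two-Gaussian mixtures matching target shape parameters
#'
#' Exhaustive grid search over two wrapped-Gaussian components
#' (alpha0, sigma each) and the mixing fraction f, scoring each candidate
#' against the target (b1p, b2p, c2p) by the coefficient of determination;
#' near-ties are re-ranked by the differential entropy of the mixture tilt
#' density (wider, less committal distributions win ties).
#'
#' @param targets a [DichroicShapeParams-class] or numeric
#'   `c(b1p, b2p, c2p)`.
#' @param alpha0Step grid step for mean tilt angles (degrees).
#' @param sigmaGrid widths searched (degrees).
#' @param fStep mixing-fraction step.
#' @param topK number of candidates returned.
#' @return data.frame of ranked candidates with columns `alpha0A`,
#'   `sigmaA`, `alpha0B`, `sigmaB`, `f` (weight of component A), achieved
#'   `b1p`, `b2p`, `c2p`, `residual` (sum of squared target deviations),
#'   `r2`, `entropy` (bits).
#' @export
mixtureSearch <- function(targets, alpha0Step = 5, sigmaGrid = seq(5, 45, 5),
                          fStep = 0.1, topK = 20L) {
  tg <- if (methods::is(targets, "DichroicShapeParams"))
    c(targets@b1p, targets@b2p, targets@c2p) else as.numeric(targets)
  stopifnot(length(tg) == 3, all(is.finite(tg)))
  a0 <- seq(0, 90, by = alpha0Step)
  cells <- expand.grid(alpha0 = a0, sigma = sigmaGrid)
  mm <- t(vapply(seq_len(nrow(cells)), function(i)
    .momentsOfComponent(cells$alpha0[i], cells$sigma[i]), numeric(2)))
  nc <- nrow(cells)
  pair <- expand.grid(a = seq_len(nc), b = seq_len(nc))
  pair <- pair[pair$a <= pair$b, ]
  f <- seq(fStep, 1, by = fStep)
  idx <- expand.grid(p = seq_len(nrow(pair)), fi = seq_along(f))
  A <- pair$a[idx$p]; B <- pair$b[idx$p]; FF <- f[idx$fi]
  ## drop duplicate representations: f = 1 makes component B irrelevant
  keep <- !(FF >= 1 - 1e-12 & A != B)
  A <- A[keep]; B <- B[keep]; FF <- FF[keep]
  m2 <- FF * mm[A, 1] + (1 - FF) * mm[B, 1]
  m4 <- FF * mm[A, 2] + (1 - FF) * mm[B, 2]
  b1p <- (3 * m2 - 1) / (m2 + 1)
  P <- m4; Q <- 3 * (m2 - m4); R <- (3 / 8) * (1 - 2 * m2 + m4)
  dc <- 3 * P / 8 + Q / 8 + 3 * R / 8
  b2p <- (P / 2 - R / 2) / dc
  c2p <- (P / 8 - Q / 8 + R / 8) / dc
  ssres <- (b1p - tg[1])^2 + (b2p - tg[2])^2 + (c2p - tg[3])^2
  sstot <- sum((tg - mean(tg))^2)
  r2 <- if (sstot > 1e-12) 1 - ssres / sstot else 1 - ssres
  ## entropy tie-break within a pool of the best candidates
  pool <- order(ssres)[seq_len(min(length(ssres), max(200L, topK * 10L)))]
  ent <- vapply(pool, function(i) {
    d <- if (FF[i] >= 1 - 1e-12 || A[i] == B[i])
      tiltDistribution(cells$alpha0[A[i]], cells$sigma[A[i]])
    else tiltDistribution(c(cells$alpha0[A[i]], cells$alpha0[B[i]]),
                          c(cells$sigma[A[i]], cells$sigma[B[i]]),
                          c(FF[i], 1 - FF[i]))
    p <- tiltDensity(d)
    -pracma::trapz(.ALPHA_GRID, ifelse(p > 0, p * log2(p), 0))
  }, numeric(1))
  ord <- pool[order(round(ssres[pool], 6), -ent)]
  top <- ord[seq_len(min(topK, length(ord)))]
  data.frame(alpha0A = cells$alpha0[A[top]], sigmaA = cells$sigma[A[top]],
             alpha0B = cells$alpha0[B[top]], sigmaB = cells$sigma[B[top]],
             f = FF[top], b1p = b1p[top], b2p = b2p[top], c2p = c2p[top],
             residual = ssres[top], r2 = r2[top],
             entropy = ent[match(top, pool)])
}

#' Tilt distributions consistent with observed log2(r_max) values
#'
#' Returns every lookup-table cell whose predicted log2(r_max) (the signed
#' extremum of the ideal curve, resolved towards theta = 0) matches the
#' supplied value(s) within tolerance. A 1P value alone selects a level-set
#' curve of cells (one shape parameter); adding a 2P value narrows the set.
#'
#' @param log2rmax1p,log2rmax2p observed values (either may be `NULL`).
#' @param table lookup table; default [defaultLookupTable()].
#' @param geometry `"membrane"` or `"filament"`.
#' @param tol matching tolerance in log2 units.
#' @return data.frame of matching cells (`alpha0`, `sigma`, `pred1p`,
#'   `pred2p`); empty with attribute `"achievableRange"` when the value is
#'   outside the achievable range.
#' @export
rmaxToOrientation <- function(log2rmax1p = NULL, log2rmax2p = NULL,
                              table = NULL,
                              geometry = c("membrane", "filament"),
                              tol = 0.05) {
  geometry <- match.arg(geometry)
  if (is.null(log2rmax1p) && is.null(log2rmax2p))
    stop("at least one modality value is required")
  if (is.null(table)) table <- defaultLookupTable()
  grid <- seq(0, 179.5, by = 0.5)
  dist0 <- pmin(grid, 180 - grid)
  predFor <- function(modality) {
    V <- .cellCurveMatrix(table, modality, geometry, grid)
    sel <- max.col(abs(V) - 1e-9 * matrix(dist0, nrow(V), ncol(V),
                                          byrow = TRUE),
                   ties.method = "first")
    V[cbind(seq_len(nrow(V)), sel)]
  }
  p1 <- predFor("1P"); p2 <- predFor("2P")
  ok <- rep(TRUE, length(p1))
  rng <- list()
  if (!is.null(log2rmax1p)) { ok <- ok & abs(p1 - log2rmax1p) <= tol
                              rng$`1P` <- range(p1) }
  if (!is.null(log2rmax2p)) { ok <- ok & abs(p2 - log2rmax2p) <= tol
                              rng$`2P` <- range(p2) }
  na <- length(table@alpha0)
  i <- which(ok)
  out <- data.frame(alpha0 = table@alpha0[(i - 1L) %% na + 1L],
                    sigma = table@sigma[(i - 1L) %/% na + 1L],
                    pred1p = p1[i], pred2p = p2[i])
  if (!nrow(out)) {
    attr(out, "achievableRange") <- rng
    message("no cells match; achievable ranges: ",
            paste(vapply(names(rng), function(n)
              sprintf("%s [%.3f, %.3f]", n, rng[[n]][1], rng[[n]][2]),
              character(1)), collapse = "; "))
  }
  out
}
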
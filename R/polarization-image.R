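## Pixel-level processing of polarization-modulated images.

.defaultCalibration <- function(backgroundH = NULL, backgroundV = NULL,
                                bleedK = 0, gainG = 1) {
  list(backgroundH = backgroundH, backgroundV = backgroundV,
       bleedK = bleedK, gainG = gainG)
}

#' Construct a mixed-polarization image
#'
#' @param pixels nonnegative intensity matrix.
#' @param scheme modulation scheme; `"per_pixel_column"` alternates
#'   polarization between adjacent columns, `"per_pixel_row"` and
#'   `"per_row"` between adjacent rows.
#' @param phase `"h_first"` or `"v_first"`.
#' @return a [MixedPolarizationImage-class].
#' @export
mixedPolarizationImage <- function(pixels,
                                   scheme = c("per_pixel_column",
                                              "per_pixel_row", "per_row"),
                                   phase = c("h_first", "v_first")) {
  methods::new("MixedPolarizationImage", pixels = pixels,
               scheme = match.arg(scheme), phase = match.arg(phase))
}

#' Construct a polarization pair
#'
#' @param fh,fv intensity matrices at horizontal / vertical excitation.
#' @param modality `"1P"` or `"2P"`.
#' @param calibration optional calibration list; see
#'   [PolarizationPair-class].
#' @return a [PolarizationPair-class].
#' @export
polarizationPair <- function(fh, fv, modality = c("1P", "2P"),
                             calibration = .defaultCalibration()) {
  methods::new("PolarizationPair", fh = fh, fv = fv,
               modality = match.arg(modality), calibration = calibration)
}

#' Construct a polarization stack
#'
#' @param frames 3-D array (rows x cols x frames) or list of matrices.
#' @param angles polarization angles in degrees (uniform increment).
#' @param modality `"1P"` or `"2P"`.
#' @return a [PolarizationStack-class].
#' @export
polarizationStack <- function(frames, angles, modality = c("1P", "2P")) {
  if (is.list(frames))
    frames <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  methods::new("PolarizationStack", frames = frames, angles = angles,
               modality = match.arg(modality))
}

## linear re-gridding of a sub-sampled channel onto all positions along the
## modulation axis (rows of m are interpolated; callers transpose as needed)
.regridRows <- function(m, haveCols, allCols) {
  t(apply(m, 1L, function(row)
    stats::approx(haveCols, row[haveCols], xout = allCols, rule = 2)$y))
}

#' De-interleave a mixed-polarization image into a co-registered pair
#'
#' Splits the interleaved frame into its horizontal- and vertical-excited
#' sub-grids and re-grids each channel to every pixel center by linear
#' interpolation along the modulation axis, so the returned pair is
#' co-registered.
#'
#' @param mixed a [MixedPolarizationImage-class].
#' @param modality `"1P"` or `"2P"` tag for the resulting pair.
#' @param calibration optional calibration list carried into the pair.
#' @return a [PolarizationPair-class].
#' @export
deinterleave <- function(mixed, modality = c("1P", "2P"),
                         calibration = .defaultCalibration()) {
  methods::validObject(mixed)
  modality <- match.arg(modality)
  px <- mixed@pixels
  byCol <- identical(mixed@scheme, "per_pixel_column")
  m <- if (byCol) px else t(px)
  n <- ncol(m)
  if (n %% 2L != 0L) stop("extent along the modulation axis must be even")
  odd <- seq(1L, n, by = 2L); even <- seq(2L, n, by = 2L)
  hIdx <- if (identical(mixed@phase, "h_first")) odd else even
  vIdx <- if (identical(mixed@phase, "h_first")) even else odd
  fh <- .regridRows(m, hIdx, seq_len(n))
  fv <- .regridRows(m, vIdx, seq_len(n))
  if (!byCol) { fh <- t(fh); fv <- t(fv) }
  polarizationPair(fh, fv, modality, calibration)
}

#' Background, bleed-through and gain correction of a polarization pair
#'
#' Subtracts the per-channel background (clamping at zero), unmixes linear
#' bleed-through `fh' = (fh - k fv) / (1 - k^2)`,
#' `fv' = (fv - k fh) / (1 - k^2)`, and scales the corrected fv by the
#' relative gain g. When no background is supplied, the 1st percentile of
#' each channel is used (unattended batch default).
#'
#' @param pair a [PolarizationPair-class]; its `calibration` supplies the
#'   defaults.
#' @param backgroundH,backgroundV,bleedK,gainG optional overrides.
#' @return the corrected [PolarizationPair-class] (calibration reset to
#'   identity).
#' @export
correctPair <- function(pair, backgroundH = NULL, backgroundV = NULL,
                        bleedK = NULL, gainG = NULL) {
  methods::validObject(pair)
  cal <- pair@calibration
  bgH <- if (!is.null(backgroundH)) backgroundH else cal$backgroundH
  bgV <- if (!is.null(backgroundV)) backgroundV else cal$backgroundV
  k <- if (!is.null(bleedK)) bleedK else cal$bleedK
  g <- if (!is.null(gainG)) gainG else cal$gainG
  if (is.null(k)) k <- 0
  if (is.null(g)) g <- 1
  if (k >= 1 || k < 0) stop("bleed-through fraction k must lie in [0, 1)")
  if (g <= 0) stop("gain must be positive")
  if (is.null(bgH)) bgH <- stats::quantile(pair@fh, 0.01, names = FALSE)
  if (is.null(bgV)) bgV <- stats::quantile(pair@fv, 0.01, names = FALSE)
  fh <- pmax(pair@fh - bgH, 0)
  fv <- pmax(pair@fv - bgV, 0)
  fh2 <- (fh - k * fv) / (1 - k^2)
  fv2 <- (fv - k * fh) / (1 - k^2)
  polarizationPair(pmax(fh2, 0), pmax(fv2, 0) * g, pair@modality,
                   .defaultCalibration(0, 0, 0, 1))
}

#' Per-pixel dichroic-ratio map from a corrected pair
#'
#' `r = fh / fv` at every pixel where both channels reach the intensity
#' threshold; other pixels are masked invalid rather than erroring.
#'
#' @param pair a corrected [PolarizationPair-class].
#' @param minIntensity per-channel validity threshold.
#' @return a [PixelLDMap-class] in pair mode (`ld` = r, azimuth absent).
#' @export
dichroicRatioMap <- function(pair, minIntensity = 0) {
  methods::validObject(pair)
  fh <- pair@fh; fv <- pair@fv
  valid <- fh >= minIntensity & fv >= minIntensity & fv > 0
  ld <- matrix(NA_real_, nrow(fh), ncol(fh))
  ld[valid] <- fh[valid] / fv[valid]
  methods::new("PixelLDMap", intensity = fh + fv, ld = ld,
               azimuth = matrix(NA_real_, nrow(fh), ncol(fh)),
               valid = valid, fitParams = list(), mode = "pair")
}

#' Per-pixel cos^2 fit of a multi-polarization stack
#'
#' Fits `F = A + B cos^2(theta - C)` to every pixel's intensity profile
#' across polarization angles. For angles uniformly covering the
#' half-circle the fit is the closed-form harmonic regression
#' `a0 = mean(F)`, `a2 = (2/N) sum F cos 2theta`,
#' `b2 = (2/N) sum F sin 2theta`, `m = sqrt(a2^2 + b2^2)`,
#' `r_max = (a0 + m) / (a0 - m)`, `azimuth = atan2(b2, a2) / 2 mod 180`,
#' which is exact (machine precision) on noiseless data of that form.
#' Nonuniformly covering angle sets fall back to per-pixel linear least
#' squares on the same harmonic basis (a message is emitted).
#'
#' @param stack a [PolarizationStack-class].
#' @param minIntensity pixels with mean intensity below this (or with
#'   modulation m >= a0) are invalid.
#' @return a [PixelLDMap-class] in stack mode (`ld` = r_max).
#' @export
fitStackPerPixel <- function(stack, minIntensity = 0) {
  methods::validObject(stack)
  fr <- stack@frames
  d <- dim(fr)
  nf <- d[3]
  th <- stack@angles * .DEG
  step <- diff(stack@angles)[1]
  uniformHalf <- abs((nf * step) %% 180) < 1e-6 ||
    abs((nf * step) %% 180 - 180) < 1e-6
  X <- matrix(fr, prod(d[1:2]), nf)        # pixels x frames
  if (uniformHalf) {
    a0 <- rowMeans(X)
    a2 <- (2 / nf) * as.vector(X %*% cos(2 * th))
    b2 <- (2 / nf) * as.vector(X %*% sin(2 * th))
  } else {
    message("angles do not uniformly cover the half-circle; using least squares")
    B <- cbind(1, cos(2 * th), sin(2 * th))
    cf <- t(qr.solve(B, t(X)))
    a0 <- cf[, 1]; a2 <- cf[, 2]; b2 <- cf[, 3]
  }
  m <- sqrt(a2^2 + b2^2)
  valid <- a0 >= minIntensity & a0 > m
  rmax <- ifelse(valid, (a0 + m) / (a0 - m), NA_real_)
  ## azimuth undefined at the m = 0 tie (no modulation)
  azOK <- valid & m > 1e-12 * pmax(a0, 1e-300)
  az <- ifelse(azOK, (atan2(b2, a2) / 2 / .DEG) %% 180, NA_real_)
  shape <- function(v) matrix(v, d[1], d[2])
  methods::new("PixelLDMap",
    intensity = shape(a0 * nf), ld = shape(rmax), azimuth = shape(az),
    valid = shape(valid),
    fitParams = list(a = shape(a0 - m), b = shape(2 * m), c = shape(az)),
    mode = "stack")
}

#' Photobleaching correction of a polarization stack
#'
#' Models the frame means (over an optional mask) as a single exponential
#' `mean_i = M exp(-lambda i)` via log-linear regression and divides frame
#' i by `exp(-lambda i)`, removing the monotone bleaching trend while
#' preserving the polarization modulation.
#'
#' @param stack a [PolarizationStack-class].
#' @param mask optional logical matrix restricting the mean computation.
#' @return the corrected [PolarizationStack-class].
#' @export
correctBleaching <- function(stack, mask = NULL) {
  methods::validObject(stack)
  fr <- stack@frames
  nf <- dim(fr)[3]
  mns <- vapply(seq_len(nf), function(i) {
    f <- fr[, , i]
    if (is.null(mask)) mean(f) else mean(f[mask])
  }, numeric(1))
  if (any(mns <= 0)) stop("frame means must be positive for bleaching correction")
  i <- seq_len(nf) - 1
  fit <- stats::lm.fit(cbind(1, i), log(mns))
  lambda <- -fit$coefficients[2]
  for (j in seq_len(nf)) fr[, , j] <- fr[, , j] / exp(-lambda * (j - 1))
  polarizationStack(fr, stack@angles, stack@modality)
}
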
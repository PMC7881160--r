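## Rendering of LD maps: hue encodes log2(r) (or azimuth), brightness
## encodes fluorescence intensity. All renders are pure functions of their
## inputs (identical inputs give bit-identical RGB arrays).

## hue ramp for LD: t in [0, 1] mapped blue (2/3) -> red (0) in HSV
.ldHue <- function(t) grDevices::hsv(h = (1 - t) * 2 / 3, s = 1, v = 1)

.col2rgbMat <- function(cols) t(grDevices::col2rgb(cols)) / 255

#' Render an LD map as an RGB image
#'
#' Hue linearly encodes `log2(ld)` clipped to `hueRange` (mode
#' `"ld_hue"`), or the azimuth angle on a cyclic color wheel (mode
#' `"azimuth_hue"`); brightness encodes total intensity normalized to its
#' 99th percentile over valid pixels. Invalid pixels are black.
#'
#' @param map a [PixelLDMap-class].
#' @param hueRange clip bounds of log2(ld) in log2 units, default
#'   `c(-2, 2)`.
#' @param mode `"ld_hue"` or `"azimuth_hue"`.
#' @return numeric array `nrow x ncol x 3` with values in \[0, 1\].
#' @export
renderLDImage <- function(map, hueRange = c(-2, 2),
                          mode = c("ld_hue", "azimuth_hue")) {
  mode <- match.arg(mode)
  methods::validObject(map)
  if (hueRange[1] >= hueRange[2]) stop("hueRange must satisfy lo < hi")
  d <- dim(map@intensity)
  ok <- map@valid & is.finite(map@ld)
  if (identical(mode, "azimuth_hue")) ok <- ok & !is.na(map@azimuth)
  bright <- matrix(0, d[1], d[2])
  if (any(ok)) {
    p99 <- stats::quantile(map@intensity[ok], 0.99, names = FALSE)
    if (p99 <= 0) p99 <- 1
    bright[ok] <- pmin(pmax(map@intensity[ok] / p99, 0), 1)
  }
  rgb <- array(0, dim = c(d, 3L))
  if (any(ok)) {
    if (identical(mode, "ld_hue")) {
      t <- (pmin(pmax(log2(map@ld[ok]), hueRange[1]), hueRange[2]) -
              hueRange[1]) / diff(hueRange)
      colm <- .col2rgbMat(.ldHue(t))
    } else {
      colm <- .col2rgbMat(grDevices::hsv(h = (map@azimuth[ok] %% 180) / 180,
                                         s = 1, v = 1))
    }
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[ok] <- colm[, ch] * bright[ok]
      rgb[, , ch] <- plane
    }
  }
  rgb
}

#' Render molecular azimuths as a line overlay
#'
#' Draws line segments centered on a regular grid of valid pixels, each at
#' the local azimuth angle. With `spacing = 1` and `length = 1` and
#' `colorMode = "azimuth"` the overlay degenerates to the per-pixel
#' azimuth coloring of [renderLDImage()].
#'
#' @param map a stack-mode [PixelLDMap-class] with azimuths.
#' @param spacing grid spacing between segment centers (pixels, >= 1).
#' @param length segment length in pixels; with `lengthMode = "rmax"` the
#'   length scales with `log2(r_max)` (maximal at the map's maximum).
#' @param colorMode `"fixed"` (constant `color`) or `"azimuth"` (cyclic
#'   azimuth coloring, brightness-modulated as in [renderLDImage()]).
#' @param color RGB triple in \[0, 1\] for `colorMode = "fixed"`.
#' @param lengthMode `"fixed"` or `"rmax"`.
#' @return numeric array `nrow x ncol x 3`.
#' @export
renderAzimuthOverlay <- function(map, spacing = 8, length = 6,
                                 colorMode = c("fixed", "azimuth"),
                                 color = c(1, 1, 0),
                                 lengthMode = c("fixed", "rmax")) {
  colorMode <- match.arg(colorMode)
  lengthMode <- match.arg(lengthMode)
  methods::validObject(map)
  if (spacing < 1) stop("spacing must be >= 1 pixel")
  d <- dim(map@intensity)
  ok <- map@valid & !is.na(map@azimuth)
  bright <- matrix(0, d[1], d[2])
  if (any(ok)) {
    p99 <- stats::quantile(map@intensity[ok], 0.99, names = FALSE)
    if (p99 <= 0) p99 <- 1
    bright[ok] <- pmin(pmax(map@intensity[ok] / p99, 0), 1)
  }
  rgb <- array(0, dim = c(d, 3L))
  rows <- seq(1L, d[1], by = as.integer(spacing))
  cols <- seq(1L, d[2], by = as.integer(spacing))
  lmax <- if (identical(lengthMode, "rmax"))
    max(log2(map@ld[ok]), na.rm = TRUE) else NA_real_
  for (r in rows) for (cc in cols) {
    if (!ok[r, cc]) next
    az <- map@azimuth[r, cc]
    len <- if (identical(lengthMode, "rmax")) {
      if (!is.finite(lmax) || lmax <= 0) length
      else length * max(log2(map@ld[r, cc]), 0) / lmax
    } else length
    half <- (len - 1) / 2
    colv <- if (identical(colorMode, "fixed")) color else
      .col2rgbMat(grDevices::hsv((az %% 180) / 180, 1, 1))[1, ] * bright[r, cc]
    ## x right (columns), y down (rows); angle from +x towards +y
    ts <- if (half > 0) seq(-half, half, by = 0.25) else 0
    px <- unique(cbind(round(r + ts * sin(az * .DEG)),
                       round(cc + ts * cos(az * .DEG))))
    px <- px[px[, 1] >= 1 & px[, 1] <= d[1] &
             px[, 2] >= 1 & px[, 2] <= d[2], , drop = FALSE]
    for (ch in 1:3) rgb[cbind(px, ch)] <- colv[ch]
  }
  rgb
}

#' Reference color bar for the LD hue ramp
#'
#' Produces the exact hue ramp used by [renderLDImage()], as a horizontal
#' RGB strip running from `hueRange[1]` (left) to `hueRange[2]` (right),
#' for use as a figure color bar.
#'
#' @param hueRange log2(r) clip bounds.
#' @param width,height strip size in pixels.
#' @param mode `"ld_hue"` or `"azimuth_hue"` (azimuth wheel strip over
#'   \[0, 180) degrees).
#' @return numeric array `height x width x 3`.
#' @export
ldColorbar <- function(hueRange = c(-2, 2), width = 256L, height = 24L,
                       mode = c("ld_hue", "azimuth_hue")) {
  mode <- match.arg(mode)
  t <- (seq_len(width) - 1) / (width - 1)
  colm <- if (identical(mode, "ld_hue")) .col2rgbMat(.ldHue(t)) else
    .col2rgbMat(grDevices::hsv(h = t * (width - 1) / width, s = 1, v = 1))
  rgb <- array(0, dim = c(height, width, 3L))
  for (ch in 1:3) rgb[, , ch] <- matrix(colm[, ch], height, width, byrow = TRUE)
  rgb
}
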
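## Pixel-level processing: de-interleaving, corrections, per-pixel LD maps,
## bleaching, rendering.

test_that("deinterleave splits alternating columns and is exact on constants", {
  px <- matrix(rep(c(2, 1), times = 8), nrow = 4, byrow = TRUE)
  pr <- deinterleave(mixedPolarizationImage(px, "per_pixel_column", "h_first"))
  expect_true(all(pr@fh == 2) && all(pr@fv == 1))
  ## v_first swaps the channels
  prv <- deinterleave(mixedPolarizationImage(px, "per_pixel_column", "v_first"))
  expect_true(all(prv@fv == 2) && all(prv@fh == 1))
  ## constant image: interpolation exact
  prc <- deinterleave(mixedPolarizationImage(matrix(3.7, 6, 6),
                                             "per_pixel_column", "h_first"))
  expect_true(all(prc@fh == 3.7) && all(prc@fv == 3.7))
  ## row-wise modulation
  pxr <- matrix(rep(c(5, 2), times = 3), nrow = 6)
  prr <- deinterleave(mixedPolarizationImage(pxr, "per_row", "h_first"))
  expect_true(all(prr@fh == 5) && all(prr@fv == 2))
  expect_error(deinterleave(
    mixedPolarizationImage(matrix(1, 4, 5), "per_pixel_column", "h_first")),
    "even")
})

test_that("interleave and deinterleave round-trip", {
  set.seed(1)
  fh <- matrix(runif(64, 1, 2), 8, 8)
  fv <- matrix(runif(64, 1, 2), 8, 8)
  pair <- polarizationPair(fh, fv)
  mx <- interleave(pair, "per_pixel_column", "h_first")
  expect_equal(mx@pixels[, c(1, 3, 5, 7)], fh[, c(1, 3, 5, 7)])
  expect_equal(mx@pixels[, c(2, 4, 6, 8)], fv[, c(2, 4, 6, 8)])
  ## identity on the sampled sub-grids after de-interleaving
  back <- deinterleave(mx)
  expect_equal(back@fh[, c(1, 3, 5, 7)], fh[, c(1, 3, 5, 7)])
  expect_equal(back@fv[, c(2, 4, 6, 8)], fv[, c(2, 4, 6, 8)])
})

test_that("deinterleave recovers smooth channels within the interpolation bound", {
  ## smooth ring profile: linear interpolation error is second order
  sc <- sceneSpec(distribution = tiltDistribution(90, 10), modality = "1P",
                  acquisition = list(mode = "pair"), photons = 1e4, seed = 2,
                  size = c(128L, 128L),
                  object = list(type = "ring", center = c(63.5, 63.5),
                                radius = 40, width = 4))
  out <- renderScene(sc)
  truthPair <- polarizationPair(out$truth$noiseFree$fh, out$truth$noiseFree$fv)
  mx <- interleave(truthPair, "per_pixel_column", "h_first")
  back <- deinterleave(mx)
  ## bound: max second difference along rows (h = 1 px)
  bound <- max(abs(diff(t(out$truth$noiseFree$fh), differences = 2)),
               abs(diff(t(out$truth$noiseFree$fv), differences = 2)))
  expect_lt(max(abs(back@fh - truthPair@fh)), bound + 1e-9)
  expect_lt(max(abs(back@fv - truthPair@fv)), bound + 1e-9)
})

test_that("pair correction inverts background, bleed-through and gain", {
  fh <- matrix(2, 8, 8); fv <- matrix(1, 8, 8)
  ## identity
  p0 <- correctPair(polarizationPair(fh, fv), backgroundH = 0,
                    backgroundV = 0, bleedK = 0, gainG = 1)
  expect_equal(p0@fh, fh); expect_equal(p0@fv, fv)
  ## algebraic inversion of a known mixing
  k <- 0.2
  pc <- correctPair(polarizationPair(fh + k * fv, fv + k * fh),
                    backgroundH = 0, backgroundV = 0, bleedK = k, gainG = 1)
  expect_lt(max(abs(pc@fh - 2)), 1e-12)
  expect_lt(max(abs(pc@fv - 1)), 1e-12)
  ## background larger than the signal clamps to zero
  pb <- correctPair(polarizationPair(fh, fv), backgroundH = 10,
                    backgroundV = 10, bleedK = 0, gainG = 1)
  expect_true(all(pb@fh == 0) && all(pb@fv == 0))
  expect_error(correctPair(polarizationPair(fh, fv), bleedK = 1), "k")
  ## gain scales the corrected fv
  pg <- correctPair(polarizationPair(fh, fv), backgroundH = 0,
                    backgroundV = 0, bleedK = 0, gainG = 2)
  expect_equal(pg@fv, fv * 2)
})

test_that("dichroic ratio map computes r with masking", {
  pair <- polarizationPair(matrix(2, 4, 4), matrix(1, 4, 4))
  mp <- dichroicRatioMap(pair)
  expect_true(all(mp@ld == 2))
  expect_true(all(log2(mp@ld) == 1))
  fv <- matrix(1, 4, 4); fv[2, 2] <- 0
  mp2 <- dichroicRatioMap(polarizationPair(matrix(2, 4, 4), fv))
  expect_false(mp2@valid[2, 2])
  expect_true(is.na(mp2@ld[2, 2]))
  ## below-threshold pixels masked, not errored
  mp3 <- dichroicRatioMap(pair, minIntensity = 5)
  expect_false(any(mp3@valid))
})

test_that("ring pair data match the forward model at tangent-horizontal arcs", {
  pl <- ringPipeline("1P", seed = 21)
  s <- pl$samples@samples
  arc <- s$theta < 5 | s$theta > 175
  pred <- as.numeric(predictLog2r(tiltDistribution(90, 10), 0, "1P"))
  expect_lt(abs(stats::weighted.mean(s$log2r[arc], s$weight[arc]) - pred),
            0.1)
})

test_that("harmonic per-pixel fit is exact on the cos^2 model", {
  th <- seq(0, 165, by = 15)
  F <- 1 + cos((th - 30) * pi / 180)^2
  frames <- array(rep(F, each = 4), dim = c(2, 2, 12))
  mp <- fitStackPerPixel(polarizationStack(frames, th, "1P"))
  expect_equal(mp@ld[1, 1], 2, tolerance = 1e-12)
  expect_equal(mp@azimuth[1, 1], 30, tolerance = 1e-10)
  expect_equal(mp@fitParams$a[1, 1], 1, tolerance = 1e-12)
  expect_equal(mp@fitParams$b[1, 1], 1, tolerance = 1e-12)
  ## iterative least squares reaches the same optimum
  fit <- minpack.lm::nlsLM(y ~ A + B * cos((x - C) * pi / 180)^2,
                           data.frame(x = th, y = F),
                           start = list(A = 0.9, B = 1.2, C = 20))
  co <- coef(fit)
  expect_equal(unname((co["A"] + co["B"]) / co["A"]), mp@ld[1, 1],
               tolerance = 1e-9)
  ## constant stack: r_max = 1, azimuth undefined
  cf <- array(5, dim = c(2, 2, 12))
  mpc <- fitStackPerPixel(polarizationStack(cf, th, "1P"))
  expect_equal(mpc@ld[1, 1], 1)
  expect_true(is.na(mpc@azimuth[1, 1]))
})

test_that("harmonic fit tolerates Poisson noise at 1e4 counts", {
  set.seed(9)
  th <- seq(0, 165, by = 15)
  F <- 1e4 * (1 + cos((th - 30) * pi / 180)^2) / 2
  n <- 40 * 40
  frames <- array(rpois(n * 12, rep(F, each = n)), dim = c(40, 40, 12))
  mp <- fitStackPerPixel(polarizationStack(frames, th, "1P"))
  dev <- abs(mp@azimuth - 30)
  dev <- pmin(dev, 180 - dev)
  expect_gte(mean(dev <= 2, na.rm = TRUE), 0.95)
})

test_that("pair map and stack fit agree on a noiseless 2-orientation reduction", {
  th <- seq(0, 165, by = 15)
  F <- 3 + 2 * cos(th * pi / 180)^2           # azimuth at 0
  frames <- array(rep(F, each = 4), dim = c(2, 2, 12))
  mp <- fitStackPerPixel(polarizationStack(frames, th, "1P"))
  pair <- polarizationPair(matrix(F[th == 0], 2, 2),
                           matrix(F[th == 90], 2, 2))
  dm <- dichroicRatioMap(pair)
  expect_equal(mp@ld[1, 1], dm@ld[1, 1], tolerance = 1e-12)
  expect_equal(mp@azimuth[1, 1] %% 180, 0, tolerance = 1e-9)
})

test_that("bleaching correction flattens exponential decay", {
  th <- seq(0, 165, by = 15)
  fr <- array(0, c(8, 8, 12))
  for (i in 1:12) fr[, , i] <- 5
  stc <- correctBleaching(polarizationStack(fr, th, "1P"))
  expect_equal(stc@frames, array(5, c(8, 8, 12)), tolerance = 1e-12)
  for (i in 1:12) fr[, , i] <- 5 * 0.9^(i - 1)
  stx <- correctBleaching(polarizationStack(fr, th, "1P"))
  expect_lt(diff(range(apply(stx@frames, 3, mean))), 1e-10)
  fr[, , 3] <- 0
  expect_error(correctBleaching(polarizationStack(fr, th, "1P")), "positive")
})

test_that("bleaching correction reduces the r_max bias at least 5-fold", {
  mkStack <- function(bleach, seed) {
    sc <- sceneSpec(distribution = tiltDistribution(90, 10), modality = "1P",
                    acquisition = list(mode = "stack",
                                       angles = seq(0, 165, 15)),
                    photons = 1e4, bleach = bleach, seed = seed,
                    size = c(128L, 128L),
                    object = list(type = "ring", center = c(63.5, 63.5),
                                  radius = 40, width = 3))
    renderScene(sc)$data
  }
  med <- function(st) {
    mp <- fitStackPerPixel(st, minIntensity = 300)
    stats::median(log2(mp@ld[mp@valid]), na.rm = TRUE)
  }
  ref <- med(mkStack(1, 31))
  raw <- med(mkStack(0.95, 31))
  cor <- med(correctBleaching(mkStack(0.95, 31)))
  expect_lt(abs(cor - ref), abs(raw - ref) / 5)
})

test_that("LD rendering maps hue and brightness as documented", {
  ld <- matrix(1, 4, 4)
  iv <- matrix(c(100, 200, 300, 400), 4, 4)
  m <- methods::new("PixelLDMap", intensity = iv, ld = ld,
                    azimuth = matrix(NA_real_, 4, 4),
                    valid = matrix(TRUE, 4, 4), fitParams = list(),
                    mode = "pair")
  rgb <- renderLDImage(m)
  ## ld = 1 is mid-scale: green in the blue -> red ramp
  midHue <- grDevices::col2rgb(grDevices::hsv(1 / 3, 1, 1))[, 1] / 255
  b <- iv / stats::quantile(iv, 0.99)
  for (ch in 1:3)
    expect_equal(rgb[, , ch], pmin(b, 1) * midHue[ch], tolerance = 1e-12)
  ## clip bounds map to the exact endpoint hues
  m2 <- methods::new("PixelLDMap", intensity = matrix(1, 1, 2),
                     ld = matrix(c(2^-2, 2^2), 1, 2),
                     azimuth = matrix(NA_real_, 1, 2),
                     valid = matrix(TRUE, 1, 2), fitParams = list(),
                     mode = "pair")
  rgb2 <- renderLDImage(m2, hueRange = c(-2, 2))
  expect_equal(rgb2[1, 1, ], c(0, 0, 1))    # blue end
  expect_equal(rgb2[1, 2, ], c(1, 0, 0))    # red end
  expect_error(renderLDImage(m, hueRange = c(1, 1)), "lo < hi")
  ## renders are pure functions
  expect_identical(renderLDImage(m), renderLDImage(m))
})

test_that("color bar reproduces the exact hue ramp of the renderer", {
  cb <- ldColorbar(c(-2, 2), width = 64, height = 4)
  ld <- matrix(2^seq(-2, 2, length.out = 64), 1, 64)
  m <- methods::new("PixelLDMap", intensity = matrix(1e4, 1, 64), ld = ld,
                    azimuth = matrix(NA_real_, 1, 64),
                    valid = matrix(TRUE, 1, 64), fitParams = list(),
                    mode = "pair")
  rr <- renderLDImage(m)
  expect_equal(rr[1, , ], cb[1, , ], tolerance = 1e-12)
})

test_that("azimuth overlay degenerates to the azimuth-hue rendering", {
  sc <- sceneSpec(distribution = tiltDistribution(90, 10), modality = "1P",
                  acquisition = list(mode = "stack",
                                     angles = seq(0, 165, 15)),
                  photons = 1e4, seed = 5, size = c(96L, 96L),
                  object = list(type = "ring", center = c(47.5, 47.5),
                                radius = 30, width = 3))
  mp <- fitStackPerPixel(renderScene(sc)$data, minIntensity = 100)
  expect_identical(renderAzimuthOverlay(mp, spacing = 1, length = 1,
                                        colorMode = "azimuth"),
                   renderLDImage(mp, mode = "azimuth_hue"))
  expect_error(renderAzimuthOverlay(mp, spacing = 0), "spacing")
})

test_that("overlay lines follow the local azimuth on a horizontal filament", {
  sc <- sceneSpec(object = list(type = "segment",
                                anchors = rbind(c(10, 32), c(117, 32)),
                                width = 2),
                  distribution = tiltDistribution(0.5, 15,
                                                  geometry = "filament"),
                  modality = "1P",
                  acquisition = list(mode = "stack",
                                     angles = seq(0, 165, 15)),
                  photons = 1e4, size = c(64L, 128L), seed = 6)
  mp <- fitStackPerPixel(renderScene(sc)$data, minIntensity = 500)
  az <- mp@azimuth[mp@valid & !is.na(mp@azimuth)]
  dev <- pmin(az, 180 - az)
  expect_lt(stats::median(dev), 3)
  ## fixed-color overlay only paints near the filament row
  ov <- renderAzimuthOverlay(mp, spacing = 4, length = 5,
                             colorMode = "fixed", color = c(1, 1, 0))
  lit <- which(ov[, , 1] > 0, arr.ind = TRUE)
  expect_true(all(abs(lit[, 1] - 33) <= 6))
})
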
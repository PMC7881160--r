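## Shared fixture builders. Everything is generated in code at test time.

## theta samples drawn directly from the forward model (+ optional noise)
mkThetaSamples <- function(alpha0, sigma, modality, geometry = "membrane",
                           noise = 0, n = 360, seed = 1, objectId = "obj",
                           thetas = NULL) {
  set.seed(seed)
  th <- if (is.null(thetas)) runif(n, 0, 180) else thetas
  d <- tiltDistribution(alpha0, sigma, geometry = geometry)
  y <- as.numeric(predictLog2r(d, th, modality))
  if (noise > 0) y <- y + rnorm(length(th), 0, noise)
  methods::new("ThetaSamples",
               samples = data.frame(theta = th, log2r = y, weight = 1),
               modality = modality, geometry = geometry, objectId = objectId)
}

## full image pipeline on a rendered ring scene -> ThetaSamples
ringPipeline <- function(modality, seed, alpha0 = 90, sigma = 10,
                         photons = 1e4, size = 256L, radius = 60,
                         objectId = paste0("ring", seed)) {
  sc <- sceneSpec(object = list(type = "ring",
                                center = rep((size - 1) / 2, 2),
                                radius = radius, width = 3),
                  distribution = tiltDistribution(alpha0, sigma),
                  modality = modality, photons = photons,
                  size = c(size, size), seed = seed)
  out <- renderScene(sc)
  pair <- correctPair(out$data, backgroundH = 0, backgroundV = 0)
  map <- dichroicRatioMap(pair, minIntensity = 50)
  m <- segmentOutline(map@intensity, "circle",
                      radii = seq(radius - 20, radius + 20), band = 2)
  sp <- fitSpline(m, closed = TRUE)
  list(scene = out, map = map, outline = sp,
       samples = assignTheta(map, sp, "membrane", modality = modality,
                             objectId = objectId))
}

## a clean ring intensity image (no polarization structure)
ringImage <- function(size = 101L, cx = 50, cy = 50, radius = 20,
                      width = 2, peak = 100) {
  x <- matrix(rep(seq_len(size) - 1, each = size), size)
  y <- matrix(rep(seq_len(size) - 1, size), size)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  peak * exp(-(d - radius)^2 / (2 * width^2))
}

## cells within delta of the map's r2 maximum
nearOptimalCount <- function(map, delta = 0.005) {
  sum(map@r2 >= max(map@r2, na.rm = TRUE) - delta, na.rm = TRUE)
}
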
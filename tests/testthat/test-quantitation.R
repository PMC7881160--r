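## Parametric LD-curve fitting, goodness maps, bootstrap, mixtures.

test_that("the 1P curve fit recovers noiseless parameters to 1e-6", {
  set.seed(1)
  th <- runif(300, 0, 180)
  y <- log2(1 + 0.5 * cos(2 * th * pi / 180)) -
    log2(1 - 0.5 * cos(2 * th * pi / 180))
  ts <- methods::new("ThetaSamples",
                     samples = data.frame(theta = th, log2r = y, weight = 1),
                     modality = "1P", geometry = "membrane", objectId = "o")
  f <- fit1P(ts)
  expect_lt(abs(f@a1p), 1e-6)
  expect_lt(abs(f@b1pFit - 0.5), 1e-6)
  expect_lt(abs(f@phi1 %% 180), 1e-3)
  expect_lt(abs(f@log2rmax - log2(3)), 1e-6)
  expect_gt(f@r2, 1 - 1e-10)
})

test_that("flat 1P data give zero amplitude and a flagged r2", {
  th <- seq(1, 179, by = 2)
  ts <- methods::new("ThetaSamples",
                     samples = data.frame(theta = th, log2r = 0, weight = 1),
                     modality = "1P", geometry = "membrane", objectId = "o")
  f <- fit1P(ts)
  expect_lt(abs(f@b1pFit), 1e-6)
  expect_lt(abs(f@log2rmax), 1e-6)
  expect_true(is.na(f@r2))
  expect_false(is.na(f@rmsd))
})

test_that("1P amplitude stays within 0.03 of truth under noise", {
  hits <- vapply(1:60, function(seed) {
    set.seed(seed)
    th <- runif(500, 0, 180)
    y <- log2(1 + 0.5 * cos(2 * th * pi / 180)) -
      log2(1 - 0.5 * cos(2 * th * pi / 180)) + rnorm(500, 0, 0.05)
    ts <- methods::new("ThetaSamples",
                       samples = data.frame(theta = th, log2r = y,
                                            weight = 1),
                       modality = "1P", geometry = "membrane",
                       objectId = "o")
    abs(fit1P(ts)@b1pFit - 0.5) <= 0.03
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("preconditions on sample count and span are enforced", {
  few <- methods::new("ThetaSamples",
                      samples = data.frame(theta = c(1, 2, 3),
                                           log2r = 0, weight = 1),
                      modality = "1P", geometry = "membrane", objectId = "o")
  expect_error(fit1P(few), ">= 8")
  narrow <- methods::new("ThetaSamples",
                         samples = data.frame(theta = runif(20, 0, 30),
                                              log2r = 0, weight = 1),
                         modality = "1P", geometry = "membrane",
                         objectId = "o")
  expect_error(fit1P(narrow), "span")
})

test_that("2P fits round-trip the forward model", {
  th <- seq(0.25, 179.75, by = 0.5)
  d <- tiltDistribution(90, 10)
  y <- as.numeric(predictLog2r(d, th, "2P"))
  ts <- methods::new("ThetaSamples",
                     samples = data.frame(theta = th, log2r = y, weight = 1),
                     modality = "2P", geometry = "membrane", objectId = "o")
  fr <- fit2P(ts, restricted = TRUE)
  expect_equal(fr@alpha0, 90)
  expect_equal(fr@sigma, 10)
  fu <- fit2P(ts)
  sp <- shapeParams(d)
  expect_lt(abs(fu@b2pFit - sp@b2p), 1e-4)
  expect_lt(abs(fu@c2pFit - sp@c2p), 1e-4)
  ## restricted r2 never exceeds the unrestricted r2
  expect_lte(fr@r2, fu@r2 + 1e-6)
})

test_that("restricted r2 <= unrestricted r2 on noisy data", {
  for (seed in 1:4) {
    set.seed(seed)
    a0 <- sample(10:90, 1); s <- sample(5:40, 1)
    th <- runif(250, 0, 180)
    y <- as.numeric(predictLog2r(tiltDistribution(a0, s), th, "2P")) +
      rnorm(250, 0, 0.1)
    ts <- methods::new("ThetaSamples",
                       samples = data.frame(theta = th, log2r = y,
                                            weight = 1),
                       modality = "2P", geometry = "membrane",
                       objectId = "o")
    expect_lte(fit2P(ts, restricted = TRUE)@r2, fit2P(ts)@r2 + 1e-6)
  }
})

test_that("isotropic 2P data yield vanishing shape parameters", {
  set.seed(2)
  th <- runif(200, 0, 180)
  ts <- methods::new("ThetaSamples",
                     samples = data.frame(theta = th,
                                          log2r = rnorm(200, 0, 0.01),
                                          weight = 1),
                     modality = "2P", geometry = "membrane", objectId = "o")
  f <- fit2P(ts)
  expect_lt(abs(f@b2pFit), 0.02)
  expect_lt(abs(f@c2pFit), 0.02)
})

test_that("the positivity constraint keeps adversarial 2P fits finite", {
  set.seed(3)
  th <- runif(150, 0, 180)
  ## spiky data no positive-polynomial curve can follow
  y <- ifelse(abs(th - 90) < 10, 12, -12) + rnorm(150, 0, 0.5)
  ts <- methods::new("ThetaSamples",
                     samples = data.frame(theta = th, log2r = y, weight = 1),
                     modality = "2P", geometry = "membrane", objectId = "o")
  f <- fit2P(ts)
  grid <- seq(0, 179.5, by = 0.5)
  curve <- polarLD:::.fm2PCurve(grid, f@a2p, f@b2pFit, f@c2pFit, f@phi1,
                                f@phi2, "membrane")
  expect_true(all(is.finite(curve)))
  expect_lt(f@r2, 0.9)
})

test_that("noiseless goodness maps recover the generating cell", {
  tab <- defaultLookupTable()
  ts <- mkThetaSamples(40, 20, "2P", thetas = seq(0.25, 179.75, 0.5))
  g <- goodnessMap(ts, tab)
  expect_equal(g@best, c(40, 20))
  ## 1P-only: the near-optimal set traces the b1p level set
  t1 <- mkThetaSamples(40, 20, "1P", thetas = seq(0.25, 179.75, 0.5))
  g1 <- goodnessMap(t1, tab)
  near <- which(g1@r2 >= max(g1@r2, na.rm = TRUE) - 1e-4, arr.ind = TRUE)
  expect_gt(nrow(near), 3)      # non-unique: a one-parameter family
  b1true <- shapeParams(tiltDistribution(40, 20))@b1p
  b1near <- tab@b1p[near]
  expect_lt(max(abs(b1near - b1true)), 5e-3)
  ## zero-variance data: r2 flagged, RMSD still defined
  t0 <- methods::new("ThetaSamples",
                     samples = data.frame(theta = seq(1, 179, 2), log2r = 0,
                                          weight = 1),
                     modality = "1P", geometry = "membrane", objectId = "o")
  g0 <- goodnessMap(t0, tab)
  expect_true(all(is.na(g0@r2)))
  expect_true(all(is.finite(g0@rmsd)))
})

test_that("noiseless combined inference returns the truth cell exactly", {
  tab <- defaultLookupTable()
  set.seed(7)
  for (i in 1:20) {
    a0 <- sample(5:90, 1); s <- sample(2:60, 1)
    sets <- list(mkThetaSamples(a0, s, "1P", thetas = seq(0.25, 179.75, 1)),
                 mkThetaSamples(a0, s, "2P", thetas = seq(0.25, 179.75, 1)))
    g <- goodnessMap(sets, tab)
    expect_equal(g@best, c(a0, s))
  }
})

test_that("pooling behaves like weighting and flags conflicting data", {
  tab <- defaultLookupTable()
  one <- mkThetaSamples(25, 25, "2P", noise = 0.05, seed = 3)
  dup <- methods::new("ThetaSamples", samples = one@samples,
                      modality = "2P", geometry = "membrane",
                      objectId = "copy")
  fOne <- fit2P(one)
  fDup <- suppressMessages(poolAndFit(list(one, dup), tab))$fit2p
  expect_equal(fDup@b2pFit, fOne@b2pFit, tolerance = 1e-6)
  expect_equal(fDup@log2rmax, fOne@log2rmax, tolerance = 1e-6)
  ## combined fit of conflicting truths fits worse than either alone
  s1 <- mkThetaSamples(85, 8, "1P", noise = 0.02, seed = 4)
  s2 <- mkThetaSamples(20, 30, "2P", noise = 0.02, seed = 5)
  m1 <- goodnessMap(s1, tab); m2 <- goodnessMap(s2, tab)
  mc <- goodnessMap(list(s1, s2), tab)
  expect_lt(max(mc@r2, na.rm = TRUE),
            max(max(m1@r2, na.rm = TRUE), max(m2@r2, na.rm = TRUE)))
})

test_that("combined data sharpen the degenerate 1P band", {
  tab <- defaultLookupTable()
  s1 <- mkThetaSamples(25, 25, "1P", noise = 0.03, seed = 6, n = 720)
  s2 <- mkThetaSamples(25, 25, "2P", noise = 0.03, seed = 7, n = 720)
  res <- poolAndFit(list(s1, s2), tab)
  expect_lte(max(abs(res$combined@best - c(25, 25))), 2)
  n1 <- nearOptimalCount(res$map1p)
  nc <- nearOptimalCount(res$combined)
  expect_gt(n1, 10)            # 1P alone: a one-parameter family of fits
  expect_lt(nc, n1)            # adding 2P information shrinks the set
  ## the 2P best distribution predicts the 1P curve
  pred <- res$predicted1PFrom2P
  truth <- as.numeric(predictLog2r(tiltDistribution(25, 25), pred$theta,
                                   "1P"))
  expect_lt(max(abs(pred$log2r - truth)), 0.2)
})

test_that("bootstrap confidence masks cover the truth and are stable", {
  tab <- defaultLookupTable()
  mkObj <- function(i)
    list(mkThetaSamples(90, 10, "1P", noise = 0.1, n = 120, seed = i,
                        objectId = paste0("o", i)),
         mkThetaSamples(90, 10, "2P", noise = 0.1, n = 120, seed = 500 + i,
                        objectId = paste0("o", i)))
  sets <- unlist(lapply(1:12, mkObj), recursive = FALSE)
  bm <- bootstrapConfidence(sets, tab, nBoot = 100, seed = 11)
  ia <- which(bm@alpha0 == 90); js <- which(bm@sigma == 10)
  expect_true(bm@confidence[ia, js])
  ## determinism given the seed
  bm2 <- bootstrapConfidence(sets, tab, nBoot = 100, seed = 11)
  expect_identical(bm@confidence, bm2@confidence)
  ## two seeds: mask overlap of at least 90 percent
  bm3 <- bootstrapConfidence(sets, tab, nBoot = 100, seed = 12)
  ov <- sum(bm@confidence & bm3@confidence) /
    max(sum(bm@confidence), sum(bm3@confidence))
  expect_gte(ov, 0.9)
  ## identical objects collapse the mask to (almost) one cell
  same <- unlist(lapply(1:6, function(i) {
    o <- mkObj(1)
    o[[1]]@objectId <- paste0("s", i); o[[2]]@objectId <- paste0("s", i)
    o
  }), recursive = FALSE)
  bs <- bootstrapConfidence(same, tab, nBoot = 100, seed = 13)
  expect_lte(sum(bs@confidence), 2)
  expect_warning(bootstrapConfidence(sets, tab, nBoot = 20, seed = 1),
                 "nBoot")
  expect_error(bootstrapConfidence(sets[1], tab, nBoot = 100, seed = 1),
               "2 distinct")
})

test_that("mixture search recovers degenerate and true mixtures", {
  tg <- shapeParams(tiltDistribution(90, 10))
  cand <- mixtureSearch(tg)
  top <- cand[1, ]
  expect_lt(top$residual, 1e-3)
  expect_true(top$f >= 0.95 ||
                (top$alpha0A == top$alpha0B && top$sigmaA == top$sigmaB))
  ## isotropic targets: ties resolved towards maximal entropy (widest sigma)
  iso <- mixtureSearch(c(0, 0, 0), topK = 200L)
  expect_lt(max(abs(c(iso$b1p[1], iso$b2p[1], iso$c2p[1]))), 0.05)
  ## the entropy tie-break ranks the least committal representation first:
  ## its entropy matches or beats the widest single Gaussian searched
  singles <- iso[iso$f >= 0.95 & iso$sigmaA == 45, ]
  if (nrow(singles)) expect_gte(iso$entropy[1], max(singles$entropy) - 1e-6)
  expect_gte(max(iso$sigmaA[1], iso$sigmaB[1]), 40)
  ## a true 50/50 mixture is contained among the candidates
  mix <- tiltDistribution(c(90, 20), c(10, 10), c(0.5, 0.5))
  cm <- mixtureSearch(shapeParams(mix), topK = 50)
  hit <- with(cm, (abs(alpha0A - 90) <= 10 & abs(alpha0B - 20) <= 10 &
                     abs(sigmaA - 10) <= 10 & abs(sigmaB - 10) <= 10) |
                  (abs(alpha0B - 90) <= 10 & abs(alpha0A - 20) <= 10 &
                     abs(sigmaB - 10) <= 10 & abs(sigmaA - 10) <= 10))
  expect_true(any(hit & cm$residual < 1e-3))
})

test_that("rmax-to-orientation matching narrows with both modalities", {
  tab <- defaultLookupTable()
  grid <- seq(0, 179.5, by = 0.5)
  d <- tiltDistribution(25, 25)
  v1 <- polarLD:::.log2rmaxFromCurve(grid,
    as.numeric(predictLog2r(d, grid, "1P")))
  v2 <- polarLD:::.log2rmaxFromCurve(grid,
    as.numeric(predictLog2r(d, grid, "2P")))
  both <- rmaxToOrientation(v1, v2, tab)
  expect_true(any(both$alpha0 == 25 & both$sigma == 25))
  only1 <- rmaxToOrientation(v1, table = tab)
  expect_gt(nrow(only1), nrow(both))
  ## log2rmax = 0 selects the b1p = 0 level set incl. the magic angle ridge
  lvl <- rmaxToOrientation(0, table = tab)
  expect_true(any(abs(lvl$alpha0 - 55) <= 1 & lvl$sigma <= 3))
  ## infeasible value: empty result plus the achievable range
  out <- suppressMessages(rmaxToOrientation(10, table = tab))
  expect_identical(nrow(out), 0L)
  expect_true(!is.null(attr(out, "achievableRange")))
})
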
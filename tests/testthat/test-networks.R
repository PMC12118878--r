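# Architectures, receptive fields, objectives, and engine gradients.

test_that("generator preserves shape and halves down to the declared bottleneck", {
  spec <- generatorSpec(32L, baseFilters = 8L)
  set.seed(2)
  G <- buildGenerator(spec)
  x <- matrix(runif(32 * 32, -1, 1), 32)
  y <- netForward(G, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(abs(y) <= 1))          # tanh output range
  # spatial sides of the encoder chain: 16, 8, 4, 2
  sides <- vapply(G$enc, function(b) b$geom$hOut, integer(1))
  expect_identical(sides, c(16L, 8L, 4L, 2L))
  # the canonical 8-level geometry reaches a 1x1 bottleneck at 256
  deep <- buildGenerator(generatorSpec(256L, baseFilters = 1L, nLevels = 8L))
  expect_identical(deep$enc[[8]]$geom$hOut, 1L)
  expect_error(generatorSpec(48L, nLevels = 5L), "divisible")
})

test_that("dropout placement follows the first-three/last-three block rule", {
  spec <- generatorSpec(64L, baseFilters = 4L)    # 5 levels
  G <- buildGenerator(spec)
  expect_identical(vapply(G$enc, `[[`, logical(1), "useDropout"),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(vapply(G$dec, `[[`, logical(1), "useDropout"),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # first encoder block carries no normalization
  expect_false(G$enc[[1]]$useNorm)
  expect_true(all(vapply(G$enc[-1], `[[`, logical(1), "useNorm")))
})

test_that("discriminator geometry matches the 70x70 patch classifier", {
  spec <- discriminatorSpec(256L)
  expect_identical(spec$widths, c(64L, 128L, 256L, 512L))
  expect_identical(spec$strides, c(2L, 2L, 2L, 1L, 1L))
  expect_identical(patchReceptiveField(spec), 70L)
  expect_identical(discOutputSide(spec), 30L)
  expect_error(discriminatorSpec(32L, widths = c(64L, 128L, 256L, 512L),
                                 strides = c(2L, 2L, 2L, 1L, 1L)),
               "receptive field")
})

test_that("receptive-field arithmetic and gradient footprint agree on ablated stacks", {
  # kernel-4 stride-2 stacks of depth 1 and 2: receptive fields 4 and 10
  for (cfg in list(list(w = integer(0), st = 2L, rf = 4L),
                   list(w = 8L, st = c(2L, 2L), rf = 10L))) {
    sp <- discriminatorSpec(16L, widths = cfg$w, strides = cfg$st)
    expect_identical(patchReceptiveField(sp), cfg$rf)
    set.seed(1)
    D <- buildDiscriminator(sp)
    expect_identical(unname(gradientFootprint(D)), rep(cfg$rf, 2L))
  }
})

test_that("Huber loss matches its closed forms and is C1 at the threshold", {
  z <- matrix(0, 4, 4)
  expect_equal(huberLoss(z, z), 0)
  expect_equal(huberLoss(z + 0.5, z, delta = 1), 0.125)
  expect_equal(huberLoss(z + 2, z, delta = 1), 1.5)
  expect_error(huberLoss(z, matrix(0, 3, 3)), "mismatch")
  # continuity and C1 at |r| = delta, monotone in |r|
  r <- seq(0.8, 1.2, by = 1e-4)
  vals <- vapply(r, function(ri) huberLoss(matrix(ri), matrix(0)), numeric(1))
  expect_true(all(diff(vals) > 0))
  d1 <- diff(vals) / 1e-4
  expect_lt(max(abs(diff(d1))), 1e-3)   # derivative has no jump at r = 1
})

test_that("SSIM loss is zero on self, bounded, and matches the reference implementation", {
  set.seed(11)
  x <- matrix(runif(32 * 32), 32)
  y <- pmin(pmax(x + matrix(rnorm(32 * 32, 0, 0.08), 32), 0), 1)
  expect_equal(ssimLoss(x, x), 0, tolerance = 1e-12)
  # frozen from scikit-image structural_similarity (gaussian_weights=TRUE,
  # sigma=1.5, use_sample_covariance=FALSE, data_range=1) on this fixture
  expect_equal(ssimLoss(x, y, dynamicRange = 1), 0.0376582741, tolerance = 1e-6)
  expect_gte(ssimLoss(x, 1 - x), 0)
  expect_lte(ssimLoss(x, 1 - x), 2)
  expect_error(ssimLoss(matrix(0.1, 8, 8), matrix(0.2, 8, 8)), "window")
})

test_that("objective wiring is linear with the declared weights", {
  expect_equal(generatorObjective(0, 1, 0, 100), 100)
  expect_equal(generatorObjective(0, 0, 0), 0)
  expect_equal(generatorObjective(0.7, 0.02, 0.05), 7.7)
  # slope 1 in the adversarial term, lambda in each reconstruction term
  base <- generatorObjective(0.3, 0.1, 0.2, 50)
  expect_equal(generatorObjective(1.3, 0.1, 0.2, 50) - base, 1)
  expect_equal(generatorObjective(0.3, 1.1, 0.2, 50) - base, 50)
  expect_equal(generatorObjective(0.3, 0.1, 1.2, 50) - base, 50)
})

test_that("discriminator objective reproduces the BCE limits", {
  half <- matrix(0.5, 5, 5)
  expect_equal(discriminatorObjective(half, half, fromLogits = FALSE),
               2 * log(2), tolerance = 1e-12)
  good <- matrix(1 - 1e-9, 5, 5)
  expect_lt(discriminatorObjective(good, 1 - good, fromLogits = FALSE), 1e-6)
  # logits path agrees with manual stable BCE
  set.seed(4)
  zr <- matrix(rnorm(25), 5)
  zf <- matrix(rnorm(25), 5)
  manual <- mean(-log(plogis(zr))) + mean(-log(1 - plogis(zf)))
  expect_equal(discriminatorObjective(zr, zf), manual, tolerance = 1e-10)
})

test_that("dropout zeroes half the units in training and none at inference", {
  set.seed(8)
  X <- array(1, c(100, 100, 1))
  d <- PADenoise:::dropoutForward(X, 0.5, training = TRUE)
  expect_lt(abs(mean(d$Y == 0) - 0.5), 0.01)
  expect_equal(mean(d$Y), 1, tolerance = 0.05)   # inverted scaling keeps E[x]
  expect_identical(PADenoise:::dropoutForward(X, 0.5, training = FALSE)$Y, X)
})

test_that("layer backward passes match finite differences", {
  set.seed(42)
  geom <- PADenoise:::convGeom(6L, 6L, 3L, 4L, 2L, 1L)
  X <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  W <- matrix(rnorm(48 * 2), 48, 2)
  b <- rnorm(2)
  cf <- PADenoise:::convForward(X, W, b, geom)
  Tg <- array(rnorm(length(cf$Y)), dim(cf$Y))
  cb <- PADenoise:::convBackward(Tg, cf$cols, W, geom)
  lossX <- function(v) sum(PADenoise:::convForward(array(v, dim(X)), W, b, geom)$Y * Tg)
  expect_equal(as.vector(cb$dX), numGrad(lossX, as.vector(X)), tolerance = 1e-6)
  lossW <- function(v) sum(PADenoise:::convForward(X, matrix(v, 48), b, geom)$Y * Tg)
  expect_equal(as.vector(cb$dW), numGrad(lossW, as.vector(W)), tolerance = 1e-6)

  geomT <- PADenoise:::convGeom(6L, 6L, 3L, 4L, 2L, 1L)
  Xt <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  Wt <- matrix(rnorm(2 * 48), 2, 48)
  bt <- rnorm(3)
  ctf <- PADenoise:::convTForward(Xt, Wt, bt, geomT)
  Tt <- array(rnorm(length(ctf$Y)), dim(ctf$Y))
  ctb <- PADenoise:::convTBackward(Tt, ctf$Xmat, Wt, geomT)
  lossXt <- function(v) sum(PADenoise:::convTForward(array(v, dim(Xt)), Wt, bt, geomT)$Y * Tt)
  expect_equal(as.vector(ctb$dXmat), numGrad(lossXt, as.vector(Xt)), tolerance = 1e-6)

  Xb <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  g <- c(1.2, 0.8); bb <- c(0.1, -0.2)
  bf <- PADenoise:::bnForward(Xb, g, bb)
  Tb <- array(rnorm(length(bf$Y)), dim(bf$Y))
  bw <- PADenoise:::bnBackward(Tb, bf, g)
  lossB <- function(v) sum(PADenoise:::bnForward(array(v, dim(Xb)), g, bb)$Y * Tb)
  expect_equal(as.vector(bw$dX), numGrad(lossB, as.vector(Xb)), tolerance = 1e-6)
})

test_that("the analytic SSIM gradient matches finite differences", {
  set.seed(13)
  x <- matrix(runif(15 * 15), 15)
  y <- matrix(runif(15 * 15), 15)
  ana <- PADenoise:::ssimLossGradient(x, y, dynamicRange = 1)
  num <- numGrad(function(v) ssimLoss(matrix(v, 15), y, dynamicRange = 1),
                 as.vector(x))
  expect_equal(as.vector(ana), num, tolerance = 1e-6)
})

test_that("MAE behaves as the U-Net objective and the baseline builds", {
  z <- matrix(0.3, 6, 6)
  expect_equal(maeLoss(z, z), 0)
  expect_equal(maeLoss(z + 0.25, z), 0.25)
  set.seed(3)
  U <- buildUnetBaseline(generatorSpec(32L, 4L))
  expect_identical(U$kind, "unet")
  out <- netForward(U, matrix(runif(1024, -1, 1), 32))
  expect_identical(dim(out), c(32L, 32L))
})
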
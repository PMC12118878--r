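# Phantom rendering, frame-average pairing, and bleaching simulation.

test_that("phantom rendering honours the declared amplitude range and is deterministic", {
  spec <- phantomSpec("tube_cross_section", radius = 14, thickness = 3,
                      amplitude = 1, backgroundLevel = 0)
  img <- makePhantom(spec, c(64L, 64L), seed = 5L)
  expect_equal(max(img), 1.0)
  expect_equal(min(img), 0.0)
  expect_identical(img, makePhantom(spec, c(64L, 64L), seed = 5L))

  vt <- phantomSpec("vessel_tree", thickness = 2.5)
  expect_identical(makePhantom(vt, c(64L, 64L), 9L), makePhantom(vt, c(64L, 64L), 9L))
  expect_false(identical(makePhantom(vt, c(64L, 64L), 9L),
                         makePhantom(vt, c(64L, 64L), 10L)))
})

test_that("fiber stroke covers the analytically expected pixel area", {
  # Straight stroke of FWHM thickness t across a w-wide image covers
  # approximately length * t pixels above half maximum.
  spec <- phantomSpec("fiber", thickness = 3)
  img <- makePhantom(spec, c(128L, 128L), seed = 1L)
  area <- sum(img > spec@backgroundLevel + 0.5 * (spec@amplitude - spec@backgroundLevel))
  expect_lt(abs(area - 128 * 3) / (128 * 3), 0.10)
})

test_that("out-of-image geometry is rejected with a descriptive error", {
  expect_error(makePhantom(phantomSpec("tube_cross_section", radius = 40),
                           c(64L, 64L), 1L), "does not fit")
  expect_error(makePhantom(phantomSpec("fiber", center = c(200, 200)),
                           c(64L, 64L), 1L), "outside")
  expect_error(makePhantom(phantomSpec("tube_cross_section"), c(16L, 16L), 1L),
               "32x32")
})

test_that("paired datasets follow the sigma/sqrt(F) frame-average law", {
  # 25600-pixel images x 8 pairs gives > 1e5 residual samples per F.
  spec <- phantomSpec("fiber", thickness = 3)
  for (f in c(1L, 16L, 128L)) {
    ds <- makePairedDataset(list(spec), 8L, FIn = f, FLabel = 25600L,
                            perFrameNoiseSigma = 0.5, seed = 3L,
                            shape = c(160L, 160L))
    resid <- unlist(lapply(ds, function(s) {
      clean <- makePhantom(spec, c(160L, 160L),
                           seed = PADenoise:::deriveSeed(s@meta$seed, 1L))
      s@input - clean
    }))
    expect_lt(abs(sd(resid) - 0.5 / sqrt(f)) / (0.5 / sqrt(f)), 0.05)
  }
  # the default acquisition protocol: inputs at 128 averages, labels at 25600
  ds <- makePairedDataset(list(spec), 8L, FIn = 128L, FLabel = 25600L,
                          perFrameNoiseSigma = 0.5, seed = 4L,
                          shape = c(160L, 160L))
  residIn <- unlist(lapply(ds, function(s) {
    s@input - makePhantom(spec, c(160L, 160L),
                          seed = PADenoise:::deriveSeed(s@meta$seed, 1L))
  }))
  residLab <- unlist(lapply(ds, function(s) {
    s@target - makePhantom(spec, c(160L, 160L),
                           seed = PADenoise:::deriveSeed(s@meta$seed, 1L))
  }))
  expect_lt(abs(sd(residIn) - 0.0441942) / 0.0441942, 0.05)
  expect_lt(abs(sd(residLab) - 0.003125) / 0.003125, 0.05)
})

test_that("paired dataset generation is reproducible and validates input", {
  specs <- defaultPhantomSet(1L)
  a <- makePairedDataset(specs, 3L, seed = 7L, shape = c(32L, 32L))
  b <- makePairedDataset(specs, 3L, seed = 7L, shape = c(32L, 32L))
  expect_identical(lapply(a, inputImage), lapply(b, inputImage))
  expect_identical(dim(a[[1]]@input), dim(a[[1]]@target))
  expect_error(makePairedDataset(specs, 0L, seed = 1L), "positive")
  expect_error(makePairedDataset(specs, 2L, FIn = 200L, FLabel = 100L), "FLabel")
})

test_that("point-exposure kinetics follow the (1-beta)^k decay", {
  expect_equal(simulatePointExposure(bleachModel(beta = 0), 50),
               rep(1, 51))
  # beta = 1e-3 over 430 pulses reproduces a ~35% amplitude drop
  tr <- simulatePointExposure(bleachModel(beta = 0.001), 430)
  expect_equal(tr[431], 0.999^430, tolerance = 1e-12)
  expect_equal(tr[431], 0.6504, tolerance = 1e-3)
  expect_true(all(diff(tr) < 0))
  expect_error(simulatePointExposure(bleachModel(beta = 0.01), 0), ">= 1")
})

test_that("raster-scan simulation matches the closed-form dose oracle", {
  # Independent oracle: position k has received P pulses from every earlier
  # position j (attenuation (1-beta*g_jk)^P) and p own pulses before its
  # p-th recorded pulse, so the frame-averaged dose is
  #   prod_j<k (1-beta*g_jk)^P * mean_p (1-beta)^p.
  spec <- phantomSpec("tube_cross_section", radius = 10, thickness = 3)
  bl <- bleachModel(beta = 0.01, stepMm = 0.1, beamSigmaMm = 0.2)
  P <- 30L
  n <- 7L
  se <- simulateRasterScan(spec, bl, n, P, noiseSigmaPerPulse = 0, seed = 2L,
                           shape = c(64L, 64L))
  g <- function(du) exp(-2 * du^2 / bl@beamSigmaMm^2)
  pos <- positionsMm(se)
  oracle <- vapply(seq_len(n), function(k) {
    pre <- 1
    for (j in seq_len(k - 1)) pre <- pre * (1 - bl@beta * g(pos[k] - pos[j]))^P
    pre * mean((1 - bl@beta * g(0))^(0:(P - 1)))
  }, numeric(1))
  expect_equal(doseAmplitudes(se), oracle * spec@amplitude, tolerance = 1e-12)
  # noiseless frames: measured peak equals the dose amplitude
  expect_equal(peakAmplitudes(se), doseAmplitudes(se), tolerance = 1e-12)
})

test_that("no-bleach and no-overlap limits show no photobleaching", {
  spec <- phantomSpec("tube_cross_section", radius = 10, thickness = 3)
  se0 <- simulateRasterScan(spec, bleachModel(beta = 0), 6L, 5L,
                            noiseSigmaPerPulse = 0, seed = 1L, c(64L, 64L))
  expect_equal(doseAmplitudes(se0), rep(spec@amplitude, 6), tolerance = 1e-12)
  # vanishing beam overlap + single pulse: every position sees fresh dye
  seNarrow <- simulateRasterScan(spec,
    bleachModel(beta = 0.05, stepMm = 0.1, beamSigmaMm = 1e-6), 6L, 1L,
    noiseSigmaPerPulse = 0, seed = 1L, c(64L, 64L))
  pct <- photobleachPercentage(seNarrow)
  expect_equal(pct$percent, rep(0, 6), tolerance = 1e-9)
})

test_that("final-position bleaching is non-decreasing in pulses per position", {
  spec <- phantomSpec("tube_cross_section", radius = 10, thickness = 3)
  bl <- bleachModel(beta = 0.01)
  final <- vapply(c(1L, 5L, 30L), function(P) {
    se <- simulateRasterScan(spec, bl, 8L, P, noiseSigmaPerPulse = 0,
                             seed = 3L, shape = c(64L, 64L))
    tail(photobleachPercentage(se)$percent, 1)
  }, numeric(1))
  expect_true(all(diff(final) >= 0))
  expect_error(simulateRasterScan(spec, bl, 1L, 1L, 0, 1L), ">= 2")
  expect_error(bleachModel(beta = 1.2), "beta")
})
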
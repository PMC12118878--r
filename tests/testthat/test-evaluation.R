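# Experiment harnesses. Uses the shared cached test-scale cGAN.

test_that("compareMethods includes the raw input row and honours identity methods", {
  clean <- lapply(1:3, function(k) {
    makePhantom(phantomSpec("fiber", thickness = 3, amplitude = 0.9),
                c(32L, 32L), k)
  })
  roi <- testBenchRoi()
  tab <- compareMethods(clean, noiseSpec("gaussian", sigma = 0.1),
                        list(copy = identity), roi, seeds = 1L)
  expect_setequal(tab$method, c("input", "copy"))
  expect_equal(tab[tab$method == "copy", -1], tab[tab$method == "input", -1],
               ignore_attr = TRUE)
  # zero-noise spec: every pass-through method scores the clean image
  tab0 <- compareMethods(clean, noiseSpec("gaussian", sigma = 0),
                         list(copy = identity), roi, seeds = 1L)
  expect_equal(tab0[tab0$method == "input", "snrMean"],
               mean(vapply(clean, snr, numeric(1), roi = roi)))
})

test_that("compareMethods aggregates are invariant to image order and robust to failures", {
  clean <- lapply(1:4, function(k) {
    makePhantom(phantomSpec("fiber", thickness = 3, amplitude = 0.8 + 0.03 * k),
                c(32L, 32L), k)
  })
  roi <- testBenchRoi()
  ns <- noiseSpec("gaussian", sigma = 0.1)
  t1 <- compareMethods(clean, ns, list(sg = savitzkyGolay), roi, seeds = 2L)
  t2 <- compareMethods(rev(clean), ns, list(sg = savitzkyGolay), roi, seeds = 2L)
  expect_equal(t1[t1$method == "sg", "snrMean"], t2[t2$method == "sg", "snrMean"],
               tolerance = 1e-12)
  # a failing method is recorded and the run continues
  warns <- testthat::capture_warnings(
    tf <- compareMethods(clean, ns,
                         list(bad = function(x) stop("boom"), sg = savitzkyGolay),
                         roi, seeds = 1L))
  expect_true(all(grepl("failed", warns)) && length(warns) == length(clean))
  expect_true(is.na(tf[tf$method == "bad", "snrMean"]))
  expect_true(is.finite(tf[tf$method == "sg", "snrMean"]))
})

test_that("the trained cGAN improves metrics on its own training noise", {
  model <- getTestModel()
  clean <- lapply(heldOutPairs(), targetImage)
  roi <- testBenchRoi()
  st <- noiseInvarianceStudy(clean, list(noiseSpec("gaussian", sigma = 0.1)),
                             model, roi, seeds = 1L)
  noisy <- st[st$stage == "noisy", ]
  den <- st[st$stage == "denoised", ]
  expect_gt(mean(den$snr), mean(noisy$snr))
  expect_gt(median(den$gcnr), median(noisy$gcnr))
})

test_that("the Gaussian-trained model transfers to unseen noise models", {
  # Platform-flexibility protocol: train on one noise type, evaluate on all
  # four. The study set carries a realistic nonzero background baseline --
  # count and multiplicative noise are degenerate on an exactly-zero floor.
  model <- getTestModel()
  fib <- phantomSpec("fiber", thickness = 3, orientation = 0.15,
                     amplitude = 0.9, backgroundLevel = 0.1)
  clean <- lapply(1:6, function(k) makePhantom(fib, c(32L, 32L), k))
  roi <- testBenchRoi()
  specs <- list(noiseSpec("gaussian", sigma = 0.1),
                noiseSpec("poisson", scale = 100),
                noiseSpec("salt_pepper", density = 0.1),
                noiseSpec("speckle", variance = 0.1))
  st <- noiseInvarianceStudy(clean, specs, model, roi, seeds = 1:2)
  for (kind in vapply(specs, noiseKind, character(1))) {
    sk <- st[st$noise == kind, ]
    # SNR improves in the median under every noise model
    expect_gt(median(sk$snr[sk$stage == "denoised"]),
              median(sk$snr[sk$stage == "noisy"]))
  }
  # distribution separability also improves wherever the corruption
  # broadens the intensity histograms (impulse noise instead concentrates
  # them, so GCNR is not the discriminating metric there; see vignette)
  for (kind in c("gaussian", "poisson", "speckle")) {
    sk <- st[st$noise == kind, ]
    expect_gte(median(sk$gcnr[sk$stage == "denoised"]),
               median(sk$gcnr[sk$stage == "noisy"]))
  }
  expect_identical(nrow(noiseInvarianceStudy(clean, list(), model, roi)), 0L)
})

test_that("denoised SNR degrades as injected Gaussian variance grows", {
  model <- getTestModel()
  clean <- lapply(heldOutPairs()[1:4], targetImage)
  roi <- testBenchRoi()
  sigmas <- c(0, 0.05, 0.1, 0.2, 0.4)
  tab <- varianceSweep(clean, sigmas, model, roi, seeds = 1L)
  expect_identical(nrow(tab), length(sigmas))
  expect_equal(tab$snrNoisy[1],
               mean(vapply(lapply(clean, function(x) pmin(pmax(x, 0), 1)),
                           snr, numeric(1), roi = roi)))
  rho <- cor(tab$sigma, tab$snrDenoised, method = "spearman")
  expect_lt(rho, 0)
  expect_error(varianceSweep(clean, rev(sigmas), model, roi), "ascending")
})

test_that("photobleach percentages follow their defining arithmetic", {
  spec <- phantomSpec("tube_cross_section", radius = 10, thickness = 3)
  se <- simulateRasterScan(spec, bleachModel(beta = 0.02), 6L, 10L,
                           noiseSigmaPerPulse = 0, seed = 4L, c(64L, 64L))
  pct <- photobleachPercentage(se)
  expect_equal(pct$percent[1], 0)
  amps <- c(100, 90, 65)
  fake <- se
  expect_equal(photobleachPercentage(se, amplitudes = c(amps, 80, 70, 60))$percent[3],
               35)
  # invariant under global rescaling of the trace
  a <- doseAmplitudes(se)
  expect_equal(photobleachPercentage(se, amplitudes = a)$percent,
               photobleachPercentage(se, amplitudes = 7.3 * a)$percent,
               tolerance = 1e-12)
  expect_error(photobleachPercentage(se, amplitudes = c(0, a[-1])), "zero reference")
})

test_that("the bleaching experiment reproduces the dose/quality trade-off", {
  model <- getTestModel()
  spec <- phantomSpec("tube_cross_section", radius = 9, thickness = 3,
                      amplitude = 0.9)
  rep0 <- bleachingExperiment(spec, bleachModel(beta = 0), model,
                              nPositions = 6L, nPulseAverage = 5L,
                              noiseSigmaPerPulse = 0.1, seed = 2L,
                              shape = c(32L, 32L))
  expect_true(all(abs(unlist(rep0$percent[, -1])) < 1e-9))

  rep <- bleachingExperiment(spec, bleachModel(beta = 0.01), model,
                             nPositions = 10L, nPulseAverage = 30L,
                             noiseSigmaPerPulse = 0.1, seed = 3L,
                             shape = c(32L, 32L))
  n <- nrow(rep$percent)
  # averaging bleaches strictly more than single-pulse at the scan end
  expect_gt(rep$percent$nPulseAverage[n], rep$percent$singlePulse[n])
  # denoising cannot un-bleach: identical dose schedule, identical percents
  expect_identical(rep$percent$singlePulse, rep$percent$denoisedSinglePulse)
  # but it buys SNR on the single-pulse frames
  expect_gt(rep$snr["denoisedSinglePulse"], rep$snr["singlePulse"])
})
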
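# Shared fixtures and a lazily trained, cached test-scale cGAN model.

# Test-scale benchmark conditions: 32x32 phantoms, Gaussian sigma-0.1
# corruption emulated as 25-frame averages of sigma-0.5 per-frame noise,
# base-16 generator, 1500 steps, 32 training pairs. The methods vignette
# documents this as the package's test-size choice; the desk profile
# (64x64, base 32, 2000 steps, 200 pairs) is the default elsewhere.
# Held-out evaluation uses fiber targets with the signal box aligned to
# the stroke and the background box above it.
testBenchSide <- 32L
testBenchRoi <- function() roiSpec(c(12L, 4L, 20L, 28L), c(2L, 2L, 9L, 29L))

testBenchData <- function(seed, nPairs = 32L) {
  makePairedDataset(defaultPhantomSet(seed), nPairs, FIn = 25L,
                    FLabel = 25600L, perFrameNoiseSigma = 0.5, seed = seed,
                    shape = c(testBenchSide, testBenchSide))
}

trainTestCGAN <- function(seed, steps = 1500L) {
  trainCGAN(testBenchData(seed), generatorSpec(testBenchSide, 16L),
            discriminatorSpec(testBenchSide),
            trainConfig(steps = steps, seed = seed))
}

heldOutPairs <- function(seed = 1L, nPairs = 8L) {
  fib <- phantomSpec("fiber", thickness = 3, orientation = 0.15,
                     amplitude = 0.9)
  makePairedDataset(list(fib), nPairs, FIn = 25L, FLabel = 25600L,
                    perFrameNoiseSigma = 0.5, seed = seed + 500L,
                    shape = c(testBenchSide, testBenchSide))
}

.paTestCache <- new.env(parent = emptyenv())

# One shared trained model (seed 1), reused by the evaluation and
# acceptance tests so the suite trains as few networks as possible.
getTestModel <- function() {
  if (is.null(.paTestCache$model)) .paTestCache$model <- trainTestCGAN(1L)
  .paTestCache$model
}

meanMetrics <- function(imgs, roi) {
  colMeans(do.call(rbind, lapply(imgs, function(im) {
    unlist(evaluateImage(pmin(pmax(im, 0), 1), roi))
  })))
}

# Central-difference numerical gradient.
numGrad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
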
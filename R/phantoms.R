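# Synthetic photoacoustic phantoms, paired frame-averaged samples and
# raster-scan photobleaching simulation. These generators replace real
# LED-system / AR-PAM acquisitions so the whole pipeline runs at desk scale.

renderTube <- function(spec, shape) {
  h <- shape[1]; w <- shape[2]
  ctr <- spec@center
  if (any(is.na(ctr))) ctr <- c((h + 1L) %/% 2L, (w + 1L) %/% 2L)
  R <- spec@radius; t <- spec@thickness
  if (ctr[1] - R - t < 1 || ctr[1] + R + t > h ||
      ctr[2] - R - t < 1 || ctr[2] + R + t > w) {
    stop("tube geometry (center, radius, thickness) does not fit inside the image")
  }
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((r - ctr[1])^2 + (cc - ctr[2])^2)
  sr <- t / (2 * sqrt(2 * log(2)))           # FWHM -> Gaussian sigma
  ring <- exp(-(d - R)^2 / (2 * sr^2))
  # B-mode tube walls: strongest where the wall is perpendicular to the
  # axial direction, i.e. at the top and bottom of the cross-section.
  ang <- abs(r - ctr[1]) / pmax(d, 1e-9)
  field <- ring * ang^2
  field[field < 1e-12] <- 0
  field
}

renderFiber <- function(spec, shape) {
  h <- shape[1]; w <- shape[2]
  ctr <- spec@center
  if (any(is.na(ctr))) ctr <- c((h + 1L) %/% 2L, (w + 1L) %/% 2L)
  if (ctr[1] < 1 || ctr[1] > h || ctr[2] < 1 || ctr[2] > w) {
    stop("fiber center lies outside the image")
  }
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  # Perpendicular distance to the line through `center` at `orientation`
  # (0 rad = along the lateral axis).
  dperp <- abs(-sin(spec@orientation) * (cc - ctr[2]) +
                cos(spec@orientation) * (r - ctr[1]))
  sr <- spec@thickness / (2 * sqrt(2 * log(2)))
  field <- exp(-dperp^2 / (2 * sr^2))
  field[field < 1e-12] <- 0
  field
}

renderVesselTree <- function(spec, shape) {
  h <- shape[1]; w <- shape[2]
  field <- matrix(0, h, w)
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  nBranch <- sample(3:5, 1)
  for (b in seq_len(nBranch)) {
    pos <- c(runif(1, 0.2 * h, 0.8 * h), runif(1, 0.1 * w, 0.3 * w))
    ang <- runif(1, -pi / 6, pi / 6)
    thick <- spec@thickness * runif(1, 0.6, 1.2)
    sr <- thick / (2 * sqrt(2 * log(2)))
    nStep <- ceiling(0.8 * w)
    for (s in seq_len(nStep)) {
      ang <- ang + rnorm(1, 0, 0.08)            # meandering walk
      pos <- pos + c(sin(ang), cos(ang))
      if (pos[1] < 2 || pos[1] > h - 1 || pos[2] < 2 || pos[2] > w - 1) break
      blob <- exp(-((r - pos[1])^2 + (cc - pos[2])^2) / (2 * sr^2))
      field <- pmax(field, blob)
    }
  }
  field[field < 1e-12] <- 0
  field
}

#' Render a synthetic photoacoustic target image
#'
#' Deterministically renders the geometry described by a [PhantomSpec-class]
#' into a `[0,1]` image: a tube cross-section shows the two bright wall arcs
#' characteristic of B-mode imaging of a dye-filled tube, a fiber a single
#' thin bright stroke, and a vessel tree a few meandering branches. The
#' rendered field is scaled so its maximum equals `amplitude` exactly, on a
#' constant `backgroundLevel`.
#'
#' @param spec a [PhantomSpec-class].
#' @param shape image dimensions `c(rows, cols)`, at least 32x32.
#' @param seed integer seed (only the vessel tree consumes randomness, but
#'   every geometry is a pure function of `(spec, shape, seed)`).
#' @return an image matrix of dimension `shape`.
#' @examples
#' img <- makePhantom(phantomSpec("tube_cross_section", radius = 14), c(64, 64), seed = 1)
#' range(img)
#' @export
makePhantom <- function(spec, shape = c(64L, 64L), seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  if (shape[1] < 32L || shape[2] < 32L) stop("shape must be at least 32x32")
  field <- withSeed(seed, switch(spec@kind,
    tube_cross_section = renderTube(spec, shape),
    fiber = renderFiber(spec, shape),
    vessel_tree = renderVesselTree(spec, shape)))
  mx <- max(field)
  if (mx <= 0) stop("degenerate phantom: empty field")
  spec@backgroundLevel + (spec@amplitude - spec@backgroundLevel) * field / mx
}

#' Generate paired low/high-SNR samples by simulated frame averaging
#'
#' Builds each pair from one clean phantom plus additive zero-mean Gaussian
#' per-frame noise averaged over `FIn` (input) and `FLabel` (label) frames,
#' so that the residual noise standard deviation is
#' `perFrameNoiseSigma / sqrt(F)`. The averaged residual field is drawn
#' directly from its exact distribution `N(0, sigma^2/F)`; input and target
#' are spatially aligned by construction. Defaults mirror an LED-system
#' acquisition protocol of 128-average inputs and 25600-average labels.
#'
#' @param specs list of [PhantomSpec-class] objects, cycled over pairs.
#' @param nPairs number of pairs to generate.
#' @param FIn frame averages of the noisy input.
#' @param FLabel frame averages of the clean label; must exceed `FIn`.
#' @param perFrameNoiseSigma standard deviation of single-frame noise.
#' @param seed master seed; per-pair seeds are derived by a fixed counter
#'   scheme so the dataset is order-independent.
#' @param shape image dimensions.
#' @return list of [PairedSample-class] objects.
#' @export
makePairedDataset <- function(specs, nPairs, FIn = 128L, FLabel = 25600L,
                              perFrameNoiseSigma = 0.5, seed = 1L,
                              shape = c(64L, 64L)) {
  if (nPairs <= 0) stop("nPairs must be positive")
  if (!(FLabel > FIn && FIn >= 1)) stop("need FLabel > FIn >= 1")
  if (perFrameNoiseSigma <= 0) stop("perFrameNoiseSigma must be positive")
  if (!is.list(specs)) specs <- list(specs)
  lapply(seq_len(nPairs), function(k) {
    sp <- specs[[(k - 1L) %% length(specs) + 1L]]
    sk <- deriveSeed(seed, k)
    withSeed(sk, {
      clean <- makePhantom(sp, shape, seed = deriveSeed(sk, 1L))
      input <- clean + matrix(rnorm(prod(shape), 0, perFrameNoiseSigma / sqrt(FIn)),
                              shape[1], shape[2])
      target <- clean + matrix(rnorm(prod(shape), 0, perFrameNoiseSigma / sqrt(FLabel)),
                               shape[1], shape[2])
      pairedSample(input, target,
        meta = list(procedure = "frame_average", FIn = FIn, FLabel = FLabel,
                    perFrameNoiseSigma = perFrameNoiseSigma, seed = sk,
                    kind = sp@kind))
    })
  })
}

# Unit-peak lateral beam profile at offset `du` (mm); beamSigmaMm is the
# 1/e^2 intensity radius.
beamProfile <- function(du, beamSigmaMm) exp(-2 * du^2 / beamSigmaMm^2)

#' Simulate repeated single-point illumination of a dye target
#'
#' The noiseless bleaching kinetics trace for `nPulses` pulses delivered at
#' one spot: `A_k = A0 * (1 - beta)^k`, for `k = 0..nPulses`.
#'
#' @param bleach a [BleachModel-class].
#' @param nPulses number of pulses delivered.
#' @param A0 initial amplitude.
#' @return numeric vector of length `nPulses + 1`.
#' @examples
#' tail(simulatePointExposure(bleachModel(beta = 0.001), 430), 1) # ~35% drop
#' @export
simulatePointExposure <- function(bleach, nPulses, A0 = 1) {
  stopifnot(is(bleach, "BleachModel"))
  if (nPulses < 1) stop("nPulses must be >= 1")
  A0 * (1 - bleach@beta)^(0:nPulses)
}

#' Simulate a raster scan over a photobleachable dye target
#'
#' Scans `nPositions` lateral positions spaced `stepMm` apart. The local dye
#' concentration at lateral coordinate `u` decays multiplicatively by
#' `(1 - beta * g(u - x_j))` after every pulse delivered at position `x_j`,
#' with `g` the unit-peak Gaussian beam profile; because the beam is wider
#' than the step, later positions are pre-bleached before their own scan.
#' The frame at position `k` is the average of `pulsesPerPosition` pulse
#' images, each carrying fresh additive Gaussian noise and the concentration
#' current at its own pulse time (bleaching is applied between pulses, so an
#' n-pulse average reflects mid-decay amplitudes).
#'
#' @param spec target geometry, a [PhantomSpec-class].
#' @param bleach a [BleachModel-class].
#' @param nPositions number of scan positions (>= 2).
#' @param pulsesPerPosition pulses averaged per frame.
#' @param noiseSigmaPerPulse additive noise std of a single pulse image.
#' @param seed integer seed.
#' @param shape frame dimensions.
#' @return a [ScanSeries-class].
#' @export
simulateRasterScan <- function(spec, bleach, nPositions, pulsesPerPosition = 1L,
                               noiseSigmaPerPulse = 0.1, seed = 1L,
                               shape = c(64L, 64L)) {
  stopifnot(is(spec, "PhantomSpec"), is(bleach, "BleachModel"))
  if (nPositions < 2) stop("nPositions must be >= 2")
  pulsesPerPosition <- as.integer(pulsesPerPosition)
  clean <- makePhantom(spec, shape, seed = deriveSeed(seed, 0L))
  half <- spec@backgroundLevel + 0.5 * (spec@amplitude - spec@backgroundLevel)
  inside <- which(clean > half, arr.ind = TRUE)
  region <- as.integer(c(min(inside[, 1]), min(inside[, 2]),
                         max(inside[, 1]), max(inside[, 2])))
  pos <- bleach@stepMm * (seq_len(nPositions) - 1L)
  conc <- rep(1, nPositions)                   # local dye concentration c(u)
  framesList <- vector("list", nPositions)
  dose <- numeric(nPositions)
  peaks <- numeric(nPositions)
  npx <- prod(shape)
  withSeed(seed, {
    for (k in seq_len(nPositions)) {
      acc <- matrix(0, shape[1], shape[2])
      cs <- numeric(pulsesPerPosition)
      for (p in seq_len(pulsesPerPosition)) {
        cs[p] <- conc[k]
        frame <- clean * conc[k]
        if (noiseSigmaPerPulse > 0) {
          frame <- frame + matrix(rnorm(npx, 0, noiseSigmaPerPulse),
                                  shape[1], shape[2])
        }
        acc <- acc + frame
        conc <- conc * (1 - bleach@beta * beamProfile(pos - pos[k], bleach@beamSigmaMm))
      }
      framesList[[k]] <- acc / pulsesPerPosition
      dose[k] <- mean(cs) * spec@amplitude
      peaks[k] <- max(boxPixels(framesList[[k]], region))
    }
  })
  new("ScanSeries", frames = framesList, positionsMm = pos,
      pulsesPerPosition = pulsesPerPosition, peakAmplitudes = peaks,
      doseAmplitudes = dose, signalRegion = region,
      meta = list(beta = bleach@beta, beamSigmaMm = bleach@beamSigmaMm,
                  stepMm = bleach@stepMm, noiseSigmaPerPulse = noiseSigmaPerPulse,
                  seed = seed, kind = spec@kind))
}
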
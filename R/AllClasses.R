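#' @import methods
NULL

# Images throughout the package are plain numeric matrices in [0,1] with
# rows = axial (z) and cols = lateral (x); pixel spacing is carried by the
# objects that need it (ScanSeries, BleachModel) rather than by every image.

#' Geometric description of a synthetic photoacoustic target
#'
#' Describes one of three target geometries used by the phantom generator:
#' a tube cross-section (two bright wall arcs, as produced by a dye-filled
#' polyethylene tube imaged in B-mode), a thin fiber, or a small vessel tree.
#'
#' @slot kind one of `"tube_cross_section"`, `"fiber"`, `"vessel_tree"`.
#' @slot center target centre in pixels `c(row, col)`; `NA` means image centre.
#' @slot radius tube radius in pixels (tube geometry only).
#' @slot thickness wall/stroke thickness in pixels, measured as the
#'   full width at half maximum of the Gaussian cross-profile.
#' @slot orientation stroke angle in radians (fiber geometry; 0 = lateral).
#' @slot amplitude peak signal level of the rendered target.
#' @slot backgroundLevel constant background level, `0 <= background < amplitude`.
#' @export
setClass("PhantomSpec",
  representation(kind = "character", center = "numeric", radius = "numeric",
                 thickness = "numeric", orientation = "numeric",
                 amplitude = "numeric", backgroundLevel = "numeric"))

setValidity("PhantomSpec", function(object) {
  kinds <- c("tube_cross_section", "fiber", "vessel_tree")
  if (!object@kind %in% kinds) {
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  }
  if (object@backgroundLevel < 0) return("backgroundLevel must be >= 0")
  if (object@amplitude <= object@backgroundLevel) {
    return("amplitude must exceed backgroundLevel")
  }
  if (object@thickness <= 0) return("thickness must be positive")
  if (object@kind == "tube_cross_section" && object@radius <= 0) {
    return("tube radius must be positive")
  }
  TRUE
})

#' Construct a PhantomSpec
#'
#' @param kind target geometry, see [PhantomSpec-class].
#' @param center pixel centre `c(row, col)` or `NA` for the image centre.
#' @param radius tube radius in pixels.
#' @param thickness stroke/wall thickness in pixels (FWHM).
#' @param orientation fiber angle in radians.
#' @param amplitude peak signal level.
#' @param backgroundLevel constant background level.
#' @return a [PhantomSpec-class] object.
#' @examples
#' phantomSpec("tube_cross_section", radius = 18, thickness = 4)
#' @export
phantomSpec <- function(kind = c("tube_cross_section", "fiber", "vessel_tree"),
                        center = NA_real_, radius = 16, thickness = 3,
                        orientation = 0, amplitude = 1, backgroundLevel = 0) {
  kind <- match.arg(kind)
  new("PhantomSpec", kind = kind, center = as.numeric(center),
      radius = radius, thickness = thickness, orientation = orientation,
      amplitude = amplitude, backgroundLevel = backgroundLevel)
}

#' Per-pulse photobleaching model
#'
#' Mono-exponential bleaching kinetics: each laser pulse delivered at lateral
#' position \eqn{x_j} multiplies the local dye concentration at position
#' \eqn{u} by \eqn{1 - \beta g(u - x_j)}, where \eqn{g} is a unit-peak
#' Gaussian beam profile of 1/e^2 radius `beamSigmaMm`. A beam wider than the
#' scan step is what pre-bleaches positions before they are scanned.
#'
#' @slot beta per-pulse bleaching fraction at beam centre, `0 <= beta < 1`.
#' @slot beamSigmaMm lateral 1/e^2 Gaussian beam radius in mm.
#' @slot stepMm raster scan step in mm (default 0.1, i.e. 100 um).
#' @export
setClass("BleachModel",
  representation(beta = "numeric", beamSigmaMm = "numeric", stepMm = "numeric"))

setValidity("BleachModel", function(object) {
  if (object@beta < 0 || object@beta >= 1) return("beta must lie in [0, 1)")
  if (object@beamSigmaMm <= 0) return("beamSigmaMm must be positive")
  if (object@stepMm <= 0) return("stepMm must be positive")
  TRUE
})

#' Construct a BleachModel
#'
#' @param beta per-pulse bleaching fraction at the beam centre.
#' @param stepMm scan step size in mm.
#' @param beamSigmaMm 1/e^2 beam radius in mm; defaults to twice the step,
#'   the broad-illumination regime of acoustic-resolution systems.
#' @return a [BleachModel-class] object.
#' @examples
#' bleachModel(beta = 0.01)
#' @export
bleachModel <- function(beta = 0.01, stepMm = 0.1, beamSigmaMm = 2 * stepMm) {
  new("BleachModel", beta = beta, beamSigmaMm = beamSigmaMm, stepMm = stepMm)
}

#' @export
setGeneric("bleachRate", function(x) standardGeneric("bleachRate"))
#' @describeIn BleachModel-class per-pulse bleaching fraction.
#' @param x a `BleachModel`.
#' @export
setMethod("bleachRate", "BleachModel", function(x) x@beta)

#' Ordered raster-scan acquisition over a photobleachable target
#'
#' One frame per lateral scan position, each the average of
#' `pulsesPerPosition` single-pulse images. `peakAmplitudes` is the measured
#' per-position peak over the target region of the (noisy) frame;
#' `doseAmplitudes` is the noiseless amplitude implied by the delivered
#' light dose alone, which is what photobleaching quantification compares.
#'
#' @slot frames list of image matrices, one per scan position.
#' @slot positionsMm strictly increasing lateral positions in mm.
#' @slot pulsesPerPosition pulses averaged into each frame.
#' @slot peakAmplitudes per-position peak amplitude of the acquired frame.
#' @slot doseAmplitudes per-position noiseless amplitude (dose trace).
#' @slot signalRegion inclusive pixel box `c(row0, col0, row1, col1)` of the
#'   target used for peak extraction.
#' @slot meta provenance list (bleach model parameters, noise level, seed).
#' @export
setClass("ScanSeries",
  representation(frames = "list", positionsMm = "numeric",
                 pulsesPerPosition = "integer", peakAmplitudes = "numeric",
                 doseAmplitudes = "numeric", signalRegion = "integer",
                 meta = "list"))

setValidity("ScanSeries", function(object) {
  n <- length(object@frames)
  if (length(object@positionsMm) != n || length(object@peakAmplitudes) != n) {
    return("frames, positionsMm and peakAmplitudes must have equal length")
  }
  if (n >= 2 && any(diff(object@positionsMm) <= 0)) {
    return("positionsMm must be strictly increasing")
  }
  if (object@pulsesPerPosition < 1L) return("pulsesPerPosition must be >= 1")
  TRUE
})

#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @describeIn ScanSeries-class list of frames.
#' @param x a `ScanSeries`.
#' @export
setMethod("frames", "ScanSeries", function(x) x@frames)
#' @export
setGeneric("positionsMm", function(x) standardGeneric("positionsMm"))
#' @describeIn ScanSeries-class lateral positions in mm.
#' @export
setMethod("positionsMm", "ScanSeries", function(x) x@positionsMm)
#' @export
setGeneric("peakAmplitudes", function(x) standardGeneric("peakAmplitudes"))
#' @describeIn ScanSeries-class per-position measured peak amplitudes.
#' @export
setMethod("peakAmplitudes", "ScanSeries", function(x) x@peakAmplitudes)
#' @export
setGeneric("doseAmplitudes", function(x) standardGeneric("doseAmplitudes"))
#' @describeIn ScanSeries-class per-position noiseless dose amplitudes.
#' @export
setMethod("doseAmplitudes", "ScanSeries", function(x) x@doseAmplitudes)
#' @export
setGeneric("signalRegion", function(x) standardGeneric("signalRegion"))
#' @describeIn ScanSeries-class target pixel box used for peak extraction.
#' @export
setMethod("signalRegion", "ScanSeries", function(x) x@signalRegion)

setMethod("show", "ScanSeries", function(object) {
  cat(sprintf("ScanSeries: %d positions, %d pulse(s)/position, frames %dx%d\n",
              length(object@frames), object@pulsesPerPosition,
              nrow(object@frames[[1]]), ncol(object@frames[[1]])))
  cat(sprintf("  lateral range %.2f-%.2f mm; peak amplitude %.3f -> %.3f\n",
              min(object@positionsMm), max(object@positionsMm),
              object@peakAmplitudes[1],
              object@peakAmplitudes[length(object@peakAmplitudes)]))
})

#' A (noisy input, clean target) training pair
#'
#' @slot input noisy image matrix.
#' @slot target clean label image matrix, same shape as `input`.
#' @slot meta provenance list: generation procedure, frame-average counts
#'   or noise parameters, and the seed that reproduces the pair.
#' @export
setClass("PairedSample",
  representation(input = "matrix", target = "matrix", meta = "list"))

setValidity("PairedSample", function(object) {
  if (!all(dim(object@input) == dim(object@target))) {
    return("input and target must have identical shape")
  }
  TRUE
})

#' Construct a PairedSample
#' @param input noisy input image matrix.
#' @param target clean target image matrix.
#' @param meta provenance list.
#' @return a [PairedSample-class].
#' @export
pairedSample <- function(input, target, meta = list()) {
  new("PairedSample", input = input, target = target, meta = meta)
}

#' @export
setGeneric("inputImage", function(x) standardGeneric("inputImage"))
#' @describeIn PairedSample-class noisy input image.
#' @param x a `PairedSample`.
#' @export
setMethod("inputImage", "PairedSample", function(x) x@input)
#' @export
setGeneric("targetImage", function(x) standardGeneric("targetImage"))
#' @describeIn PairedSample-class clean target image.
#' @export
setMethod("targetImage", "PairedSample", function(x) x@target)

setMethod("show", "PairedSample", function(object) {
  cat(sprintf("PairedSample %dx%d (%s)\n", nrow(object@input), ncol(object@input),
              if (length(object@meta)) paste(names(object@meta), collapse = ", ")
              else "no meta"))
})

#' Signal / background regions for no-reference quality metrics
#'
#' Boxes are inclusive 1-based pixel bounds `c(row0, col0, row1, col1)`,
#' the idiomatic R convention. The signal box plays the role of the target
#' ROI and the background box the role of the noise-only region in the
#' SNR, CNR and GCNR definitions.
#'
#' @slot signalBox inclusive pixel bounds of the signal ROI.
#' @slot backgroundBox inclusive pixel bounds of the background region.
#' @export
setClass("ROISpec",
  representation(signalBox = "integer", backgroundBox = "integer"))

setValidity("ROISpec", function(object) {
  for (b in list(object@signalBox, object@backgroundBox)) {
    if (length(b) != 4L) return("boxes must be c(row0, col0, row1, col1)")
    if (b[3] < b[1] || b[4] < b[2]) return("box is empty")
    if ((b[3] - b[1] + 1L) * (b[4] - b[2] + 1L) < 4L) {
      return("each box must contain at least 4 pixels")
    }
  }
  if (!boxesDisjoint(object@signalBox, object@backgroundBox)) {
    return("signal and background boxes must be disjoint")
  }
  TRUE
})

#' Construct an ROISpec
#' @param signalBox inclusive 1-based `c(row0, col0, row1, col1)` signal box.
#' @param backgroundBox same form, background region; must be disjoint.
#' @return an [ROISpec-class].
#' @examples
#' roiSpec(c(20, 20, 40, 40), c(2, 2, 12, 12))
#' @export
roiSpec <- function(signalBox, backgroundBox) {
  new("ROISpec", signalBox = as.integer(signalBox),
      backgroundBox = as.integer(backgroundBox))
}

#' @export
setGeneric("signalBox", function(x) standardGeneric("signalBox"))
#' @describeIn ROISpec-class signal box accessor.
#' @param x an `ROISpec`.
#' @export
setMethod("signalBox", "ROISpec", function(x) x@signalBox)
#' @export
setGeneric("backgroundBox", function(x) standardGeneric("backgroundBox"))
#' @describeIn ROISpec-class background box accessor.
#' @export
setMethod("backgroundBox", "ROISpec", function(x) x@backgroundBox)

#' Synthetic corruption descriptor
#'
#' Names one of the four injected noise models together with its parameters:
#' additive Gaussian (`sigma`), scaled-count Poisson (`scale`),
#' salt-and-pepper (`density`), or multiplicative uniform speckle
#' (`variance`).
#'
#' @slot kind one of `"gaussian"`, `"poisson"`, `"salt_pepper"`, `"speckle"`.
#' @slot params named list of kind-specific parameters.
#' @export
setClass("NoiseSpec", representation(kind = "character", params = "list"))

setValidity("NoiseSpec", function(object) {
  kinds <- c("gaussian", "poisson", "salt_pepper", "speckle")
  if (!object@kind %in% kinds) {
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  }
  p <- object@params
  ok <- switch(object@kind,
    gaussian = !is.null(p$sigma) && p$sigma >= 0,
    poisson = !is.null(p$scale) && p$scale > 0,
    salt_pepper = !is.null(p$density) && p$density >= 0 && p$density <= 1,
    speckle = !is.null(p$variance) && p$variance >= 0)
  if (!ok) return(sprintf("invalid parameters for kind '%s'", object@kind))
  TRUE
})

#' Construct a NoiseSpec
#' @param kind noise model name.
#' @param sigma Gaussian standard deviation.
#' @param scale Poisson count scale (variance = mean / scale).
#' @param density salt-and-pepper fraction of destroyed pixels.
#' @param variance speckle multiplier variance.
#' @return a [NoiseSpec-class].
#' @examples
#' noiseSpec("gaussian", sigma = 0.1)
#' @export
noiseSpec <- function(kind = c("gaussian", "poisson", "salt_pepper", "speckle"),
                      sigma = 0.1, scale = 100, density = 0.1, variance = 0.1) {
  kind <- match.arg(kind)
  params <- switch(kind,
    gaussian = list(sigma = sigma),
    poisson = list(scale = scale),
    salt_pepper = list(density = density),
    speckle = list(variance = variance))
  new("NoiseSpec", kind = kind, params = params)
}

#' @export
setGeneric("noiseKind", function(x) standardGeneric("noiseKind"))
#' @describeIn NoiseSpec-class noise model name.
#' @param x a `NoiseSpec`.
#' @export
setMethod("noiseKind", "NoiseSpec", function(x) x@kind)
#' @export
setGeneric("noiseParams", function(x) standardGeneric("noiseParams"))
#' @describeIn NoiseSpec-class parameter list.
#' @export
setMethod("noiseParams", "NoiseSpec", function(x) x@params)

#' Log-compressed 2D noise power spectrum
#'
#' Stores `log(1 + |FFT|^2)` of a source image, zero-frequency centred, plus
#' the raw complex FFT so cross-power spectra can be formed later.
#'
#' @slot logPower log-compressed, centred power spectrum matrix.
#' @slot normalized whether `logPower` was divided by its maximum.
#' @slot sourceId free-text label of the source image/system.
#' @slot fftc complex FFT of the source image (unshifted), retained so that
#'   cross-power spectra between profiles can be computed.
#' @export
setClass("NoiseProfile",
  representation(logPower = "matrix", normalized = "logical",
                 sourceId = "character", fftc = "matrix"))

setMethod("show", "NoiseProfile", function(object) {
  cat(sprintf("NoiseProfile '%s': %dx%d, %s\n", object@sourceId,
              nrow(object@logPower), ncol(object@logPower),
              if (object@normalized) "normalized to max 1" else "unnormalized"))
})

#' Optimizer and objective hyper-parameters for network training
#'
#' Defaults follow the reference cGAN training recipe: Adam with learning rate 1e-4,
#' beta1 = 0.5, beta2 = 0.999, epsilon = 1e-7, batch size 1; generator
#' objective weight lambdaDl = 100 and Huber threshold delta = 1.
#'
#' @slot lr learning rate.
#' @slot beta1,beta2,epsilon Adam moment decays and stabilizer.
#' @slot batchSize images per step (1; each step sees a single pair).
#' @slot steps number of optimization steps.
#' @slot seed run seed controlling init, shuffling and dropout.
#' @slot checkpointEvery write a checkpoint every this many steps (0 = only
#'   at the end, and only when a checkpoint directory is supplied).
#' @slot lambdaDl weight of the Huber and SSIM reconstruction terms.
#' @slot delta Huber threshold.
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", beta1 = "numeric", beta2 = "numeric",
                 epsilon = "numeric", batchSize = "integer", steps = "integer",
                 seed = "integer", checkpointEvery = "integer",
                 lambdaDl = "numeric", delta = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@lr <= 0) return("lr must be positive")
  if (object@beta1 < 0 || object@beta1 >= 1) return("beta1 must lie in [0,1)")
  if (object@beta2 < 0 || object@beta2 >= 1) return("beta2 must lie in [0,1)")
  if (object@steps < 1L) return("steps must be >= 1")
  TRUE
})

#' Construct a TrainConfig
#'
#' @param lr,beta1,beta2,epsilon Adam hyper-parameters.
#' @param batchSize images per step.
#' @param steps optimization steps; the full-scale run uses 40000, the
#'   desk-scale preset 2000.
#' @param seed integer run seed.
#' @param checkpointEvery checkpoint period in steps (0 = final only).
#' @param lambdaDl reconstruction weight in the generator objective.
#' @param delta Huber threshold.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(lr = 1e-4, beta1 = 0.5, beta2 = 0.999, epsilon = 1e-7,
                        batchSize = 1L, steps = 2000L, seed = 1L,
                        checkpointEvery = 0L, lambdaDl = 100, delta = 1) {
  new("TrainConfig", lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
      batchSize = as.integer(batchSize), steps = as.integer(steps),
      seed = as.integer(seed), checkpointEvery = as.integer(checkpointEvery),
      lambdaDl = lambdaDl, delta = delta)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(paste0("TrainConfig: Adam(lr=%g, beta1=%g, beta2=%g, eps=%g), ",
                     "batch %d, %d steps, lambdaDl=%g, delta=%g, seed %d\n"),
              object@lr, object@beta1, object@beta2, object@epsilon,
              object@batchSize, object@steps, object@lambdaDl, object@delta,
              object@seed))
})
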
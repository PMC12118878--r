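# Experiment harnesses: denoiser comparison tables, the noise-invariance
# study, the Gaussian variance sweep, and photobleaching quantification.

#' Compare denoising methods on corrupted copies of a clean set
#'
#' For every (image, seed) the clean image is corrupted with `noise`, each
#' method is applied, and SNR/CNR/GCNR are evaluated over `roi`; rows are
#' aggregated per method as mean +/- sd. The raw noisy input is always
#' included as the `"input"` row (the single-pulse analogue). A failing
#' method is recorded with `NA` metrics and a warning; the run continues.
#'
#' @param cleanSet list of clean image matrices.
#' @param noise a [NoiseSpec-class].
#' @param methods named list of functions `function(img) -> img`.
#' @param roi an [ROISpec-class].
#' @param seeds integer vector of corruption seeds.
#' @param bins GCNR histogram bins.
#' @return `data.frame` with one row per method: n, snrMean, snrSd,
#'   cnrMean, cnrSd, gcnrMean, gcnrSd.
#' @export
compareMethods <- function(cleanSet, noise, methods, roi, seeds = 1L,
                           bins = 256L) {
  stopifnot(length(seeds) >= 1)
  cleanSet <- lapply(cleanSet, clamp, 0, 1)   # storage-range convention
  methods <- c(list(input = identity), methods)
  rows <- list()
  for (seed in seeds) {
    for (ii in seq_along(cleanSet)) {
      noisy <- applyNoise(cleanSet[[ii]], noise, contentSeed(cleanSet[[ii]], seed))
      for (nm in names(methods)) {
        res <- tryCatch(
          evaluateImage(clamp(methods[[nm]](noisy), 0, 1), roi, bins),
          error = function(e) {
            warning(sprintf("method '%s' failed on image %d (seed %d): %s",
                            nm, ii, seed, conditionMessage(e)), call. = FALSE)
            data.frame(snr = NA_real_, cnr = NA_real_, gcnr = NA_real_)
          })
        res$method <- nm; res$image <- ii; res$seed <- seed
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  long <- do.call(rbind, rows)
  agg <- lapply(split(long, long$method), function(d) {
    data.frame(method = d$method[1], n = sum(is.finite(d$snr)),
               snrMean = mean(d$snr), snrSd = stats::sd(d$snr),
               cnrMean = mean(d$cnr), cnrSd = stats::sd(d$cnr),
               gcnrMean = mean(d$gcnr), gcnrSd = stats::sd(d$gcnr))
  })
  out <- do.call(rbind, agg[unique(long$method)])
  rownames(out) <- NULL
  attr(out, "perImage") <- long
  out
}

#' Noise-invariance study of a trained denoiser
#'
#' The platform-flexibility protocol: a model trained on a single noise
#' type is evaluated against every spec in `specs`, and the per-image
#' metric distributions of the noisy inputs and denoised outputs are
#' returned in long format (ready for violin plots).
#'
#' @param cleanSet list of clean images.
#' @param specs list of [NoiseSpec-class] objects.
#' @param model trained model for [denoiseImage()].
#' @param roi an [ROISpec-class].
#' @param seeds corruption seeds.
#' @return long `data.frame` with columns noise, image, seed, stage
#'   (noisy/denoised), snr, cnr, gcnr.
#' @export
noiseInvarianceStudy <- function(cleanSet, specs, model, roi, seeds = 1L) {
  cleanSet <- lapply(cleanSet, clamp, 0, 1)
  rows <- list()
  for (spec in specs) {
    for (seed in seeds) {
      for (ii in seq_along(cleanSet)) {
        noisy <- applyNoise(cleanSet[[ii]], spec, deriveSeed(seed, ii))
        den <- denoiseImage(noisy, model)
        for (stage in c("noisy", "denoised")) {
          img <- if (stage == "noisy") clamp(noisy, 0, 1) else den
          r <- evaluateImage(img, roi)
          r$noise <- spec@kind; r$image <- ii; r$seed <- seed; r$stage <- stage
          rows[[length(rows) + 1L]] <- r
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(snr = numeric(), cnr = numeric(), gcnr = numeric(),
                      noise = character(), image = integer(),
                      seed = integer(), stage = character()))
  }
  do.call(rbind, rows)
}

#' Denoiser performance across increasing Gaussian noise levels
#'
#' @param cleanSet list of clean images.
#' @param sigmas ascending Gaussian noise standard deviations.
#' @param model trained model.
#' @param roi an [ROISpec-class].
#' @param seeds corruption seeds.
#' @return `data.frame` with one row per sigma: mean metrics of the
#'   denoised outputs (and of the noisy inputs for reference).
#' @export
varianceSweep <- function(cleanSet, sigmas, model, roi, seeds = 1L) {
  if (is.unsorted(sigmas)) stop("sigmas must be sorted ascending")
  cleanSet <- lapply(cleanSet, clamp, 0, 1)
  rows <- lapply(sigmas, function(sg) {
    den <- c(); noisy <- c()
    for (seed in seeds) {
      for (ii in seq_along(cleanSet)) {
        ni <- if (sg > 0) {
          addGaussian(cleanSet[[ii]], sg, deriveSeed(seed, ii))
        } else cleanSet[[ii]]
        d <- denoiseImage(ni, model)
        den <- rbind(den, as.matrix(evaluateImage(d, roi)))
        noisy <- rbind(noisy, as.matrix(evaluateImage(clamp(ni, 0, 1), roi)))
      }
    }
    data.frame(sigma = sg,
               snrDenoised = mean(den[, "snr"]), cnrDenoised = mean(den[, "cnr"]),
               gcnrDenoised = mean(den[, "gcnr"]),
               snrNoisy = mean(noisy[, "snr"]), gcnrNoisy = mean(noisy[, "gcnr"]))
  })
  do.call(rbind, rows)
}

#' Percentage of photobleaching along a scan
#'
#' `percent[k] = 100 * (1 - A_k / A_ref)` relative to the reference
#' position (the scan start by default), floored at 0; the unfloored value
#' is retained in `rawPercent`. Invariant under global rescaling of the
#' amplitude trace. Amplitudes default to the dose trace
#' ([doseAmplitudes()]), which reflects the delivered light dose; set
#' `amplitudes = peakAmplitudes(series)` to quantify from the measured
#' noisy peaks instead.
#'
#' @param series a [ScanSeries-class].
#' @param referenceIndex index of the no-bleach reference position.
#' @param amplitudes amplitude trace to quantify (defaults to the dose
#'   trace of `series`).
#' @return `data.frame` with columns positionMm, percent, rawPercent.
#' @export
photobleachPercentage <- function(series, referenceIndex = 1L,
                                  amplitudes = doseAmplitudes(series)) {
  stopifnot(is(series, "ScanSeries"))
  aRef <- amplitudes[referenceIndex]
  if (!is.finite(aRef) || aRef <= 0) stop("zero reference amplitude")
  raw <- 100 * (1 - amplitudes / aRef)
  data.frame(positionMm = series@positionsMm, percent = pmax(raw, 0),
             rawPercent = raw)
}

peakFromFrame <- function(frame, region) max(boxPixels(frame, region))

#' The photobleaching trade-off experiment
#'
#' Simulates the same raster scan three ways: (a) single-pulse
#' illumination, raw; (b) `nPulseAverage`-pulse averaged illumination; and
#' (c) single-pulse followed by cGAN denoising of every frame. Bleaching
#' percentages are quantified from each mode's dose trace — mode (c) shares
#' mode (a)'s illumination schedule, so their bleaching is identical by
#' construction (denoising changes SNR, never the delivered dose) — while
#' per-mode SNR over the tube region makes the dose/quality trade-off
#' visible.
#'
#' @param spec target geometry, a [PhantomSpec-class].
#' @param bleach a [BleachModel-class].
#' @param model trained denoiser for mode (c).
#' @param nPositions scan positions.
#' @param nPulseAverage pulses per position of mode (b) (default 30).
#' @param noiseSigmaPerPulse per-pulse additive noise std.
#' @param seed simulation seed.
#' @param shape frame dimensions.
#' @param roi optional [ROISpec-class] for SNR; derived from the tube
#'   region when `NULL`.
#' @return list of class `"BleachReport"`: `positionsMm`, `percent`
#'   (data.frame with columns singlePulse, nPulseAverage,
#'   denoisedSinglePulse), `rawPeakPercent` (same modes, quantified from
#'   noisy/denoised frame peaks), `snr` (per-mode mean SNR), `series`
#'   (the two simulated [ScanSeries-class] objects).
#' @export
bleachingExperiment <- function(spec, bleach, model, nPositions = 23L,
                                nPulseAverage = 30L, noiseSigmaPerPulse = 0.1,
                                seed = 1L, shape = c(64L, 64L), roi = NULL) {
  sA <- simulateRasterScan(spec, bleach, nPositions, 1L,
                           noiseSigmaPerPulse, seed, shape)
  sB <- simulateRasterScan(spec, bleach, nPositions, nPulseAverage,
                           noiseSigmaPerPulse, deriveSeed(seed, 2L), shape)
  denoised <- lapply(frames(sA), denoiseImage, model = model)
  region <- signalRegion(sA)
  if (is.null(roi)) {
    bgBox <- backgroundBoxFor(region, shape)
    roi <- roiSpec(region, bgBox)
  }
  pA <- photobleachPercentage(sA)
  pB <- photobleachPercentage(sB)
  pC <- pA  # same illumination schedule: the dose trace is mode (a)'s
  peakPct <- function(frs, series) {
    amps <- vapply(frs, peakFromFrame, numeric(1), region = region)
    photobleachPercentage(series, amplitudes = amps)$rawPercent
  }
  snrOf <- function(frs) mean(vapply(frs, function(f) {
    snr(clamp(f, 0, 1), roi)
  }, numeric(1)))
  structure(list(
    positionsMm = positionsMm(sA),
    percent = data.frame(positionMm = positionsMm(sA),
                         singlePulse = pA$percent,
                         nPulseAverage = pB$percent,
                         denoisedSinglePulse = pC$percent),
    rawPeakPercent = data.frame(positionMm = positionsMm(sA),
                                singlePulse = peakPct(frames(sA), sA),
                                nPulseAverage = peakPct(frames(sB), sB),
                                denoisedSinglePulse = peakPct(denoised, sA)),
    snr = c(singlePulse = snrOf(frames(sA)),
            nPulseAverage = snrOf(frames(sB)),
            denoisedSinglePulse = snrOf(denoised)),
    series = list(singlePulse = sA, nPulseAverage = sB)),
    class = "BleachReport")
}

# First corner box disjoint from the target region, trying successively
# smaller boxes so tight frames still get a usable background.
backgroundBoxFor <- function(region, shape) {
  for (sz in c(10L, 8L, 6L, 4L)) {
    for (cand in list(
      c(2L, 2L, 1L + sz, 1L + sz),
      c(shape[1] - sz - 1L, 2L, shape[1] - 2L, 1L + sz),
      c(2L, shape[2] - sz - 1L, 1L + sz, shape[2] - 2L),
      c(shape[1] - sz - 1L, shape[2] - sz - 1L, shape[1] - 2L, shape[2] - 2L))) {
      if (boxesDisjoint(cand, region)) return(as.integer(cand))
    }
  }
  stop("no background region disjoint from the target could be placed")
}

#' @export
print.BleachReport <- function(x, ...) {
  n <- length(x$positionsMm)
  cat(sprintf("BleachReport: %d positions (%.2f-%.2f mm)\n", n,
              x$positionsMm[1], x$positionsMm[n]))
  cat(sprintf("  final-position bleaching: single %.2f%%, %d-pulse avg %.2f%%, denoised single %.2f%%\n",
              x$percent$singlePulse[n],
              x$series$nPulseAverage@pulsesPerPosition,
              x$percent$nPulseAverage[n], x$percent$denoisedSinglePulse[n]))
  cat(sprintf("  mean SNR: single %.2f, avg %.2f, denoised %.2f\n",
              x$snr["singlePulse"], x$snr["nPulseAverage"],
              x$snr["denoisedSinglePulse"]))
  invisible(x)
}
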
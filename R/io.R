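# File I/O: float32 TIFF images, paired-dataset directories with YAML
# manifests, and ScanSeries directories.

#' Write an image as 32-bit TIFF
#'
#' The canonical on-disk image format: 32-bit samples resolving the
#' `[0, 1]` storage range to 2^-32 (better than single-precision float).
#' Values are clipped to the storage range at write time (and only then).
#'
#' @param img image matrix.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeImageTiff <- function(img, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(clamp(img, 0, 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' Read an image written by [writeImageTiff()]
#'
#' @param path TIFF file path.
#' @return image matrix.
#' @export
readImageTiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}

#' Write a paired dataset as a directory of TIFF pairs plus a manifest
#'
#' Each pair becomes `pair%04d_input.tif` / `pair%04d_target.tif`; the
#' YAML manifest records every pair's provenance metadata so the dataset is
#' reconstructible from seeds.
#'
#' @param pairs list of [PairedSample-class] objects.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
writePairedDataset <- function(pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    writeImageTiff(pairs[[k]]@input, file.path(dir, sprintf("pair%04d_input.tif", k)))
    writeImageTiff(pairs[[k]]@target, file.path(dir, sprintf("pair%04d_target.tif", k)))
    meta[[k]] <- pairs[[k]]@meta
  }
  yaml::write_yaml(list(nPairs = length(pairs), pairs = meta),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a paired dataset directory
#'
#' @param dir dataset directory written by [writePairedDataset()].
#' @return list of [PairedSample-class] objects.
#' @export
readPairedDataset <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  lapply(seq_len(man$nPairs), function(k) {
    pairedSample(readImageTiff(file.path(dir, sprintf("pair%04d_input.tif", k))),
                 readImageTiff(file.path(dir, sprintf("pair%04d_target.tif", k))),
                 meta = if (length(man$pairs) >= k) man$pairs[[k]] else list())
  })
}

#' Write a ScanSeries as a directory of frames plus a YAML sidecar
#'
#' Frames go to `frame%04d.tif` (32-bit); positions, amplitudes, the
#' signal region and the bleach-model attributes go to `series.yaml`.
#'
#' @param series a [ScanSeries-class].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
writeScanSeries <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(series@frames)) {
    writeImageTiff(series@frames[[k]], file.path(dir, sprintf("frame%04d.tif", k)))
  }
  yaml::write_yaml(list(
    positionsMm = series@positionsMm,
    pulsesPerPosition = series@pulsesPerPosition,
    peakAmplitudes = series@peakAmplitudes,
    doseAmplitudes = series@doseAmplitudes,
    signalRegion = series@signalRegion,
    meta = series@meta), file.path(dir, "series.yaml"), precision = 15L)
  invisible(dir)
}

#' Read a ScanSeries directory written by [writeScanSeries()]
#'
#' @param dir series directory.
#' @return a [ScanSeries-class]. Frame pixel values reflect the float32
#'   storage (clipped to `[0, 1]`); amplitude traces come from the sidecar
#'   at full precision.
#' @export
readScanSeries <- function(dir) {
  y <- yaml::read_yaml(file.path(dir, "series.yaml"))
  n <- length(y$positionsMm)
  fr <- lapply(seq_len(n), function(k) {
    readImageTiff(file.path(dir, sprintf("frame%04d.tif", k)))
  })
  new("ScanSeries", frames = fr, positionsMm = as.numeric(y$positionsMm),
      pulsesPerPosition = as.integer(y$pulsesPerPosition),
      peakAmplitudes = as.numeric(y$peakAmplitudes),
      doseAmplitudes = as.numeric(y$doseAmplitudes),
      signalRegion = as.integer(y$signalRegion),
      meta = if (is.null(y$meta)) list() else y$meta)
}
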
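# No-reference image-quality metrics over user-declared signal/background
# regions: SNR = mu_ROI / sd_BG, CNR = sd_ROI / sd_BG, and the generalized
# CNR, 1 minus the overlap of the two regions' intensity distributions.
# All three operate on pixel values as-is (no absolute value, no dB).

checkRoi <- function(img, roi) {
  stopifnot(is(roi, "ROISpec"))
  checkBoxInside(roi@signalBox, dim(img), "signalBox")
  checkBoxInside(roi@backgroundBox, dim(img), "backgroundBox")
  invisible(roi)
}

#' Signal-to-noise ratio over declared regions
#'
#' `SNR = mu_ROI / sd_BG`: mean of the signal box divided by the standard
#' deviation of the background box, reported as a plain ratio in arbitrary
#' units (never dB). Invariant under common positive scaling of the image;
#' shifts under additive offsets.
#'
#' @param img image matrix.
#' @param roi an [ROISpec-class].
#' @return SNR ratio.
#' @export
snr <- function(img, roi) {
  assertImage(img)
  checkRoi(img, roi)
  sBG <- stats::sd(boxPixels(img, roi@backgroundBox))
  if (sBG == 0) stop("degenerate background: zero variance")
  mean(boxPixels(img, roi@signalBox)) / sBG
}

#' Contrast-to-noise ratio over declared regions
#'
#' `CNR = sd_ROI / sd_BG`: standard deviation of the signal box divided by
#' that of the background box.
#'
#' @inheritParams snr
#' @return CNR ratio.
#' @export
cnr <- function(img, roi) {
  assertImage(img)
  checkRoi(img, roi)
  sBG <- stats::sd(boxPixels(img, roi@backgroundBox))
  if (sBG == 0) stop("degenerate background: zero variance")
  stats::sd(boxPixels(img, roi@signalBox)) / sBG
}

#' Generalized contrast-to-noise ratio
#'
#' `GCNR = 1 - sum_b min(h1_b, h2_b)` where `h1`, `h2` are histograms of
#' the signal and background pixels over shared bin edges spanning the
#' pooled min..max, each normalized to sum 1. Bounded in `[0, 1]`: 0 for
#' identical intensity distributions, 1 for fully separated ones. Invariant
#' under common monotonic intensity remappings (bins are recomputed on the
#' remapped pooled range).
#'
#' @inheritParams snr
#' @param bins number of shared histogram bins (default 256).
#' @return GCNR in `[0, 1]`.
#' @export
gcnr <- function(img, roi, bins = 256L) {
  assertImage(img)
  checkRoi(img, roi)
  s <- as.vector(boxPixels(img, roi@signalBox))
  b <- as.vector(boxPixels(img, roi@backgroundBox))
  lo <- min(s, b); hi <- max(s, b)
  if (hi == lo) {
    warning("zero-width pooled intensity range; returning GCNR = 0")
    return(0)
  }
  edges <- seq(lo, hi, length.out = bins + 1L)
  h1 <- tabulate(pmin(findInterval(s, edges, rightmost.closed = TRUE), bins),
                 nbins = bins) / length(s)
  h2 <- tabulate(pmin(findInterval(b, edges, rightmost.closed = TRUE), bins),
                 nbins = bins) / length(b)
  clamp(1 - sum(pmin(h1, h2)), 0, 1)
}

#' Compute all three quality metrics of an image
#'
#' @inheritParams gcnr
#' @return one-row `data.frame` with columns `snr`, `cnr`, `gcnr`.
#' @export
evaluateImage <- function(img, roi, bins = 256L) {
  data.frame(snr = snr(img, roi), cnr = cnr(img, roi),
             gcnr = gcnr(img, roi, bins))
}

#' Batch metric evaluation with mean +/- sd summary
#'
#' @param imgs list of image matrices.
#' @param roi an [ROISpec-class].
#' @param bins GCNR histogram bins.
#' @return list with `rows` (per-image `data.frame`) and `summary`
#'   (mean and sd of each metric).
#' @export
evaluateImages <- function(imgs, roi, bins = 256L) {
  rows <- do.call(rbind, lapply(imgs, evaluateImage, roi = roi, bins = bins))
  rows$image <- seq_len(nrow(rows))
  summary <- data.frame(
    metric = c("snr", "cnr", "gcnr"),
    mean = c(mean(rows$snr), mean(rows$cnr), mean(rows$gcnr)),
    sd = c(stats::sd(rows$snr), stats::sd(rows$cnr), stats::sd(rows$gcnr)))
  list(rows = rows, summary = summary)
}
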
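# Synthetic corruption operators and noise-profile characterization.
#
# The four injectors mirror the noise models used to probe denoiser
# robustness: additive Gaussian, scaled-count Poisson, salt-and-pepper
# impulse noise, and multiplicative uniform speckle. None of them clip to
# the storage range; clipping happens only at file write, so residual
# statistics can be measured exactly.

#' Add i.i.d. Gaussian noise
#'
#' @param img image matrix.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return `img + N(0, sigma^2)`, unclipped.
#' @export
addGaussian <- function(img, sigma, seed = 1L) {
  assertImage(img)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  withSeed(seed, img + matrix(rnorm(length(img), 0, sigma), nrow(img), ncol(img)))
}

#' Add scaled-count Poisson (shot) noise
#'
#' Models photon counting at `scale` expected counts per unit intensity:
#' `out = Poisson(img * scale) / scale`, so the per-pixel variance equals
#' `mean / scale` and the noise-free limit is `scale -> Inf`.
#'
#' @param img non-negative image matrix.
#' @param scale count scale (> 0).
#' @param seed integer seed.
#' @return noisy image, same shape.
#' @export
addPoisson <- function(img, scale = 100, seed = 1L) {
  assertImage(img)
  if (any(img < 0)) stop("Poisson noise requires a non-negative image")
  if (scale <= 0) stop("scale must be positive")
  withSeed(seed, matrix(rpois(length(img), img * scale), nrow(img), ncol(img)) / scale)
}

#' Destroy a fraction of pixels with salt-and-pepper noise
#'
#' Exactly `round(density * N)` pixels, chosen uniformly without
#' replacement, are set to the image range maximum ("salt") or minimum
#' ("pepper") with equal probability; all other pixels are untouched.
#' The range is the declared storage range `[0, 1]`.
#'
#' @param img image matrix.
#' @param density fraction of destroyed pixels in `[0, 1]`.
#' @param seed integer seed.
#' @param range extreme values used for salt and pepper.
#' @return corrupted image, same shape.
#' @export
addSaltPepper <- function(img, density = 0.1, seed = 1L, range = c(0, 1)) {
  assertImage(img)
  if (density < 0 || density > 1) stop("density must lie in [0, 1]")
  if (density == 0) return(img)
  n <- length(img)
  k <- round(density * n)
  withSeed(seed, {
    idx <- sample.int(n, k)
    salt <- runif(k) < 0.5
    out <- img
    out[idx[salt]] <- range[2]
    out[idx[!salt]] <- range[1]
    out
  })
}

#' Add multiplicative uniform speckle noise
#'
#' `out = img * (1 + u)` with `u` i.i.d. `Uniform(-a, a)` and
#' `a = sqrt(3 * variance)`, so that `var(u) = variance` and the mean of the
#' multiplier is exactly 1.
#'
#' @param img image matrix.
#' @param variance variance of the zero-mean uniform multiplier (>= 0).
#' @param seed integer seed.
#' @return corrupted image, same shape.
#' @export
addSpeckle <- function(img, variance = 0.1, seed = 1L) {
  assertImage(img)
  if (variance < 0) stop("variance must be >= 0")
  if (variance == 0) return(img)
  a <- sqrt(3 * variance)
  withSeed(seed, img * (1 + matrix(runif(length(img), -a, a), nrow(img), ncol(img))))
}

#' Apply a NoiseSpec to an image
#'
#' Dispatches to the corruption operator named by the spec.
#'
#' @param img image matrix.
#' @param spec a [NoiseSpec-class].
#' @param seed integer seed.
#' @return corrupted image.
#' @export
applyNoise <- function(img, spec, seed = 1L) {
  stopifnot(is(spec, "NoiseSpec"))
  p <- spec@params
  switch(spec@kind,
    gaussian = addGaussian(img, p$sigma, seed),
    poisson = addPoisson(img, p$scale, seed),
    salt_pepper = addSaltPepper(img, p$density, seed),
    speckle = addSpeckle(img, p$variance, seed))
}

#' Write a NoiseSpec to / read one from YAML
#'
#' @param spec a [NoiseSpec-class].
#' @param path YAML file path.
#' @return `readNoiseSpecYaml` returns a [NoiseSpec-class];
#'   `writeNoiseSpecYaml` returns `path` invisibly.
#' @export
writeNoiseSpecYaml <- function(spec, path) {
  stopifnot(is(spec, "NoiseSpec"))
  yaml::write_yaml(list(kind = spec@kind, params = spec@params), path)
  invisible(path)
}

#' @rdname writeNoiseSpecYaml
#' @export
readNoiseSpecYaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(noiseSpec, c(list(kind = y$kind), y$params))
}

#' Log-compressed 2D power spectrum of an image
#'
#' Computes `P = log(1 + |FFT2(img)|^2)` with the zero-frequency bin moved
#' to the array centre; `log(1 + .)` compresses the dynamic range while
#' staying defined at empty bins. With `normalize = TRUE` the log-compressed
#' spectrum is divided by its maximum so `max(logPower) == 1`.
#'
#' @param img image matrix.
#' @param normalize divide by the spectrum maximum.
#' @param sourceId free-text label stored with the profile.
#' @return a [NoiseProfile-class].
#' @export
logPowerSpectrum <- function(img, normalize = TRUE, sourceId = "") {
  assertImage(img)
  F <- stats::fft(img)
  P <- log1p(Mod(F)^2)
  Pc <- fftshift2(P)
  if (normalize) {
    mx <- max(Pc)
    if (mx <= 0) stop("degenerate spectrum: all-zero image cannot be normalized")
    Pc <- Pc / mx
  }
  new("NoiseProfile", logPower = Pc, normalized = normalize,
      sourceId = sourceId, fftc = F)
}

#' Cross-power spectrum of two noise profiles
#'
#' `log(1 + |F_a * conj(F_b)|)`, zero-frequency centred like
#' [logPowerSpectrum()], highlighting frequency regions where the two noise
#' profiles carry common energy.
#'
#' @param a,b [NoiseProfile-class] objects of equal shape.
#' @return matrix of the same shape as the sources.
#' @export
crossPowerSpectrum <- function(a, b) {
  stopifnot(is(a, "NoiseProfile"), is(b, "NoiseProfile"))
  if (!all(dim(a@fftc) == dim(b@fftc))) stop("profiles have different shapes")
  fftshift2(log1p(Mod(a@fftc * Conj(b@fftc))))
}

#' Pearson correlation of two flattened log-power spectra
#'
#' The similarity scalar used to compare noise profiles between imaging
#' systems: correlations well below 0.8 indicate dissimilar noise.
#'
#' @param a,b [NoiseProfile-class] objects of equal shape.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
spectrumCorrelation <- function(a, b) {
  stopifnot(is(a, "NoiseProfile"), is(b, "NoiseProfile"))
  if (!all(dim(a@logPower) == dim(b@logPower))) stop("profiles have different shapes")
  x <- as.vector(a@logPower); y <- as.vector(b@logPower)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance spectrum")
  stats::cor(x, y)
}

#' Robust additive-noise standard deviation estimate
#'
#' One-level Haar diagonal-detail median-absolute-deviation estimator:
#' the diagonal wavelet coefficients of a smooth image are dominated by the
#' noise, whose std is `MAD / 0.6745` (the Donoho-Johnstone rule). Used as
#' the sigma front end for the BM3D baseline.
#'
#' @param img image matrix, at least 8x8.
#' @return non-negative noise std estimate.
#' @export
estimateNoiseSigma <- function(img) {
  assertImage(img)
  if (nrow(img) < 8L || ncol(img) < 8L) stop("image must be at least 8x8")
  h <- 2L * (nrow(img) %/% 2L); w <- 2L * (ncol(img) %/% 2L)
  x <- img[seq_len(h), seq_len(w)]
  odd <- seq(1L, h, by = 2L); oddc <- seq(1L, w, by = 2L)
  # Orthonormal Haar diagonal detail: unit-variance image noise stays
  # unit-variance in d.
  d <- (x[odd, oddc] + x[odd + 1L, oddc + 1L] -
        x[odd, oddc + 1L] - x[odd + 1L, oddc]) / 2
  stats::median(abs(d - stats::median(d))) / 0.6745
}
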
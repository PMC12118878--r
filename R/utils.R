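# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their `(arguments, seed)` and never disturb the caller's RNG stream.
#' @noRd
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

# Stable per-item seed derivation: order-independent counter scheme, kept
# strictly inside 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483587 + 7919 * (as.numeric(k) %% 200003)) %% 2147483587 + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Seed derived from image content rather than list position, so batch
# harnesses corrupt each image identically no matter the ordering.
contentSeed <- function(img, seed) {
  h <- (sum(abs(img)) * 1e4) %% 99991 + (stats::sd(img) * 1e5) %% 9973
  deriveSeed(seed, floor(h))
}

assertImage <- function(img, minSide = 2L, name = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("'%s' must be a numeric matrix (rows = axial, cols = lateral)", name))
  }
  if (any(!is.finite(img))) stop(sprintf("'%s' contains non-finite values", name))
  if (nrow(img) < minSide || ncol(img) < minSide) {
    stop(sprintf("'%s' must be at least %dx%d", name, minSide, minSide))
  }
  invisible(img)
}

# Quadrant swap that moves the zero-frequency bin to the array centre,
# matching the usual display convention for 2D spectra.
fftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c((floor(h / 2) + 1):h, 1:floor(h / 2)), c((floor(w / 2) + 1):w, 1:floor(w / 2))]
}

# Dense banded filtering matrix for separable "valid" or zero-padded "same"
# convolution along one dimension; symmetric kernels make the transpose the
# exact adjoint, which the SSIM gradient relies on.
filterBandMatrix <- function(n, kernel, mode = c("same", "valid")) {
  mode <- match.arg(mode)
  k <- length(kernel)
  half <- (k - 1L) %/% 2L
  if (mode == "valid") {
    m <- n - k + 1L
    if (m < 1L) stop("kernel longer than signal")
    out <- matrix(0, m, n)
    for (i in seq_len(m)) out[i, i:(i + k - 1L)] <- kernel
  } else {
    out <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      keep <- j >= 1L & j <= n
      out[i, j[keep]] <- kernel[keep]
    }
  }
  out
}

gaussianKernel1d <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Inclusive 1-based box c(row0, col0, row1, col1) -> pixel values.
boxPixels <- function(img, box) {
  img[box[1]:box[3], box[2]:box[4]]
}

checkBoxInside <- function(box, dim, what = "box") {
  if (length(box) != 4L) stop(sprintf("'%s' must be c(row0, col0, row1, col1)", what))
  if (box[1] < 1L || box[2] < 1L || box[3] > dim[1] || box[4] > dim[2]) {
    stop(sprintf("'%s' [%s] lies outside the %dx%d image", what,
                 paste(box, collapse = ","), dim[1], dim[2]))
  }
  if (box[3] < box[1] || box[4] < box[2]) stop(sprintf("'%s' is empty", what))
  invisible(TRUE)
}

boxesDisjoint <- function(a, b) {
  a[3] < b[1] || b[3] < a[1] || a[4] < b[2] || b[4] < a[2]
}
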
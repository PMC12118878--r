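# Network architectures and objectives: the U-Net generator, the PatchGAN
# discriminator, and the adversarial + Huber + SSIM training objectives.

#' Generator architecture description
#'
#' Pix2Pix-style U-Net geometry: kernel-4 stride-2 convolutions in the
#' encoder, transposed convolutions in the decoder, skip concatenations
#' level to level, batch normalization everywhere except the first encoder
#' block, and 0.5 dropout in all but the first three encoder blocks and all
#' but the last three decoder blocks. The default depth halves the image
#' down to a 2x2 bottleneck (`nLevels = log2(side) - 1`).
#'
#' @param side square input side, divisible by `2^nLevels`.
#' @param baseFilters channel width of the first encoder block.
#' @param nLevels number of down/up-sampling levels.
#' @param dropoutP dropout probability in `[0, 1)`.
#' @param activation hidden activation, `"relu"` (default) or `"lrelu"`.
#' @param encoderDropoutSkip number of leading encoder blocks without dropout.
#' @param decoderDropoutSkip number of trailing decoder blocks without dropout.
#' @return a list of class `"GeneratorSpec"`.
#' @export
generatorSpec <- function(side, baseFilters = 64L,
                          nLevels = as.integer(log2(side)) - 1L,
                          dropoutP = 0.5, activation = c("relu", "lrelu"),
                          encoderDropoutSkip = 3L, decoderDropoutSkip = 3L) {
  activation <- match.arg(activation)
  if (dropoutP < 0 || dropoutP >= 1) stop("dropoutP must lie in [0, 1)")
  if (side %% 2^nLevels != 0) stop("side must be divisible by 2^nLevels")
  if (2^nLevels > side) stop("2^nLevels must not exceed the image side")
  structure(list(side = as.integer(side), baseFilters = as.integer(baseFilters),
                 nLevels = as.integer(nLevels), dropoutP = dropoutP,
                 activation = activation,
                 encoderDropoutSkip = as.integer(encoderDropoutSkip),
                 decoderDropoutSkip = as.integer(decoderDropoutSkip)),
            class = "GeneratorSpec")
}

#' PatchGAN discriminator architecture description
#'
#' Kernel-4 convolution stack scoring overlapping patches of the
#' channel-concatenated (condition, candidate) pair. The full-scale stack
#' (widths 64-128-256-512 plus a 1-channel head, strides 2,2,2,1,1) has a
#' 70x70 receptive field and produces a 30x30 score map for 256x256 input.
#' The first block carries no normalization; hidden blocks use ReLU and the
#' final layer a leaky rectifier. Smaller inputs get a reduced stack whose
#' receptive field fits inside the image, since a discriminator whose
#' receptive field exceeds its input is rejected.
#'
#' @param side square input side.
#' @param widths hidden channel widths (one per stride-listed block, head
#'   excluded).
#' @param strides strides of the blocks plus the head
#'   (`length(widths) + 1` entries).
#' @param alpha leaky-rectifier slope of the final activation.
#' @return a list of class `"DiscriminatorSpec"`.
#' @export
discriminatorSpec <- function(side = 256L, widths = NULL, strides = NULL,
                              alpha = 0.2) {
  if (is.null(widths)) {
    if (side >= 128L) {
      widths <- c(64L, 128L, 256L, 512L); strides <- c(2L, 2L, 2L, 1L, 1L)
    } else if (side >= 64L) {
      widths <- c(32L, 64L, 128L); strides <- c(2L, 2L, 1L, 1L)
    } else {
      widths <- c(32L, 64L); strides <- c(2L, 1L, 1L)
    }
  }
  if (length(strides) != length(widths) + 1L) {
    stop("strides must have length(widths) + 1 entries (head included)")
  }
  spec <- structure(list(side = as.integer(side), widths = as.integer(widths),
                         strides = as.integer(strides), kernel = 4L,
                         alpha = alpha),
                    class = "DiscriminatorSpec")
  if (patchReceptiveField(spec) > side) {
    stop(sprintf("input (%d px) smaller than the discriminator receptive field (%d px)",
                 side, patchReceptiveField(spec)))
  }
  spec
}

#' Receptive field of one discriminator output unit
#'
#' Composes the kernel/stride chain backwards:
#' `r_i = r_{i+1} * s_i + (k_i - s_i)` starting from `r = 1` at the output.
#'
#' @param spec a `"DiscriminatorSpec"`.
#' @return receptive-field side length in input pixels.
#' @examples
#' patchReceptiveField(discriminatorSpec(256)) # 70
#' @export
patchReceptiveField <- function(spec) {
  r <- 1L
  for (s in rev(spec$strides)) r <- r * s + (spec$kernel - s)
  r
}

encFilters <- function(spec) {
  spec$baseFilters * pmin(2^(seq_len(spec$nLevels) - 1L), 8L)
}

#' Build the U-Net generator
#'
#' Instantiates weights (truncated-normal he-style initialization) and the
#' im2col geometries for every layer of the encoder-decoder described by a
#' [generatorSpec()]. Consumes the ambient RNG stream; seed it for
#' reproducible builds.
#'
#' @param spec a `"GeneratorSpec"`.
#' @param inChannels input channel count (1 for grayscale B-scans).
#' @return an opaque generator model list used by [netForward()] and the
#'   training functions.
#' @export
buildGenerator <- function(spec, inChannels = 1L) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  L <- spec$nLevels
  f <- encFilters(spec)
  k <- 4L
  side <- spec$side
  enc <- vector("list", L)
  cIn <- inChannels
  h <- side
  for (i in seq_len(L)) {
    enc[[i]] <- list(
      geom = convGeom(h, h, cIn, k, 2L, 1L),
      W = heInit(k * k * cIn, f[i], k * k * cIn),
      b = numeric(f[i]),
      g = rep(1, f[i]), bt = numeric(f[i]),
      useNorm = (i > 1L) && (h / 2L > 1L),     # instance stats degenerate at 1x1
      useDropout = i > spec$encoderDropoutSkip)
    cIn <- f[i]
    h <- h %/% 2L
  }
  dec <- vector("list", L)
  for (j in seq_len(L)) {
    cInD <- if (j == 1L) f[L] else 2L * f[L - j + 1L]
    cOutD <- if (j < L) f[L - j] else inChannels
    hOut <- h * 2L
    dec[[j]] <- list(
      geomT = convGeom(hOut, hOut, cOutD, k, 2L, 1L),
      W = heInit(cInD, k * k * cOutD, k * k * cInD),
      b = numeric(cOutD),
      g = rep(1, cOutD), bt = numeric(cOutD),
      useNorm = j < L,
      useDropout = j <= L - spec$decoderDropoutSkip)
    h <- hOut
  }
  list(kind = "generator", spec = spec, inChannels = inChannels,
       enc = enc, dec = dec)
}

#' Build the PatchGAN discriminator
#'
#' @param spec a `"DiscriminatorSpec"`.
#' @param inChannels channels of the concatenated (condition, candidate)
#'   input (2 for a grayscale pair).
#' @return an opaque discriminator model list.
#' @export
buildDiscriminator <- function(spec, inChannels = 2L) {
  stopifnot(inherits(spec, "DiscriminatorSpec"))
  k <- spec$kernel
  widths <- c(spec$widths, 1L)
  nb <- length(widths)
  blocks <- vector("list", nb)
  cIn <- inChannels
  h <- spec$side
  for (i in seq_len(nb)) {
    s <- spec$strides[i]
    geom <- convGeom(h, h, cIn, k, s, 1L)
    blocks[[i]] <- list(
      geom = geom,
      W = heInit(k * k * cIn, widths[i], k * k * cIn),
      b = numeric(widths[i]),
      g = rep(1, widths[i]), bt = numeric(widths[i]),
      useNorm = i > 1L && i < nb,
      act = if (i < nb) "relu" else "lrelu")
    cIn <- widths[i]
    h <- geom$hOut
  }
  list(kind = "discriminator", spec = spec, inChannels = inChannels,
       blocks = blocks, outSide = h)
}

# Shared conv -> norm -> dropout -> activation block.
blockForward <- function(X, blk, act, dropoutP, training) {
  cf <- convForward(X, blk$W, blk$b, blk$geom)
  Z <- cf$Y
  bn <- NULL
  if (blk$useNorm) { bn <- bnForward(Z, blk$g, blk$bt); Z <- bn$Y }
  dr <- if (isTRUE(blk$useDropout)) dropoutForward(Z, dropoutP, training)
        else list(Y = Z, mask = NULL)
  A <- actForward(dr$Y, act)
  list(A = A, cache = list(cols = cf$cols, bn = bn, mask = dr$mask,
                           preact = dr$Y, out = A))
}

blockBackward <- function(dA, blk, cache, act) {
  dZ <- actBackward(dA, cache$preact, cache$out, act)
  if (!is.null(cache$mask)) dZ <- dZ * cache$mask
  dg <- dbt <- NULL
  if (!is.null(cache$bn)) {
    bb <- bnBackward(dZ, cache$bn, blk$g)
    dZ <- bb$dX; dg <- bb$dGamma; dbt <- bb$dBeta
  }
  cb <- convBackward(dZ, cache$cols, blk$W, blk$geom)
  list(dX = cb$dX, dW = cb$dW, db = cb$db, dg = dg, dbt = dbt)
}

catChannels <- function(A, B) {
  d <- dim(A)
  array(c(A, B), c(d[1], d[2], d[3] + dim(B)[3]))
}

# Generator forward pass on a (side, side, inChannels) array scaled to
# [-1, 1]. Returns the tanh output and the caches needed for backprop.
genForward <- function(model, X, training = FALSE) {
  spec <- model$spec
  L <- spec$nLevels
  encOut <- vector("list", L)
  encCache <- vector("list", L)
  A <- X
  for (i in seq_len(L)) {
    bf <- blockForward(A, model$enc[[i]], spec$activation, spec$dropoutP, training)
    A <- bf$A
    encOut[[i]] <- A
    encCache[[i]] <- bf$cache
  }
  decCache <- vector("list", L)
  for (j in seq_len(L)) {
    blk <- model$dec[[j]]
    ct <- convTForward(A, blk$W, blk$b, blk$geomT)
    Z <- ct$Y
    bn <- NULL
    if (blk$useNorm) { bn <- bnForward(Z, blk$g, blk$bt); Z <- bn$Y }
    dr <- if (blk$useDropout) dropoutForward(Z, spec$dropoutP, training)
          else list(Y = Z, mask = NULL)
    if (j < L) {
      Aj <- actForward(dr$Y, spec$activation)
      A <- catChannels(Aj, encOut[[L - j]])
    } else {
      Aj <- actForward(dr$Y, "tanh")
      A <- Aj
    }
    decCache[[j]] <- list(Xmat = ct$Xmat, bn = bn, mask = dr$mask,
                          preact = dr$Y, out = Aj)
  }
  list(Y = A, encOut = encOut, encCache = encCache, decCache = decCache)
}

# Backward pass through the generator; returns flat gradient lists for the
# encoder and decoder blocks.
genBackward <- function(model, fwd, dY) {
  spec <- model$spec
  L <- spec$nLevels
  dEnc <- vector("list", L)   # per-block param grads
  dDec <- vector("list", L)
  dSkip <- vector("list", L)  # grads flowing into encoder activations
  dA <- dY
  for (j in rev(seq_len(L))) {
    blk <- model$dec[[j]]
    cache <- decCacheJ <- fwd$decCache[[j]]
    if (j < L) {
      # dA is the gradient w.r.t. concat(act_j, encOut[L-j]): split it.
      cAct <- dim(cache$out)[3]
      dAct <- dA[, , seq_len(cAct), drop = FALSE]
      dSkipPart <- dA[, , -seq_len(cAct), drop = FALSE]
      dSkip[[L - j]] <- if (is.null(dSkip[[L - j]])) dSkipPart
                        else dSkip[[L - j]] + dSkipPart
      dZ <- actBackward(dAct, cache$preact, cache$out, spec$activation)
    } else {
      dZ <- actBackward(dA, cache$preact, cache$out, "tanh")
    }
    if (!is.null(cache$mask)) dZ <- dZ * cache$mask
    dg <- dbt <- NULL
    if (!is.null(cache$bn)) {
      bb <- bnBackward(dZ, cache$bn, blk$g)
      dZ <- bb$dX; dg <- bb$dGamma; dbt <- bb$dBeta
    }
    cb <- convTBackward(dZ, cache$Xmat, blk$W, blk$geomT)
    dDec[[j]] <- list(dW = cb$dWt, db = cb$db, dg = dg, dbt = dbt)
    hIn <- blk$geomT$hOut  # convT input side == geomT output-side of the conv view
    cIn <- nrow(blk$W)
    dA <- array(cb$dXmat, c(hIn, blk$geomT$wOut, cIn))
  }
  # dA now carries the gradient w.r.t. encOut[[L]] from the decoder chain.
  for (i in rev(seq_len(L))) {
    dAi <- dA
    if (!is.null(dSkip[[i]])) dAi <- dAi + dSkip[[i]]
    bb <- blockBackward(dAi, model$enc[[i]], fwd$encCache[[i]], spec$activation)
    dEnc[[i]] <- list(dW = bb$dW, db = bb$db, dg = bb$dg, dbt = bb$dbt)
    dA <- bb$dX
  }
  list(enc = dEnc, dec = dDec, dInput = dA)
}

# Discriminator forward on a (side, side, 2) array; returns the logit map.
# training = TRUE uses instance statistics in the normalization layers (the
# batch-size-1 training behaviour); training = FALSE freezes them to a
# per-channel affine, which keeps the conv stack's locality intact (the
# receptive-field probe relies on this).
discForward <- function(model, X, training = FALSE) {
  nb <- length(model$blocks)
  caches <- vector("list", nb)
  A <- X
  for (i in seq_len(nb)) {
    blk <- model$blocks[[i]]
    cf <- convForward(A, blk$W, blk$b, blk$geom)
    Z <- cf$Y
    bn <- NULL
    fixedNorm <- FALSE
    if (blk$useNorm) {
      if (training) {
        bn <- bnForward(Z, blk$g, blk$bt)
        Z <- bn$Y
      } else {
        fixedNorm <- TRUE
        Z <- sweep(sweep(Z, 3L, blk$g, "*"), 3L, blk$bt, "+")
      }
    }
    A2 <- actForward(Z, blk$act, model$spec$alpha)
    caches[[i]] <- list(cols = cf$cols, bn = bn, fixedNorm = fixedNorm,
                        preact = Z, out = A2)
    A <- A2
  }
  list(logits = A, caches = caches)
}

discBackward <- function(model, fwd, dLogits) {
  nb <- length(model$blocks)
  grads <- vector("list", nb)
  dA <- dLogits
  for (i in rev(seq_len(nb))) {
    blk <- model$blocks[[i]]
    cache <- fwd$caches[[i]]
    dZ <- actBackward(dA, cache$preact, cache$out, blk$act, model$spec$alpha)
    dg <- dbt <- NULL
    if (!is.null(cache$bn)) {
      bb <- bnBackward(dZ, cache$bn, blk$g)
      dZ <- bb$dX; dg <- bb$dGamma; dbt <- bb$dBeta
    } else if (isTRUE(cache$fixedNorm)) {
      dZ <- sweep(dZ, 3L, blk$g, "*")
    }
    cb <- convBackward(dZ, cache$cols, blk$W, blk$geom)
    grads[[i]] <- list(dW = cb$dW, db = cb$db, dg = dg, dbt = dbt)
    dA <- cb$dX
  }
  list(blocks = grads, dInput = dA)
}

#' Patch score map of a (condition, candidate) image pair
#'
#' Runs the discriminator on the channel-concatenated pair and returns the
#' post-sigmoid per-patch scores (probabilities that each 70x70 patch of
#' the pair is a real acquisition). Inputs are `[0,1]` images; rescaling to
#' the network range is handled here.
#'
#' @param model a built discriminator.
#' @param condition the noisy conditioning image.
#' @param candidate the clean/generated candidate image.
#' @param training use instance-normalization statistics (training mode).
#' @return matrix of patch scores in `(0, 1)`.
#' @export
discriminatorScores <- function(model, condition, candidate, training = FALSE) {
  side <- model$spec$side
  stopifnot(all(dim(condition) == c(side, side)),
            all(dim(candidate) == c(side, side)))
  X <- array(c(2 * condition - 1, 2 * candidate - 1), c(side, side, 2L))
  drop(stats::plogis(discForward(model, X, training)$logits))
}

#' Gradient-footprint probe of the discriminator receptive field
#'
#' Empirically confirms the receptive-field arithmetic: backpropagates from
#' a single output unit (the central one by default) to the input and
#' measures the side lengths of the bounding box of nonzero input-gradient
#' pixels. Gradients are accumulated over `nProbes` random inputs so that
#' rectifier dead zones of any single draw cannot shrink the footprint.
#'
#' @param model a built discriminator.
#' @param seed seed for the probe inputs.
#' @param unit output unit `c(row, col)`; defaults to the map centre.
#' @param nProbes number of random inputs to accumulate.
#' @return named integer vector `c(rows, cols)` of the footprint box.
#' @export
gradientFootprint <- function(model, seed = 1L, unit = NULL, nProbes = 3L) {
  side <- model$spec$side
  acc <- matrix(0, side, side)
  for (p in seq_len(nProbes)) {
    X <- withSeed(deriveSeed(seed, p), {
      array(stats::runif(side * side * model$inChannels, -1, 1),
            c(side, side, model$inChannels))
    })
    fw <- discForward(model, X, training = FALSE)
    d <- dim(fw$logits)
    u <- if (is.null(unit)) c((d[1] + 1L) %/% 2L, (d[2] + 1L) %/% 2L) else unit
    dL <- array(0, d)
    dL[u[1], u[2], 1] <- 1
    bk <- discBackward(model, fw, dL)
    acc <- acc + apply(abs(bk$dInput), c(1, 2), max)
  }
  rows <- range(which(rowSums(acc) > 1e-14))
  cols <- range(which(colSums(acc) > 1e-14))
  c(rows = rows[2] - rows[1] + 1L, cols = cols[2] - cols[1] + 1L)
}

#' Discriminator output map side for a given input side
#'
#' @param spec a `"DiscriminatorSpec"`.
#' @return spatial side length of the patch score map.
#' @examples
#' discOutputSide(discriminatorSpec(256)) # 30
#' @export
discOutputSide <- function(spec) {
  h <- spec$side
  for (s in spec$strides) h <- (h + 2L - spec$kernel) %/% s + 1L
  h
}

# --- objectives -------------------------------------------------------------

#' Huber loss
#'
#' Elementwise piecewise penalty, quadratic for residual magnitudes up to
#' `delta` and linear beyond, reduced by the mean over all elements:
#' `0.5 r^2` for `|r| <= delta`, `delta * (|r| - delta/2)` otherwise.
#' Continuous with continuous first derivative at `|r| = delta`.
#'
#' @param pred,target arrays of identical shape.
#' @param delta transition threshold (> 0).
#' @return mean Huber penalty.
#' @examples
#' huberLoss(matrix(0.5, 2, 2), matrix(0, 2, 2)) # 0.125
#' huberLoss(matrix(2, 2, 2), matrix(0, 2, 2))   # 1.5
#' @export
huberLoss <- function(pred, target, delta = 1) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  if (delta <= 0) stop("delta must be positive")
  r <- pred - target
  a <- abs(r)
  mean(ifelse(a <= delta, 0.5 * r^2, delta * (a - 0.5 * delta)))
}

huberGradient <- function(pred, target, delta = 1) {
  r <- pred - target
  g <- ifelse(abs(r) <= delta, r, delta * sign(r))
  g / length(r)
}

ssimConstants <- function(dynamicRange) {
  list(C1 = (0.01 * dynamicRange)^2, C2 = (0.03 * dynamicRange)^2)
}

ssimMoments <- function(x, y, windowSize, sigma) {
  kern <- gaussianKernel1d(windowSize, sigma)
  Fh <- filterBandMatrix(nrow(x), kern, "valid")
  Fw <- filterBandMatrix(ncol(x), kern, "valid")
  G <- function(z) Fh %*% z %*% t(Fw)
  list(Fh = Fh, Fw = Fw, u1 = G(x), v1 = G(y), u2 = G(x^2), v2 = G(y^2),
       u11 = G(x * y))
}

ssimMap <- function(mom, C1, C2) {
  sxy <- mom$u11 - mom$u1 * mom$v1
  sx2 <- mom$u2 - mom$u1^2
  sy2 <- mom$v2 - mom$v1^2
  A1 <- 2 * mom$u1 * mom$v1 + C1
  A2 <- 2 * sxy + C2
  B1 <- mom$u1^2 + mom$v1^2 + C1
  B2 <- sx2 + sy2 + C2
  list(S = (A1 * A2) / (B1 * B2), A1 = A1, A2 = A2, B1 = B1, B2 = B2)
}

#' Structural-similarity loss
#'
#' `1 - SSIM(pred, target)` with the standard constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` and an 11x11 Gaussian window of
#' sigma 1.5; the SSIM map is computed over fully valid window positions
#' and averaged. Value in `[0, 2]` (SSIM lies in `[-1, 1]`); 0 iff the
#' images are identical.
#'
#' @param pred,target image matrices of identical shape, at least the
#'   window size in each dimension.
#' @param dynamicRange declared dynamic range `L` of the data (1 for
#'   `[0,1]` images, 2 for network-scale `[-1,1]` tensors).
#' @param windowSize,sigma Gaussian window parameters.
#' @return scalar loss.
#' @export
ssimLoss <- function(pred, target, dynamicRange = 1, windowSize = 11L,
                     sigma = 1.5) {
  pred <- drop(pred); target <- drop(target)
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  if (nrow(pred) < windowSize || ncol(pred) < windowSize) {
    stop("image smaller than the SSIM window")
  }
  cc <- ssimConstants(dynamicRange)
  mom <- ssimMoments(pred, target, windowSize, sigma)
  1 - mean(ssimMap(mom, cc$C1, cc$C2)$S)
}

# Analytic gradient of ssimLoss w.r.t. pred, via the raw-moment chain rule;
# the Gaussian band matrices are symmetric kernels so their transposes are
# the exact adjoints of the valid-mode filtering.
ssimLossGradient <- function(pred, target, dynamicRange = 1, windowSize = 11L,
                             sigma = 1.5) {
  pred <- drop(pred); target <- drop(target)
  cc <- ssimConstants(dynamicRange)
  mom <- ssimMoments(pred, target, windowSize, sigma)
  sm <- ssimMap(mom, cc$C1, cc$C2)
  B1B2 <- sm$B1 * sm$B2
  dS_du11 <- 2 * sm$A1 / B1B2
  dS_du2 <- -sm$A1 * sm$A2 / (B1B2 * sm$B2)
  dS_du1 <- 2 * mom$v1 * (sm$A2 - sm$A1) / B1B2 -
    2 * mom$u1 * sm$A1 * sm$A2 * (sm$B2 - sm$B1) / (B1B2^2)
  Gt <- function(z) t(mom$Fh) %*% z %*% mom$Fw
  N <- length(sm$S)
  dMean <- (Gt(dS_du1) + 2 * pred * Gt(dS_du2) + target * Gt(dS_du11)) / N
  -dMean
}

#' Mean absolute error
#'
#' @param pred,target arrays of identical shape.
#' @return mean of `|pred - target|`.
#' @export
maeLoss <- function(pred, target) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  mean(abs(pred - target))
}

maeGradient <- function(pred, target) sign(pred - target) / length(pred)

#' Binary cross-entropy of a patch score map against a constant label
#'
#' Computed from logits for numerical stability.
#'
#' @param logits logit array.
#' @param label 0 (fake) or 1 (real).
#' @return mean BCE.
#' @export
bceWithLogits <- function(logits, label) {
  mean(pmax(logits, 0) - logits * label + log1p(exp(-abs(logits))))
}

bceLogitsGradient <- function(logits, label) {
  (stats::plogis(logits) - label) / length(logits)
}

#' Combined generator objective
#'
#' `l_adv + lambdaDl * (l_huber + l_ssim)`: the adversarial term plus the
#' weighted Huber and SSIM reconstruction terms (default weight 100).
#'
#' @param lAdv adversarial generator loss.
#' @param lHuber Huber reconstruction loss.
#' @param lSsim SSIM loss.
#' @param lambdaDl reconstruction weight.
#' @return total generator loss.
#' @examples
#' generatorObjective(0, 1, 0)            # 100
#' generatorObjective(0.7, 0.02, 0.05)    # 7.7
#' @export
generatorObjective <- function(lAdv, lHuber, lSsim, lambdaDl = 100) {
  lAdv + lambdaDl * (lHuber + lSsim)
}

#' Discriminator objective
#'
#' Binary cross-entropy of the real-pair score map against all-ones labels
#' plus that of the fake-pair map against all-zeros, averaged per map and
#' summed (the unchanged Pix2Pix discriminator loss). Chance scores of 0.5
#' everywhere give `2 log 2`.
#'
#' @param realScores score map of a (condition, real) pair.
#' @param fakeScores score map of a (condition, generated) pair.
#' @param fromLogits whether the maps are logits (default) or
#'   post-sigmoid probabilities.
#' @return scalar discriminator loss.
#' @export
discriminatorObjective <- function(realScores, fakeScores, fromLogits = TRUE) {
  if (fromLogits) {
    bceWithLogits(realScores, 1) + bceWithLogits(fakeScores, 0)
  } else {
    p <- clamp(realScores, 1e-12, 1 - 1e-12)
    q <- clamp(fakeScores, 1e-12, 1 - 1e-12)
    mean(-log(p)) + mean(-log(1 - q))
  }
}

#' Build the supervised U-Net baseline
#'
#' The same encoder-decoder skeleton as the cGAN generator, intended for
#' supervised training with the mean-absolute-error loss only (no
#' adversary); see [trainUnet()].
#'
#' @inheritParams buildGenerator
#' @return an opaque model list.
#' @export
buildUnetBaseline <- function(spec, inChannels = 1L) {
  m <- buildGenerator(spec, inChannels)
  m$kind <- "unet"
  m
}

#' Run a network forward on an image
#'
#' Low-level single-image forward pass on the network scale: input and
#' output are `[-1, 1]` matrices. Most users want [denoiseImage()], which
#' owns the `[0,1]` rescaling and padding.
#'
#' @param model a built generator/U-Net model.
#' @param x input matrix scaled to `[-1, 1]`.
#' @param training enable training-mode stochasticity (dropout).
#' @return output matrix on the network scale.
#' @export
netForward <- function(model, x, training = FALSE) {
  X <- array(x, c(nrow(x), ncol(x), 1L))
  drop(genForward(model, X, training)$Y)
}
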
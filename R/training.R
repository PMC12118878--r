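# Alternating cGAN optimization and supervised U-Net training with the
# reference hyper-parameters, plus the inference wrapper and checkpointing.

toNetScale <- function(img) 2 * img - 1
fromNetScale <- function(x) clamp((x + 1) / 2, 0, 1)

collectGenParams <- function(model) {
  p <- list()
  for (part in c("enc", "dec")) {
    for (i in seq_along(model[[part]])) {
      blk <- model[[part]][[i]]
      for (nm in c("W", "b", "g", "bt")) {
        p[[paste(part, i, nm, sep = ".")]] <- blk[[nm]]
      }
    }
  }
  p
}

setGenParams <- function(model, p) {
  for (part in c("enc", "dec")) {
    for (i in seq_along(model[[part]])) {
      for (nm in c("W", "b", "g", "bt")) {
        model[[part]][[i]][[nm]] <- p[[paste(part, i, nm, sep = ".")]]
      }
    }
  }
  model
}

flattenGenGrads <- function(gr) {
  p <- list()
  for (part in c("enc", "dec")) {
    for (i in seq_along(gr[[part]])) {
      blk <- gr[[part]][[i]]
      map <- c(W = "dW", b = "db", g = "dg", bt = "dbt")
      for (nm in names(map)) p[[paste(part, i, nm, sep = ".")]] <- blk[[map[[nm]]]]
    }
  }
  p
}

collectDiscParams <- function(model) {
  p <- list()
  for (i in seq_along(model$blocks)) {
    for (nm in c("W", "b", "g", "bt")) {
      p[[paste("blk", i, nm, sep = ".")]] <- model$blocks[[i]][[nm]]
    }
  }
  p
}

setDiscParams <- function(model, p) {
  for (i in seq_along(model$blocks)) {
    for (nm in c("W", "b", "g", "bt")) {
      model$blocks[[i]][[nm]] <- p[[paste("blk", i, nm, sep = ".")]]
    }
  }
  model
}

flattenDiscGrads <- function(gr) {
  p <- list()
  map <- c(W = "dW", b = "db", g = "dg", bt = "dbt")
  for (i in seq_along(gr$blocks)) {
    for (nm in names(map)) {
      p[[paste("blk", i, nm, sep = ".")]] <- gr$blocks[[i]][[map[[nm]]]]
    }
  }
  p
}

sumGrads <- function(a, b) {
  for (nm in names(a)) {
    if (!is.null(a[[nm]]) && !is.null(b[[nm]])) a[[nm]] <- a[[nm]] + b[[nm]]
  }
  a
}

checkFinite <- function(..., step) {
  vals <- c(...)
  if (any(!is.finite(vals))) {
    stop(sprintf("training diverged at step %d: non-finite loss (%s)",
                 step, paste(signif(vals, 4), collapse = ", ")))
  }
}

epochOrder <- function(n, steps) {
  # random reshuffle per epoch; with batch 1 this is the step sequence
  ord <- integer(0)
  while (length(ord) < steps) ord <- c(ord, sample.int(n))
  ord[seq_len(steps)]
}

#' Train the conditional GAN denoiser
#'
#' Alternating optimization, one sample per step: first one
#' discriminator update (binary cross-entropy on the real and generated
#' pair score maps) followed by one generator update of the combined
#' objective `L_cGAN + lambdaDl * (L_huber + L_ssim)`. Both networks use
#' Adam with the configured learning rate, moment decays and epsilon;
#' batch size is 1 and samples are visited in reshuffled epochs. The run is
#' fully seeded: weight init, shuffling and dropout all derive from
#' `cfg@seed`. Any non-finite loss aborts with a diagnostic.
#'
#' @param dataset list of [PairedSample-class] objects of identical shape.
#' @param genSpec a `"GeneratorSpec"`; defaults to a spec matching the data.
#' @param discSpec a `"DiscriminatorSpec"`; defaults to a stack whose
#'   receptive field fits the image side.
#' @param cfg a [TrainConfig-class].
#' @param checkpointDir optional directory for periodic and final
#'   checkpoints (written with [saveModel()]).
#' @param verbose print progress every 100 steps.
#' @return a trained model list with elements `generator`, `log`
#'   (per-step `data.frame` with columns step, lDisc, lAdv, lHuber, lSsim,
#'   totalG), `cfg`, and `type = "cgan"`.
#' @export
trainCGAN <- function(dataset, genSpec = NULL, discSpec = NULL,
                      cfg = trainConfig(), checkpointDir = NULL,
                      verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  side <- nrow(dataset[[1]]@input)
  for (s in dataset) {
    if (!all(dim(s@input) == c(side, side))) {
      stop("all pairs must be square images of identical shape")
    }
  }
  if (is.null(genSpec)) genSpec <- generatorSpec(side, baseFilters = 32L)
  if (is.null(discSpec)) discSpec <- discriminatorSpec(side)
  set.seed(cfg@seed)
  G <- buildGenerator(genSpec)
  D <- buildDiscriminator(discSpec)
  gState <- adamInit(collectGenParams(G))
  dState <- adamInit(collectDiscParams(D))
  lambda <- cfg@lambdaDl
  delta <- cfg@delta
  ord <- epochOrder(length(dataset), cfg@steps)
  log <- data.frame(step = seq_len(cfg@steps), lDisc = NA_real_,
                    lAdv = NA_real_, lHuber = NA_real_, lSsim = NA_real_,
                    totalG = NA_real_)
  for (step in seq_len(cfg@steps)) {
    s <- dataset[[ord[step]]]
    x <- toNetScale(s@input)
    y <- toNetScale(s@target)
    X <- array(x, c(side, side, 1L))

    gfw <- genForward(G, X, training = TRUE)
    fake <- gfw$Y

    # --- discriminator update ---
    realIn <- array(c(x, y), c(side, side, 2L))
    fakeIn <- array(c(x, fake), c(side, side, 2L))
    dfR <- discForward(D, realIn, training = TRUE)
    dfF <- discForward(D, fakeIn, training = TRUE)
    lDisc <- discriminatorObjective(dfR$logits, dfF$logits)
    gR <- discBackward(D, dfR, bceLogitsGradient(dfR$logits, 1))
    gF <- discBackward(D, dfF, bceLogitsGradient(dfF$logits, 0))
    dGrads <- sumGrads(flattenDiscGrads(gR), flattenDiscGrads(gF))
    up <- adamStep(collectDiscParams(D), dGrads, dState,
                   cfg@lr, cfg@beta1, cfg@beta2, cfg@epsilon)
    D <- setDiscParams(D, up$params); dState <- up$state

    # --- generator update (against the freshly updated discriminator) ---
    fakeIn <- array(c(x, fake), c(side, side, 2L))
    dfG <- discForward(D, fakeIn, training = TRUE)
    lAdv <- bceWithLogits(dfG$logits, 1)
    advBack <- discBackward(D, dfG, bceLogitsGradient(dfG$logits, 1))
    dFakeAdv <- advBack$dInput[, , 2L, drop = FALSE]

    fakeMat <- drop(fake)
    lHuber <- huberLoss(fakeMat, y, delta)
    lSsim <- ssimLoss(fakeMat, y, dynamicRange = 2)
    totalG <- generatorObjective(lAdv, lHuber, lSsim, lambda)
    checkFinite(lDisc, lAdv, lHuber, lSsim, step = step)

    dFake <- dFakeAdv +
      array(lambda * (huberGradient(fakeMat, y, delta) +
                      ssimLossGradient(fakeMat, y, dynamicRange = 2)),
            dim(fake))
    gb <- genBackward(G, gfw, dFake)
    up <- adamStep(collectGenParams(G), flattenGenGrads(gb), gState,
                   cfg@lr, cfg@beta1, cfg@beta2, cfg@epsilon)
    G <- setGenParams(G, up$params); gState <- up$state

    log[step, 2:6] <- c(lDisc, lAdv, lHuber, lSsim, totalG)
    if (verbose && step %% 100L == 0L) {
      message(sprintf("step %d: D %.4f, G %.4f (adv %.4f, huber %.5f, ssim %.5f)",
                      step, lDisc, totalG, lAdv, lHuber, lSsim))
    }
    if (!is.null(checkpointDir) && cfg@checkpointEvery > 0L &&
        step %% cfg@checkpointEvery == 0L) {
      saveModel(list(generator = G, log = log[seq_len(step), ], cfg = cfg,
                     type = "cgan"),
                file.path(checkpointDir, sprintf("step%06d", step)))
    }
  }
  model <- list(generator = G, log = log, cfg = cfg, type = "cgan")
  if (!is.null(checkpointDir)) saveModel(model, file.path(checkpointDir, "final"))
  model
}

#' Train the supervised U-Net baseline
#'
#' Mean-absolute-error descent with Adam on the same encoder-decoder
#' skeleton; identical logging, seeding and checkpoint contract as
#' [trainCGAN()].
#'
#' @param dataset list of [PairedSample-class] objects.
#' @param spec a `"GeneratorSpec"`.
#' @param cfg a [TrainConfig-class]; the conventional supervised Adam
#'   moments are `beta1 = 0.9`, `beta2 = 0.999`.
#' @param checkpointDir optional checkpoint directory.
#' @param verbose print progress.
#' @return trained model list with `type = "unet"` and a log with columns
#'   step, lMae.
#' @export
trainUnet <- function(dataset, spec = NULL,
                      cfg = trainConfig(beta1 = 0.9), checkpointDir = NULL,
                      verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  side <- nrow(dataset[[1]]@input)
  if (is.null(spec)) spec <- generatorSpec(side, baseFilters = 32L)
  set.seed(cfg@seed)
  G <- buildUnetBaseline(spec)
  gState <- adamInit(collectGenParams(G))
  ord <- epochOrder(length(dataset), cfg@steps)
  log <- data.frame(step = seq_len(cfg@steps), lMae = NA_real_)
  for (step in seq_len(cfg@steps)) {
    s <- dataset[[ord[step]]]
    x <- toNetScale(s@input)
    y <- toNetScale(s@target)
    gfw <- genForward(G, array(x, c(side, side, 1L)), training = TRUE)
    pred <- drop(gfw$Y)
    lMae <- maeLoss(pred, y)
    checkFinite(lMae, step = step)
    gb <- genBackward(G, gfw, array(maeGradient(pred, y), dim(gfw$Y)))
    up <- adamStep(collectGenParams(G), flattenGenGrads(gb), gState,
                   cfg@lr, cfg@beta1, cfg@beta2, cfg@epsilon)
    G <- setGenParams(G, up$params); gState <- up$state
    log$lMae[step] <- lMae
    if (verbose && step %% 100L == 0L) {
      message(sprintf("step %d: MAE %.5f", step, lMae))
    }
    if (!is.null(checkpointDir) && cfg@checkpointEvery > 0L &&
        step %% cfg@checkpointEvery == 0L) {
      saveModel(list(generator = G, log = log[seq_len(step), ], cfg = cfg,
                     type = "unet"),
                file.path(checkpointDir, sprintf("step%06d", step)))
    }
  }
  model <- list(generator = G, log = log, cfg = cfg, type = "unet")
  if (!is.null(checkpointDir)) saveModel(model, file.path(checkpointDir, "final"))
  model
}

#' Denoise an image with a trained model
#'
#' Inference wrapper owning the scaling conventions: the `[0,1]` image is
#' rescaled to the network's `[-1,1]` range, reflection-padded up to the
#' model's input side if needed, run through the generator with dropout
#' disabled (unless `stochastic = TRUE`), cropped back, and returned
#' clamped to `[0,1]`.
#'
#' @param img image matrix in `[0, 1]` (values outside are clamped).
#' @param model a trained model from [trainCGAN()] / [trainUnet()].
#' @param stochastic keep dropout active at inference.
#' @return denoised image, same shape as the input.
#' @export
denoiseImage <- function(img, model, stochastic = FALSE) {
  assertImage(img)
  G <- model$generator
  side <- G$spec$side
  h <- nrow(img); w <- ncol(img)
  if (h > side || w > side) {
    stop(sprintf("image (%dx%d) larger than the model input (%dx%d)",
                 h, w, side, side))
  }
  x <- clamp(img, 0, 1)
  if (h < side || w < side) {
    padded <- matrix(0, side, side)
    padded[seq_len(h), seq_len(w)] <- x
    if (h < side) padded[(h + 1):side, seq_len(w)] <- x[h - seq_len(side - h) + 1L, ]
    if (w < side) padded[, (w + 1):side] <- padded[, w - seq_len(side - w) + 1L]
    x <- padded
  }
  out <- netForward(G, toNetScale(x), training = stochastic)
  fromNetScale(out)[seq_len(h), seq_len(w)]
}

#' Save a trained model checkpoint
#'
#' Writes `<path>.rds` (weights and log) plus a JSON metadata sidecar
#' `<path>.json` with the architecture summary, step count and seed.
#'
#' @param model trained model list.
#' @param path checkpoint path without extension.
#' @return invisibly, the `.rds` path.
#' @export
saveModel <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  rds <- paste0(path, ".rds")
  saveRDS(model, rds)
  meta <- list(type = model$type,
               side = model$generator$spec$side,
               baseFilters = model$generator$spec$baseFilters,
               nLevels = model$generator$spec$nLevels,
               steps = nrow(model$log),
               seed = model$cfg@seed,
               package = as.character(utils::packageVersion("PADenoise")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(rds)
}

#' Load a model checkpoint written by [saveModel()]
#'
#' @param path checkpoint path without extension.
#' @return the model list.
#' @export
loadModel <- function(path) readRDS(paste0(path, ".rds"))
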
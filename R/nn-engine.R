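# Minimal convolutional network engine.
#
# Tensors are base arrays (rows, cols, channels); convolutions are lowered
# to BLAS matrix products through precomputed im2col/col2im index maps, and
# gradients are hand-derived per layer. The col2im scatter loops over the
# k*k kernel offsets, within which the target indices of different sliding
# windows are guaranteed disjoint, so each offset is one vectorized add.
# This keeps desk-scale cGAN training tractable in pure R.

convGeom <- function(hIn, wIn, cIn, k, s, pad) {
  hP <- hIn + 2L * pad; wP <- wIn + 2L * pad
  hOut <- (hP - k) %/% s + 1L
  wOut <- (wP - k) %/% s + 1L
  if (hOut < 1L || wOut < 1L) stop("input smaller than kernel")
  r0 <- (seq_len(hOut) - 1L) * s
  c0 <- (seq_len(wOut) - 1L) * s
  corner <- as.vector(outer(r0 + 1L, c0 * hP, "+"))     # n, row-fastest
  off <- as.vector(outer(seq_len(k) - 1L, (seq_len(k) - 1L) * hP, "+"))
  spatial <- outer(corner, off, "+")                    # n x k*k
  n <- nrow(spatial)
  kk <- k * k
  gather <- matrix(0L, n, kk * cIn)
  for (ch in seq_len(cIn)) {
    gather[, (ch - 1L) * kk + seq_len(kk)] <- spatial + (ch - 1L) * hP * wP
  }
  scatter <- vector("list", kk)
  chOff <- rep((seq_len(cIn) - 1L) * hP * wP, each = n)
  for (t in seq_len(kk)) scatter[[t]] <- rep(spatial[, t], cIn) + chOff
  list(hIn = hIn, wIn = wIn, cIn = cIn, k = k, s = s, pad = pad,
       hP = hP, wP = wP, hOut = hOut, wOut = wOut, n = n,
       gather = gather, scatter = scatter)
}

padArr <- function(X, pad) {
  if (pad == 0L) return(X)
  d <- dim(X)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- X
  out
}

unpadArr <- function(Xp, pad, h, w) {
  if (pad == 0L) return(Xp)
  Xp[pad + seq_len(h), pad + seq_len(w), , drop = FALSE]
}

im2col <- function(X, geom) {
  Xp <- padArr(X, geom$pad)
  matrix(Xp[geom$gather], geom$n, ncol(geom$gather))
}

col2im <- function(cols, geom, cOut) {
  kk <- geom$k^2
  acc <- numeric(geom$hP * geom$wP * cOut)
  for (t in seq_len(kk)) {
    idx <- geom$scatter[[t]]
    acc[idx] <- acc[idx] + as.vector(cols[, (seq_len(cOut) - 1L) * kk + t])
  }
  array(acc, c(geom$hP, geom$wP, cOut))
}

# --- convolution ------------------------------------------------------------

# W: (k*k*cIn) x cOut, b: length cOut
convForward <- function(X, W, b, geom) {
  cols <- im2col(X, geom)
  Y <- cols %*% W
  Y <- Y + rep(b, each = geom$n)
  list(Y = array(Y, c(geom$hOut, geom$wOut, length(b))), cols = cols)
}

convBackward <- function(dY, cols, W, geom) {
  cOut <- dim(dY)[3]
  dYmat <- matrix(dY, geom$n, cOut)
  dW <- crossprod(cols, dYmat)
  db <- colSums(dYmat)
  dXp <- col2im(tcrossprod(dYmat, W), geom, geom$cIn)
  list(dW = dW, db = db,
       dX = unpadArr(dXp, geom$pad, geom$hIn, geom$wIn))
}

# --- transposed convolution -------------------------------------------------
# Uses the geometry of the conv that maps the *output* back to the input:
# geomT = convGeom(hOut, wOut, cOut, k, s, pad) with geomT$n == hIn*wIn.
# Wt: cIn x (k*k*cOut), b: length cOut.

convTForward <- function(X, Wt, b, geomT) {
  d <- dim(X)
  Xmat <- matrix(X, d[1] * d[2], d[3])
  cols <- Xmat %*% Wt
  cOut <- length(b)
  Yp <- col2im(cols, geomT, cOut)
  Y <- unpadArr(Yp, geomT$pad, geomT$hIn, geomT$wIn)
  Y <- Y + rep(b, each = geomT$hIn * geomT$wIn)
  list(Y = Y, Xmat = Xmat)
}

convTBackward <- function(dY, Xmat, Wt, geomT) {
  cOut <- dim(dY)[3]
  dYp <- padArr(dY, geomT$pad)
  dcols <- matrix(dYp[geomT$gather], geomT$n, ncol(geomT$gather))
  dXmat <- tcrossprod(dcols, Wt)
  dWt <- crossprod(Xmat, dcols)
  db <- colSums(matrix(dY, geomT$hIn * geomT$wIn, cOut))
  list(dWt = dWt, db = db, dXmat = dXmat)
}

# --- normalization ----------------------------------------------------------
# Batch normalization at batch size 1 normalizes each channel over its
# spatial extent (instance-style statistics); the same statistics are used
# at inference, the usual Pix2Pix behaviour.

bnForward <- function(X, gamma, beta, eps = 1e-3) {
  d <- dim(X)
  n <- d[1] * d[2]
  Xm <- matrix(X, n, d[3])
  m <- colMeans(Xm)
  xc <- sweep(Xm, 2L, m)
  v <- colSums(xc^2) / n
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  Y <- sweep(xhat, 2L, gamma, "*")
  Y <- sweep(Y, 2L, beta, "+")
  list(Y = array(Y, d), xhat = xhat, xc = xc, inv = inv, n = n)
}

bnBackward <- function(dY, cache, gamma) {
  d <- dim(dY)
  n <- cache$n
  dYm <- matrix(dY, n, d[3])
  dg <- colSums(dYm * cache$xhat)
  db <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, gamma, "*")
  dv <- colSums(dxhat * cache$xc) * (-0.5) * cache$inv^3
  dm <- -colSums(dxhat) * cache$inv
  dX <- sweep(dxhat, 2L, cache$inv, "*") +
    sweep(cache$xc, 2L, 2 * dv / n, "*") +
    matrix(dm / n, n, d[3], byrow = TRUE)
  list(dX = array(dX, d), dGamma = dg, dBeta = db)
}

# --- activations ------------------------------------------------------------

actForward <- function(X, kind, alpha = 0.2) {
  switch(kind,
    relu = pmax(X, 0),
    lrelu = ifelse(X > 0, X, alpha * X),
    tanh = tanh(X),
    linear = X)
}

actBackward <- function(dY, X, Y, kind, alpha = 0.2) {
  switch(kind,
    relu = dY * (X > 0),
    lrelu = dY * ifelse(X > 0, 1, alpha),
    tanh = dY * (1 - Y^2),
    linear = dY)
}

# Inverted dropout; consumes the ambient RNG stream (seeded by the caller).
dropoutForward <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  mask <- array((stats::runif(length(X)) >= p) / (1 - p), dim(X))
  list(Y = X * mask, mask = mask)
}

# --- initialization ---------------------------------------------------------

truncNorm <- function(n, sd) {
  x <- stats::rnorm(n, 0, sd)
  bad <- which(abs(x) > 2 * sd)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > 2 * sd]
  }
  x
}

# he_normal: truncated normal with sd = sqrt(2 / fanIn).
heInit <- function(nrow, ncol, fanIn) {
  matrix(truncNorm(nrow * ncol, sqrt(2 / fanIn)), nrow, ncol)
}

# --- Adam -------------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
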
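# Dense encoder-decoder (DED): a tied-weight multilayer perceptron over
# flattened occupancy volumes.  Architecture N -> k -> k -> N where N is the
# voxel count and k the hidden width; the output layer reuses the transpose
# of the input weight matrix (tied weights), the input is multiplied by a
# Bernoulli mask during training (denoising-autoencoder style), batch
# normalization follows every layer but the last, ReLU activations inside,
# sigmoid at the output.  Trained with Adam on a BCE + boundary-weighted
# negative-DICE mix, optionally with spatial weight-smoothing regularization
# (SWR) on the voxel-indexed input/output weights.

EPS_DICE <- 1e-7
EPS_CLAMP <- 1e-7

#' DED network configuration
#'
#' @slot grid the [GridSpec-class] of input/target volumes.
#' @slot hidden hidden layer sizes; one or two entries, all equal (the tied
#'   output layer maps the last hidden layer back through the input weights).
#' @slot alpha loss mix in \[0, 1\]: `alpha * BCE - (1 - alpha) * DICE`.
#' @slot lambdaSwr SWR strength (0 disables; named variants: 0 "No SWR",
#'   0.05 "SWR005", 75 "SWR75").
#' @slot betaMask,sigmaMask boundary-mask parameters (see [boundaryMask()]).
#' @slot maskMode `"peaked"` or `"literal"` boundary-mask form.
#' @slot useBoundaryMask logical; FALSE trains with a uniform mask.
#' @slot maskRate input Bernoulli zeroing rate in \[0, 1) during training.
#' @slot diceSquared use squared terms in the soft-DICE denominator.
#' @slot lr,batchSize,epochs,seed optimizer settings.
#' @export
setClass("DEDConfig", representation(grid = "GridSpec", hidden = "integer",
  alpha = "numeric", lambdaSwr = "numeric", betaMask = "numeric",
  sigmaMask = "numeric", maskMode = "character", useBoundaryMask = "logical",
  maskRate = "numeric", diceSquared = "logical", lr = "numeric",
  batchSize = "integer", epochs = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@hidden) < 1L || length(object@hidden) > 2L)
      return("hidden must have one or two entries")
    if (any(object@hidden <= 0L)) return("hidden sizes must be positive")
    if (length(unique(object@hidden)) != 1L)
      return("tied weights require equal hidden sizes")
    if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0, 1]")
    if (object@lambdaSwr < 0) return("lambdaSwr must be >= 0")
    if (object@maskRate < 0 || object@maskRate >= 1)
      return("maskRate must be in [0, 1)")
    if (!object@maskMode %in% c("peaked", "literal"))
      return("maskMode must be 'peaked' or 'literal'")
    TRUE
  })

#' @rdname DEDConfig-class
#' @param grid,hidden,alpha,lambdaSwr,betaMask,sigmaMask,maskMode
#'   see slot documentation.
#' @param useBoundaryMask,maskRate,diceSquared,lr,batchSize,epochs,seed
#'   see slot documentation.
#' @export
DEDConfig <- function(grid = GridSpec(), hidden = c(350L, 350L), alpha = 2 / 5,
                      lambdaSwr = 0.05, betaMask = 14, sigmaMask = 1.5,
                      maskMode = "peaked", useBoundaryMask = TRUE,
                      maskRate = 0.3, diceSquared = FALSE, lr = 1e-3,
                      batchSize = 20L, epochs = 300L, seed = 1L) {
  new("DEDConfig", grid = grid, hidden = as.integer(hidden), alpha = alpha,
      lambdaSwr = lambdaSwr, betaMask = betaMask, sigmaMask = sigmaMask,
      maskMode = maskMode, useBoundaryMask = useBoundaryMask,
      maskRate = maskRate, diceSquared = diceSquared, lr = lr,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed))
}

#' DED model (weights + configuration + training history)
#'
#' The input/output weights are tied: a single matrix `W` (N voxels x k
#' hidden units) serves as the encoder weights and, transposed, as the
#' decoder weights, so the tying invariant holds after every optimizer step
#' by construction.  `tiedWeightError()` materializes both uses and returns
#' their maximal absolute difference.
#'
#' @slot config a [DEDConfig-class].
#' @slot params named list of parameter arrays (`W`, `W2`, `bOut`, batch-norm
#'   scales/offsets `g1`, `be1`, `g2`, `be2`).
#' @slot bn running batch-norm statistics.
#' @slot history per-epoch data.frame (loss, bce, dice, swr).
#' @export
setClass("DEDModel", representation(config = "DEDConfig", params = "list",
                                    bn = "list", history = "data.frame"))

setMethod("show", "DEDModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "DEDModel: %d -> %s -> %d, alpha=%.3g, lambda=%.3g, %d epoch(s) trained\n",
    prod(cfg@grid@dims), paste(cfg@hidden, collapse = " -> "),
    prod(cfg@grid@dims), cfg@alpha, cfg@lambdaSwr, nrow(object@history)))
})

#' Initialize a DED model
#'
#' Seeded Glorot-style initialization; batch-norm scales start at 1,
#' offsets and biases at 0, running statistics at (0, 1).
#'
#' @param cfg a [DEDConfig-class].
#' @return An untrained [DEDModel-class].
#' @export
initDED <- function(cfg) {
  validObject(cfg)
  N <- prod(cfg@grid@dims)
  k <- cfg@hidden[1]
  withLocalSeed(cfg@seed, {
    W <- matrix(rnorm(N * k, sd = sqrt(2 / (N + k))), N, k)
    W2 <- if (length(cfg@hidden) == 2L)
      matrix(rnorm(k * k, sd = sqrt(2 / (2 * k))), k, k) else NULL
    params <- list(W = W, W2 = W2, bOut = numeric(N),
                   g1 = rep(1, k), be1 = numeric(k),
                   g2 = if (!is.null(W2)) rep(1, k),
                   be2 = if (!is.null(W2)) numeric(k))
    bn <- list(rm1 = numeric(k), rv1 = rep(1, k),
               rm2 = if (!is.null(W2)) numeric(k),
               rv2 = if (!is.null(W2)) rep(1, k))
    new("DEDModel", config = cfg, params = params, bn = bn,
        history = data.frame())
  })
}

#' Residual of the weight-tying invariant
#'
#' @param model a [DEDModel-class].
#' @return `max |W_out - t(W_in)|`, zero whenever the tying holds.
#' @export
tiedWeightError <- function(model) {
  Wout <- t(model@params$W) # materialized decoder weights
  max(abs(Wout - t(model@params$W)))
}

#' Total number of unique trainable weights (untied count)
#'
#' @param cfg a [DEDConfig-class].
#' @return list with `weights` (unique weight-matrix entries) and `biases`.
#' @export
dedParameterCount <- function(cfg) {
  N <- prod(cfg@grid@dims); k <- cfg@hidden[1]
  w <- N * k + if (length(cfg@hidden) == 2L) k * k else 0
  b <- N + 2L * k * length(cfg@hidden) # bOut + BN scale/offset pairs
  list(weights = w, biases = b)
}

sigmoid <- function(s) 1 / (1 + exp(-s))

bnForward <- function(A, g, be, rm, rv, batchStats, momentum = 0.1,
                      eps = 1e-5) {
  if (batchStats) {
    mu <- colMeans(A)
    va <- colMeans(A^2) - mu^2
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * va
  } else {
    mu <- rm; va <- rv
  }
  istd <- 1 / sqrt(va + eps)
  Ahat <- sweep(sweep(A, 2L, mu, "-"), 2L, istd, "*")
  Y <- sweep(sweep(Ahat, 2L, g, "*"), 2L, be, "+")
  list(Y = Y, Ahat = Ahat, istd = istd, g = g, rm = rm, rv = rv)
}

bnBackward <- function(dY, cache) {
  B <- nrow(dY)
  dg <- colSums(dY * cache$Ahat)
  dbe <- colSums(dY)
  dAhat <- sweep(dY, 2L, cache$g, "*")
  sum1 <- colSums(dAhat)
  sum2 <- colSums(dAhat * cache$Ahat)
  dA <- sweep(dAhat, 2L, sum1 / B, "-") -
    sweep(cache$Ahat, 2L, sum2 / B, "*")
  dA <- sweep(dA, 2L, cache$istd, "*")
  list(dA = dA, dg = dg, dbe = dbe)
}

# core forward pass on a B x N matrix; masking consumes the current RNG
# stream when maskInput is TRUE
dedForwardCore <- function(model, X, maskInput = FALSE, batchStats = FALSE,
                           keepCache = FALSE) {
  p <- model@params; bn <- model@bn; cfg <- model@config
  Xm <- X
  if (maskInput && cfg@maskRate > 0) {
    M <- matrix(rbinom(length(X), 1L, 1 - cfg@maskRate), nrow(X))
    Xm <- X * M
  }
  A1 <- Xm %*% p$W
  c1 <- bnForward(A1, p$g1, p$be1, bn$rm1, bn$rv1, batchStats)
  H1 <- pmax(c1$Y, 0)
  if (!is.null(p$W2)) {
    A2 <- H1 %*% p$W2
    c2 <- bnForward(A2, p$g2, p$be2, bn$rm2, bn$rv2, batchStats)
    H2 <- pmax(c2$Y, 0)
  } else {
    A2 <- NULL; c2 <- NULL; H2 <- H1
  }
  S <- tcrossprod(H2, p$W)
  S <- sweep(S, 2L, p$bOut, "+")
  Xhat <- sigmoid(S)
  out <- list(Xhat = Xhat, rm1 = c1$rm, rv1 = c1$rv,
              rm2 = if (!is.null(c2)) c2$rm, rv2 = if (!is.null(c2)) c2$rv)
  if (keepCache)
    out <- c(out, list(Xm = Xm, c1 = c1, H1 = H1, c2 = c2, H2 = H2))
  out
}

#' Forward pass of the DED network
#'
#' Flattens the input volume, optionally applies the training-time input
#' mask, runs the tied-weight MLP and returns the voxel-wise probability
#' volume.  Inference (`training = FALSE`) is deterministic.
#'
#' @param model a [DEDModel-class].
#' @param input an [OccupancyVolume-class] on the model's grid.
#' @param training apply the Bernoulli input mask (consumes RNG draws).
#' @param batchStats use batch statistics in the normalization layers
#'   (defaults to `training`); with a single input, batch statistics are
#'   degenerate, so inference always uses the running statistics.
#' @return A [ProbabilityVolume-class].
#' @export
dedForward <- function(model, input, training = FALSE,
                       batchStats = training) {
  if (!identical(input@grid@dims, model@config@grid@dims))
    stop("input grid does not match the model grid")
  X <- matrix(as.numeric(input@values), 1L)
  res <- dedForwardCore(model, X, maskInput = training,
                        batchStats = batchStats)
  ProbabilityVolume(array(res$Xhat[1L, ], model@config@grid@dims),
                    model@config@grid)
}

#' Reconstruct a chamber from a voxelized catheter path
#'
#' Convenience wrapper: deterministic inference of the trained model on a
#' path occupancy volume.
#'
#' @param model a trained [DEDModel-class].
#' @param pathVolume an [OccupancyVolume-class] of the catheter path.
#' @return A [ProbabilityVolume-class].
#' @export
reconstruct <- function(model, pathVolume) dedForward(model, pathVolume)

asValues <- function(x) if (is(x, "VoxelVolume")) as.numeric(x@values) else as.numeric(x)
maskValues <- function(mask) {
  if (is.null(mask)) return(1)
  if (is(mask, "BoundaryMask")) as.numeric(mask@weights) else as.numeric(mask)
}

#' Soft (weighted) DICE coefficient
#'
#' `2 * sum(w x z) / (sum(w x) + sum(w z))` with an epsilon (1e-7) in
#' numerator and denominator; a uniform mask reduces to the standard soft
#' DICE.  With `squared = TRUE` the denominator uses `x^2` and `z^2`.
#'
#' @param x prediction ([ProbabilityVolume-class], volume, or array).
#' @param z target ([OccupancyVolume-class] or array).
#' @param mask optional [BoundaryMask-class] (or array of weights).
#' @param squared use squared denominator terms.
#' @return scalar in \[0, 1\].
#' @export
diceScore <- function(x, z, mask = NULL, squared = FALSE) {
  xv <- asValues(x); zv <- asValues(z); w <- maskValues(mask)
  num <- 2 * sum(w * xv * zv) + EPS_DICE
  den <- if (squared) sum(w * xv^2) + sum(w * zv^2) + EPS_DICE
         else sum(w * xv) + sum(w * zv) + EPS_DICE
  num / den
}

#' Mean binary cross-entropy
#'
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @inheritParams diceScore
#' @return nonnegative scalar.
#' @export
bceLoss <- function(x, z) {
  xv <- pmin(pmax(asValues(x), EPS_CLAMP), 1 - EPS_CLAMP)
  zv <- asValues(z)
  -mean(zv * log(xv) + (1 - zv) * log(1 - xv))
}

#' Combined reconstruction loss
#'
#' `alpha * BCE(x, z) - (1 - alpha) * DICE(x, z)` (weighted DICE when a
#' boundary mask is given); lower is better, approaching `-(1 - alpha)` for
#' a perfect prediction.
#'
#' @inheritParams diceScore
#' @param alpha mix in \[0, 1\].
#' @return scalar loss.
#' @export
dedLoss <- function(x, z, mask = NULL, alpha = 2 / 5, squared = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * bceLoss(x, z) - (1 - alpha) * diceScore(x, z, mask, squared)
}

#' Boundary enhancement mask
#'
#' Computes per-voxel loss weights from the unsigned Euclidean distance
#' `D(v)` of each voxel to the boundary voxel set (occupied voxels with an
#' empty 6-neighbour), in voxel units by default.  Two forms are available:
#'
#' * `mode = "peaked"` (default): `1 + beta * PN(D) / PN(0)` -- maximal
#'   (`1 + beta`) on the boundary, decaying to 1 far from it, matching the
#'   stated intent that most weight falls over the boundary.
#' * `mode = "literal"`: `(1 + beta) / (1 + PN(D))` -- the literal algebraic form,
#'   which *increases* with distance from the boundary (from about 11.85 at
#'   `D = 0` to 15 far away for `beta = 14`, `sigma = 1.5`).
#'
#' `PN` is the normal density with mean 0 and standard deviation `sigma`.
#'
#' @param z an [OccupancyVolume-class] with nonempty boundary.
#' @param beta weight amplitude (default 14).
#' @param sigma decay scale of the density (default 1.5, voxel units).
#' @param mode `"peaked"` or `"literal"`.
#' @param units `"voxel"` (default) or `"mm"` for the distance field.
#' @return A [BoundaryMask-class].
#' @export
boundaryMask <- function(z, beta = 14, sigma = 1.5,
                         mode = c("peaked", "literal"), units = c("voxel", "mm")) {
  mode <- match.arg(mode); units <- match.arg(units)
  bnd <- boundaryVoxels(z)
  if (!any(bnd)) stop("volume has an empty boundary; cannot build mask")
  sp <- if (units == "mm") rep(z@grid@spacing, 3L) else c(1, 1, 1)
  D <- .edt3(bnd, as.integer(dim(bnd)), sp)
  PN <- dnorm(D, 0, sigma)
  w <- if (mode == "peaked") 1 + beta * PN / dnorm(0, 0, sigma)
       else (1 + beta) / (1 + PN)
  new("BoundaryMask", grid = z@grid, weights = array(w, dim(D)),
      distance = array(D, dim(D)), mode = mode)
}

#' Spatial weight-smoothing penalty
#'
#' Each hidden unit's input-weight vector is reshaped onto the voxel grid;
#' the penalty is the sum over units and voxels of the squared forward
#' finite-difference spatial gradient, doubled to account for the tied
#' output layer sharing the same weights.
#'
#' @param model a [DEDModel-class], or a weight matrix (N x k) if `dims` is
#'   given.
#' @param dims grid dims when `model` is a plain matrix.
#' @return nonnegative scalar penalty (excluding the lambda factor).
#' @export
swrPenalty <- function(model, dims = NULL) {
  W <- if (is(model, "DEDModel")) model@params$W else model
  if (is.null(dims)) dims <- gridDims(model@config@grid)
  .swrGradC(W, as.integer(dims), FALSE)$penalty
}

#' Mean spatial roughness of the input weights
#'
#' Mean over units and voxels of the squared spatial gradient of the
#' voxel-indexed weights (the quantity the SWR term shrinks).
#'
#' @param model a [DEDModel-class].
#' @return nonnegative scalar.
#' @export
weightRoughness <- function(model) {
  W <- model@params$W
  swrPenalty(model) / 2 / length(W)
}

#' Threshold a probability volume
#'
#' Voxels with value `>= threshold` become 1.  Idempotent and monotone in
#' the threshold.
#'
#' @param x a [ProbabilityVolume-class] or [OccupancyVolume-class].
#' @param threshold in (0, 1).
#' @return An [OccupancyVolume-class].
#' @export
binarize <- function(x, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  OccupancyVolume(array(as.numeric(x@values >= threshold), dim(x@values)),
                  x@grid)
}

volumesToMatrix <- function(volumes, grid) {
  X <- matrix(0, length(volumes), prod(grid@dims))
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!identical(v@grid@dims, grid@dims)) stop("volume grid mismatch")
    X[i, ] <- as.numeric(v@values)
  }
  X
}

adamStep <- function(state, name, grad, lr, t, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  m <- state$m[[name]]; v <- state$v[[name]]
  if (is.null(m)) { m <- grad * 0; v <- grad * 0 }
  m <- b1 * m + (1 - b1) * grad
  v <- b2 * v + (1 - b2) * grad^2
  state$m[[name]] <- m; state$v[[name]] <- v
  mhat <- m / (1 - b1^t); vhat <- v / (1 - b2^t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

# one minibatch: forward (with input masking), loss, and all parameter
# gradients.  Returns the updated running BN statistics alongside.
dedBatchGrad <- function(model, xb, zb, wb, maskInput = TRUE) {
  cfg <- model@config
  N <- ncol(xb); nb_ <- nrow(xb)
  fw <- dedForwardCore(model, xb, maskInput = maskInput, batchStats = TRUE,
                       keepCache = TRUE)
  xhat <- fw$Xhat
  xc <- pmin(pmax(xhat, EPS_CLAMP), 1 - EPS_CLAMP)
  bce <- -rowMeans(zb * log(xc) + (1 - zb) * log(1 - xc))
  num <- 2 * rowSums(wb * xhat * zb) + EPS_DICE
  if (cfg@diceSquared) {
    den <- rowSums(wb * xhat^2) + rowSums(wb * zb^2) + EPS_DICE
    dnum <- 2 * wb * zb
    dden <- 2 * wb * xhat
  } else {
    den <- rowSums(wb * xhat) + rowSums(wb * zb) + EPS_DICE
    dnum <- 2 * wb * zb
    dden <- wb
  }
  dice <- num / den
  loss <- mean(cfg@alpha * bce - (1 - cfg@alpha) * dice)
  swrRes <- if (cfg@lambdaSwr > 0)
    .swrGradC(model@params$W, as.integer(cfg@grid@dims), TRUE)
  swr <- if (is.null(swrRes)) 0 else swrRes$penalty
  # gradient wrt the pre-sigmoid activations
  dBCE_dS <- (xhat - zb) / N
  dDICE_dx <- (dnum * den - num * dden) / den^2
  dS <- (cfg@alpha * dBCE_dS -
         (1 - cfg@alpha) * dDICE_dx * xhat * (1 - xhat)) / nb_
  dbOut <- colSums(dS)
  dW <- crossprod(dS, fw$H2)          # output-layer use of W
  dH2 <- dS %*% model@params$W
  if (!is.null(model@params$W2)) {
    dY2 <- dH2 * (fw$c2$Y > 0)
    b2b <- bnBackward(dY2, fw$c2)
    dW2 <- crossprod(fw$H1, b2b$dA)
    dH1 <- b2b$dA %*% t(model@params$W2)
    dg2 <- b2b$dg; dbe2 <- b2b$dbe
  } else {
    dH1 <- dH2; dW2 <- NULL; dg2 <- NULL; dbe2 <- NULL
  }
  dY1 <- dH1 * (fw$c1$Y > 0)
  b1b <- bnBackward(dY1, fw$c1)
  dW <- dW + crossprod(fw$Xm, b1b$dA) # input-layer use of W
  # the SWR term enters the objective as the per-weight mean of the
  # penalty, so lambda is comparable across grid sizes and hidden widths
  if (cfg@lambdaSwr > 0)
    dW <- dW + (cfg@lambdaSwr / length(model@params$W)) * swrRes$grad
  list(loss = loss, bce = mean(bce), dice = mean(dice), swr = swr,
       grads = list(W = dW, W2 = dW2, bOut = dbOut, g1 = b1b$dg,
                    be1 = b1b$dbe, g2 = dg2, be2 = dbe2),
       bn = list(rm1 = fw$rm1, rv1 = fw$rv1, rm2 = fw$rm2, rv2 = fw$rv2))
}

#' Train the DED network
#'
#' Minimizes `alpha BCE - (1 - alpha) DICE + lambda * SWR` with Adam over
#' minibatches of (path volume, target volume) pairs.  Boundary-enhancement
#' masks are precomputed per target (unless disabled in the config).
#' Training is deterministic for a fixed config seed; the tied-weight
#' invariant holds after every step by construction (a single stored matrix
#' serves both layers).  A non-finite loss aborts with a diagnostic naming
#' the offending epoch/batch.
#'
#' @param inputs list of path [OccupancyVolume-class]s (network inputs).
#' @param targets list of ground-truth [OccupancyVolume-class]s.
#' @param cfg a [DEDConfig-class].
#' @param valInputs,valTargets optional validation pairs, evaluated (without
#'   masking) once per epoch.
#' @param verbose print per-epoch progress every `verbose` epochs (0 = quiet).
#' @return A trained [DEDModel-class] with a per-epoch `history` data.frame
#'   (columns epoch, loss, bce, dice, swr, and valDice when validation data
#'   are given).
#' @export
trainDED <- function(inputs, targets, cfg, valInputs = NULL,
                     valTargets = NULL, verbose = 0L) {
  stopifnot(length(inputs) == length(targets), length(inputs) >= 1L)
  X <- volumesToMatrix(inputs, cfg@grid)
  Z <- volumesToMatrix(targets, cfg@grid)
  N <- ncol(X); B <- nrow(X)
  Om <- if (cfg@useBoundaryMask) {
    t(vapply(targets, function(z)
      as.numeric(boundaryMask(z, cfg@betaMask, cfg@sigmaMask,
                              cfg@maskMode)@weights), numeric(N)))
  } else matrix(1, B, N)
  XV <- if (!is.null(valInputs)) volumesToMatrix(valInputs, cfg@grid)
  ZV <- if (!is.null(valTargets)) volumesToMatrix(valTargets, cfg@grid)
  model <- initDED(cfg)
  # private copies of the parameter arrays: the Adam kernel updates them in
  # place, which is safe only while this function holds the sole reference
  model@params <- lapply(model@params, function(x) if (is.null(x)) NULL else x + 0)
  madam <- lapply(model@params, function(x) if (is.null(x)) NULL else x * 0)
  vadam <- lapply(model@params, function(x) if (is.null(x)) NULL else x * 0)
  hist <- vector("list", cfg@epochs)
  tAdam <- 0L
  withLocalSeed(cfg@seed + 1L, {
    for (epoch in seq_len(cfg@epochs)) {
      ord <- sample.int(B)
      nb <- ceiling(B / cfg@batchSize)
      eLoss <- eBce <- eDice <- 0
      for (bi in seq_len(nb)) {
        rows <- ord[((bi - 1L) * cfg@batchSize + 1L):min(bi * cfg@batchSize, B)]
        nb_ <- length(rows)
        bg <- dedBatchGrad(model, X[rows, , drop = FALSE],
                           Z[rows, , drop = FALSE],
                           Om[rows, , drop = FALSE])
        if (!is.finite(bg$loss))
          stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi))
        model@bn <- bg$bn
        tAdam <- tAdam + 1L
        for (nm in names(bg$grads)) {
          if (is.null(model@params[[nm]])) next
          .adamStepC(model@params[[nm]], madam[[nm]], vadam[[nm]],
                     bg$grads[[nm]], cfg@lr, 0.9, 0.999, 0.9^tAdam,
                     0.999^tAdam, 1e-8)
        }
        eLoss <- eLoss + bg$loss * nb_ / B
        eBce <- eBce + bg$bce * nb_ / B
        eDice <- eDice + bg$dice * nb_ / B
      }
      swr <- if (cfg@lambdaSwr > 0) swrPenalty(model@params$W, cfg@grid@dims)
             else NA_real_
      row <- data.frame(epoch = epoch, loss = eLoss, bce = eBce,
                        dice = eDice, swr = swr)
      if (!is.null(XV)) {
        pv <- dedForwardCore(model, XV, maskInput = FALSE, batchStats = FALSE)
        row$valDice <- mean(vapply(seq_len(nrow(XV)), function(i)
          diceScore(pv$Xhat[i, ], ZV[i, ]), numeric(1)))
      }
      hist[[epoch]] <- row
      if (verbose > 0 && epoch %% verbose == 0)
        message(sprintf("epoch %d: loss %.4f dice %.4f", epoch, eLoss, eDice))
    }
  })
  model@history <- do.call(rbind, hist)
  model
}
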
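# Volumetric convolutional baseline (V-Net style): an encoder of
# convolution + batch-norm + ReLU stages each followed by max-pooling that
# halves the volume, a bottleneck with dropout, and a mirrored decoder of
# learned up-sampling stages (nearest-neighbour upsampling followed by a
# learned convolution) with same-size skip concatenations.  The first and
# last convolutions use an enlarged receptive field.  Inputs whose dims are
# not divisible by 2^stages are zero-padded symmetrically and the output is
# cropped back.  Feature arrays have dim (D, H, W, C).

#' V-Net configuration
#'
#' @slot grid input [GridSpec-class].
#' @slot stages number of resolution halvings (default 4).
#' @slot baseFilters channel count of the first stage (doubling per stage,
#'   capped at 128).
#' @slot kernelFirst,kernelLast enlarged first/last kernel sizes (odd).
#' @slot kernel interior kernel size (odd).
#' @slot dropout dropout rate at the bottleneck.
#' @slot alpha loss mix as in [DEDConfig-class] (uniform DICE weighting,
#'   no SWR: the smoothing penalty is specific to voxel-indexed dense
#'   weights and does not apply to convolutional filters).
#' @slot lr,batchSize,epochs,seed optimizer settings.
#' @export
setClass("VNetConfig", representation(grid = "GridSpec", stages = "integer",
  baseFilters = "integer", kernelFirst = "integer", kernelLast = "integer",
  kernel = "integer", dropout = "numeric", alpha = "numeric", lr = "numeric",
  batchSize = "integer", epochs = "integer", seed = "integer"),
  validity = function(object) {
    if (object@stages < 1L) return("stages must be >= 1")
    if (object@baseFilters < 1L) return("baseFilters must be >= 1")
    ks <- c(object@kernelFirst, object@kernelLast, object@kernel)
    if (any(ks %% 2L == 0L)) return("kernel sizes must be odd")
    if (object@dropout < 0 || object@dropout >= 1)
      return("dropout must be in [0, 1)")
    TRUE
  })

#' @rdname VNetConfig-class
#' @param grid,stages,baseFilters,kernelFirst,kernelLast,kernel,dropout
#'   see slot documentation.
#' @param alpha,lr,batchSize,epochs,seed see slot documentation.
#' @export
VNetConfig <- function(grid = GridSpec(), stages = 4L, baseFilters = 16L,
                       kernelFirst = 5L, kernelLast = 5L, kernel = 3L,
                       dropout = 0.1, alpha = 2 / 5, lr = 1e-3,
                       batchSize = 10L, epochs = 200L, seed = 1L) {
  new("VNetConfig", grid = grid, stages = as.integer(stages),
      baseFilters = as.integer(baseFilters),
      kernelFirst = as.integer(kernelFirst),
      kernelLast = as.integer(kernelLast), kernel = as.integer(kernel),
      dropout = dropout, alpha = alpha, lr = lr,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed))
}

#' V-Net model
#'
#' @slot config a [VNetConfig-class].
#' @slot params named list of convolution weights/biases and batch-norm
#'   parameters per layer.
#' @slot bn running batch-norm statistics per layer.
#' @slot history per-epoch training metrics.
#' @export
setClass("VNetModel", representation(config = "VNetConfig", params = "list",
                                     bn = "list", history = "data.frame"))

setMethod("show", "VNetModel", function(object) {
  cfg <- object@config
  nw <- sum(vapply(object@params, function(l) length(l$Wm) + length(l$b),
                   numeric(1)))
  cat(sprintf("VNetModel: %d stage(s), base %d filters, %d parameters, %d epoch(s) trained\n",
              cfg@stages, cfg@baseFilters, nw, nrow(object@history)))
})

# layer plan: encoder convs, bottleneck, decoder convs (deepest first)
vnetLayerPlan <- function(cfg) {
  S <- cfg@stages
  encCh <- pmin(cfg@baseFilters * 2^(seq_len(S) - 1L), 128L)
  layers <- list()
  inCh <- 1L
  for (s in seq_len(S)) {
    k <- if (s == 1L) cfg@kernelFirst else cfg@kernel
    layers[[paste0("enc", s)]] <- list(k = k, cin = inCh, cout = encCh[s],
                                       bn = TRUE)
    inCh <- encCh[s]
  }
  layers[["bottleneck"]] <- list(k = cfg@kernel, cin = encCh[S],
                                 cout = encCh[S], bn = TRUE)
  up <- encCh[S]
  for (s in rev(seq_len(S))) {
    cin <- up + encCh[s] # upsampled features + skip concatenation
    if (s > 1L) {
      cout <- encCh[s - 1L]
      layers[[paste0("dec", s)]] <- list(k = cfg@kernel, cin = cin,
                                         cout = cout, bn = TRUE)
      up <- cout
    } else {
      layers[["dec1"]] <- list(k = cfg@kernelLast, cin = cin, cout = 1L,
                               bn = FALSE)
    }
  }
  layers
}

padTo <- function(dims, mult) as.integer(ceiling(dims / mult) * mult)

vnetPad <- function(x, padDims) {
  d <- dim(x)
  if (all(d[1:3] == padDims)) return(x)
  off <- (padDims - d[1:3]) %/% 2L
  y <- array(0, c(padDims, d[4]))
  y[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3]), ] <- x
  y
}

vnetCrop <- function(y, dims) {
  d <- dim(y)
  if (all(d[1:3] == dims)) return(y)
  off <- (d[1:3] - dims) %/% 2L
  y[off[1] + seq_len(dims[1]), off[2] + seq_len(dims[2]),
    off[3] + seq_len(dims[3]), , drop = FALSE]
}

#' Build (initialize) a V-Net model
#'
#' Seeded He-style initialization of all convolution kernels.  Errors if the
#' padded input dims are not divisible by `2^stages`.
#'
#' @param cfg a [VNetConfig-class].
#' @return An untrained [VNetModel-class].
#' @export
buildVNet <- function(cfg) {
  validObject(cfg)
  padDims <- padTo(cfg@grid@dims, 2L^cfg@stages)
  if (any(padDims %/% 2L^cfg@stages < 1L))
    stop("grid too small for the requested number of stages")
  plan <- vnetLayerPlan(cfg)
  withLocalSeed(cfg@seed, {
    params <- lapply(plan, function(l) {
      fanIn <- l$k^3 * l$cin
      lst <- list(Wm = matrix(rnorm(fanIn * l$cout, sd = sqrt(2 / fanIn)),
                              fanIn, l$cout),
                  b = numeric(l$cout), k = l$k, bn = l$bn)
      if (l$bn) { lst$g <- rep(1, l$cout); lst$be <- numeric(l$cout) }
      lst
    })
    bn <- lapply(plan, function(l)
      if (l$bn) list(rm = numeric(l$cout), rv = rep(1, l$cout)))
    new("VNetModel", config = cfg, params = params, bn = bn,
        history = data.frame())
  })
}

# conv + (BN) + activation over a batch (list of (D,H,W,C) arrays).
# activation: "relu", "sigmoid" or "linear".  Returns outputs + caches.
vnetConvLayer <- function(layer, bnStats, xs, activation, batchStats,
                          keepCache) {
  B <- length(xs)
  cols <- vector("list", B); A <- vector("list", B)
  for (i in seq_len(B)) {
    d <- dim(xs[[i]])
    cols[[i]] <- .im2col3(xs[[i]], as.integer(d), layer$k)
    A[[i]] <- sweep(crossprod(cols[[i]], layer$Wm), 2L, layer$b, "+")
  }
  spat <- dim(xs[[1]])[1:3]
  cache <- list(cols = if (keepCache) cols, inDims = dim(xs[[1]]),
                spat = spat)
  if (layer$bn) {
    Aall <- do.call(rbind, A)
    if (batchStats) {
      mu <- colMeans(Aall); va <- colMeans(Aall^2) - mu^2
      bnStats$rm <- 0.9 * bnStats$rm + 0.1 * mu
      bnStats$rv <- 0.9 * bnStats$rv + 0.1 * va
    } else { mu <- bnStats$rm; va <- bnStats$rv }
    istd <- 1 / sqrt(va + 1e-5)
    Ahat <- sweep(sweep(Aall, 2L, mu, "-"), 2L, istd, "*")
    Yall <- sweep(sweep(Ahat, 2L, layer$g, "*"), 2L, layer$be, "+")
    cache$Ahat <- if (keepCache) Ahat
    cache$istd <- istd
  } else Yall <- do.call(rbind, A)
  H <- switch(activation, relu = pmax(Yall, 0), sigmoid = sigmoid(Yall),
              linear = Yall)
  cache$Y <- if (keepCache) Yall
  cache$H <- if (keepCache) H
  nvox <- prod(spat)
  out <- lapply(seq_len(B), function(i)
    array(H[(i - 1L) * nvox + seq_len(nvox), ], c(spat, ncol(layer$Wm))))
  list(out = out, cache = cache, bn = bnStats)
}

# backward through a conv layer; dys: list of gradient arrays
vnetConvBackward <- function(layer, cache, dys, activation) {
  B <- length(dys)
  nvox <- prod(cache$spat)
  dH <- do.call(rbind, lapply(dys, function(dy)
    matrix(dy, nvox, dim(dy)[4])))
  dY <- switch(activation,
               relu = dH * (cache$Y > 0),
               sigmoid = dH * cache$H * (1 - cache$H),
               linear = dH)
  if (layer$bn) {
    n <- nrow(dY)
    dg <- colSums(dY * cache$Ahat)
    dbe <- colSums(dY)
    dAhat <- sweep(dY, 2L, layer$g, "*")
    s1 <- colSums(dAhat); s2 <- colSums(dAhat * cache$Ahat)
    dA <- sweep(dAhat, 2L, s1 / n, "-") -
      sweep(cache$Ahat, 2L, s2 / n, "*")
    dA <- sweep(dA, 2L, cache$istd, "*")
  } else { dA <- dY; dg <- NULL; dbe <- NULL }
  db <- colSums(dA)
  dWm <- matrix(0, nrow(layer$Wm), ncol(layer$Wm))
  dxs <- vector("list", B)
  for (i in seq_len(B)) {
    dAi <- dA[(i - 1L) * nvox + seq_len(nvox), , drop = FALSE]
    dWm <- dWm + cache$cols[[i]] %*% dAi
    dxs[[i]] <- .col2im3(tcrossprod(layer$Wm, dAi),
                         as.integer(cache$inDims), layer$k)
  }
  list(dxs = dxs, dWm = dWm, db = db, dg = dg, dbe = dbe)
}

concatCh <- function(a, b) {
  d <- dim(a)
  array(c(a, b), c(d[1:3], d[4] + dim(b)[4]))
}

# full forward pass; xs: list of (D,H,W,1) arrays already padded
vnetForwardCore <- function(model, xs, training, keepCache = FALSE) {
  cfg <- model@config
  S <- cfg@stages
  caches <- list(); skips <- list()
  h <- xs
  for (s in seq_len(S)) {
    nm <- paste0("enc", s)
    r <- vnetConvLayer(model@params[[nm]], model@bn[[nm]], h, "relu",
                       training, keepCache)
    model@bn[[nm]] <- r$bn
    caches[[nm]] <- r$cache
    skips[[s]] <- r$out
    pooled <- lapply(r$out, function(x)
      .maxpool3(x, as.integer(dim(x)), 2L))
    caches[[paste0("pool", s)]] <- lapply(pooled, `[[`, "argmax")
    caches[[paste0("pooldim", s)]] <- dim(r$out[[1]])
    h <- lapply(pooled, `[[`, "y")
  }
  r <- vnetConvLayer(model@params$bottleneck, model@bn$bottleneck, h, "relu",
                     training, keepCache)
  model@bn$bottleneck <- r$bn
  caches$bottleneck <- r$cache
  h <- r$out
  if (training && cfg@dropout > 0) {
    masks <- lapply(h, function(x)
      array(rbinom(length(x), 1L, 1 - cfg@dropout) / (1 - cfg@dropout),
            dim(x)))
    h <- mapply(function(x, m) x * m, h, masks, SIMPLIFY = FALSE)
    caches$dropMasks <- masks
  }
  for (s in rev(seq_len(S))) {
    up <- lapply(h, function(x) .upsample3(x, as.integer(dim(x)), 2L))
    caches[[paste0("updim", s)]] <- dim(h[[1]])
    cat_ <- mapply(concatCh, up, skips[[s]], SIMPLIFY = FALSE)
    caches[[paste0("upch", s)]] <- dim(up[[1]])[4]
    nm <- paste0("dec", s)
    act <- if (s > 1L) "relu" else "sigmoid"
    r <- vnetConvLayer(model@params[[nm]], model@bn[[nm]], cat_, act,
                       training, keepCache)
    if (model@params[[nm]]$bn) model@bn[[nm]] <- r$bn
    caches[[nm]] <- r$cache
    h <- r$out
  }
  list(out = h, caches = caches, model = model)
}

#' V-Net forward pass (inference)
#'
#' Deterministic prediction of the occupancy probability volume for one
#' path volume.
#'
#' @param model a [VNetModel-class].
#' @param input an [OccupancyVolume-class] on the model grid.
#' @return A [ProbabilityVolume-class].
#' @export
vnetForward <- function(model, input) {
  cfg <- model@config
  if (!identical(input@grid@dims, cfg@grid@dims))
    stop("input grid does not match the model grid")
  padDims <- padTo(cfg@grid@dims, 2L^cfg@stages)
  x <- vnetPad(array(input@values, c(dim(input@values), 1L)), padDims)
  res <- vnetForwardCore(model, list(x), training = FALSE)
  y <- vnetCrop(res$out[[1]], cfg@grid@dims)
  ProbabilityVolume(array(y, cfg@grid@dims), cfg@grid)
}

#' Train the V-Net baseline
#'
#' Same data contract and loss as [trainDED()] with a uniform DICE mask and
#' no smoothing penalty.  Deterministic per config seed.
#'
#' @inheritParams trainDED
#' @param cfg a [VNetConfig-class].
#' @return A trained [VNetModel-class].
#' @export
trainVNet <- function(inputs, targets, cfg, verbose = 0L) {
  stopifnot(length(inputs) == length(targets), length(inputs) >= 1L)
  model <- buildVNet(cfg)
  padDims <- padTo(cfg@grid@dims, 2L^cfg@stages)
  xs <- lapply(inputs, function(v)
    vnetPad(array(v@values, c(dim(v@values), 1L)), padDims))
  zsArr <- lapply(targets, function(v)
    vnetPad(array(v@values, c(dim(v@values), 1L)), padDims))
  B <- length(xs)
  N <- prod(padDims)
  layerNames <- names(model@params)
  state <- list(m = list(), v = list())
  tAdam <- 0L
  hist <- vector("list", cfg@epochs)
  withLocalSeed(cfg@seed + 1L, {
    for (epoch in seq_len(cfg@epochs)) {
      ord <- sample.int(B)
      nbatch <- ceiling(B / cfg@batchSize)
      eLoss <- eDice <- 0
      for (bi in seq_len(nbatch)) {
        rows <- ord[((bi - 1L) * cfg@batchSize + 1L):min(bi * cfg@batchSize, B)]
        fw <- vnetForwardCore(model, xs[rows], training = TRUE,
                              keepCache = TRUE)
        model <- fw$model
        nb_ <- length(rows)
        dys <- vector("list", nb_)
        bls <- dls <- numeric(nb_)
        for (i in seq_len(nb_)) {
          xhat <- as.numeric(fw$out[[i]])
          zv <- as.numeric(zsArr[[rows[i]]])
          xc <- pmin(pmax(xhat, EPS_CLAMP), 1 - EPS_CLAMP)
          bls[i] <- -mean(zv * log(xc) + (1 - zv) * log(1 - xc))
          num <- 2 * sum(xhat * zv) + EPS_DICE
          den <- sum(xhat) + sum(zv) + EPS_DICE
          dls[i] <- num / den
          dBCE <- (xhat - zv) / (xc * (1 - xc)) / N
          dDICE <- (2 * zv * den - num) / den^2
          dxhat <- (cfg@alpha * dBCE - (1 - cfg@alpha) * dDICE) / nb_
          dys[[i]] <- array(dxhat, dim(fw$out[[i]]))
        }
        loss <- mean(cfg@alpha * bls - (1 - cfg@alpha) * dls)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi))
        grads <- vnetBackwardCore(model, fw$caches, dys)
        tAdam <- tAdam + 1L
        for (nm in layerNames) {
          for (pn in c("Wm", "b", "g", "be")) {
            if (is.null(model@params[[nm]][[pn]])) next
            g <- grads[[nm]][[pn]]
            key <- paste0(nm, ".", pn)
            state <- adamStep(state, key, g, cfg@lr, tAdam)
            model@params[[nm]][[pn]] <- model@params[[nm]][[pn]] + state$delta
          }
        }
        eLoss <- eLoss + loss * nb_ / B
        eDice <- eDice + mean(dls) * nb_ / B
      }
      hist[[epoch]] <- data.frame(epoch = epoch, loss = eLoss, dice = eDice)
      if (verbose > 0 && epoch %% verbose == 0)
        message(sprintf("vnet epoch %d: loss %.4f dice %.4f", epoch, eLoss,
                        eDice))
    }
  })
  model@history <- do.call(rbind, hist)
  model
}

# full backward pass mirroring vnetForwardCore
vnetBackwardCore <- function(model, caches, dys) {
  cfg <- model@config
  S <- cfg@stages
  grads <- list()
  d <- dys
  for (s in seq_len(S)) { # decoder, shallowest first
    nm <- paste0("dec", s)
    act <- if (s > 1L) "relu" else "sigmoid"
    bw <- vnetConvBackward(model@params[[nm]], caches[[nm]], d, act)
    grads[[nm]] <- bw[c("dWm", "db", "dg", "dbe")]
    names(grads[[nm]]) <- c("Wm", "b", "g", "be")
    upch <- caches[[paste0("upch", s)]]
    dskip <- lapply(bw$dxs, function(dx)
      dx[, , , upch + seq_len(dim(dx)[4] - upch), drop = FALSE])
    dup <- lapply(bw$dxs, function(dx)
      dx[, , , seq_len(upch), drop = FALSE])
    d <- lapply(dup, function(dx)
      .upsample3Backward(dx, as.integer(dim(dx)), 2L))
    # gradients flowing into the skip connections are added when the
    # matching encoder stage is reached
    caches[[paste0("dskip", s)]] <- dskip
  }
  if (!is.null(caches$dropMasks))
    d <- mapply(function(dx, m) dx * m, d, caches$dropMasks, SIMPLIFY = FALSE)
  bw <- vnetConvBackward(model@params$bottleneck, caches$bottleneck, d, "relu")
  grads$bottleneck <- bw[c("dWm", "db", "dg", "dbe")]
  names(grads$bottleneck) <- c("Wm", "b", "g", "be")
  d <- bw$dxs
  for (s in rev(seq_len(S))) { # encoder, deepest first
    nm <- paste0("enc", s)
    dpool <- lapply(seq_along(d), function(i)
      .maxpool3Backward(d[[i]], caches[[paste0("pool", s)]][[i]],
                        as.integer(caches[[paste0("pooldim", s)]])))
    dsum <- mapply(function(a, b) a + b, dpool, caches[[paste0("dskip", s)]],
                   SIMPLIFY = FALSE)
    bw <- vnetConvBackward(model@params[[nm]], caches[[nm]], dsum, "relu")
    grads[[nm]] <- bw[c("dWm", "db", "dg", "dbe")]
    names(grads[[nm]]) <- c("Wm", "b", "g", "be")
    d <- bw$dxs
  }
  grads
}
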
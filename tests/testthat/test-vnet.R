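# V-Net baseline: construction, shape preservation, determinism,
# toy convergence.

test_that("build is seeded; zeroed final layer outputs 0.5; shapes preserved", {
  cfg <- VNetConfig(grid = GridSpec(12, 5), stages = 2L, baseFilters = 4L,
                    seed = 8L)
  m1 <- buildVNet(cfg); m2 <- buildVNet(cfg)
  expect_identical(m1@params, m2@params)
  m0 <- m1
  m0@params$dec1$Wm[] <- 0
  m0@params$dec1$b[] <- 0
  v <- randomVolume(c(12L, 12L, 12L), p = 0.2, seed = 3, spacing = 5)
  out <- vnetForward(m0, v)
  expect_true(all(abs(voxelValues(out) - 0.5) < 1e-12))
  expect_identical(gridDims(out), gridDims(v))
  # prediction is deterministic at inference
  expect_identical(voxelValues(vnetForward(m1, v)),
                   voxelValues(vnetForward(m1, v)))
  # invalid configurations are rejected
  expect_error(VNetConfig(stages = 0L), "stages")
  expect_error(VNetConfig(kernel = 4L), "odd")
})

test_that("non-divisible grids are padded and cropped back", {
  cfg <- VNetConfig(grid = GridSpec(11, 5), stages = 2L, baseFilters = 2L,
                    seed = 1L)
  m <- buildVNet(cfg)
  v <- randomVolume(c(11L, 11L, 11L), p = 0.3, seed = 5, spacing = 5)
  out <- vnetForward(m, v)
  expect_identical(gridDims(out), c(11L, 11L, 11L))
  expect_true(all(voxelValues(out) >= 0 & voxelValues(out) <= 1))
})

test_that("V-Net gradients match finite differences on a tiny net", {
  cfg <- VNetConfig(grid = GridSpec(4, 5), stages = 1L, baseFilters = 2L,
                    kernelFirst = 3L, kernelLast = 3L, dropout = 0,
                    seed = 2L)
  m <- buildVNet(cfg)
  set.seed(9)
  xs <- lapply(1:2, function(i) array(rbinom(64, 1, 0.3), c(4, 4, 4, 1)))
  zs <- lapply(1:2, function(i) array(rbinom(64, 1, 0.5), c(4, 4, 4, 1)))
  lossOf <- function(model) {
    fw <- atriarecon:::vnetForwardCore(model, xs, training = TRUE)
    mean(vapply(1:2, function(i) {
      xhat <- pmin(pmax(as.numeric(fw$out[[i]]), 1e-7), 1 - 1e-7)
      zv <- as.numeric(zs[[i]])
      bce <- -mean(zv * log(xhat) + (1 - zv) * log(1 - xhat))
      dice <- (2 * sum(xhat * zv) + 1e-7) / (sum(xhat) + sum(zv) + 1e-7)
      cfg@alpha * bce - (1 - cfg@alpha) * dice
    }, numeric(1)))
  }
  fw <- atriarecon:::vnetForwardCore(m, xs, training = TRUE, keepCache = TRUE)
  N <- 64
  dys <- lapply(1:2, function(i) {
    xhat <- as.numeric(fw$out[[i]]); zv <- as.numeric(zs[[i]])
    xc <- pmin(pmax(xhat, 1e-7), 1 - 1e-7)
    num <- 2 * sum(xhat * zv) + 1e-7
    den <- sum(xhat) + sum(zv) + 1e-7
    dBCE <- (xhat - zv) / (xc * (1 - xc)) / N
    dDICE <- (2 * zv * den - num) / den^2
    array((cfg@alpha * dBCE - (1 - cfg@alpha) * dDICE) / 2, c(4, 4, 4, 1))
  })
  grads <- atriarecon:::vnetBackwardCore(m, fw$caches, dys)
  for (nm in c("enc1", "bottleneck", "dec1")) {
    g <- grads[[nm]]$Wm
    idx <- sample(length(g), 4)
    num <- vapply(idx, function(i) {
      m2 <- m; m2@params[[nm]]$Wm[i] <- m2@params[[nm]]$Wm[i] + 1e-6
      m3 <- m; m3@params[[nm]]$Wm[i] <- m3@params[[nm]]$Wm[i] - 1e-6
      (lossOf(m2) - lossOf(m3)) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(num - g[idx]) / pmax(abs(num), 1e-6)), 2e-3,
              label = paste("vnet gradient of", nm))
  }
})

test_that("V-Net converges on the ellipsoid completion toy problem", {
  pairs <- toyEllipsoidPairs(30, seed = 101)
  ins <- lapply(pairs, `[[`, "inp"); tgts <- lapply(pairs, `[[`, "tgt")
  cfg <- VNetConfig(grid = GridSpec(12, 5), stages = 2L, baseFilters = 4L,
                    epochs = 60L, batchSize = 10L, seed = 3L, lr = 3e-3)
  m <- trainVNet(ins, tgts, cfg)
  expect_lt(tail(m@history$loss, 1), m@history$loss[1])
  dice <- mean(vapply(seq_along(ins), function(i)
    diceScore(binarize(vnetForward(m, ins[[i]])), tgts[[i]]), numeric(1)))
  expect_gt(dice, 0.9)
  # objective without SWR equals the plain BCE/DICE mix: the model has no
  # spatially indexed dense weights, so no smoothing penalty exists
  expect_false("swr" %in% names(m@history))
})
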
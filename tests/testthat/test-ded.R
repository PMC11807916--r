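# DED building blocks: loss arithmetic, boundary mask, SWR penalty,
# forward pass, binarization.

test_that("dice and loss arithmetic behave as specified", {
  v <- fixtureDatasetVolume(1L)
  expect_equal(diceScore(v, v), 1, tolerance = 1e-9)
  # perfect binary prediction at alpha = 2/5 -> loss -> -3/5
  expect_equal(dedLoss(v, v, alpha = 2 / 5), -0.6, tolerance = 1e-5)
  # x == 0.5 everywhere, alpha = 1 (pure BCE) -> ln 2
  half <- ProbabilityVolume(array(0.5, gridDims(v)), voxelGrid(v))
  expect_equal(dedLoss(half, v, alpha = 1), log(2), tolerance = 1e-12)
  # disjoint supports -> dice ~ 0
  a <- array(0, c(4, 4, 4)); a[1, 1, 1] <- 1
  b <- array(0, c(4, 4, 4)); b[4, 4, 4] <- 1
  g <- GridSpec(4, 2)
  expect_lt(diceScore(OccupancyVolume(a, g), OccupancyVolume(b, g)), 1e-6)
  # weighted dice with any positive mask is 1 for a perfect prediction
  w <- array(runif(prod(gridDims(v))) + 0.5, gridDims(v))
  expect_equal(diceScore(v, v, mask = w), 1, tolerance = 1e-9)
  # uniform mask equals plain dice
  p <- ProbabilityVolume(array(runif(prod(gridDims(v))), gridDims(v)),
                         voxelGrid(v))
  expect_equal(diceScore(p, v, mask = array(1, gridDims(v))),
               diceScore(p, v), tolerance = 1e-12)
  # alpha = 0 degenerates to the negative dice
  expect_equal(dedLoss(p, v, alpha = 0), -diceScore(p, v), tolerance = 1e-12)
  # loss bounds for clamped probabilities
  expect_gte(dedLoss(p, v, alpha = 2 / 5), -(1 - 2 / 5))
})

test_that("boundary mask matches the closed forms in both modes", {
  v <- fixtureDatasetVolume(1L)
  lit <- boundaryMask(v, beta = 14, sigma = 1.5, mode = "literal")
  pn0 <- dnorm(0, 0, 1.5)
  expect_equal(min(lit@weights), 15 / (1 + pn0), tolerance = 1e-9)
  expect_equal(15 / (1 + pn0), 11.8487, tolerance = 1e-4)
  expect_lt(max(lit@weights), 15 + 1e-12)
  expect_gt(max(lit@weights), 15 - 1e-3) # far voxels approach 1 + beta
  # literal form increases with distance; peaked decreases
  pk <- boundaryMask(v, beta = 14, sigma = 1.5, mode = "peaked")
  expect_equal(max(pk@weights), 15, tolerance = 1e-9)
  expect_equal(min(pk@weights), 1, tolerance = 1e-3)
  onB <- pk@distance == 0
  expect_true(all(pk@weights[onB] == 15))
  expect_true(all(pk@weights[!onB] < 15))
  expect_error(boundaryMask(OccupancyVolume(array(0, c(4, 4, 4)),
                                            GridSpec(4, 2))),
               "empty")
})

test_that("distance-to-boundary field is an exact EDT", {
  # single seed voxel: distances are exact Euclidean voxel distances
  m <- array(FALSE, c(7L, 7L, 7L)); m[4, 4, 4] <- TRUE
  d <- atriarecon:::.edt3(m, c(7L, 7L, 7L), c(1, 1, 1))
  idx <- as.matrix(expand.grid(1:7, 1:7, 1:7))
  expect_equal(as.numeric(d), sqrt(colSums((t(idx) - c(4, 4, 4))^2)),
               tolerance = 1e-12)
  # mm spacing scales distances
  d2 <- atriarecon:::.edt3(m, c(7L, 7L, 7L), c(2.5, 2.5, 2.5))
  expect_equal(as.numeric(d2), 2.5 * as.numeric(d), tolerance = 1e-12)
})

test_that("SWR penalty: zero for constant maps, hand value for ramps, quadratic", {
  k <- 3L; dims <- c(3L, 3L, 3L)
  Wconst <- matrix(rep(c(1, 2, 5), each = 27), 27, k)
  expect_equal(swrPenalty(Wconst, dims), 0)
  ramp <- matrix(as.numeric(slice.index(array(0, dims), 1)), ncol = 1)
  expect_equal(swrPenalty(ramp, dims), 36)
  W <- matrix(rnorm(27 * k), 27, k)
  expect_equal(swrPenalty(2 * W, dims), 4 * swrPenalty(W, dims),
               tolerance = 1e-9)
})

test_that("initialization is seeded, tied, and has the right parameter count", {
  cfg <- DEDConfig(grid = GridSpec(12, 5), hidden = c(16L, 16L), seed = 4L)
  m1 <- initDED(cfg); m2 <- initDED(cfg)
  expect_identical(m1@params, m2@params)
  expect_equal(tiedWeightError(m1), 0)
  pc <- dedParameterCount(DEDConfig(grid = GridSpec(45, 2.666)))
  expect_equal(pc$weights, 91125 * 350 + 350 * 350)
  expect_error(DEDConfig(hidden = c(0L, 0L)), "positive")
})

test_that("forward pass: sigmoid(0) = 0.5 for zero weights; inference deterministic", {
  cfg <- DEDConfig(grid = GridSpec(8, 5), hidden = c(6L, 6L), seed = 1L)
  m <- initDED(cfg)
  for (nm in names(m@params))
    if (!is.null(m@params[[nm]]) && nm != "g1" && nm != "g2")
      m@params[[nm]][] <- 0
  v <- randomVolume(c(8L, 8L, 8L), p = 0.3, seed = 2, spacing = 5)
  out <- dedForward(m, v)
  expect_true(all(abs(voxelValues(out) - 0.5) < 1e-12))
  m2 <- initDED(cfg)
  expect_identical(voxelValues(dedForward(m2, v)),
                   voxelValues(dedForward(m2, v)))
  # training-mode forward with mask rate 0 equals inference when the
  # normalization uses its running (eval) statistics
  cfg0 <- DEDConfig(grid = GridSpec(8, 5), hidden = c(6L, 6L), maskRate = 0,
                    seed = 1L)
  m3 <- initDED(cfg0)
  expect_equal(voxelValues(dedForward(m3, v, training = TRUE,
                                      batchStats = FALSE)),
               voxelValues(dedForward(m3, v)), tolerance = 1e-12)
  # grid mismatch errors
  expect_error(dedForward(m3, fixtureDatasetVolume(1L)), "grid")
})

test_that("batch gradients match finite differences (incl. SWR and mask)", {
  set.seed(1)
  grid <- GridSpec(5, 5); N <- 125L
  mkv <- function() array(rbinom(N, 1, 0.4), c(5, 5, 5))
  X <- matrix(c(mkv(), mkv(), mkv()), 3, N, byrow = TRUE)
  Z <- matrix(c(mkv(), mkv(), mkv()), 3, N, byrow = TRUE)
  W <- matrix(runif(3 * N), 3, N) + 0.5
  cfg <- DEDConfig(grid = grid, hidden = c(7L, 7L), lambdaSwr = 0.3,
                   seed = 9L)
  m <- initDED(cfg)
  bg <- atriarecon:::dedBatchGrad(m, X, Z, W, maskInput = FALSE)
  lossFun <- function(mm) {
    b <- atriarecon:::dedBatchGrad(mm, X, Z, W, maskInput = FALSE)
    b$loss + cfg@lambdaSwr * b$swr / length(mm@params$W)
  }
  eps <- 1e-6
  for (nm in c("W", "W2", "bOut", "g1", "be2")) {
    g <- bg$grads[[nm]]
    idx <- sample(length(g), min(5, length(g)))
    num <- vapply(idx, function(i) {
      m2 <- m; m2@params[[nm]][i] <- m2@params[[nm]][i] + eps
      m3 <- m; m3@params[[nm]][i] <- m3@params[[nm]][i] - eps
      (lossFun(m2) - lossFun(m3)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - g[idx]) / pmax(abs(num), 1e-6)), 1e-3,
              label = paste("gradient of", nm))
  }
})

test_that("binarize: >= tie rule, idempotent, monotone", {
  g <- GridSpec(4, 2)
  p <- ProbabilityVolume(array(0.5, c(4, 4, 4)), g)
  b <- binarize(p)
  expect_true(all(voxelValues(b) == 1)) # ties go to 1
  expect_identical(voxelValues(binarize(binarize(p))), voxelValues(binarize(p)))
  q <- ProbabilityVolume(array(runif(64), c(4, 4, 4)), g)
  lo <- sum(voxelValues(binarize(q, 0.3)))
  hi <- sum(voxelValues(binarize(q, 0.7)))
  expect_gte(lo, hi)
  expect_error(binarize(q, 0), "threshold")
})
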
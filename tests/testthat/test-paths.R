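# Path simulation: entries, traversal graph, Dijkstra, composition,
# augmentation, and binning.

test_that("ostia entries are interior voxels near their landmarks", {
  shape <- fixtureShape(); vol <- fixtureVolume()
  entries <- locateOstiaEntries(shape, vol)
  vox <- attr(entries, "voxel")
  expect_true(all(voxelValues(vol)[vox] == 1))
  d <- sqrt(rowSums((landmarkCoords(entries) -
                     landmarkCoords(shape)[rownames(landmarkCoords(entries)), ])^2))
  expect_true(all(d <= 3 * gridSpacing(vol)))
})

test_that("traversal graph edge costs follow the navigability functional", {
  vol <- randomVolume(c(3L, 3L, 3L), p = 1, spacing = 2)
  g0 <- buildTraversalGraph(vol, navigabilityWeight = 0)
  # with zero weight, axis-aligned edges cost exactly the spacing
  axis <- abs(voxelCenters(g0@grid, g0@nodes[g0@edges[, 1]]) -
              voxelCenters(g0@grid, g0@nodes[g0@edges[, 2]]))
  isAxis <- rowSums(axis > 1e-9) == 1L
  expect_true(all(abs(g0@costs[isAxis] - 2) < 1e-12))
  # center of a 3^3 all-interior block has 26 incident edges
  ctr <- which(g0@nodes == subToLinearR(c(3, 3, 3), c(2, 2, 2)))
  expect_equal(sum(g0@edges == ctr), 26L)
  # wall-hugging steps cost strictly more for positive weight
  g2 <- buildTraversalGraph(fixtureVolume(), navigabilityWeight = 2)
  wd <- (g2@wallDist[g2@edges[, 1]] + g2@wallDist[g2@edges[, 2]]) / 2
  len <- sqrt(rowSums((voxelCenters(g2@grid, g2@nodes[g2@edges[, 1]]) -
                       voxelCenters(g2@grid, g2@nodes[g2@edges[, 2]]))^2))
  expect_true(all(g2@costs > len - 1e-12))
  ord <- order(wd)
  expect_gt(mean(g2@costs[ord[1:50]] / len[ord[1:50]]),
            mean(g2@costs[rev(ord)[1:50]] / len[rev(ord)[1:50]]))
})

test_that("Dijkstra matches a brute-force Bellman-Ford oracle on random interiors", {
  nAgree <- 0L
  for (trial in 1:60) {
    vol <- randomVolume(c(5L, 5L, 5L), p = 0.75, seed = trial)
    lab <- labelComponents(voxelValues(vol) == 1, 26L)
    sizes <- attr(lab, "sizes")
    if (length(sizes) == 0L) next
    main <- which.max(sizes)
    keep <- array(as.numeric(lab == main), dim(lab))
    if (sum(keep) < 2L) next
    vol <- OccupancyVolume(keep, voxelGrid(vol))
    w <- if (trial %% 2L) 0 else 2
    g <- buildTraversalGraph(vol, navigabilityWeight = w)
    nodes <- g@nodes
    src <- nodes[1 + trial %% length(nodes)]
    dst <- nodes[length(nodes) - trial %% length(nodes)]
    res <- shortestPath(g, src, dst)
    oracle <- bellmanFordCost(length(nodes), g@edges, g@costs,
                              match(src, nodes), match(dst, nodes))
    expect_equal(res$cost, oracle, tolerance = 1e-12)
    # path is a valid walk with matching accumulated cost
    if (length(res$path) > 1L) {
      steps <- voxelCenters(g@grid, res$path)
      expect_true(all(voxelValues(vol)[res$path] == 1))
    }
    nAgree <- nAgree + 1L
  }
  expect_gte(nAgree, 50L)
})

test_that("Dijkstra agrees with igraph on a weighted interior graph", {
  skip_if_not_installed("igraph")
  vol <- fixtureDatasetVolume(1L)
  g <- buildTraversalGraph(vol, navigabilityWeight = 2)
  ig <- igraph::graph_from_edgelist(g@edges, directed = FALSE)
  src <- 5L; dst <- length(g@nodes) - 3L
  igd <- igraph::distances(ig, v = src, to = dst, weights = g@costs)[1, 1]
  res <- shortestPath(g, g@nodes[src], g@nodes[dst])
  expect_equal(res$cost, igd, tolerance = 1e-10)
})

test_that("src == dst gives a single-node zero-cost path; unreachable errors", {
  vol <- fixtureDatasetVolume(1L)
  g <- buildTraversalGraph(vol, 1)
  n1 <- g@nodes[1]
  expect_equal(shortestPath(g, n1, n1), list(path = n1, cost = 0))
  expect_error(shortestPath(g, n1, 1L), "not interior")
  # disconnected interiors are rejected with component sizes
  v <- array(0, c(5, 5, 5)); v[1, 1, 1] <- 1; v[5, 5, 5] <- 1
  expect_error(buildTraversalGraph(OccupancyVolume(v, GridSpec(5, 2))),
               "component sizes")
})

test_that("composed paths stay interior and traverse legs in order", {
  ds <- fixtureDataset()
  for (s in ds@samples[1:4]) {
    p <- composePath(s$shape, s$volume)
    segs <- unique(pathSegments(p))
    expect_identical(segs, atriarecon:::SEGMENT_LEVELS[1:4])
    expect_true(all(table(pathSegments(p)) >= 1L))
    # every pre-augmentation point sits in an occupied voxel
    sub <- pointsToVoxels(voxelGrid(s$volume), pathPoints(p))
    lin <- subToLinearR(gridDims(s$volume), sub)
    expect_true(all(voxelValues(s$volume)[lin] == 1))
    # endpoints: septum entry first, PVRS entry last
    entries <- locateOstiaEntries(s$shape, s$volume)
    expect_equal(unname(pathPoints(p)[1, ]),
                 unname(landmarkCoords(entries, "septum")))
    expect_equal(unname(pathPoints(p)[nrow(pathPoints(p)), ]),
                 unname(landmarkCoords(entries, "ostium_PVRS")))
  }
})

test_that("navigability weight pushes paths toward the chamber center", {
  ds <- fixtureDataset()
  meanWall <- function(w) {
    mean(vapply(ds@samples, function(s) {
      g <- buildTraversalGraph(s$volume, w)
      p <- composePath(s$shape, s$volume, w, graph = g)
      sub <- pointsToVoxels(voxelGrid(s$volume), pathPoints(p))
      lin <- subToLinearR(gridDims(s$volume), sub)
      mean(g@wallDist[match(lin, g@nodes)])
    }, numeric(1)))
  }
  expect_gte(meanWall(2), meanWall(0) - 1e-9)
})

test_that("augmentation respects count, interior filter, and jitter order", {
  shape <- fixtureShape()
  vol <- fixtureVolume()
  path <- composePath(shape, vol)
  # n = 0 and sF = 0 are no-ops
  expect_identical(augmentPath(path, shape, AugmentationConfig(n = 0)), path)
  expect_identical(augmentPath(path, shape, AugmentationConfig(sF = 0)), path)
  # with muS = 0 all augmentation points are strictly interior and the kept
  # count is within binomial tolerance of n * sF * |path| * P(interior)
  nP <- nrow(pathPoints(path))
  cfg <- AugmentationConfig(n = 10L, sigma = 2, sF = 0.5, muS = 0, seed = 2L)
  aug <- augmentPath(path, shape, cfg)
  added <- pathSegments(aug) == "augmentation"
  inside <- atriarecon:::.pointsInMesh(pathPoints(aug)[added, , drop = FALSE],
                                       meshVertices(shape), meshFaces(shape))
  expect_true(all(inside))
  expected <- 10 * 0.5 * nP
  expect_lt(sum(added), expected + 4 * sqrt(10 * nP * 0.25))
  # determinism per seed
  expect_identical(pathPoints(augmentPath(path, shape, cfg)),
                   pathPoints(aug))
})

test_that("point binning marks exactly the traversed voxels", {
  grid <- GridSpec(10, 2)
  ctr <- voxelCenters(grid, 55L)
  p1 <- PathPointCloud(rbind(ctr, ctr + 0.2)) # two points, same voxel
  expect_equal(sum(voxelValues(pathToVolume(p1, grid))), 1)
  # a straight 26-connected diagonal of L voxels -> exactly L voxels
  L <- 7L
  idx <- cbind(1:L, 1:L, 1:L)
  pts <- voxelCenters(grid, subToLinearR(gridDims(grid), idx))
  expect_equal(sum(voxelValues(pathToVolume(PathPointCloud(pts), grid))), L)
  # outliers are clipped with a message; all-outside errors
  out <- PathPointCloud(rbind(ctr, c(999, 999, 999)))
  expect_message(pathToVolume(out, grid), "clipped 1")
  allOut <- PathPointCloud(rbind(c(999, 0, 0), c(999, 1, 1)))
  expect_error(pathToVolume(allOut, grid), "outside the grid")
})
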
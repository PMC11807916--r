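# Shape construction, voxelization, and dataset generation.

test_that("mean-parameter atrium is a closed genus-0 mesh inside the grid", {
  shape <- fixtureShape()
  V <- meshVertices(shape); F <- meshFaces(shape)
  aud <- atriarecon:::.meshEdgeAudit(F, nrow(V))
  expect_true(aud$closed)
  expect_equal(nrow(V) - aud$nEdges + nrow(F), 2) # Euler characteristic
  # bounding box fits the default 120 mm grid extent with >= 5 mm margin
  expect_true(all(abs(V) <= 60 - 5))
})

test_that("landmarks lie on the surface and PV directions are separated", {
  shape <- fixtureShape()
  lm <- landmarkCoords(shape)
  d <- atriarecon:::.nearestVertexDist(lm, meshVertices(shape))
  expect_true(all(d <= 2 * 2.666))
  model <- defaultShapeModel()
  dirs <- sapply(atriarecon:::PV_NAMES, function(pv)
    atriarecon:::dirFromAngles(model@mean[paste0(pv, "_theta")],
                               model@mean[paste0(pv, "_phi")]))
  ang <- acos(pmin(crossprod(dirs), 1))
  diag(ang) <- Inf
  expect_gt(min(ang) * 180 / pi, 20)
})

test_that("voxelization matches analytic volumes within 5%", {
  grid <- GridSpec()
  ball <- sphereMesh(20, res = 1.2)
  vol <- voxelizeShape(AtriumShape(ball, fixtureShape()@landmarks), grid)
  analytic <- 4 / 3 * pi * 20^3 / grid@spacing^3
  expect_lt(abs(sum(voxelValues(vol)) - analytic) / analytic, 0.05)
  # empty region far from the mesh stays empty
  corner <- voxelValues(vol)[1:5, 1:5, 1:5]
  expect_true(all(corner == 0))
})

test_that("voxel boundary shell is one connected component", {
  vol <- fixtureVolume()
  shell <- boundaryVoxels(vol)
  lab <- labelComponents(shell, 26L)
  expect_equal(length(attr(lab, "sizes")), 1L)
})

test_that("meshes exceeding the grid extent name the overflowing axis", {
  big <- sphereMesh(70, res = 4)
  expect_error(voxelizeShape(AtriumShape(big, fixtureShape()@landmarks),
                             GridSpec()), "x axis")
})

test_that("dataset generation is deterministic, split disjoint, filter idempotent", {
  ds <- fixtureDataset()
  expect_length(ds@samples, 8L)
  expect_length(intersect(ds@trainIdx, ds@testIdx), 0L)
  ds2 <- generateDataset(6, 2, defaultShapeModel(), GridSpec(24, 5),
                         seed = 11, meshRes = 2.5)
  expect_identical(lapply(ds@samples, function(s) s$volume@values),
                   lapply(ds2@samples, function(s) s$volume@values))
  model <- defaultShapeModel()
  for (s in ds@samples) {
    expect_true(isPlausible(s$shape@params, model)) # 100% pass on re-check
    expect_true(isConnectedInterior(s$volume))
  }
  # empty test split is allowed
  ds0 <- generateDataset(2, 0, defaultShapeModel(), GridSpec(24, 5),
                         seed = 3, meshRes = 3)
  expect_length(ds0@testIdx, 0L)
})

test_that("generated volumes are binary with connected nonempty interior", {
  for (s in fixtureDataset()@samples) {
    v <- voxelValues(s$volume)
    expect_true(all(v %in% c(0, 1)))
    expect_gt(sum(v), 0)
  }
})
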
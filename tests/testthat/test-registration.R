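# Rigid registration, mean shape, and clinical-style preprocessing.

test_that("identical point sets give the identity transform", {
  pts <- matrix(rnorm(12), 4, 3)
  tf <- rigidRegister(pts, pts)
  expect_equal(tf@rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf@translation, c(0, 0, 0), tolerance = 1e-12)
})

test_that("synthetic rigid motions are recovered exactly on 4-point ostia sets", {
  withr::with_seed(7, {
    worst <- 0
    for (i in 1:100) {
      src <- matrix(rnorm(12, sd = 20), 4, 3)
      # guard against near-collinear draws
      if (svd(scale(src, scale = FALSE))$d[2] < 1) next
      R0 <- randomRotation(); t0 <- rnorm(3, sd = 30)
      tgt <- sweep(src %*% t(R0), 2, t0, "+")
      tf <- rigidRegister(src, tgt)
      worst <- max(worst,
                   max(abs(tf@rotation - R0)), max(abs(tf@translation - t0)),
                   max(abs(applyTransform(src, tf) - tgt)))
    }
    expect_lt(worst, 1e-9)
  })
})

test_that("a 90-degree z-rotation of 4 ostia registers with zero residual", {
  src <- rbind(c(30, 10, 5), c(25, -12, 8), c(-28, 11, 4), c(-24, -10, 9))
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  tgt <- src %*% t(Rz)
  tf <- rigidRegister(src, tgt)
  expect_lt(sqrt(mean(rowSums((applyTransform(src, tf) - tgt)^2))), 1e-9)
})

test_that("degenerate collinear configurations are rejected, reflections never returned", {
  line <- cbind(1:4, 2 * (1:4), -1 * (1:4))
  expect_error(rigidRegister(line, line + 1), "collinear|degenerate")
  withr::with_seed(21, {
    for (i in 1:20) {
      src <- matrix(rnorm(12, sd = 10), 4, 3)
      tgt <- matrix(rnorm(12, sd = 10), 4, 3)
      if (svd(scale(src, scale = FALSE))$d[2] < 1 ||
          svd(scale(tgt, scale = FALSE))$d[2] < 1) next
      tf <- rigidRegister(src, tgt)
      expect_gt(det(tf@rotation), 0)
    }
  })
})

test_that("under 1 mm landmark noise, 4-point rotations stay within 5 degrees", {
  withr::with_seed(13, {
    errs <- replicate(100, {
      src <- rbind(c(30, 12, 6), c(26, -13, 9), c(-29, 12, 5), c(-25, -11, 10))
      R0 <- randomRotation(); t0 <- rnorm(3, sd = 20)
      tgt <- sweep(src %*% t(R0), 2, t0, "+") + matrix(rnorm(12, sd = 1), 4, 3)
      tf <- rigidRegister(src, tgt)
      tr <- sum(diag(t(R0) %*% tf@rotation))
      acos(pmin(1, (tr - 1) / 2)) * 180 / pi
    })
    # Monte-Carlo estimate of the rotation error under 1 mm landmark noise
    expect_lt(mean(errs), 5)
    expect_lt(median(errs), 5)
  })
})

test_that("transforms are isometries and invert cleanly on point clouds", {
  cloud <- PathPointCloud(matrix(rnorm(60, sd = 15), 20, 3),
                          rep("unknown", 20))
  tf <- RigidTransform(randomRotation(), c(4, -2, 7))
  moved <- applyTransform(cloud, tf)
  expect_identical(pathSegments(moved), pathSegments(cloud))
  expect_equal(as.numeric(dist(pathPoints(moved))),
               as.numeric(dist(pathPoints(cloud))), tolerance = 1e-9)
  back <- applyTransform(moved, invertTransform(tf))
  expect_equal(pathPoints(back), pathPoints(cloud), tolerance = 1e-9)
  expect_equal(pathPoints(applyTransform(cloud, RigidTransform())),
               pathPoints(cloud))
})

test_that("mean shape averages volumes and landmarks", {
  ds <- fixtureDataset()
  vols <- lapply(ds@samples, `[[`, "volume")
  lms <- lapply(ds@samples, function(s) s$shape@landmarks)
  ms <- computeMeanShape(vols, lms)
  expect_true(all(voxelValues(ms@meanField) >= 0 &
                  voxelValues(ms@meanField) <= 1))
  expect_equal(voxelValues(ms@binary),
               array(as.numeric(voxelValues(ms@meanField) >= 0.5),
                     gridDims(ms@binary)))
  expect_equal(landmarkCoords(ms),
               Reduce(`+`, lapply(lms, landmarkCoords)) / length(lms),
               tolerance = 1e-12)
  # single volume: mean is that volume
  ms1 <- computeMeanShape(vols[1], lms[1])
  expect_equal(voxelValues(ms1@meanField), voxelValues(vols[[1]]))
  # two disjoint volumes: values in {0, 0.5}; ties kept at binarization
  a <- array(0, c(4, 4, 4)); a[1:2, , ] <- 1
  b <- array(0, c(4, 4, 4)); b[3:4, , ] <- 1
  g <- GridSpec(4, 2)
  ms2 <- computeMeanShape(list(OccupancyVolume(a, g), OccupancyVolume(b, g)),
                          lms[1:2])
  expect_true(all(voxelValues(ms2@meanField) %in% c(0, 0.5)))
  expect_true(all(voxelValues(ms2@binary)[voxelValues(ms2@meanField) == 0.5] == 1))
  # binarized mean of the synthetic dataset is a valid connected volume
  expect_true(isConnectedInterior(ms@binary))
  # grid mismatch errors
  expect_error(computeMeanShape(list(vols[[1]], OccupancyVolume(a, g)),
                                lms[1:2]), "common grid")
})

test_that("clinical preprocessing is invariant to rigid motion of the input", {
  ds <- fixtureDataset()
  s <- ds@samples[[1]]
  ms <- computeMeanShape(lapply(ds@samples, `[[`, "volume"),
                         lapply(ds@samples, function(s) s$shape@landmarks))
  cloud <- composePath(s$shape, s$volume)
  tags <- lapply(setNames(atriarecon:::PV_NAMES, atriarecon:::PV_NAMES),
                 function(pv) landmarkCoords(s$shape, paste0("ostium_", pv)))
  v1 <- preprocessClinical(cloud, tags, ms, voxelGrid(s$volume))
  # rotate the whole acquisition (cloud + tags) and preprocess again
  tf <- RigidTransform(randomRotation(), c(25, -10, 14))
  cloud2 <- applyTransform(cloud, tf)
  tags2 <- lapply(tags, function(p) as.numeric(applyTransform(matrix(p, 1), tf)))
  v2 <- preprocessClinical(cloud2, tags2, ms, voxelGrid(s$volume))
  expect_identical(voxelValues(v1), voxelValues(v2))
  # tags exactly at the mean-shape ostia (one point per PV): centroids equal
  # those points, the registration is the identity, and the volume is the
  # direct voxelization of the cloud
  msTags <- lapply(setNames(atriarecon:::PV_NAMES, atriarecon:::PV_NAMES),
                   function(pv) landmarkCoords(ms, paste0("ostium_", pv)))
  vId <- preprocessClinical(cloud, msTags, ms, voxelGrid(s$volume))
  tfId <- attr(vId, "transform")
  expect_equal(tfId@rotation, diag(3), tolerance = 1e-9)
  expect_equal(tfId@translation, c(0, 0, 0), tolerance = 1e-9)
  direct <- pathToVolume(cloud, voxelGrid(s$volume))
  expect_identical(voxelValues(vId), voxelValues(direct))
  # missing PV tag errors with the vein name
  expect_error(preprocessClinical(cloud, tags[1:3], ms), "PVRS")
})
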
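# The scaled-down reconstruction benchmark (computed once, shared across
# acceptance blocks): 24^3 grid at 5 mm pitch, 200 train + 50 test synthetic atria,
# default path augmentation, DED "SWR005" variant (hidden 350+350,
# alpha = 2/5, lambda = 0.05, boundary mask on), 150 epochs.

benchmarkGrid <- function() GridSpec(24, 5)

fixtureBenchmark <- function() fixture("benchmark", function() {
  grid <- benchmarkGrid()
  ds <- generateDataset(200, 50, defaultShapeModel(), grid, seed = 17,
                        meshRes = 2.5)
  pv <- simulatePathVolumes(ds, seed = 18)
  cfg <- DEDConfig(grid = grid, hidden = c(350L, 350L), lambdaSwr = 0.05,
                   epochs = 150L, batchSize = 20L, seed = 19L)
  net <- trainDED(pv[ds@trainIdx],
                  lapply(datasetSamples(ds, "train"), `[[`, "volume"), cfg)
  trainS <- datasetSamples(ds, "train")
  ms <- computeMeanShape(lapply(trainS, `[[`, "volume"),
                         lapply(trainS, function(s) s$shape@landmarks))
  testI <- ds@testIdx
  recon <- lapply(pv[testI], function(v) extractMesh(reconstruct(net, v)))
  msMesh <- extractMesh(ms@meanField)
  gt <- lapply(datasetSamples(ds, "test"), function(s) extractMesh(s$volume))
  lms <- lapply(datasetSamples(ds, "test"), function(s) s$shape@landmarks)
  res <- evaluateBenchmark(
    list(ded = recon, mean_shape = rep(list(msMesh), length(testI))),
    gt, lms, radii = c(10, 15, 20, 25, Inf))
  dice <- vapply(testI, function(i)
    diceScore(binarize(dedForward(net, pv[[i]])), ds@samples[[i]]$volume),
    numeric(1))
  list(ds = ds, pv = pv, net = net, ms = ms, res = res, testDice = dice)
})
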
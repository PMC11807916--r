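# Run configuration and the end-to-end pipeline: generate shapes ->
# simulate paths -> train -> reconstruct -> evaluate, with per-stage
# artifacts and a manifest (config hash, seed) for provenance.

#' Default run configuration
#'
#' The complete configuration list used by [runPipeline()]; user YAML files
#' override these values key by key.
#'
#' @return nested config list.
#' @export
runConfigDefaults <- function() {
  list(
    seed = 1L,
    outDir = "atriarecon-run",
    grid = list(dims = 45L, spacing = 2.666),
    shapes = list(nTrain = 200L, nTest = 50L, meshRes = 2, sdScale = 1,
                  threshold = 3),
    paths = list(navigabilityWeight = 2,
                 augment = list(n = 5L, sigma = 2, sF = 0.5, muS = 1)),
    model = list(variant = "swr005", hidden = 350L, epochs = 150L,
                 lr = 1e-3, batchSize = 20L, maskRate = 0.3),
    evaluation = list(radii = c(10, 15, 20, 25, Inf)))
}

mergeConfig <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop(sprintf("unknown config key '%s%s'", path, nm))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]],
                                    paste0(path, nm, "."))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Read / write a run configuration (YAML)
#'
#' The configuration round-trips losslessly; unknown keys are rejected with
#' the offending key path.
#'
#' @param path YAML file.
#' @return `readRunConfig`: a complete config list (user values merged over
#'   package defaults).
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- mergeConfig(runConfigDefaults(), if (is.null(user)) list() else user)
  cfg$evaluation$radii <- as.numeric(
    ifelse(cfg$evaluation$radii %in% c("Inf", ".inf"), Inf,
           cfg$evaluation$radii))
  cfg
}

#' @rdname readRunConfig
#' @param config a config list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# named DED variants: lambda / augmentation / boundary mask settings
dedVariantConfig <- function(variant, grid, hidden, epochs, lr, batchSize,
                             maskRate, seed) {
  variant <- match.arg(variant, c("noswr", "swr005", "swr75", "noaug"))
  lambda <- switch(variant, noswr = 0, swr005 = 0.05, swr75 = 75,
                   noaug = 0.05)
  DEDConfig(grid = grid, hidden = rep(as.integer(hidden), 2L),
            alpha = 2 / 5, lambdaSwr = lambda,
            useBoundaryMask = (variant != "noaug"), maskRate = maskRate,
            lr = lr, batchSize = as.integer(batchSize),
            epochs = as.integer(epochs), seed = as.integer(seed))
}

#' Simulate path input volumes for a dataset
#'
#' For every sample: compose the septum-to-PVRS traversal, optionally
#' augment it, and bin it onto the grid.  Augmentation seeds are derived
#' deterministically from `seed` and the sample index.
#'
#' @param dataset an [AtriumDataset-class].
#' @param navigabilityWeight see [buildTraversalGraph()].
#' @param augment an [AugmentationConfig-class], or `NULL` to skip
#'   augmentation ("no aug" variant).
#' @param seed integer seed for the augmentation draws.
#' @return list of path [OccupancyVolume-class]s (one per sample), with the
#'   composed [PathPointCloud-class]s as attribute `clouds`.
#' @export
simulatePathVolumes <- function(dataset, navigabilityWeight = 2,
                                augment = AugmentationConfig(), seed = 1L) {
  vols <- vector("list", length(dataset@samples))
  clouds <- vector("list", length(dataset@samples))
  for (i in seq_along(dataset@samples)) {
    s <- dataset@samples[[i]]
    path <- composePath(s$shape, s$volume, navigabilityWeight)
    if (!is.null(augment)) {
      cfgI <- augment
      cfgI@seed <- (as.integer(seed) * 7919L + i) %% .Machine$integer.max
      path <- augmentPath(path, s$shape, cfgI)
    }
    clouds[[i]] <- path
    vols[[i]] <- pathToVolume(path, dataset@grid)
  }
  attr(vols, "clouds") <- clouds
  vols
}

#' Run the full reconstruction pipeline
#'
#' Executes generate-shapes, generate-paths, train (DED variant), mean-shape
#' baseline, reconstruct and evaluate, writing per-stage artifacts under
#' `config$outDir`: volumes (NIfTI), paths (CSV), meshes (PLY), training
#' history and the Table-style results CSV, plus a `manifest.yaml` with the
#' config hash and seed.  Stages reuse existing artifacts when `resume` is
#' TRUE and a stage's outputs are present (only the trained checkpoint is
#' reused; earlier stages are deterministic given the seed).
#'
#' @param config a config list from [readRunConfig()] (or
#'   `runConfigDefaults()`).
#' @param resume reuse an existing checkpoint if present.
#' @param verbose print stage progress.
#' @return the results `data.frame` from [evaluateBenchmark()], invisibly.
#' @export
runPipeline <- function(config = runConfigDefaults(), resume = FALSE,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "setup"
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfgPath <- file.path(out, "config.yaml")
  writeRunConfig(config, cfgPath)
  manifest <- list(configHash = unname(tools::md5sum(cfgPath)),
                   seed = config$seed,
                   package = as.character(utils::packageVersion("atriarecon")))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  tryCatch({
    stage <- "generate-shapes"
    grid <- GridSpec(config$grid$dims, config$grid$spacing)
    model <- defaultShapeModel(sdScale = config$shapes$sdScale,
                               threshold = config$shapes$threshold)
    say("[%s] %d train + %d test shapes", stage, config$shapes$nTrain,
        config$shapes$nTest)
    ds <- generateDataset(config$shapes$nTrain, config$shapes$nTest, model,
                          grid, seed = config$seed,
                          meshRes = config$shapes$meshRes)
    stage <- "generate-paths"
    say("[%s] composing and augmenting catheter paths", stage)
    aug <- if (identical(config$model$variant, "noaug")) NULL
           else do.call(AugmentationConfig, config$paths$augment)
    pathVols <- simulatePathVolumes(ds, config$paths$navigabilityWeight,
                                    aug, seed = config$seed + 1L)
    stage <- "train"
    ckpt <- file.path(out, "checkpoint.rds")
    dcfg <- dedVariantConfig(config$model$variant, grid,
                             config$model$hidden, config$model$epochs,
                             config$model$lr, config$model$batchSize,
                             config$model$maskRate, config$seed)
    if (resume && file.exists(ckpt)) {
      say("[%s] reusing checkpoint %s", stage, ckpt)
      net <- loadCheckpoint(ckpt)
    } else {
      say("[%s] training DED variant '%s' (%d epochs)", stage,
          config$model$variant, dcfg@epochs)
      net <- trainDED(pathVols[ds@trainIdx],
                      lapply(datasetSamples(ds, "train"), `[[`, "volume"),
                      dcfg)
      saveCheckpoint(net, ckpt)
      write.csv(net@history, file.path(out, "history.csv"),
                row.names = FALSE)
    }
    stage <- "baseline"
    trainSamples <- datasetSamples(ds, "train")
    ms <- computeMeanShape(lapply(trainSamples, `[[`, "volume"),
                           lapply(trainSamples, function(s) s$shape@landmarks))
    stage <- "reconstruct"
    testIdx <- ds@testIdx
    say("[%s] reconstructing %d test cases", stage, length(testIdx))
    recon <- lapply(pathVols[testIdx], function(v)
      extractMesh(reconstruct(net, v)))
    msMesh <- extractMesh(ms@meanField)
    gt <- lapply(datasetSamples(ds, "test"), function(s)
      extractMesh(s$volume))
    lms <- lapply(datasetSamples(ds, "test"), function(s) s$shape@landmarks)
    stage <- "evaluate"
    res <- evaluateBenchmark(
      list(ded = recon, mean_shape = rep(list(msMesh), length(testIdx))),
      gt, lms, radii = config$evaluation$radii)
    write.csv(res, file.path(out, "results.csv"), row.names = FALSE)
    say("[%s] wrote %s", stage, file.path(out, "results.csv"))
    invisible(res)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding the configuration, all weight arrays and
#' running statistics, and the training history.
#'
#' @param model a [DEDModel-class] or [VNetModel-class].
#' @param path checkpoint file (`.rds`).
#' @return `path` (save) / the model (load).
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)
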
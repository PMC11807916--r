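#' @name accessors
#' @title Accessors for atriarecon objects
#' @description Small accessor generics used throughout the package instead
#'   of direct slot access.
#' @param x an atriarecon object.
#' @param name landmark name (for `landmarkCoords`).
NULL

#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))
#' @rdname accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))
#' @rdname accessors
#' @export
setGeneric("landmarkCoords", function(x, name = NULL) standardGeneric("landmarkCoords"))
#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setGeneric("pathPoints", function(x) standardGeneric("pathPoints"))
#' @rdname accessors
#' @export
setGeneric("pathSegments", function(x) standardGeneric("pathSegments"))

setMethod("gridDims", "GridSpec", function(x) x@dims)
setMethod("gridSpacing", "GridSpec", function(x) x@spacing)
setMethod("gridOrigin", "GridSpec", function(x) x@origin)
setMethod("gridDims", "VoxelVolume", function(x) x@grid@dims)
setMethod("gridSpacing", "VoxelVolume", function(x) x@grid@spacing)
setMethod("gridOrigin", "VoxelVolume", function(x) x@grid@origin)
setMethod("voxelValues", "VoxelVolume", function(x) x@values)
setMethod("voxelGrid", "VoxelVolume", function(x) x@grid)
setMethod("voxelGrid", "BoundaryMask", function(x) x@grid)

setMethod("landmarkCoords", "LandmarkSet", function(x, name = NULL) {
  if (is.null(name)) x@coords else {
    if (!name %in% rownames(x@coords)) stop("no landmark named '", name, "'")
    x@coords[name, ]
  }
})
setMethod("landmarkCoords", "AtriumShape", function(x, name = NULL)
  landmarkCoords(x@landmarks, name))
setMethod("landmarkCoords", "MeanShape", function(x, name = NULL)
  landmarkCoords(x@landmarks, name))

setMethod("meshVertices", "TriMesh", function(x) x@vertices)
setMethod("meshFaces", "TriMesh", function(x) x@faces)
setMethod("meshVertices", "AtriumShape", function(x) x@mesh@vertices)
setMethod("meshFaces", "AtriumShape", function(x) x@mesh@faces)

setMethod("pathPoints", "PathPointCloud", function(x) x@points)
setMethod("pathSegments", "PathPointCloud", function(x) x@segment)

#' @rdname accessors
#' @export
setGeneric("shapeMesh", function(x) standardGeneric("shapeMesh"))
setMethod("shapeMesh", "AtriumShape", function(x) x@mesh)

#' @rdname accessors
#' @export
setGeneric("datasetSamples", function(x, split = c("all", "train", "test"))
  standardGeneric("datasetSamples"))
#' @param split which split to return.
#' @rdname accessors
setMethod("datasetSamples", "AtriumDataset",
  function(x, split = c("all", "train", "test")) {
    split <- match.arg(split)
    idx <- switch(split, all = seq_along(x@samples), train = x@trainIdx,
                  test = x@testIdx)
    x@samples[idx]
  })

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d x %d voxels, %.4g mm pitch (extent %.1f mm)\n",
              object@dims[1], object@dims[2], object@dims[3], object@spacing,
              object@dims[1] * object@spacing))
})

setMethod("show", "OccupancyVolume", function(object) {
  cat(sprintf("OccupancyVolume: %s voxels, %d occupied (%.1f%%), %.4g mm pitch\n",
              paste(object@grid@dims, collapse = "x"), sum(object@values),
              100 * mean(object@values), object@grid@spacing))
})

setMethod("show", "ProbabilityVolume", function(object) {
  cat(sprintf("ProbabilityVolume: %s voxels, values in [%.3f, %.3f]\n",
              paste(object@grid@dims, collapse = "x"), min(object@values),
              max(object@values)))
})

setMethod("show", "AtriumShape", function(object) {
  cat(sprintf("AtriumShape '%s': %d vertices, %d faces, %d landmarks\n",
              object@id, nrow(object@mesh@vertices), nrow(object@mesh@faces),
              nrow(object@landmarks@coords)))
})

setMethod("show", "PathPointCloud", function(object) {
  tab <- table(factor(object@segment, levels = c(SEGMENT_LEVELS, "unknown")))
  tab <- tab[tab > 0]
  cat(sprintf("PathPointCloud (%s): %d points [%s]\n", object@sourceId,
              nrow(object@points),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "TraversalGraph", function(object) {
  cat(sprintf("TraversalGraph: %d interior voxels, %d edges\n",
              length(object@nodes), nrow(object@edges)))
})

setMethod("show", "ShapeModelSpec", function(object) {
  cat(sprintf("ShapeModelSpec: %d parameters, Mahalanobis threshold %.2f\n",
              length(object@mean), object@threshold))
})

setMethod("show", "MeanShape", function(object) {
  cat("MeanShape baseline:\n  ")
  show(object@meanField)
  cat(sprintf("  binarized occupancy: %d voxels\n", sum(object@binary@values)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "AtriumDataset", function(object) {
  cat(sprintf("AtriumDataset: %d samples (%d train / %d test) on %s grid, seed %d\n",
              length(object@samples), length(object@trainIdx),
              length(object@testIdx),
              paste(object@grid@dims, collapse = "x"), object@seed))
})
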
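#' @useDynLib atriarecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rbinom dnorm pt sd setNames
#' @importFrom utils head tail read.csv write.csv
NULL

LANDMARK_NAMES <- c("septum", "ostium_PVLS", "ostium_PVLI",
                    "ostium_PVRI", "ostium_PVRS")
PV_NAMES <- c("PVLS", "PVLI", "PVRI", "PVRS")
SEGMENT_LEVELS <- c("septum->PVLS", "PVLS->PVLI", "PVLI->PVRI",
                    "PVRI->PVRS", "augmentation")

#' Voxel grid geometry
#'
#' A `GridSpec` describes a regular voxel grid: the number of voxels per
#' axis, the edge length of a voxel in mm, and the mm coordinates of the
#' center of voxel (1,1,1).  The default is the 45^3 grid with a 2.666 mm
#' voxel pitch (a 120 mm cube), centered on the origin, which comfortably
#' contains an adult left atrium.
#'
#' @slot dims integer(3), voxels per axis.
#' @slot spacing numeric(1), mm per voxel edge.
#' @slot origin numeric(3), mm coordinates of the first voxel center.
#' @export
setClass("GridSpec", representation(dims = "integer", spacing = "numeric",
                                    origin = "numeric"),
  validity = function(object) {
    if (length(object@dims) != 3L || any(object@dims <= 0L))
      return("dims must be three positive integers")
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
      return("spacing must be a single positive number")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be three finite numbers")
    TRUE
  })

#' Construct a voxel grid specification
#'
#' @param dims voxels per axis (length 3, or a single value recycled).
#' @param spacing voxel edge length in mm.
#' @param origin mm coordinates of the center of the first voxel; by default
#'   the grid is centered on the origin.
#' @return A [GridSpec-class] object.
#' @examples
#' grid <- GridSpec()                # 45^3, 2.666 mm pitch
#' GridSpec(24, spacing = 5)         # scaled-down benchmark grid
#' @export
GridSpec <- function(dims = c(45L, 45L, 45L), spacing = 2.666, origin = NULL) {
  dims <- as.integer(rep_len(dims, 3L))
  if (is.null(origin)) origin <- -(dims - 1L) / 2 * spacing
  new("GridSpec", dims = dims, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

setClass("VoxelVolume", representation("VIRTUAL", grid = "GridSpec",
                                       values = "array"))

#' Binary occupancy volume
#'
#' An `OccupancyVolume` is a binary scalar field over a [GridSpec-class]:
#' 1 marks voxels whose center lies inside (or on) the chamber, 0 elsewhere.
#' It is the network's target representation and (for voxelized catheter
#' paths) its input representation.
#'
#' @slot grid a [GridSpec-class].
#' @slot values numeric array with `dim == dims(grid)`, values in \{0, 1\}.
#' @export
setClass("OccupancyVolume", contains = "VoxelVolume",
  validity = function(object) {
    if (!identical(dim(object@values), as.integer(object@grid@dims)))
      return("values dim does not match grid dims")
    if (any(!(object@values %in% c(0, 1))))
      return("occupancy values must all be 0 or 1")
    TRUE
  })

#' Probability volume
#'
#' Voxel-wise probabilities in \[0, 1\] over a [GridSpec-class], as produced by
#' the reconstruction networks before thresholding.
#'
#' @slot grid a [GridSpec-class].
#' @slot values numeric array with values in \[0, 1\].
#' @export
setClass("ProbabilityVolume", contains = "VoxelVolume",
  validity = function(object) {
    if (!identical(dim(object@values), as.integer(object@grid@dims)))
      return("values dim does not match grid dims")
    r <- range(object@values)
    if (!all(is.finite(r)) || r[1] < 0 || r[2] > 1)
      return("probability values must lie in [0, 1]")
    TRUE
  })

#' @rdname OccupancyVolume-class
#' @param values numeric/logical array of 0/1 values.
#' @param grid a [GridSpec-class] matching `dim(values)`.
#' @export
OccupancyVolume <- function(values, grid) {
  v <- array(as.numeric(values), dim = dim(values))
  new("OccupancyVolume", grid = grid, values = v)
}

#' @rdname ProbabilityVolume-class
#' @param values numeric array of probabilities.
#' @param grid a [GridSpec-class] matching `dim(values)`.
#' @export
ProbabilityVolume <- function(values, grid) {
  new("ProbabilityVolume", grid = grid,
      values = array(as.numeric(values), dim = dim(values)))
}

#' Named anatomical landmarks
#'
#' Holds the five mandatory landmarks (septum and the four PV ostia:
#' left-superior, left-inferior, right-inferior, right-superior) plus an
#' optional appendage point, as mm coordinates.
#'
#' @slot coords numeric matrix, one row per landmark, rownames are landmark
#'   names, columns x/y/z in mm.
#' @export
setClass("LandmarkSet", representation(coords = "matrix"),
  validity = function(object) {
    if (ncol(object@coords) != 3L) return("coords must have 3 columns")
    if (!all(LANDMARK_NAMES %in% rownames(object@coords)))
      return(paste("missing landmark(s):",
                   paste(setdiff(LANDMARK_NAMES, rownames(object@coords)),
                         collapse = ", ")))
    if (any(!is.finite(object@coords))) return("landmark coordinates must be finite")
    TRUE
  })

#' @rdname LandmarkSet-class
#' @param coords named list of xyz triples, or a matrix with rownames.
#' @export
LandmarkSet <- function(coords) {
  if (is.list(coords)) {
    m <- do.call(rbind, lapply(coords, as.numeric))
    rownames(m) <- names(coords)
    coords <- m
  }
  colnames(coords) <- c("x", "y", "z")
  new("LandmarkSet", coords = coords)
}

#' Triangular surface mesh
#'
#' @slot vertices numeric matrix (n x 3), mm.
#' @slot faces integer matrix (m x 3), 1-based vertex indices.
#' @export
setClass("TriMesh", representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    if (ncol(object@vertices) != 3L) return("vertices must have 3 columns")
    if (ncol(object@faces) != 3L) return("faces must have 3 columns")
    if (nrow(object@faces) > 0 &&
        (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices)))
      return("face indices out of range")
    TRUE
  })

#' @rdname TriMesh-class
#' @param vertices,faces see slot documentation.
#' @export
TriMesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  new("TriMesh", vertices = vertices, faces = faces)
}

#' Atrium shape: mesh plus landmarks
#'
#' A closed (watertight) triangular mesh of an atrium-like chamber together
#' with its named landmarks, and optionally the generator parameters that
#' produced it.
#'
#' @slot mesh a [TriMesh-class].
#' @slot landmarks a [LandmarkSet-class].
#' @slot params generator parameters (named numeric) or `NULL`.
#' @slot id character identifier.
#' @export
setClass("AtriumShape", representation(mesh = "TriMesh",
                                       landmarks = "LandmarkSet",
                                       params = "ANY", id = "character"))

#' @rdname AtriumShape-class
#' @param mesh,landmarks,params,id see slot documentation.
#' @export
AtriumShape <- function(mesh, landmarks, params = NULL, id = "shape") {
  new("AtriumShape", mesh = mesh, landmarks = landmarks, params = params,
      id = id)
}

#' Statistical shape model specification
#'
#' Mean vector and covariance of the multivariate normal over generator
#' parameters, plus the plausibility threshold (a Mahalanobis distance from
#' the mean) used to filter implausible samples.  The defaults are fixed,
#' documented values chosen to produce anatomically plausible atrium-like
#' shapes; they are not estimates learned from imaging data.
#'
#' @slot mean named numeric parameter vector.
#' @slot covariance symmetric positive semi-definite matrix.
#' @slot threshold maximal admissible Mahalanobis distance from the mean.
#' @export
setClass("ShapeModelSpec", representation(mean = "numeric",
                                          covariance = "matrix",
                                          threshold = "numeric"),
  validity = function(object) {
    d <- length(object@mean)
    if (!all(dim(object@covariance) == c(d, d)))
      return("covariance dimension does not match mean")
    if (max(abs(object@covariance - t(object@covariance))) > 1e-8)
      return("covariance must be symmetric")
    ev <- eigen(object@covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      return("covariance must be positive semi-definite")
    if (!is.finite(object@threshold)) return("threshold must be finite")
    TRUE
  })

#' Ordered catheter path point cloud
#'
#' Ordered 3D points in mm tracing a (simulated or acquired) catheter
#' traversal, with a segment label per point identifying the traversal leg
#' (`septum->PVLS`, `PVLS->PVLI`, `PVLI->PVRI`, `PVRI->PVRS`) or
#' `augmentation` for scatter points added around the path.
#'
#' @slot points numeric matrix (n x 3), mm.
#' @slot segment character vector of per-point labels.
#' @slot sourceId id of the shape the path was generated in.
#' @export
setClass("PathPointCloud", representation(points = "matrix",
                                          segment = "character",
                                          sourceId = "character"),
  validity = function(object) {
    if (ncol(object@points) != 3L) return("points must have 3 columns")
    if (nrow(object@points) != length(object@segment))
      return("one segment label per point required")
    if (nrow(object@points) < 2L) return("a path needs at least 2 points")
    known <- object@segment %in% c(SEGMENT_LEVELS, "unknown")
    if (!all(known)) return("unknown segment label")
    TRUE
  })

#' @rdname PathPointCloud-class
#' @param points,segment,sourceId see slot documentation.
#' @export
PathPointCloud <- function(points, segment = rep("unknown", nrow(points)),
                           sourceId = "unknown") {
  colnames(points) <- c("x", "y", "z")
  new("PathPointCloud", points = points, segment = as.character(segment),
      sourceId = sourceId)
}

#' Path augmentation configuration
#'
#' Controls the stochastic thickening of a simulated path into a realistic
#' catheter point cloud: around every path point, `n` isotropic Gaussian
#' samples with scale `sigma` (mm) are drawn, kept independently with
#' probability `sF`, filtered to the mesh interior, and finally jittered by a
#' Gaussian displacement of scale `muS` (mm) which may push points slightly
#' through the wall, mimicking tissue deformation by the catheter.
#'
#' @slot n samples per path point.
#' @slot sigma mm scatter scale.
#' @slot sF per-point keep probability in \[0, 1\].
#' @slot muS mm jitter scale applied after the interior filter.
#' @slot seed integer RNG seed.
#' @export
setClass("AugmentationConfig", representation(n = "integer", sigma = "numeric",
                                              sF = "numeric", muS = "numeric",
                                              seed = "integer"),
  validity = function(object) {
    if (object@n < 0L) return("n must be >= 0")
    if (object@sigma < 0 || object@muS < 0) return("sigma and muS must be >= 0")
    if (object@sF < 0 || object@sF > 1) return("sF must be in [0, 1]")
    TRUE
  })

#' @rdname AugmentationConfig-class
#' @param n,sigma,sF,muS,seed see slot documentation.
#' @export
AugmentationConfig <- function(n = 5L, sigma = 2, sF = 0.5, muS = 1,
                               seed = 1L) {
  new("AugmentationConfig", n = as.integer(n), sigma = sigma, sF = sF,
      muS = muS, seed = as.integer(seed))
}

#' Interior voxel traversal graph
#'
#' Nodes are interior voxels; edges connect 26-neighbour interior voxel
#' pairs.  The edge cost is the Euclidean step length scaled by a
#' navigability factor `1 + w / (1 + dWall)` where `dWall` is the mm distance
#' of the step midpoint from the chamber wall, so for `w > 0` steps hugging
#' the wall are more expensive and shortest paths curve toward the chamber
#' center, as a catheter tip does.
#'
#' @slot nodes integer linear voxel indices (into the grid array).
#' @slot edges integer matrix (e x 2) of node indices (into `nodes`).
#' @slot costs numeric positive edge costs.
#' @slot wallDist numeric mm wall distance per node.
#' @slot grid the underlying [GridSpec-class].
#' @export
setClass("TraversalGraph", representation(nodes = "integer", edges = "matrix",
                                          costs = "numeric",
                                          wallDist = "numeric",
                                          grid = "GridSpec"),
  validity = function(object) {
    if (length(object@costs) != nrow(object@edges))
      return("one cost per edge required")
    if (length(object@costs) && min(object@costs) <= 0)
      return("edge costs must be positive")
    if (length(object@wallDist) != length(object@nodes))
      return("one wall distance per node required")
    TRUE
  })

#' Rigid transform (rotation + translation)
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation mm triple.
#' @export
setClass("RigidTransform", representation(rotation = "matrix",
                                          translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      return("rotation must be orthonormal (R'R = I within 1e-9)")
    if (det(R) < 0) return("reflections are not rigid transforms")
    if (length(object@translation) != 3L) return("translation must be length 3")
    TRUE
  })

#' @rdname RigidTransform-class
#' @param rotation,translation see slot documentation.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Mean shape baseline
#'
#' The voxel-wise average of the training occupancy volumes, its binarization
#' at 0.5, and the arithmetic mean of the per-shape landmarks.  Serves both
#' as the no-learning reconstruction baseline and as the reference frame for
#' rigid PV-ostia registration of acquired point clouds.
#'
#' @slot meanField a [ProbabilityVolume-class] (voxel-wise average).
#' @slot binary an [OccupancyVolume-class], `meanField >= 0.5`.
#' @slot landmarks a [LandmarkSet-class] of mean landmark positions.
#' @export
setClass("MeanShape", representation(meanField = "ProbabilityVolume",
                                     binary = "OccupancyVolume",
                                     landmarks = "LandmarkSet"))

#' Boundary enhancement mask
#'
#' Per-voxel loss weights concentrating training signal near the chamber
#' wall, derived from the unsigned distance `D(v)` (voxel units by default)
#' of every voxel to the boundary voxel set.
#'
#' @slot grid the [GridSpec-class].
#' @slot weights numeric array of positive weights.
#' @slot distance numeric array, distance-to-boundary field.
#' @slot mode `"peaked"` or `"literal"` (see [boundaryMask()]).
#' @export
setClass("BoundaryMask", representation(grid = "GridSpec", weights = "array",
                                        distance = "array", mode = "character"),
  validity = function(object) {
    if (any(!is.finite(object@weights)) || any(object@weights <= 0))
      return("mask weights must be positive and finite")
    TRUE
  })

#' Collection of generated atrium samples
#'
#' @slot samples list of lists with elements `shape` ([AtriumShape-class]) and
#'   `volume` ([OccupancyVolume-class]).
#' @slot trainIdx,testIdx integer indices of the train/test split.
#' @slot grid the common [GridSpec-class].
#' @slot seed the generator seed.
#' @export
setClass("AtriumDataset", representation(samples = "list", trainIdx = "integer",
                                         testIdx = "integer", grid = "GridSpec",
                                         seed = "integer"))
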
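# Mean-shape baseline and rigid PV-ostia registration: the voxel-wise
# average of training volumes defines both the no-learning reconstruction
# and the coordinate frame into which acquired point clouds are registered
# (by their tagged PV ostia, least squares, no scaling) before voxelization.

#' Compute the mean-shape baseline
#'
#' Voxel-wise arithmetic mean of the ground-truth occupancy volumes, its
#' binarization at 0.5 (ties kept), and the arithmetic mean of the per-shape
#' landmark positions.
#'
#' @param volumes list of [OccupancyVolume-class] on a common grid.
#' @param landmarkSets list of matching [LandmarkSet-class] objects.
#' @return A [MeanShape-class].
#' @export
computeMeanShape <- function(volumes, landmarkSets) {
  stopifnot(length(volumes) >= 1L, length(volumes) == length(landmarkSets))
  grid <- volumes[[1]]@grid
  acc <- array(0, grid@dims)
  for (v in volumes) {
    if (!identical(v@grid@dims, grid@dims) ||
        !isTRUE(all.equal(v@grid@spacing, grid@spacing)))
      stop("volumes are not on a common grid")
    acc <- acc + v@values
  }
  mf <- acc / length(volumes)
  nms <- rownames(landmarkSets[[1]]@coords)
  lm <- Reduce(`+`, lapply(landmarkSets, function(l) l@coords[nms, ])) /
    length(landmarkSets)
  new("MeanShape",
      meanField = ProbabilityVolume(mf, grid),
      binary = OccupancyVolume(array(as.numeric(mf >= 0.5), grid@dims), grid),
      landmarks = LandmarkSet(lm))
}

#' Least-squares rigid registration of corresponding point sets
#'
#' Finds the rotation and translation minimizing
#' `sum ||R s_i + t - t_i||^2` over matched source/target points, via the
#' SVD of the cross-covariance with reflection correction (no scaling).
#' Requires at least three non-collinear correspondences; rows are matched
#' by name when both matrices have rownames.
#'
#' @param source,target numeric matrices (n x 3), n >= 3.
#' @return A [RigidTransform-class].
#' @export
rigidRegister <- function(source, target) {
  if (!is.null(rownames(source)) && !is.null(rownames(target))) {
    if (!setequal(rownames(source), rownames(target)))
      stop("source/target point names do not match")
    target <- target[rownames(source), , drop = FALSE]
  }
  stopifnot(nrow(source) == nrow(target), nrow(source) >= 3L)
  cs <- colMeans(source); ct <- colMeans(target)
  S <- sweep(source, 2L, cs); T <- sweep(target, 2L, ct)
  sv <- svd(crossprod(S, T)) # H = S' T
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate (collinear) point configuration; rotation is not unique")
  R <- sv$v %*% diag(c(1, 1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  RigidTransform(R, ct - as.numeric(R %*% cs))
}

#' Apply a rigid transform to points or a point cloud
#'
#' Maps every point `p` to `R p + t`; labels are preserved.
#'
#' @param x a [PathPointCloud-class], [LandmarkSet-class] or n x 3 matrix.
#' @param transform a [RigidTransform-class].
#' @return Object of the same class as `x`.
#' @export
applyTransform <- function(x, transform) {
  tp <- function(P)
    sweep(P %*% t(transform@rotation), 2L, transform@translation, "+")
  if (is(x, "PathPointCloud")) {
    PathPointCloud(tp(x@points), x@segment, x@sourceId)
  } else if (is(x, "LandmarkSet")) {
    m <- tp(x@coords); rownames(m) <- rownames(x@coords); LandmarkSet(m)
  } else tp(x)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  RigidTransform(Rt, -as.numeric(Rt %*% transform@translation))
}

#' Preprocess a clinical-style point cloud into a network input volume
#'
#' Per-PV centroids of the physician-tagged points are rigidly registered to
#' the mean shape's PV ostia (least squares, 4 correspondences); the
#' transform is applied to the full cloud, which is then binned into an
#' occupancy volume on the network grid.  The output is invariant to rigid
#' motion of the input (cloud and tags moved together).
#'
#' @param cloud a [PathPointCloud-class] in acquisition coordinates (mm).
#' @param taggedPvPoints named list `PVLS/PVLI/PVRI/PVRS`, each an n x 3
#'   matrix (or xyz vector) of tagged points; each PV needs >= 1 point.
#' @param meanShape a [MeanShape-class] providing the target ostia.
#' @param grid [GridSpec-class] of the network input.
#' @return An [OccupancyVolume-class] with attribute `transform` (the
#'   [RigidTransform-class] used).
#' @export
preprocessClinical <- function(cloud, taggedPvPoints, meanShape,
                               grid = GridSpec()) {
  missing <- setdiff(PV_NAMES, names(taggedPvPoints))
  if (length(missing))
    stop("missing tagged points for vein(s): ", paste(missing, collapse = ", "))
  cent <- t(vapply(PV_NAMES, function(pv) {
    p <- taggedPvPoints[[pv]]
    if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
    if (nrow(p) < 1L) stop("missing tagged points for vein(s): ", pv)
    colMeans(p)
  }, numeric(3)))
  targets <- landmarkCoords(meanShape)[paste0("ostium_", PV_NAMES), ]
  rownames(targets) <- PV_NAMES
  tf <- rigidRegister(cent, targets)
  vol <- pathToVolume(applyTransform(cloud, tf), grid)
  attr(vol, "transform") <- tf
  vol
}

#' Reconstruction by the mean-shape baseline
#'
#' The baseline "reconstruction" is the same binarized mean volume for every
#' input (inputs are registered into the mean-shape frame beforehand).
#'
#' @param meanShape a [MeanShape-class].
#' @return The binarized mean [OccupancyVolume-class].
#' @export
meanShapePrediction <- function(meanShape) meanShape@binary
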
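# Grid geometry helpers shared across modules.

#' Voxel center coordinates along each axis
#'
#' @param grid a [GridSpec-class].
#' @return list with numeric vectors `x`, `y`, `z` of voxel center
#'   coordinates in mm.
#' @export
voxelAxes <- function(grid) {
  list(x = grid@origin[1] + (seq_len(grid@dims[1]) - 1L) * grid@spacing,
       y = grid@origin[2] + (seq_len(grid@dims[2]) - 1L) * grid@spacing,
       z = grid@origin[3] + (seq_len(grid@dims[3]) - 1L) * grid@spacing)
}

#' mm coordinates of voxel centers given linear indices
#'
#' @param grid a [GridSpec-class].
#' @param idx 1-based linear indices into the grid array.
#' @return numeric matrix (length(idx) x 3) of mm coordinates.
#' @export
voxelCenters <- function(grid, idx) {
  ijk <- arrayInd(idx, grid@dims)
  sweep(sweep(ijk - 1L, 2L, rep(grid@spacing, 3L), "*"), 2L, grid@origin, "+")
}

#' Nearest voxel (as array subscripts) for mm points
#'
#' @param grid a [GridSpec-class].
#' @param points numeric matrix (n x 3) of mm coordinates.
#' @return integer matrix (n x 3) of 1-based subscripts; points outside the
#'   grid produce subscripts outside `1..dims` (callers clip or error).
#' @export
pointsToVoxels <- function(grid, points) {
  s <- sweep(points, 2L, grid@origin, "-") / grid@spacing
  matrix(as.integer(round(s)), ncol = 3L) + 1L
}

subToLinear <- function(dims, sub) {
  as.integer(sub[, 1] + dims[1] * (sub[, 2] - 1L) +
             dims[1] * dims[2] * (sub[, 3] - 1L))
}

#' Boundary voxels of an occupancy volume
#'
#' A boundary voxel is occupied and has at least one empty 6-neighbour
#' (voxels on the grid border count their out-of-grid neighbours as empty).
#'
#' @param volume an [OccupancyVolume-class].
#' @return logical array marking boundary voxels.
#' @export
boundaryVoxels <- function(volume) {
  v <- volume@values
  d <- dim(v)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
  nfull <- padded[i - 1, j, k] + padded[i + 1, j, k] +
           padded[i, j - 1, k] + padded[i, j + 1, k] +
           padded[i, j, k - 1] + padded[i, j, k + 1]
  v == 1 & nfull < 6
}

#' Connected components of a binary array
#'
#' @param mask logical/0-1 array.
#' @param connectivity 6 or 26.
#' @return integer array of component labels (0 = background), with an
#'   attribute `sizes` giving voxel counts per label.
#' @export
labelComponents <- function(mask, connectivity = 6L) {
  stopifnot(connectivity %in% c(6L, 26L))
  lab <- .labelComponents3(as.logical(mask), as.integer(dim(mask)),
                           as.integer(connectivity))
  attr(lab, "sizes") <- tabulate(lab[lab > 0])
  lab
}

#' Is the occupied interior a single 6-connected component?
#'
#' @param volume an [OccupancyVolume-class].
#' @return logical scalar.
#' @export
isConnectedInterior <- function(volume) {
  lab <- labelComponents(volume@values == 1, 6L)
  length(attr(lab, "sizes")) == 1L && sum(volume@values) > 0
}
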
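# Catheter-like path simulation inside a voxelized atrium: entry points at
# the septum and the four PV ostia, a navigability-weighted traversal graph
# over interior voxels, Dijkstra routing septum -> PVLS -> PVLI -> PVRI ->
# PVRS, and stochastic augmentation of the resulting polyline into a
# realistic point cloud.

#' Locate interior entry voxels for the septum and PV ostia
#'
#' For each landmark, returns the center of the interior voxel nearest to
#' it.  Errors (naming the landmark) when no interior voxel lies within
#' `3 * spacing` of a landmark.
#'
#' @param shape an [AtriumShape-class] (supplies the landmarks).
#' @param volume the [OccupancyVolume-class] voxelized from the shape.
#' @return A [LandmarkSet-class] of entry points (voxel centers, mm), with
#'   attribute `voxel` holding the linear voxel index per entry.
#' @export
locateOstiaEntries <- function(shape, volume) {
  interior <- which(volume@values == 1)
  if (length(interior) == 0L) stop("volume has no interior voxels")
  centers <- voxelCenters(volume@grid, interior)
  lmNames <- c("septum", paste0("ostium_", PV_NAMES))
  entries <- matrix(0, length(lmNames), 3L,
                    dimnames = list(lmNames, c("x", "y", "z")))
  vox <- integer(length(lmNames))
  for (i in seq_along(lmNames)) {
    lm <- landmarkCoords(shape, lmNames[i])
    d2 <- colSums((t(centers) - lm)^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > 3 * volume@grid@spacing)
      stop(sprintf("no interior voxel within 3*spacing of landmark '%s'",
                   lmNames[i]))
    entries[i, ] <- centers[j, ]
    vox[i] <- interior[j]
  }
  out <- LandmarkSet(entries)
  attr(out, "voxel") <- setNames(vox, lmNames)
  out
}

#' Build the navigability-weighted interior traversal graph
#'
#' Nodes are interior voxels, edges join 26-neighbouring interior voxels.
#' The cost of a step is its Euclidean length times
#' `1 + w / (1 + dWall(midpoint))`, with `dWall` the mm distance to the
#' nearest wall (boundary) voxel, taken as the mean of the endpoint wall
#' distances.  `w = 0` gives plain geometric shortest paths; `w > 0`
#' penalizes wall-hugging so routes curve toward the chamber center.
#'
#' @param volume an [OccupancyVolume-class] with a connected interior.
#' @param navigabilityWeight nonnegative scalar `w`.
#' @return A [TraversalGraph-class].
#' @export
buildTraversalGraph <- function(volume, navigabilityWeight = 2) {
  stopifnot(navigabilityWeight >= 0)
  v <- volume@values
  dims <- dim(v)
  interior <- which(v == 1)
  if (length(interior) == 0L) stop("volume has no interior voxels")
  lab <- labelComponents(v == 1, 26L)
  sizes <- attr(lab, "sizes")
  if (length(sizes) > 1L)
    stop(sprintf("interior is disconnected (component sizes: %s)",
                 paste(sort(sizes, decreasing = TRUE), collapse = ", ")))
  nodeOf <- array(0L, dims)
  nodeOf[interior] <- seq_along(interior)
  bnd <- boundaryVoxels(volume)
  dwall <- .edt3(bnd, as.integer(dims), rep(volume@grid@spacing, 3L))
  wallDist <- dwall[interior]
  sub <- arrayInd(interior, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep each undirected pair once (lexicographically positive offsets)
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  from <- integer(0); to <- integer(0); len <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sub + matrix(offs[r, ], nrow(sub), 3L, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] & nb[, 2] >= 1L &
          nb[, 2] <= dims[2] & nb[, 3] >= 1L & nb[, 3] <= dims[3]
    nbl <- subToLinear(dims, nb[ok, , drop = FALSE])
    tgt <- nodeOf[nbl]
    hit <- tgt > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, tgt[hit])
    len <- c(len, rep(sqrt(sum(offs[r, ]^2)) * volume@grid@spacing,
                      sum(hit)))
  }
  mid <- (wallDist[from] + wallDist[to]) / 2
  costs <- len * (1 + navigabilityWeight / (1 + mid))
  new("TraversalGraph", nodes = as.integer(interior),
      edges = cbind(from = from, to = to), costs = costs,
      wallDist = wallDist, grid = volume@grid)
}

#' Shortest path between two voxels of a traversal graph
#'
#' Dijkstra's algorithm with a deterministic tie-break: among equal-cost
#' shortest paths, each node's predecessor is the smallest-index neighbour
#' achieving its distance, so results are byte-stable across platforms.
#'
#' @param graph a [TraversalGraph-class].
#' @param src,dst linear voxel indices (must be graph nodes).
#' @return list with `path` (linear voxel indices, src first) and `cost`.
#' @export
shortestPath <- function(graph, src, dst) {
  nodeIdx <- match(c(src, dst), graph@nodes)
  if (any(is.na(nodeIdx)))
    stop("src/dst are not interior voxels of the graph")
  if (src == dst)
    return(list(path = as.integer(src), cost = 0))
  res <- .dijkstraPath(length(graph@nodes),
                       as.integer(graph@edges[, 1] - 1L),
                       as.integer(graph@edges[, 2] - 1L),
                       graph@costs, nodeIdx[1] - 1L, nodeIdx[2] - 1L)
  if (!res$reachable)
    stop("destination voxel is unreachable from the source")
  list(path = graph@nodes[res$path], cost = res$cost)
}

#' Compose the full septum-to-PVRS traversal path
#'
#' Concatenates the four Dijkstra legs septum->PVLS, PVLS->PVLI, PVLI->PVRI
#' and PVRI->PVRS (duplicate junction voxels dropped), converting voxel
#' centers to mm and labelling every point with its leg.
#'
#' @param shape an [AtriumShape-class].
#' @param volume its [OccupancyVolume-class].
#' @param navigabilityWeight see [buildTraversalGraph()].
#' @param graph optionally a prebuilt [TraversalGraph-class] for `volume`.
#' @return A [PathPointCloud-class] whose points are interior voxel centers.
#' @export
composePath <- function(shape, volume, navigabilityWeight = 2, graph = NULL) {
  entries <- locateOstiaEntries(shape, volume)
  vox <- attr(entries, "voxel")
  if (is.null(graph))
    graph <- buildTraversalGraph(volume, navigabilityWeight)
  stops <- c("septum", paste0("ostium_", PV_NAMES))
  pts <- NULL; seg <- character(0)
  for (leg in seq_len(4L)) {
    res <- tryCatch(shortestPath(graph, vox[stops[leg]], vox[stops[leg + 1]]),
                    error = function(e)
                      stop(sprintf("leg %s unreachable: %s",
                                   SEGMENT_LEVELS[leg], conditionMessage(e))))
    idx <- res$path
    if (leg > 1L) idx <- idx[-1L] # drop duplicated junction voxel
    pts <- rbind(pts, voxelCenters(volume@grid, idx))
    seg <- c(seg, rep(SEGMENT_LEVELS[leg], length(idx)))
  }
  PathPointCloud(pts, seg, sourceId = shape@id)
}

#' Augment a simulated path into a realistic catheter point cloud
#'
#' Around every path point, draws `n` isotropic Gaussian samples
#' (`sd = sigma` mm), keeps each independently with probability `sF`,
#' discards samples outside the ground-truth mesh, then jitters the
#' survivors by a Gaussian displacement of scale `muS` mm.  The jitter is
#' applied after the interior filter, so augmented clouds may slightly exit
#' the chamber, as a catheter pushing the wall does.  The original path
#' points are always retained.  Deterministic for a fixed `cfg@seed`.
#'
#' @param path a [PathPointCloud-class].
#' @param shape the [AtriumShape-class] the path lives in.
#' @param cfg an [AugmentationConfig-class].
#' @return A [PathPointCloud-class] with added `augmentation`-labelled points.
#' @export
augmentPath <- function(path, shape, cfg) {
  validObject(cfg)
  nP <- nrow(path@points)
  if (cfg@n == 0L || cfg@sF == 0) return(path)
  withLocalSeed(cfg@seed, {
    base <- path@points[rep(seq_len(nP), each = cfg@n), , drop = FALSE]
    samples <- base + matrix(rnorm(3L * nrow(base), sd = cfg@sigma),
                             ncol = 3L)
    keep <- runif(nrow(samples)) < cfg@sF
    samples <- samples[keep, , drop = FALSE]
    if (nrow(samples) > 0L) {
      inside <- .pointsInMesh(samples, shape@mesh@vertices, shape@mesh@faces)
      samples <- samples[inside, , drop = FALSE]
    }
    if (nrow(samples) > 0L && cfg@muS > 0)
      samples <- samples + matrix(rnorm(3L * nrow(samples)), ncol = 3L) * cfg@muS
    if (nrow(samples) == 0L) return(path)
    PathPointCloud(rbind(path@points, samples),
                   c(path@segment, rep("augmentation", nrow(samples))),
                   sourceId = path@sourceId)
  })
}

#' Bin a point cloud into a path occupancy volume
#'
#' Marks every voxel containing at least one point (nearest-voxel-center
#' binning).  Points outside the grid are clipped with a message giving the
#' count; if all points fall outside, an error is raised.
#'
#' @param path a [PathPointCloud-class] (or plain n x 3 matrix).
#' @param grid a [GridSpec-class].
#' @return An [OccupancyVolume-class] marking traversed voxels.
#' @export
pathToVolume <- function(path, grid) {
  pts <- if (is(path, "PathPointCloud")) path@points else path
  sub <- pointsToVoxels(grid, pts)
  ok <- sub[, 1] >= 1L & sub[, 1] <= grid@dims[1] &
        sub[, 2] >= 1L & sub[, 2] <= grid@dims[2] &
        sub[, 3] >= 1L & sub[, 3] <= grid@dims[3]
  if (!any(ok)) stop("all path points fall outside the grid")
  if (any(!ok))
    message(sprintf("pathToVolume: clipped %d point(s) outside the grid",
                    sum(!ok)))
  v <- array(0, grid@dims)
  v[subToLinear(grid@dims, sub[ok, , drop = FALSE])] <- 1
  OccupancyVolume(v, grid)
}
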
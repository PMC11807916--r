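# Evaluation: iso-surface mesh extraction from (probability) volumes and the
# metric suite -- radius-restricted symmetric surface-to-surface distances
# around the PV ostia, Hausdorff distance, and the paired one-tailed t-test
# against the mean-shape baseline.

#' Extract the iso-surface mesh of a volume
#'
#' Marching-tetrahedra iso-surface of the voxel field at `iso` (default
#' 0.5), in mm coordinates.  The field is padded with a zero layer so
#' surfaces touching the grid border close; only the largest connected
#' component is kept.  Errors when no voxel value crosses the iso level.
#'
#' @param volume a [ProbabilityVolume-class] or [OccupancyVolume-class].
#' @param iso iso level in (0, 1).
#' @param keepLargest retain only the largest connected component (default);
#'   set FALSE to keep every component (e.g. for solids with cavities).
#' @return A [TriMesh-class].
#' @export
extractMesh <- function(volume, iso = 0.5, keepLargest = TRUE) {
  v <- volume@values
  if (min(v) >= iso || max(v) < iso)
    stop("volume does not cross the iso level; no surface to extract")
  d <- dim(v) + 2L
  padded <- array(0, d)
  padded[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- v
  ax <- voxelAxes(volume@grid)
  sp <- volume@grid@spacing
  mm <- .marchingTets(padded, d,
                      c(ax$x[1] - sp, ax$x, tail(ax$x, 1) + sp),
                      c(ax$y[1] - sp, ax$y, tail(ax$y, 1) + sp),
                      c(ax$z[1] - sp, ax$z, tail(ax$z, 1) + sp), iso)
  if (nrow(mm$faces) == 0L) stop("empty iso-surface")
  keep <- if (keepLargest) {
    comp <- .meshFaceComponents(mm$faces, nrow(mm$vertices))
    comp == which.max(tabulate(comp))
  } else rep(TRUE, nrow(mm$faces))
  faces <- mm$faces[keep, , drop = FALSE]
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(mm$vertices)); remap[used] <- seq_along(used)
  TriMesh(mm$vertices[used, , drop = FALSE],
          matrix(remap[faces], ncol = 3L))
}

restrictVertices <- function(verts, interestPoints, radius) {
  if (!is.finite(radius)) return(seq_len(nrow(verts)))
  keep <- rep(FALSE, nrow(verts))
  for (i in seq_len(nrow(interestPoints))) {
    d2 <- colSums((t(verts) - interestPoints[i, ])^2)
    keep <- keep | d2 <= radius^2
  }
  which(keep)
}

#' Radius-restricted symmetric surface distance
#'
#' Mean nearest-vertex distance between two meshes, restricted to vertices
#' within `radius` mm of at least one of the four PV ostium interest points
#' (the union of balls; `radius = Inf` disables the restriction).  Both
#' directions are computed over their restricted source vertex sets against
#' the full other mesh; the symmetric value is the average of the two
#' directional means.
#'
#' @param a,b [TriMesh-class] objects (e.g. reconstruction and ground truth).
#' @param interestPoints a [LandmarkSet-class] (its four `ostium_*` points
#'   are used) or an n x 3 matrix of interest points.
#' @param radius restriction radius in mm, or `Inf` for unbounded.
#' @return list with `mean`, `sd`, `n` (symmetric, i.e. pooled over both
#'   directions), and per-direction means `meanAB`, `meanBA`; entries are
#'   `NA` (with `n = 0`) when no vertex falls inside the radius.
#' @export
symmetricSurfaceDistance <- function(a, b, interestPoints = NULL,
                                     radius = Inf) {
  if (is(interestPoints, "LandmarkSet"))
    interestPoints <- interestPoints@coords[paste0("ostium_", PV_NAMES), ,
                                            drop = FALSE]
  if (is.null(interestPoints) && is.finite(radius))
    stop("a finite radius requires interest points")
  ia <- restrictVertices(a@vertices, interestPoints, radius)
  ib <- restrictVertices(b@vertices, interestPoints, radius)
  if (length(ia) == 0L || length(ib) == 0L)
    return(list(mean = NA_real_, sd = NA_real_, n = 0L,
                meanAB = NA_real_, meanBA = NA_real_))
  dab <- .nearestVertexDist(a@vertices[ia, , drop = FALSE], b@vertices)
  dba <- .nearestVertexDist(b@vertices[ib, , drop = FALSE], a@vertices)
  list(mean = (mean(dab) + mean(dba)) / 2,
       sd = sd(c(dab, dba)), n = length(dab) + length(dba),
       meanAB = mean(dab), meanBA = mean(dba))
}

#' Hausdorff distance between two meshes
#'
#' Maximum over both directions of the maximal nearest-vertex distance.
#'
#' @param a,b [TriMesh-class] objects.
#' @return distance in mm.
#' @export
hausdorffDistance <- function(a, b) {
  max(max(.nearestVertexDist(a@vertices, b@vertices)),
      max(.nearestVertexDist(b@vertices, a@vertices)))
}

#' Paired one-tailed t-test for error improvement
#'
#' Tests whether the baseline's per-case errors exceed the method's, i.e.
#' the one-tailed paired t-test of `mean(baseline - method) > 0`, returning
#' the exact Student-t tail probability.  With zero variance of the
#' differences the test degenerates: p is 0 when the method is uniformly
#' better, 1 when uniformly worse, and 0.5 when the lists are identical.
#'
#' @param methodErrors,baselineErrors equal-length (>= 2) numeric vectors of
#'   per-case errors, paired by case.
#' @return p-value.
#' @export
pairedOneTailedTTest <- function(methodErrors, baselineErrors) {
  stopifnot(length(methodErrors) == length(baselineErrors),
            length(methodErrors) >= 2L)
  d <- baselineErrors - methodErrors
  if (sd(d) == 0) {
    if (mean(d) > 0) return(0)
    if (mean(d) < 0) return(1)
    return(0.5)
  }
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  pt(tstat, df = n - 1, lower.tail = FALSE)
}

#' Benchmark a set of reconstructions against ground truth
#'
#' Computes, per method and restriction radius, the across-case mean and
#' standard deviation of the symmetric surface distance, the mean Hausdorff
#' distance, and the paired one-tailed p-value versus the mean-shape
#' baseline (when a method named `"mean_shape"` is present).
#'
#' @param reconstructions named list (one entry per method) of lists of
#'   [TriMesh-class] reconstructions, matched by position to ground truth.
#' @param groundTruths list of ground-truth [TriMesh-class] objects.
#' @param landmarkSets list of [LandmarkSet-class] (interest points per case).
#' @param radii numeric vector of restriction radii in mm (Inf = unbounded).
#' @param baseline name of the baseline method for p-values.
#' @return `data.frame` with columns method, radius_mm, mean_mm, std_mm,
#'   p_value, hausdorff_mm; attribute `perCase` holds the per-case distance
#'   matrices.
#' @export
evaluateBenchmark <- function(reconstructions, groundTruths, landmarkSets,
                              radii = c(10, 15, 20, 25, Inf),
                              baseline = "mean_shape") {
  nCase <- length(groundTruths)
  stopifnot(nCase >= 1L, length(landmarkSets) == nCase)
  for (m in names(reconstructions))
    if (length(reconstructions[[m]]) != nCase)
      stop(sprintf("method '%s' has %d reconstructions for %d cases", m,
                   length(reconstructions[[m]]), nCase))
  perCase <- list()
  for (m in names(reconstructions)) {
    dmat <- matrix(NA_real_, nCase, length(radii),
                   dimnames = list(NULL, paste0("r", radii)))
    hd <- numeric(nCase)
    for (i in seq_len(nCase)) {
      a <- reconstructions[[m]][[i]]; b <- groundTruths[[i]]
      # nearest-vertex profiles once per case; radius restriction then only
      # selects which source vertices enter the mean
      dab <- .nearestVertexDist(a@vertices, b@vertices)
      dba <- .nearestVertexDist(b@vertices, a@vertices)
      ip <- landmarkSets[[i]]@coords[paste0("ostium_", PV_NAMES), ,
                                     drop = FALSE]
      for (j in seq_along(radii)) {
        ia <- restrictVertices(a@vertices, ip, radii[j])
        ib <- restrictVertices(b@vertices, ip, radii[j])
        if (length(ia) && length(ib))
          dmat[i, j] <- (mean(dab[ia]) + mean(dba[ib])) / 2
      }
      hd[i] <- max(max(dab), max(dba))
    }
    perCase[[m]] <- list(dist = dmat, hausdorff = hd)
  }
  rows <- list()
  for (m in names(reconstructions)) {
    for (j in seq_along(radii)) {
      errs <- perCase[[m]]$dist[, j]
      p <- if (m != baseline && baseline %in% names(perCase) &&
               nCase >= 2L && !anyNA(errs))
        pairedOneTailedTTest(errs, perCase[[baseline]]$dist[, j])
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, radius_mm = radii[j], mean_mm = mean(errs),
        std_mm = sd(errs), p_value = p,
        hausdorff_mm = mean(perCase[[m]]$hausdorff))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "perCase") <- perCase
  out
}
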
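# Construction of atrium-like shapes from generator parameters.
#
# The shape is the zero level set of an analytic signed-distance-style field:
# a gently bent ellipsoidal chamber body, four capsule PV tubes anchored at
# the body wall, and a spherical appendage bump, combined with a log-sum-exp
# soft minimum (blend width 4 mm) so junctions are smooth.  The surface is
# extracted by marching tetrahedra on the field sampled at `meshRes` mm,
# independent of the (much coarser) training grid.

BLEND_W <- 4 # mm, soft-union blend width

# signed distance to a bent ellipsoid (approximate but sign-exact);
# p is an n x 3 matrix
sdfBody <- function(p, a, bend) {
  y <- p[, 2] - bend * (p[, 3] / a[3])^2
  q1 <- p[, 1] / a[1]; q2 <- y / a[2]; q3 <- p[, 3] / a[3]
  k0 <- sqrt(q1^2 + q2^2 + q3^2)
  k1 <- sqrt((q1 / a[1])^2 + (q2 / a[2])^2 + (q3 / a[3])^2)
  d <- ifelse(k1 > 0, k0 * (k0 - 1) / k1, -min(a))
  d
}

sdfCapsule <- function(p, A, B, r) {
  ba <- B - A
  pa <- sweep(p, 2L, A, "-")
  h <- pmin(1, pmax(0, (pa %*% ba) / sum(ba^2)))
  d <- pa - outer(as.numeric(h), ba)
  sqrt(rowSums(d^2)) - r
}

sdfSphere <- function(p, C, r) {
  sqrt(rowSums(sweep(p, 2L, C, "-")^2)) - r
}

# log-sum-exp soft minimum across the columns of a matrix of distances
softMin <- function(D, w = BLEND_W) {
  m <- do.call(pmin, as.data.frame(D))
  m - w * log(rowSums(exp(-(D - m) / w)))
}

# distance from the origin to the body surface along unit direction `dir`
raySurface <- function(sdfFun, dir, tMax = 90) {
  f <- function(t) sdfFun(matrix(dir * t, 1L))
  if (f(0) >= 0) stop("ray origin is not interior")
  stats::uniroot(f, c(0, tMax), tol = 1e-8)$root
}

# assemble the blended field + landmark geometry for a parameter vector
atriumField <- function(params) {
  gp <- function(nm) unname(params[nm])
  a <- c(gp("body_a"), gp("body_b"), gp("body_c"))
  bend <- gp("bend_amp")
  body <- function(p) sdfBody(p, a, bend)
  tubes <- lapply(PV_NAMES, function(pv) {
    dir <- dirFromAngles(gp(paste0(pv, "_theta")), gp(paste0(pv, "_phi")))
    tSurf <- raySurface(body, dir)
    A <- dir * (tSurf - 4)          # embedded anchor for a clean blend
    B <- dir * (tSurf - 4 + gp(paste0(pv, "_length")))
    list(name = pv, dir = dir, tSurf = tSurf, A = A, B = B,
         r = gp(paste0(pv, "_radius")))
  })
  names(tubes) <- PV_NAMES
  appDir <- dirFromAngles(gp("app_theta"), gp("app_phi"))
  appSurf <- raySurface(body, appDir)
  appC <- appDir * appSurf
  appR <- 0.8 * gp("app_size")
  septDir <- dirFromAngles(gp("sept_theta"), gp("sept_phi"))
  sdf <- function(p) {
    D <- cbind(body(p),
               do.call(cbind, lapply(tubes, function(tb)
                 sdfCapsule(p, tb$A, tb$B, tb$r))),
               sdfSphere(p, appC, appR))
    softMin(D)
  }
  list(sdf = sdf, body = body, tubes = tubes, appDir = appDir, appC = appC,
       appR = appR, septDir = septDir, a = a)
}

# surface landmark: root of the blended field along origin + base + t * dir
surfacePoint <- function(sdf, base, dir, tMax = 60) {
  f <- function(t) sdf(matrix(base + dir * t, 1L))
  lo <- 0
  if (f(0) >= 0) stop("landmark ray does not start inside the shape")
  hi <- tMax
  while (f(hi) < 0 && hi < 400) hi <- hi * 2
  t0 <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  base + dir * t0
}

# a unit vector perpendicular to dir, chosen deterministically
perpDir <- function(dir) {
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- c(dir[2] * ref[3] - dir[3] * ref[2],
         dir[3] * ref[1] - dir[1] * ref[3],
         dir[1] * ref[2] - dir[2] * ref[1])
  v / sqrt(sum(v^2))
}

shapeRejection <- function(msg) {
  structure(class = c("atriareconShapeRejection", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Build an atrium-like mesh from generator parameters
#'
#' Constructs the watertight triangular surface of a chamber with four PV
#' tubes and an appendage bump, and places the five mandatory landmarks:
#' each PV ostium on the surface rim where its tube meets the chamber body,
#' and the septum point on the right-posterior body wall.  Degenerate
#' parameter combinations whose surface is not a single closed genus-0 mesh
#' raise a rejection condition (class `atriareconShapeRejection`) so that
#' callers can resample.
#'
#' @param params named numeric parameter vector (see [defaultShapeModel()]).
#' @param meshRes sampling pitch of the field in mm (mesh resolution).
#' @param id identifier stored on the shape.
#' @return An [AtriumShape-class].
#' @examples
#' shape <- buildAtrium(defaultShapeModel()@mean, meshRes = 3)
#' shape
#' @export
buildAtrium <- function(params, meshRes = 1, id = "shape") {
  geom <- atriumField(params)
  reach <- max(geom$a) + 2
  for (tb in geom$tubes)
    reach <- max(reach, max(abs(c(tb$B - tb$r - BLEND_W, tb$B + tb$r + BLEND_W))))
  reach <- max(reach, max(abs(geom$appC)) + geom$appR + BLEND_W)
  reach <- reach + 2 * meshRes
  n <- ceiling(2 * reach / meshRes) + 1L
  ax <- seq(-reach, reach, length.out = n)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  fld <- geom$sdf(pts)
  mm <- .marchingTets(fld, c(n, n, n), ax, ax, ax, 0)
  if (nrow(mm$faces) == 0L) stop(shapeRejection("empty surface"))
  comp <- .meshFaceComponents(mm$faces, nrow(mm$vertices))
  sizes <- tabulate(comp)
  keep <- comp == which.max(sizes)
  faces <- mm$faces[keep, , drop = FALSE]
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(mm$vertices)); remap[used] <- seq_along(used)
  faces <- matrix(remap[faces], ncol = 3L)
  verts <- mm$vertices[used, , drop = FALSE]
  audit <- .meshEdgeAudit(faces, nrow(verts))
  if (!audit$closed)
    stop(shapeRejection("surface is not watertight"))
  euler <- nrow(verts) - audit$nEdges + nrow(faces)
  if (euler != 2)
    stop(shapeRejection(sprintf("surface is not genus 0 (Euler %d)", euler)))
  lm <- list()
  for (pv in PV_NAMES) {
    tb <- geom$tubes[[pv]]
    base <- tb$dir * tb$tSurf
    lm[[paste0("ostium_", pv)]] <-
      surfacePoint(geom$sdf, base, perpDir(tb$dir))
  }
  lm[["septum"]] <- surfacePoint(geom$sdf, c(0, 0, 0), geom$septDir)
  lm[["appendage"]] <- surfacePoint(geom$sdf, c(0, 0, 0), geom$appDir)
  AtriumShape(TriMesh(mm$vertices[used, , drop = FALSE], faces),
              LandmarkSet(lm), params = params, id = id)
}

#' Voxelize a closed mesh onto a grid
#'
#' Marks every voxel whose center lies inside the mesh.  Inside testing uses
#' parity counting along voxel columns with deterministically jittered rays
#' (robust for watertight meshes in general position).
#'
#' @param shape an [AtriumShape-class] or [TriMesh-class].
#' @param grid a [GridSpec-class]; the mesh must fit inside the grid extent.
#' @return An [OccupancyVolume-class].
#' @examples
#' shape <- buildAtrium(defaultShapeModel()@mean, meshRes = 3)
#' vol <- voxelizeShape(shape, GridSpec())
#' vol
#' @export
voxelizeShape <- function(shape, grid) {
  mesh <- if (is(shape, "AtriumShape")) shape@mesh else shape
  ax <- voxelAxes(grid)
  lo <- c(ax$x[1], ax$y[1], ax$z[1]) - grid@spacing / 2
  hi <- c(tail(ax$x, 1), tail(ax$y, 1), tail(ax$z, 1)) + grid@spacing / 2
  vr <- apply(mesh@vertices, 2L, range)
  for (d in 1:3)
    if (vr[1, d] < lo[d] || vr[2, d] > hi[d])
      stop(sprintf("mesh exceeds the grid extent along the %s axis",
                   c("x", "y", "z")[d]))
  occ <- .voxelizeMesh(mesh@vertices, mesh@faces, ax$x, ax$y, ax$z)
  OccupancyVolume(array(as.numeric(occ), dim = grid@dims), grid)
}

#' Generate a dataset of synthetic atria with occupancy volumes
#'
#' Repeatedly samples parameters from the shape model, keeps draws passing
#' the plausibility filter, builds the mesh (resampling on degenerate
#' geometry), voxelizes it, and requires the voxel interior to be one
#' 6-connected component.  Produces exactly `nTrain + nTest` accepted
#' samples, split disjointly, reproducibly for a fixed seed.
#'
#' @param nTrain,nTest number of training / test samples (nTest may be 0).
#' @param model a [ShapeModelSpec-class].
#' @param grid a [GridSpec-class] for the occupancy volumes.
#' @param seed integer seed.
#' @param meshRes mesh sampling pitch in mm.
#' @return An [AtriumDataset-class].
#' @examples
#' ds <- generateDataset(2, 1, defaultShapeModel(), GridSpec(24, 5),
#'                       seed = 7, meshRes = 3)
#' ds
#' @export
generateDataset <- function(nTrain, nTest, model = defaultShapeModel(),
                            grid = GridSpec(), seed = 1L, meshRes = 1) {
  stopifnot(nTrain >= 1L, nTest >= 0L)
  needed <- nTrain + nTest
  samples <- vector("list", needed)
  accepted <- 0L
  attempts <- 0L
  while (accepted < needed) {
    attempts <- attempts + 1L
    if (attempts > 1e5L ||
        (attempts >= 1e4L && accepted / attempts < 0.01))
      stop("shape acceptance rate below 1%; check the shape model spec")
    aseed <- (as.integer(seed) * 10007L + attempts) %% .Machine$integer.max
    params <- sampleShapeParams(model, aseed)
    if (!isPlausible(params, model)) next
    shape <- tryCatch(
      buildAtrium(params, meshRes = meshRes,
                  id = sprintf("atrium_%d_%05d", as.integer(seed), attempts)),
      atriareconShapeRejection = function(e) NULL)
    if (is.null(shape)) next
    vol <- tryCatch(voxelizeShape(shape, grid), error = function(e) NULL)
    if (is.null(vol) || sum(vol@values) == 0 || !isConnectedInterior(vol)) next
    accepted <- accepted + 1L
    samples[[accepted]] <- list(shape = shape, volume = vol)
  }
  new("AtriumDataset", samples = samples, trainIdx = seq_len(nTrain),
      testIdx = as.integer(nTrain + seq_len(nTest)), grid = grid,
      seed = as.integer(seed))
}
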
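# Statistical shape model: a multivariate normal over the generator
# parameters, with a Mahalanobis-distance plausibility filter.  The defaults
# below are fixed, documented choices producing plausible atrium-like shapes
# (chamber body ~55-65 mm across, 4 PV tubes of 5-8 mm radius, an appendage
# bump); they are not learned from imaging data.

# Parameter vector layout (all numeric, named):
#   body_a, body_b, body_c   ellipsoid semi-axes, mm
#   bend_amp                 posterior bend amplitude of the body, mm
#   <PV>_theta, <PV>_phi     ostium direction (polar/azimuth, radians)
#   <PV>_radius, <PV>_length tube radius / length, mm
#   app_theta, app_phi       appendage direction
#   app_size                 appendage bump radius, mm
#   sept_theta, sept_phi     septum direction (landmark placement)
# Coordinate convention: +x toward the patient's left, +y posterior,
# +z superior.

shapeParamNames <- function() {
  pv <- unlist(lapply(PV_NAMES, function(p)
    paste0(p, c("_theta", "_phi", "_radius", "_length"))))
  c("body_a", "body_b", "body_c", "bend_amp", pv,
    "app_theta", "app_phi", "app_size", "sept_theta", "sept_phi")
}

# direction unit vector from polar angle theta (from +z) and azimuth phi
# (in the xy-plane from +x)
dirFromAngles <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

anglesFromDir <- function(d) {
  d <- d / sqrt(sum(d^2))
  c(theta = acos(d[3]), phi = atan2(d[2], d[1]))
}

#' Default statistical shape model
#'
#' Returns the package's default [ShapeModelSpec-class]: a multivariate
#' normal over 25 generator parameters (chamber semi-axes, body bend, four
#' PV tube direction/radius/length blocks, appendage, septum direction) with
#' a diagonal covariance and a plausibility threshold of Mahalanobis
#' distance 3.
#'
#' @param sdScale multiplies all default standard deviations (0 gives a
#'   degenerate model that always returns the mean shape).
#' @param threshold Mahalanobis-distance plausibility threshold.
#' @return A [ShapeModelSpec-class].
#' @examples
#' model <- defaultShapeModel()
#' length(model@mean)
#' @export
defaultShapeModel <- function(sdScale = 1, threshold = 3) {
  nm <- shapeParamNames()
  mu <- setNames(numeric(length(nm)), nm)
  sdv <- setNames(numeric(length(nm)), nm)
  mu[c("body_a", "body_b", "body_c")] <- c(32, 26, 24)
  sdv[c("body_a", "body_b", "body_c")] <- c(2.5, 2.0, 2.0)
  mu["bend_amp"] <- 4;  sdv["bend_amp"] <- 1.5
  pvDirs <- list(
    PVLS = c( 0.72, 0.38,  0.58), PVLI = c( 0.80, 0.40, -0.45),
    PVRI = c(-0.78, 0.47, -0.42), PVRS = c(-0.72, 0.45,  0.53))
  for (p in PV_NAMES) {
    ang <- anglesFromDir(pvDirs[[p]])
    mu[paste0(p, "_theta")] <- ang["theta"]
    mu[paste0(p, "_phi")] <- ang["phi"]
    mu[paste0(p, "_radius")] <- 6.5
    mu[paste0(p, "_length")] <- 15
    sdv[paste0(p, c("_theta", "_phi"))] <- 0.10
    sdv[paste0(p, "_radius")] <- 0.7
    sdv[paste0(p, "_length")] <- 0      # fixed: tube length at the mean
  }
  angApp <- anglesFromDir(c(0.55, -0.65, 0.52))
  mu["app_theta"] <- angApp["theta"]; mu["app_phi"] <- angApp["phi"]
  mu["app_size"] <- 10
  sdv[c("app_theta", "app_phi")] <- 0  # fixed: appendage direction at mean
  sdv["app_size"] <- 1.5
  angSep <- anglesFromDir(c(-0.62, 0.72, -0.31))
  mu["sept_theta"] <- angSep["theta"]; mu["sept_phi"] <- angSep["phi"]
  sdv[c("sept_theta", "sept_phi")] <- 0 # fixed: septum direction at mean
  # 17 parameters vary; the rest are pinned to the mean so that the
  # Mahalanobis-3 plausibility gate keeps a workable fraction (~6%) of draws
  cov <- diag((sdv * sdScale)^2)
  dimnames(cov) <- list(nm, nm)
  new("ShapeModelSpec", mean = mu, covariance = cov, threshold = threshold)
}

# symmetric matrix square root via eigendecomposition; errors on
# meaningfully negative eigenvalues (non-PSD covariance)
covSqrt <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  if (min(e$values) < -tol)
    stop("covariance is not positive semi-definite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Sample generator parameters from the shape model
#'
#' Draws one parameter vector from the model's multivariate normal.  The
#' draw is deterministic for a fixed `(model, seed)` pair.
#'
#' @param model a [ShapeModelSpec-class].
#' @param seed integer seed.
#' @return named numeric parameter vector.
#' @examples
#' p <- sampleShapeParams(defaultShapeModel(), seed = 1)
#' p["body_a"]
#' @export
sampleShapeParams <- function(model, seed) {
  L <- covSqrt(model@covariance)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  z <- rnorm(length(model@mean))
  setNames(as.numeric(model@mean + L %*% z), names(model@mean))
}

# save/restore the global RNG state so seeded package internals do not
# disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# run expr with a locally seeded RNG, restoring the caller's stream after
withLocalSeed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  expr
}

#' Plausibility score of a parameter vector
#'
#' Returns the multivariate-normal log-density of `params` under the model,
#' up to an additive constant: `-0.5 * Mahalanobis(params, mean)^2`.  Higher
#' is more plausible; the model mean attains the maximum (0).  For singular
#' covariances the Mahalanobis distance uses the pseudo-inverse, and
#' directions outside the covariance's range make a sample implausible
#' (-Inf) unless the deviation in those directions is zero.
#'
#' @param params named numeric parameter vector.
#' @param model a [ShapeModelSpec-class].
#' @return scalar score (<= 0).
#' @seealso [isPlausible()]
#' @export
plausibilityScore <- function(params, model) {
  stopifnot(all(is.finite(params)))
  d <- as.numeric(params) - as.numeric(model@mean)
  e <- eigen(model@covariance, symmetric = TRUE)
  tol <- 1e-10 * max(abs(e$values), 1)
  pos <- e$values > tol
  proj <- t(e$vectors) %*% d
  if (any(!pos & abs(proj) > 1e-8)) return(-Inf)
  m2 <- sum(proj[pos]^2 / e$values[pos])
  -0.5 * m2
}

#' @rdname plausibilityScore
#' @return `isPlausible` returns TRUE when the Mahalanobis distance from the
#'   model mean is at most `model@threshold`.
#' @export
isPlausible <- function(params, model) {
  s <- plausibilityScore(params, model)
  s >= -0.5 * model@threshold^2
}
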
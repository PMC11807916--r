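# Shared I/O: volumes as NIfTI (spacing/origin in the header), point clouds
# as CSV (x_mm, y_mm, z_mm, segment) or ASCII PLY, landmarks and transforms
# as JSON, run configuration as YAML.

#' Write a volume to a NIfTI file
#'
#' Binary occupancy volumes are stored as 8-bit integers, probability
#' volumes as 32-bit float; spacing and origin go into the header.
#'
#' @param volume an [OccupancyVolume-class] or [ProbabilityVolume-class].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  sp <- volume@grid@spacing
  img <- RNifti::asNifti(volume@values)
  RNifti::pixdim(img) <- rep(sp, 3L)
  aff <- diag(c(rep(sp, 3L), 1))
  aff[1:3, 4] <- volume@grid@origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  dt <- if (is(volume, "OccupancyVolume")) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a volume from a NIfTI file
#'
#' @param path NIfTI file written by [writeVolume()] (or compatible).
#' @param expectGrid optional [GridSpec-class]; a dims mismatch errors and a
#'   spacing mismatch warns (no resampling is attempted).
#' @return [OccupancyVolume-class] if the data are binary, otherwise
#'   [ProbabilityVolume-class].
#' @export
readVolume <- function(path, expectGrid = NULL) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)[1]
  aff <- RNifti::xform(img)
  origin <- as.numeric(aff[1:3, 4])
  grid <- GridSpec(dim(vals), spacing = sp, origin = origin)
  if (!is.null(expectGrid)) {
    if (!identical(as.integer(dim(vals)), expectGrid@dims))
      stop(sprintf("volume is %s but %s expected",
                   paste(dim(vals), collapse = "x"),
                   paste(expectGrid@dims, collapse = "x")))
    if (abs(sp - expectGrid@spacing) > 1e-4)
      warning(sprintf(
        "volume spacing %.4g differs from expected %.4g; refusing to resample",
        sp, expectGrid@spacing))
  }
  if (all(vals %in% c(0, 1))) OccupancyVolume(vals, grid)
  else ProbabilityVolume(pmin(pmax(vals, 0), 1), grid)
}

#' Write a path point cloud
#'
#' CSV dialect: columns `x_mm`, `y_mm`, `z_mm`, `segment`.  PLY dialect:
#' ASCII PLY with vertex positions only (segment labels are not
#' representable in plain PLY and are dropped with a message).
#'
#' @param cloud a [PathPointCloud-class].
#' @param path output file; format chosen by extension (`.csv` or `.ply`).
#' @return `path`, invisibly.
#' @export
writeCloud <- function(cloud, path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    if (length(unique(cloud@segment)) > 1L)
      message("writeCloud: PLY output drops segment labels")
    writePly(TriMesh(cloud@points, matrix(integer(0), 0L, 3L)), path)
  } else {
    df <- data.frame(x_mm = cloud@points[, 1], y_mm = cloud@points[, 2],
                     z_mm = cloud@points[, 3], segment = cloud@segment)
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a path point cloud
#'
#' @param path `.csv` (columns `x_mm`, `y_mm`, `z_mm`, optional `segment`,
#'   defaulting to `"unknown"`) or `.ply` file.
#' @return A [PathPointCloud-class].
#' @export
readCloud <- function(path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    mesh <- readPly(path)
    if (nrow(mesh@vertices) < 2L) stop("point cloud file has < 2 points")
    return(PathPointCloud(mesh@vertices))
  }
  df <- read.csv(path)
  if (nrow(df) < 2L) stop("point cloud file has < 2 points")
  req <- c("x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(df)))
    stop("CSV must have columns x_mm, y_mm, z_mm")
  seg <- if ("segment" %in% names(df)) as.character(df$segment)
         else rep("unknown", nrow(df))
  PathPointCloud(as.matrix(df[, req]), seg)
}

#' Write a triangle mesh as ASCII PLY or STL
#'
#' @param mesh a [TriMesh-class].
#' @param path output file (`.ply` or `.stl`).
#' @param quality optional per-vertex scalar written as a PLY `quality`
#'   property (e.g. surface distances for error maps).
#' @return `path`, invisibly.
#' @export
writePly <- function(mesh, path, quality = NULL) {
  if (grepl("\\.stl$", path, ignore.case = TRUE)) return(writeStl(mesh, path))
  con <- file(path, "w")
  on.exit(close(con))
  nV <- nrow(mesh@vertices); nF <- nrow(mesh@faces)
  hdr <- c("ply", "format ascii 1.0", sprintf("element vertex %d", nV),
           "property float x", "property float y", "property float z")
  if (!is.null(quality)) hdr <- c(hdr, "property float quality")
  hdr <- c(hdr, sprintf("element face %d", nF),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vm <- mesh@vertices
  if (!is.null(quality)) vm <- cbind(vm, quality)
  writeLines(apply(vm, 1L, function(r) paste(format(r, trim = TRUE), collapse = " ")), con)
  if (nF > 0)
    writeLines(paste(3L, mesh@faces[, 1] - 1L, mesh@faces[, 2] - 1L,
                     mesh@faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh (or point cloud)
#'
#' @param path `.ply` file with float vertex properties x, y, z.
#' @return A [TriMesh-class] (faces empty for pure point clouds).
#' @export
readPly <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != "ply") stop("not a PLY file")
  endHdr <- which(lines == "end_header")[1]
  if (is.na(endHdr)) stop("malformed PLY: no end_header")
  nV <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1]))
  nFLine <- grep("^element face ", lines, value = TRUE)
  nF <- if (length(nFLine)) as.integer(sub("element face ", "", nFLine[1])) else 0L
  body <- lines[(endHdr + 1L):length(lines)]
  vrows <- strsplit(trimws(body[seq_len(nV)]), "\\s+")
  verts <- t(vapply(vrows, function(r) as.numeric(r[1:3]), numeric(3)))
  faces <- if (nF > 0) {
    frows <- strsplit(trimws(body[nV + seq_len(nF)]), "\\s+")
    t(vapply(frows, function(r) as.integer(r[2:4]) + 1L, integer(3)))
  } else matrix(integer(0), 0L, 3L)
  TriMesh(verts, faces)
}

writeStl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid atriarecon", con)
  V <- mesh@vertices; F <- mesh@faces
  for (t in seq_len(nrow(F))) {
    p <- V[F[t, ], , drop = FALSE]
    n <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) - (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
           (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) - (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
           (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) - (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", p[, 1], p[, 2], p[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid atriarecon", con)
  invisible(path)
}

#' Write landmarks as JSON
#'
#' Format: `{"name": [x, y, z], ...}` in mm.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(landmarks, path) {
  l <- lapply(seq_len(nrow(landmarks@coords)),
              function(i) as.numeric(landmarks@coords[i, ]))
  names(l) <- rownames(landmarks@coords)
  jsonlite::write_json(l, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read landmarks from JSON
#'
#' @param path `.json` file written by [writeLandmarks()].
#' @return A [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  LandmarkSet(lapply(l, as.numeric))
}

#' Write / read a rigid transform as JSON
#'
#' @param transform a [RigidTransform-class].
#' @param path `.json` file.
#' @return `path` (write) / a [RigidTransform-class] (read).
#' @export
writeTransform <- function(transform, path) {
  jsonlite::write_json(list(rotation = transform@rotation,
                            translation = transform@translation),
                       path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  RigidTransform(matrix(as.numeric(l$rotation), 3L, 3L),
                 as.numeric(l$translation))
}
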
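#' Labelled voxel volume
#'
#' A 3D integer label grid from a segmented micro-CT scan, with per-axis
#' voxel spacing and a label-semantics map. By convention label 0 is
#' background; the body (cephalothorax + abdomen) and the legs carry
#' separate labels so the body-only centre of mass can be computed with
#' the legs excluded.
#'
#' @param grid 3D integer array of labels.
#' @param spacing Per-axis voxel spacing (mm), length 3.
#' @param labels Named list mapping semantics to label values, e.g.
#'   `list(body = 1, legs = 2)`.
#' @param origin World coordinate of the centre of voxel (1,1,1) (mm).
#' @return An object of class `labelled_volume`.
#' @export
labelled_volume <- function(grid, spacing = c(1, 1, 1),
                            labels = list(body = 1, legs = 2),
                            origin = c(0, 0, 0)) {
  stopifnot(length(dim(grid)) == 3, length(spacing) == 3,
            all(spacing > 0), length(origin) == 3)
  if (!any(grid != 0)) stop("volume has no nonzero voxels", call. = FALSE)
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 labels = labels, origin = as.numeric(origin)),
            class = "labelled_volume")
}

#' Centre of mass of selected labels of a voxel volume
#'
#' Uniform density within the included labels (the homogeneous-and-solid
#' assumption used for segmented bodies): the CoM is the unweighted mean
#' of the included voxel centres in world coordinates.
#'
#' @param volume A [labelled_volume()].
#' @param include_labels Integer label values to include (e.g. the body
#'   label only, excluding legs).
#' @return Numeric length-3 CoM (mm).
#' @export
voxel_com <- function(volume, include_labels) {
  sel <- which(array(volume$grid %in% include_labels, dim(volume$grid)),
               arr.ind = TRUE)
  if (nrow(sel) == 0) {
    stop("empty selection: no voxels carry the included label(s)",
         call. = FALSE)
  }
  centres <- sweep(sweep((sel - 1), 2, volume$spacing, "*"),
                   2, volume$origin, "+")
  unname(colMeans(centres))
}

#' Triangle mesh
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces Integer m x 3 matrix of vertex indices (1-based),
#'   consistently outward oriented.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  storage.mode(faces) <- "integer"
  if (any(faces < 1) || any(faces > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' Check mesh watertightness and orientation
#'
#' A mesh encloses a volume only if every undirected edge is shared by
#' exactly two triangles traversed in opposite directions (consistent
#' outward orientation, no boundary, no non-manifold edges).
#'
#' @param mesh A [tri_mesh()].
#' @return List with `ok` and, when not ok, a `defects` character vector.
#' @export
check_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  defects <- character(0)
  cnt <- table(key)
  if (any(cnt != 2)) {
    defects <- c(defects, sprintf(
      "%d edge(s) not shared by exactly 2 triangles", sum(cnt != 2)))
  }
  dir_key <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dir_key)) {
    defects <- c(defects,
                 "inconsistent orientation: repeated directed edge(s)")
  }
  list(ok = length(defects) == 0, defects = defects)
}

#' Centre of mass and volume of a watertight triangle mesh
#'
#' Signed-tetrahedron decomposition against a reference point (uniform
#' density): each face forms a tetrahedron with the reference point; the
#' volume-weighted mean of the tetrahedron centroids is the solid CoM.
#' The result is independent of the reference point for a closed,
#' consistently oriented mesh.
#'
#' @param mesh A [tri_mesh()].
#' @param ref Reference point for the decomposition (default origin).
#' @param check Verify watertightness first (recommended).
#' @return List with `com` (length-3, mm) and `volume` (mm^3, positive
#'   for outward orientation).
#' @export
mesh_com <- function(mesh, ref = c(0, 0, 0), check = TRUE) {
  if (check) {
    wt <- check_watertight(mesh)
    if (!wt$ok) {
      stop("mesh integrity error: ", paste(wt$defects, collapse = "; "),
           call. = FALSE)
    }
  }
  v <- sweep(mesh$vertices, 2, ref)
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c_ <- v[mesh$faces[, 3], , drop = FALSE]
  # signed tetra volume = det[a b c]/6
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  vol6 <- sum(det6)
  if (abs(vol6) < .Machine$double.eps) {
    stop("mesh encloses zero volume", call. = FALSE)
  }
  centroid <- colSums((a + b + c_) / 4 * det6) / vol6
  list(com = unname(centroid + ref), volume = vol6 / 6)
}

#' Downsample a labelled volume by block-majority binning
#'
#' Maps each 2x2x2 (for `factor = 2`) block to its majority label, with
#' ties resolved to the lowest label value, and doubles the voxel
#' spacing. Grids whose dimensions are not divisible by the factor are
#' padded with background (label 0) with a warning.
#'
#' @param volume A [labelled_volume()].
#' @param factor Integer binning factor per axis.
#' @return A [labelled_volume()] at the coarser resolution.
#' @export
binning_downsample <- function(volume, factor = 2L) {
  g <- volume$grid
  d <- dim(g)
  pad <- (factor - d %% factor) %% factor
  if (any(pad > 0)) {
    warning("grid dimensions not divisible by the binning factor; ",
            "padding with background", call. = FALSE)
    g2 <- array(0L, d + pad)
    g2[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- g
    g <- g2
    d <- dim(g)
  }
  nd <- d %/% factor
  out <- array(0L, nd)
  # decompose indices into block and within-block parts
  labs <- sort(unique(as.vector(g)))
  counts <- array(0L, c(nd, length(labs)))
  for (li in seq_along(labs)) {
    mask <- (g == labs[li]) * 1L
    acc <- array(0L, nd)
    for (i in seq_len(factor)) for (j in seq_len(factor))
      for (k in seq_len(factor)) {
        acc <- acc + mask[seq(i, d[1], factor),
                          seq(j, d[2], factor),
                          seq(k, d[3], factor)]
      }
    counts[, , , li] <- acc
  }
  best <- array(1L, nd)
  best_cnt <- counts[, , , 1]
  for (li in seq_along(labs)[-1]) {
    better <- counts[, , , li] > best_cnt     # strict: ties keep lower label
    best[better] <- li
    best_cnt[better] <- counts[, , , li][better]
  }
  out[] <- labs[best]
  labelled_volume(out, spacing = volume$spacing * factor,
                  labels = volume$labels,
                  origin = volume$origin + (factor - 1) / 2 * volume$spacing)
}

#' Read / write ASCII STL meshes
#'
#' Minimal ASCII STL support for the mesh interchange format used in
#' micro-CT workflows. Vertices repeated across facets are merged exactly
#' on read. `write_stl` emits one facet per triangle with a recomputed
#' normal.
#'
#' @param path STL file path.
#' @return `read_stl`: a [tri_mesh()].
#' @export
read_stl <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- lines[startsWith(lines, "vertex")]
  if (length(vl) == 0 || length(vl) %% 3 != 0) {
    stop("malformed ASCII STL: vertex count not a multiple of 3",
         call. = FALSE)
  }
  coords <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(coords, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

#' @rdname read_stl
#' @param mesh A [tri_mesh()].
#' @param name Solid name written in the header.
#' @export
write_stl <- function(mesh, path, name = "mesh") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  v <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    a <- v[f[1], ]; b <- v[f[2], ]; c_ <- v[f[3], ]
    nrm <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
             (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
             (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
                 sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
                 sprintf("      vertex %.9g %.9g %.9g", c_[1], c_[2], c_[3]),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read / write labelled volumes as NIfTI
#'
#' Thin wrappers storing the label grid with the voxel spacing in the
#' NIfTI pixdim; the micro-CT workflow's native grid format.
#'
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @param labels Label-semantics map attached on read.
#' @return `read_volume_nifti`: a [labelled_volume()].
#' @export
read_volume_nifti <- function(path, labels = list(body = 1, legs = 2)) {
  img <- RNifti::readNifti(path)
  grid <- array(as.integer(round(img)), dim(img))
  labelled_volume(grid, spacing = RNifti::pixdim(img)[1:3], labels = labels)
}

#' @rdname read_volume_nifti
#' @param volume A [labelled_volume()].
#' @export
write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$grid)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Axis-aligned unit-cube test mesh (12 triangles)
#' @param origin Corner position.
#' @param side Edge length.
#' @return A [tri_mesh()].
#' @export
unit_cube_mesh <- function(origin = c(0, 0, 0), side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side),
                             z = c(0, side)))
  v <- sweep(v, 2, origin, "+")
  # outward-oriented faces of the cube with the expand.grid vertex order
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),     # z = 0 (down)
    c(5, 6, 7), c(6, 8, 7),     # z = side (up)
    c(1, 2, 5), c(2, 6, 5),     # y = 0
    c(3, 7, 4), c(4, 7, 8),     # y = side
    c(1, 5, 3), c(3, 5, 7),     # x = 0
    c(2, 4, 6), c(4, 8, 6))     # x = side
  tri_mesh(v, f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron with vertices projected to the sphere; a
#' closed-form test solid for volume and centroid checks.
#'
#' @param centre Sphere centre.
#' @param radius Sphere radius.
#' @param subdivisions Subdivision rounds (>= 0).
#' @return A [tri_mesh()].
#' @export
icosphere_mesh <- function(centre = c(0, 0, 0), radius = 1,
                           subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(parent = emptyenv())
    nv <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mget(key, envir = edge_mid, ifnotfound = list(NULL))[[1]]
      if (!is.null(got)) return(got)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- rbind(nv, m)
      id <- nrow(nv)
      assign(key, id, envir = edge_mid)
      id
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
      a <- midpoint(i, j); b <- midpoint(j, k); c_ <- midpoint(k, i)
      nf <- rbind(nf, c(i, a, c_), c(j, b, a), c(k, c_, b), c(a, b, c_))
    }
    v <- nv; f <- nf
  }
  tri_mesh(sweep(v * radius, 2, centre, "+"), f)
}
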
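#' Triangulated surface mesh
#'
#' Construct and validate a triangle mesh: an `n x 3` matrix of vertex
#' coordinates (millimetres) plus an `m x 3` integer matrix of 1-based
#' vertex indices, one row per triangular face. Degenerate faces (zero
#' area, or repeated vertex indices) are dropped with a warning rather
#' than rejected, so meshes from real scanners remain usable.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per face, 1-based vertex indices.
#' @return An object of class `triangle_mesh` with elements `vertices`
#'   and `faces`.
#' @examples
#' m <- make_geometry("cube", size_mm = 10)
#' m
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(vertices) < 3L || nrow(faces) < 1L) stop("empty mesh")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face index out of range")

  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  areas <- face_areas(mesh)
  repeated <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  bad <- repeated | areas <= 1e-12
  if (any(bad)) {
    warning(sprintf("dropped %d degenerate face(s)", sum(bad)))
    mesh$faces <- faces[!bad, , drop = FALSE]
    if (nrow(mesh$faces) < 1L) stop("all faces degenerate")
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- bounding_box(x)
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bounding box [mm]: x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
              bb$lo[1], bb$hi[1], bb$lo[2], bb$hi[2], bb$lo[3], bb$hi[3]))
  invisible(x)
}

tri_corners <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-face areas, normals, and derived mesh quantities
#'
#' `face_areas` returns triangle areas in mm^2; `face_normals` unit
#' outward normals (orientation as stored); `vertex_normals`
#' angle-weighted unit vertex normals; `mesh_centroid` the area-weighted
#' surface centroid; `bounding_box` the axis-aligned bounds; and
#' `mesh_volume` the signed enclosed volume (positive for outward-oriented
#' closed surfaces).
#'
#' @param mesh a [triangle_mesh()].
#' @return Numeric vector (`face_areas`), matrix of unit vectors
#'   (`face_normals`, `vertex_normals`), length-3 vector
#'   (`mesh_centroid`), list with `lo`, `hi`, `extent`, `diagonal`
#'   (`bounding_box`), or scalar (`mesh_volume`).
#' @export
face_areas <- function(mesh) {
  tc <- tri_corners(mesh)
  cr <- cross3(tc$b - tc$a, tc$c - tc$a)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  tc <- tri_corners(mesh)
  cr <- cross3(tc$b - tc$a, tc$c - tc$a)
  nrm <- sqrt(rowSums(cr^2))
  nrm[nrm == 0] <- 1
  cr / nrm
}

#' @rdname face_areas
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  # angle-weighted accumulation: weight each face normal by the interior
  # angle at the vertex, which makes the result tessellation-independent
  out <- matrix(0, nrow(v), 3)
  for (corner in 1:3) {
    i0 <- f[, corner]
    i1 <- f[, (corner %% 3) + 1]
    i2 <- f[, ((corner + 1) %% 3) + 1]
    e1 <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    e2 <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- e2 / sqrt(rowSums(e2^2))
    ang <- acos(pmin(1, pmax(-1, rowSums(e1 * e2))))
    for (k in 1:3) {
      acc <- rowsum(fn[, k] * ang, group = i0)
      idx <- as.integer(rownames(acc))
      out[idx, k] <- out[idx, k] + acc[, 1]
    }
  }
  nrm <- sqrt(rowSums(out^2))
  nrm[nrm == 0] <- 1
  out / nrm
}

#' @rdname face_areas
#' @export
mesh_centroid <- function(mesh) {
  tc <- tri_corners(mesh)
  ar <- face_areas(mesh)
  ctr <- (tc$a + tc$b + tc$c) / 3
  colSums(ctr * ar) / sum(ar)
}

#' @rdname face_areas
#' @export
bounding_box <- function(mesh) {
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  list(lo = lo, hi = hi, extent = hi - lo,
       diagonal = sqrt(sum((hi - lo)^2)))
}

#' @rdname face_areas
#' @export
mesh_volume <- function(mesh) {
  tc <- tri_corners(mesh)
  sum(rowSums(tc$a * cross3(tc$b, tc$c))) / 6
}

#' Merge duplicate vertices
#'
#' Merges vertices closer than `tol` (mm) by snapping to a tolerance
#' grid; face indices are remapped. Used by [read_stl()] to turn facet
#' soups into indexed meshes.
#'
#' @param vertices numeric `n x 3` matrix.
#' @param faces integer `m x 3` matrix of 1-based indices.
#' @param tol merge tolerance in mm.
#' @return List with `vertices`, remapped `faces`, and `n_merged`.
#' @export
merge_duplicate_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  new_v <- vertices[first, , drop = FALSE]
  new_f <- matrix(remap[faces], ncol = 3)
  list(vertices = new_v, faces = new_f,
       n_merged = nrow(vertices) - nrow(new_v))
}
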
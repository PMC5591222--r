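#' Read a triangulated surface from an STL file
#'
#' Auto-detects the ASCII and binary STL dialects. Vertices repeated
#' across facets are merged when closer than 1e-6 mm, so the result is an
#' indexed mesh rather than a triangle soup.
#'
#' @param path path to an `.stl` file.
#' @param merge_tol merge tolerance in mm for duplicate vertices.
#' @return A [triangle_mesh()].
#' @seealso [write_stl()]
#' @export
read_stl <- function(path, merge_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  if (size < 15) stop("STL format error at byte 0: file too short")
  con <- file(path, "rb")
  head5 <- rawToChar(readBin(con, "raw", 5))
  close(con)
  looks_ascii <- identical(tolower(head5), "solid")
  if (looks_ascii) {
    out <- try(read_stl_ascii(path), silent = TRUE)
    if (!inherits(out, "try-error")) {
      m <- merge_duplicate_vertices(out$vertices, out$faces, merge_tol)
      if (m$n_merged > 0)
        message(sprintf("read_stl: merged %d duplicate vertices", m$n_merged))
      return(triangle_mesh(m$vertices, m$faces))
    }
    # some binary writers also start their 80-byte header with "solid";
    # fall through to the binary reader before giving up
  }
  out <- read_stl_binary(path)
  m <- merge_duplicate_vertices(out$vertices, out$faces, merge_tol)
  if (m$n_merged > 0)
    message(sprintf("read_stl: merged %d duplicate vertices", m$n_merged))
  triangle_mesh(m$vertices, m$faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0) stop("STL format error: no vertex records")
  if (length(vl) %% 3 != 0)
    stop("STL format error at line ", vl[length(vl)],
         ": vertex count not a multiple of 3")
  coords <- t(vapply(strsplit(trimws(lines[vl]), "\\s+"), function(tok) {
    x <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(x))) stop("STL format error: non-numeric vertex")
    x
  }, numeric(3)))
  nf <- length(vl) / 3
  list(vertices = coords,
       faces = matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}

read_stl_binary <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(nf) || nf < 0)
    stop("STL format error at byte 80: bad facet count")
  expected <- 84 + 50 * as.double(nf)
  if (expected != size)
    stop(sprintf(paste0("STL format error at byte 80: facet count %d ",
                        "implies %.0f bytes but file has %.0f"),
                 nf, expected, size))
  if (nf == 0) stop("empty mesh")
  payload <- readBin(con, "raw", 50 * nf)
  rec <- matrix(payload, nrow = 50)          # one column per facet record
  floats <- readBin(as.vector(rec[1:48, ]), "numeric",
                    n = 12 * nf, size = 4, endian = "little")
  fl <- matrix(floats, nrow = 12)            # normal(3) + 3 vertices
  verts <- matrix(0, 3 * nf, 3)
  for (v in 1:3)                             # rows 1:3 hold the facet normal
    verts[seq(v, by = 3, length.out = nf), ] <- t(fl[3 * v + 1:3, , drop = FALSE])
  list(vertices = verts,
       faces = matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}

#' Write a triangle mesh to an STL file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param dialect `"binary"` (84 + 50 bytes/facet, little-endian) or
#'   `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0) stop("mesh has no faces")
  tc <- tri_corners(mesh)
  fn <- face_normals(mesh)
  nf <- nrow(mesh$faces)
  if (dialect == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    block <- sprintf(
      paste0("  facet normal %.9g %.9g %.9g\n    outer loop\n",
             "      vertex %.9g %.9g %.9g\n      vertex %.9g %.9g %.9g\n",
             "      vertex %.9g %.9g %.9g\n    endloop\n  endfacet"),
      fn[, 1], fn[, 2], fn[, 3],
      tc$a[, 1], tc$a[, 2], tc$a[, 3],
      tc$b[, 1], tc$b[, 2], tc$b[, 3],
      tc$c[, 1], tc$c[, 2], tc$c[, 3])
    writeLines(block, con)
    writeLines("endsolid mesh", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "binary STL (meshfidelity)"))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # 12 floats per facet followed by a 2-byte attribute count of zero
    dat <- rbind(t(fn), t(tc$a), t(tc$b), t(tc$c))   # 12 x nf
    for (i in seq_len(nf)) {
      writeBin(dat[, i], con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' Stochastic area-uniform surface sample
#'
#' Draws `n` points uniformly over the mesh surface: each face is chosen
#' with probability proportional to its area, then a point is placed
#' uniformly inside the face via reflected barycentric coordinates. This
#' is the stochastic point set used by the ICP alignment.
#'
#' @param mesh a [triangle_mesh()].
#' @param n number of points (>= 3).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return An object of class `point_set`: list with `points` (n x 3
#'   matrix, mm), `n`, `source_seed`, and the sampled `face` indices.
#' @export
sample_surface <- function(mesh, n, seed) {
  if (n < 3) stop("n must be >= 3")
  areas <- face_areas(mesh)
  with_seed(seed, {
    fi <- sample.int(length(areas), n, replace = TRUE, prob = areas)
    u <- runif(n)
    v <- runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]
    v[flip] <- 1 - v[flip]
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    c <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    pts <- a + u * (b - a) + v * (c - a)
    structure(list(points = pts, n = as.integer(n),
                   source_seed = as.integer(seed), face = fi),
              class = "point_set")
  })
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("point_set: %d surface points (seed %d)\n", x$n, x$source_seed))
  invisible(x)
}

#' Export a point set as CSV
#'
#' @param ps a `point_set`.
#' @param path output path; columns `x,y,z` in mm.
#' @return `path`, invisibly.
#' @export
write_point_set <- function(ps, path) {
  df <- as.data.frame(ps$points)
  names(df) <- c("x", "y", "z")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
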
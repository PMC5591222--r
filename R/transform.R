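#' Rigid-body transform
#'
#' A rotation matrix plus translation vector, applied to column-vector
#' points as `R x + t`. Construction enforces orthogonality
#' (`|R'R - I| < 1e-9`) and `det(R) = +1`.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthogonal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must have determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", sprintf("%.6f", x$translation), "\n")
  invisible(x)
}

#' Apply, compose, and invert rigid transforms
#'
#' `apply_transform` maps an `n x 3` point matrix (or a mesh) through the
#' transform; `compose_transform(a, b)` returns the transform equivalent
#' to applying `b` first, then `a`; `invert_transform` returns the
#' inverse.
#'
#' @param transform,a,b `rigid_transform` objects.
#' @param x an `n x 3` matrix of points or a [triangle_mesh()].
#' @return Transformed points/mesh, or a `rigid_transform`.
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "triangle_mesh")) {
    out <- x
    out$vertices <- apply_transform(transform, x$vertices)
    return(out)
  }
  x <- as.matrix(x)
  t(transform$rotation %*% t(x) + transform$translation)
}

#' @rdname apply_transform
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Rotation about an axis through a point
#'
#' Rodrigues rotation by `angle` radians about unit `axis`, centred on
#' `center` (so `center` is a fixed point).
#'
#' @param axis length-3 axis (normalised internally).
#' @param angle radians.
#' @param center fixed point of the rotation (mm).
#' @return A `rigid_transform`.
#' @export
rotation_about <- function(axis, angle, center = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  # re-orthogonalise against accumulated floating error
  s <- svd(R)
  R <- s$u %*% t(s$v)
  rigid_transform(R, as.numeric(center - R %*% center))
}

#' Write / read a transform as a homogeneous 4x4 text matrix
#'
#' Plain-text exchange format: four rows of four numbers (row-major).
#'
#' @param transform a `rigid_transform`.
#' @param path file path.
#' @return `write_transform`: `path` invisibly; `read_transform`: a
#'   `rigid_transform`.
#' @export
write_transform <- function(transform, path) {
  H <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  writeLines(apply(H, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " ")), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  H <- as.matrix(read.table(path))
  stopifnot(all(dim(H) == c(4, 4)))
  rigid_transform(H[1:3, 1:3], H[1:3, 4])
}
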
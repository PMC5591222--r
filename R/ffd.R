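#' Free-form deformation lattice
#'
#' Builds an `l x m x n` grid of control points on the axis-aligned
#' bounding box of a mesh, together with the local box coordinates
#' `(s, t, u)` in `[0,1]^3` of every mesh vertex. With undisplaced
#' control points the lattice reproduces the mesh exactly (Bernstein
#' partition of unity).
#'
#' @param mesh a [triangle_mesh()].
#' @param dims integer triple: control points per axis, each >= 2.
#' @return An object of class `ffd_lattice`: `control` (`prod(dims) x 3`
#'   control point matrix, mm), `dims`, `grid_index` (integer triple per
#'   control point), `stu` (vertex box coordinates), `box`, `n_vertices`.
#' @export
build_lattice <- function(mesh, dims = c(4, 4, 4)) {
  stopifnot(inherits(mesh, "triangle_mesh"), length(dims) == 3)
  dims <- as.integer(dims)
  if (any(dims < 2)) stop("lattice dims must each be >= 2")
  bb <- bounding_box(mesh)
  if (any(bb$extent <= 0)) stop("flat bounding box: mesh has no extent ",
                                "on some axis")
  gi <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                              j = seq_len(dims[2]) - 1L,
                              k = seq_len(dims[3]) - 1L))
  ctrl <- cbind(bb$lo[1] + gi[, 1] / (dims[1] - 1) * bb$extent[1],
                bb$lo[2] + gi[, 2] / (dims[2] - 1) * bb$extent[2],
                bb$lo[3] + gi[, 3] / (dims[3] - 1) * bb$extent[3])
  stu <- sweep(sweep(mesh$vertices, 2, bb$lo), 2, bb$extent, "/")
  structure(list(control = ctrl, dims = dims, grid_index = gi, stu = stu,
                 box = bb, n_vertices = nrow(mesh$vertices)),
            class = "ffd_lattice")
}

# n x (deg+1) matrix of Bernstein basis values B_{i,deg}(x)
bernstein_basis <- function(x, deg) {
  outer(x, 0:deg, function(xx, i)
    choose(deg, i) * xx^i * (1 - xx)^(deg - i))
}

#' Apply a free-form deformation to a mesh
#'
#' Maps every vertex through the trivariate tensor-product Bernstein
#' polynomial of the lattice control points (the classical Sederberg and
#' Parry formulation, degree `dims - 1` per axis). Topology is unchanged.
#'
#' @param lattice a [build_lattice()] result, possibly with displaced
#'   `control` points.
#' @param mesh the same mesh the lattice was built for.
#' @return The deformed [triangle_mesh()].
#' @export
apply_ffd <- function(lattice, mesh) {
  stopifnot(inherits(lattice, "ffd_lattice"), inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$vertices) != lattice$n_vertices)
    stop("lattice was built for a different mesh (vertex count differs)")
  bb <- bounding_box(mesh)
  if (max(abs(bb$lo - lattice$box$lo)) > 1e-9 ||
      max(abs(bb$hi - lattice$box$hi)) > 1e-9)
    stop("lattice was built for a different mesh (bounding box differs)")
  dims <- lattice$dims
  Bs <- bernstein_basis(lattice$stu[, 1], dims[1] - 1L)
  Bt <- bernstein_basis(lattice$stu[, 2], dims[2] - 1L)
  Bu <- bernstein_basis(lattice$stu[, 3], dims[3] - 1L)
  # weight of control point (i,j,k) at a vertex is Bs_i * Bt_j * Bu_k;
  # accumulate over the (small) control grid
  gi <- lattice$grid_index
  out <- matrix(0, lattice$n_vertices, 3)
  for (cidx in seq_len(nrow(gi))) {
    w <- Bs[, gi[cidx, 1] + 1L] * Bt[, gi[cidx, 2] + 1L] *
      Bu[, gi[cidx, 3] + 1L]
    out <- out + w %o% lattice$control[cidx, ]
  }
  res <- mesh
  res$vertices <- out
  res
}

#' Random perturbation specification
#'
#' The `random(M, R, V)` operator used to validate the fidelity metric:
#' binary flags for random translation (`M`) and random rotation (`R`),
#' and the fraction `V` of lattice control points displaced by the
#' free-form deformation. Control-point motion is bounded by
#' `max_displacement_fraction` of the longest bounding-box axis
#' (default 10%).
#'
#' @param M 0 or 1: apply a random translation (each component uniform
#'   within plus/minus one bounding-box diagonal).
#' @param R 0 or 1: apply a uniform random rotation about the mesh
#'   centroid (axis uniform on the sphere, angle uniform in (0, 180]
#'   degrees).
#' @param V fraction in `[0, 1]` of control points displaced.
#' @param max_displacement_fraction bound on each control-point
#'   displacement, as a fraction of the longest bounding-box axis.
#' @param seed integer seed.
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(M = 0, R = 0, V = 0,
                             max_displacement_fraction = 0.10, seed = 1) {
  if (!M %in% c(0, 1) || !R %in% c(0, 1)) stop("M and R must be 0 or 1")
  if (V < 0 || V > 1) stop("V must be in [0, 1]")
  if (max_displacement_fraction <= 0 || max_displacement_fraction > 1)
    stop("max_displacement_fraction must be in (0, 1]")
  structure(list(M = as.integer(M), R = as.integer(R), V = V,
                 max_displacement_fraction = max_displacement_fraction,
                 seed = as.integer(seed)),
            class = "deformation_spec")
}

#' Randomly deform a mesh with known ground truth
#'
#' Applies, in order: (i) bounded free-form distortion of a random subset
#' of lattice control points (`V`), (ii) a uniform random rotation about
#' the centroid (`R`), (iii) a random translation (`M`). For a fixed
#' seed the displaced control-point sets are nested across increasing
#' `V` (a fixed random order of control points is truncated at
#' `ceiling(V * n)`), so severity comparisons across `V` are paired.
#'
#' @param mesh a [triangle_mesh()].
#' @param spec a [deformation_spec()].
#' @param dims lattice resolution, see [build_lattice()].
#' @return List with `mesh` (deformed) and `record` (class
#'   `deformation_record`): the applied rotation/translation, displaced
#'   control indices and displacement vectors, and the seed — the ground
#'   truth for validation.
#' @export
random_deform <- function(mesh, spec, dims = c(4, 4, 4)) {
  stopifnot(inherits(spec, "deformation_spec"))
  lattice <- build_lattice(mesh, dims)
  n_ctrl <- nrow(lattice$control)
  bb <- lattice$box
  bound <- spec$max_displacement_fraction * max(bb$extent)

  with_seed(spec$seed, {
    # draw the full displacement stream regardless of V so that rotation
    # and translation draws are identical across V for the same seed
    perm <- sample.int(n_ctrl)
    dirs <- matrix(rnorm(3 * n_ctrl), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    mags <- bound * runif(n_ctrl)^(1 / 3)     # uniform in the ball
    displacements <- dirs * mags

    out <- mesh
    displaced <- integer(0)
    vecs <- matrix(numeric(0), 0, 3)
    if (spec$V > 0) {
      nd <- ceiling(spec$V * n_ctrl)
      displaced <- perm[seq_len(nd)]
      vecs <- displacements[seq_len(nd), , drop = FALSE]
      lattice$control[displaced, ] <- lattice$control[displaced, ] + vecs
      out <- apply_ffd(lattice, mesh)
    }

    rot <- rigid_transform()
    if (spec$R == 1) {
      axis <- rnorm(3)
      angle <- runif(1, 0, pi)
      rot <- rotation_about(axis, angle, center = colMeans(out$vertices))
      out <- apply_transform(rot, out)
    }

    trans <- c(0, 0, 0)
    if (spec$M == 1) {
      trans <- runif(3, -bb$diagonal, bb$diagonal)
      out$vertices <- sweep(out$vertices, 2, trans, "+")
    }

    record <- structure(list(
      spec = spec, dims = as.integer(dims),
      rotation = rot$rotation, rotation_translation = rot$translation,
      translation = trans,
      displaced_indices = displaced, displacements = vecs,
      longest_axis = max(bb$extent), seed = spec$seed),
      class = "deformation_record")
    list(mesh = out, record = record)
  })
}

#' @export
print.deformation_record <- function(x, ...) {
  cat(sprintf("deformation_record: random(M=%d, R=%d, V=%.2f), seed %d\n",
              x$spec$M, x$spec$R, x$spec$V, x$seed))
  cat(sprintf("  %d control point(s) displaced (bound %.3f mm)\n",
              length(x$displaced_indices),
              x$spec$max_displacement_fraction * x$longest_axis))
  invisible(x)
}

#' Serialise a deformation ground-truth record as key-value text
#'
#' @param record a `deformation_record` from [random_deform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deformation_record <- function(record, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    sprintf("M = %d", record$spec$M),
    sprintf("R_flag = %d", record$spec$R),
    sprintf("V = %.17g", record$spec$V),
    sprintf("max_displacement_fraction = %.17g",
            record$spec$max_displacement_fraction),
    sprintf("seed = %d", record$seed),
    sprintf("lattice_dims = %s", paste(record$dims, collapse = " ")),
    sprintf("longest_axis_mm = %.17g", record$longest_axis),
    sprintf("rotation_row1 = %s", num(record$rotation[1, ])),
    sprintf("rotation_row2 = %s", num(record$rotation[2, ])),
    sprintf("rotation_row3 = %s", num(record$rotation[3, ])),
    sprintf("rotation_translation = %s", num(record$rotation_translation)),
    sprintf("translation = %s", num(record$translation)),
    sprintf("displaced_indices = %s",
            paste(record$displaced_indices, collapse = " ")))
  if (nrow(record$displacements))
    lines <- c(lines, sprintf("displacement_%d = %s",
                              seq_len(nrow(record$displacements)),
                              apply(record$displacements, 1, num)))
  writeLines(lines, path)
  invisible(path)
}
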
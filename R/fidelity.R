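#' Signed per-vertex deviation map
#'
#' For each vertex of the reference mesh, the distance to the exact
#' closest point on the aligned test surface, signed by the angle-weighted
#' outward vertex normal of the reference: positive deviations mean the
#' test surface lies outside the reference (overbuilt material), negative
#' ones that it lies inside (undercut).
#'
#' @param reference the reference [triangle_mesh()]; deviations are
#'   evaluated at its vertices.
#' @param test the test [triangle_mesh()].
#' @param alignment [rigid_transform()] mapping the test mesh into the
#'   reference frame (identity for pre-aligned inputs).
#' @return An object of class `fidelity_map`: list with `deviation`
#'   (signed mm, one per reference vertex), `closest` (matching points on
#'   the aligned test surface), `face`, and `alignment`.
#' @export
signed_deviation <- function(reference, test,
                             alignment = rigid_transform()) {
  stopifnot(inherits(reference, "triangle_mesh"),
            inherits(test, "triangle_mesh"))
  if (nrow(test$faces) == 0) stop("empty test mesh")
  aligned <- apply_transform(alignment, test)
  cp <- closest_on_mesh(aligned, reference$vertices)
  offset <- cp$point - reference$vertices
  nrm <- vertex_normals(reference)
  d <- sqrt(cp$dist2)
  sgn <- sign(rowSums(offset * nrm))
  sgn[d == 0] <- 0
  structure(list(deviation = sgn * d, closest = cp$point, face = cp$face,
                 alignment = alignment),
            class = "fidelity_map")
}

#' @export
print.fidelity_map <- function(x, ...) {
  cat(sprintf("fidelity_map: %d vertices, deviations %.4f .. %.4f mm\n",
              length(x$deviation), min(x$deviation), max(x$deviation)))
  invisible(x)
}

#' Summary statistics of a fidelity map
#'
#' Mean signed error, upper deviation (maximum), lower deviation
#' (minimum) and population standard deviation, all in mm — the columns
#' reported for phantom fidelity tables.
#'
#' @param map a [signed_deviation()] map.
#' @param ... unused.
#' @return An object of class `fidelity_summary` with fields
#'   `mean_error`, `upper_deviation`, `lower_deviation`,
#'   `standard_deviation`, `vertex_count`.
#' @export
summarize_fidelity <- function(map) {
  d <- map$deviation
  if (length(d) == 0) stop("empty fidelity map")
  structure(list(mean_error = mean(d),
                 upper_deviation = max(d),
                 lower_deviation = min(d),
                 standard_deviation = sqrt(mean((d - mean(d))^2)),
                 vertex_count = length(d)),
            class = "fidelity_summary")
}

#' @rdname summarize_fidelity
#' @export
summary.fidelity_map <- function(object, ...) summarize_fidelity(object)

#' @export
print.fidelity_summary <- function(x, ...) {
  fmt <- function(v) {
    v <- round(v, 2)
    if (v == 0) v <- 0              # avoid "-0.00"
    sprintf("%7.2f", v)
  }
  cat("fidelity summary (mm, over", x$vertex_count, "reference vertices)\n")
  cat("  mean error:         ", fmt(x$mean_error), "\n", sep = "")
  cat("  upper deviation:    ", fmt(x$upper_deviation), "\n", sep = "")
  cat("  lower deviation:    ", fmt(x$lower_deviation), "\n", sep = "")
  cat("  standard deviation: ", fmt(x$standard_deviation), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.fidelity_summary <- function(x, ...) {
  data.frame(mean_mm = x$mean_error, upper_mm = x$upper_deviation,
             lower_mm = x$lower_deviation, std_mm = x$standard_deviation,
             n_vertices = x$vertex_count)
}

#' End-to-end fidelity assessment
#'
#' The full pipeline: ICP alignment of the test mesh onto the reference,
#' signed deviation map at the reference vertices, and summary
#' statistics.
#'
#' @inheritParams icp_align
#' @return An object of class `fidelity_assessment`: list with `map`,
#'   `summary`, `transform`, `trace`.
#' @examples
#' ref <- make_geometry("cube", size_mm = 20, resolution = 4)
#' tst <- random_deform(ref, deformation_spec(M = 1, R = 0, V = 0, seed = 7))
#' fa <- fidelity_assess(ref, tst$mesh, icp_config(n_points = 1000, seed = 1))
#' fa$summary
#' @export
fidelity_assess <- function(reference, test, config = icp_config()) {
  al <- icp_align(reference, test, config)
  map <- signed_deviation(reference, test, al$transform)
  structure(list(map = map, summary = summarize_fidelity(map),
                 transform = al$transform, trace = al$trace),
            class = "fidelity_assessment")
}

#' @export
print.fidelity_assessment <- function(x, ...) {
  print(x$trace)
  print(x$summary)
  invisible(x)
}

#' Export a fidelity map as CSV scalars and a coloured PLY surface
#'
#' Writes `<path>.csv` (vertex index, coordinates, signed deviation) and
#' `<path>.ply` (ASCII PLY with per-vertex `uchar` RGB from a diverging
#' blue-white-red colormap: white at zero deviation, clipped to
#' `range_mm`).
#'
#' @param map a [signed_deviation()] map of `reference`.
#' @param reference the reference [triangle_mesh()] the map was computed
#'   on.
#' @param path output path without extension.
#' @param range_mm length-2 colour range `c(lo, hi)` in mm with
#'   `lo < 0 < hi`; defaults to symmetric about zero at the largest
#'   absolute deviation.
#' @return Character vector of the two files written, invisibly.
#' @export
export_colormap <- function(map, reference, path, range_mm = NULL) {
  d <- map$deviation
  if (length(d) != nrow(reference$vertices))
    stop("map and reference vertex counts differ")
  if (is.null(range_mm)) {
    m <- max(abs(d), 1e-12)
    range_mm <- c(-m, m)
  }
  stopifnot(length(range_mm) == 2, range_mm[1] < 0, range_mm[2] > 0)

  csv_path <- paste0(path, ".csv")
  ply_path <- paste0(path, ".ply")
  df <- data.frame(vertex = seq_along(d),
                   x = reference$vertices[, 1],
                   y = reference$vertices[, 2],
                   z = reference$vertices[, 3],
                   deviation_mm = d)
  write.csv(df, csv_path, row.names = FALSE)

  # diverging map, mid-colour (white) pinned at zero deviation
  pal <- colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(511)
  t01 <- ifelse(d < 0,
                0.5 * (1 - pmin(1, d / range_mm[1])),
                0.5 * (1 + pmin(1, d / range_mm[2])))
  cols <- t(col2rgb(pal[pmin(511L, pmax(1L, as.integer(round(t01 * 510)) + 1L))]))

  con <- file(ply_path, "w")
  on.exit(close(con))
  nv <- nrow(reference$vertices)
  nf <- nrow(reference$faces)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g %d %d %d",
                     reference$vertices[, 1], reference$vertices[, 2],
                     reference$vertices[, 3],
                     cols[, 1], cols[, 2], cols[, 3]), con)
  writeLines(sprintf("3 %d %d %d", reference$faces[, 1] - 1L,
                     reference$faces[, 2] - 1L, reference$faces[, 3] - 1L),
             con)
  invisible(c(csv_path, ply_path))
}
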
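test_that("corner lattice and box-normalised coordinates are exact", {
  cube <- make_geometry("cube", size_mm = 10, resolution = 1)
  lat <- build_lattice(cube, dims = c(2, 2, 2))
  expect_equal(nrow(lat$control), 8)
  expect_equal(sort(unique(as.vector(lat$control))), c(-5, 5))

  m3 <- make_geometry("cube", size_mm = 10, resolution = 2)  # has centres
  lat3 <- build_lattice(m3, dims = c(3, 3, 3))
  centre_face <- which(m3$vertices[, 1] == 0 & m3$vertices[, 2] == 0 &
                         m3$vertices[, 3] == -5)
  expect_equal(lat3$stu[centre_face, ], c(0.5, 0.5, 0))

  flat <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        matrix(1:3, 1))
  expect_error(build_lattice(flat), "flat bounding box")
  expect_error(build_lattice(cube, dims = c(1, 4, 4)), ">= 2")
})

test_that("undisplaced lattice reproduces the mesh (partition of unity)", {
  for (kind in c("cube", "sphere", "torus")) {
    m <- make_geometry(kind, size_mm = 17, resolution = 3)
    lat <- build_lattice(m, dims = c(4, 4, 4))
    out <- apply_ffd(lat, m)
    expect_lt(max(abs(out$vertices - m$vertices)), 1e-9)
    expect_identical(out$faces, m$faces)
  }
})

test_that("translating all control points translates the mesh (affine precision)", {
  m <- make_geometry("blob", size_mm = 12, resolution = 3, seed = 2)
  lat <- build_lattice(m, dims = c(4, 3, 5))
  lat$control <- sweep(lat$control, 2, c(1.5, -0.25, 4), "+")
  out <- apply_ffd(lat, m)
  shift <- out$vertices - m$vertices
  expect_lt(max(abs(sweep(shift, 2, c(1.5, -0.25, 4)))), 1e-9)
})

test_that("single displaced control point matches the Bernstein polynomial", {
  cube <- make_geometry("cube", size_mm = 10, resolution = 4)
  lat <- build_lattice(cube, dims = c(4, 4, 4))
  delta <- c(0.7, -0.3, 0.2)
  ci <- which(lat$grid_index[, 1] == 3 & lat$grid_index[, 2] == 0 &
                lat$grid_index[, 3] == 3)   # a box corner control point
  lat$control[ci, ] <- lat$control[ci, ] + delta
  out <- apply_ffd(lat, cube)
  stu <- lat$stu
  bern <- function(i, n, x) choose(n, i) * x^i * (1 - x)^(n - i)
  w <- bern(3, 3, stu[, 1]) * bern(0, 3, stu[, 2]) * bern(3, 3, stu[, 3])
  expect_equal(out$vertices, cube$vertices + w %o% delta, tolerance = 1e-12)
})

test_that("random_deform respects flags, bounds, and reproducibility", {
  cube <- make_geometry("cube", size_mm = 20, resolution = 2)

  null_def <- random_deform(cube, deformation_spec(0, 0, 0, seed = 3))
  expect_equal(null_def$mesh$vertices, cube$vertices)

  tr <- random_deform(cube, deformation_spec(1, 0, 0, seed = 3))
  diffs <- tr$mesh$vertices - cube$vertices
  expect_lt(max(abs(sweep(diffs, 2, tr$record$translation))), 1e-12)
  expect_true(all(abs(tr$record$translation) <=
                    bounding_box(cube)$diagonal))

  rot <- random_deform(cube, deformation_spec(0, 1, 0, seed = 3))
  expect_equal(det(rot$record$rotation), 1, tolerance = 1e-12)
  expect_equal(sort(sqrt(rowSums(rot$mesh$vertices^2))),
               sort(sqrt(rowSums(cube$vertices^2))), tolerance = 1e-9)

  again <- random_deform(cube, deformation_spec(1, 0, 0, seed = 3))
  expect_identical(again$mesh$vertices, tr$mesh$vertices)

  expect_error(deformation_spec(V = 1.5), "V must be")
  expect_error(deformation_spec(M = 2), "0 or 1")
})

test_that("control displacement never exceeds the longest-axis bound", {
  cube <- make_geometry("cube", size_mm = 20, resolution = 1)
  for (s in 1:50) {
    v <- sample(c(0.1, 0.5, 1), 1)
    def <- random_deform(cube, deformation_spec(0, 0, v, seed = s))
    rec <- def$record
    expect_equal(nrow(rec$displacements), ceiling(v * 64))
    mx <- max(sqrt(rowSums(rec$displacements^2)))
    expect_lte(mx, 0.10 * rec$longest_axis)
  }
})

test_that("displaced control sets are nested across V for a fixed seed", {
  cube <- make_geometry("cube", size_mm = 20, resolution = 1)
  d1 <- random_deform(cube, deformation_spec(0, 0, 0.1, seed = 9))
  d2 <- random_deform(cube, deformation_spec(0, 0, 0.5, seed = 9))
  expect_true(all(d1$record$displaced_indices %in%
                    d2$record$displaced_indices))
  expect_equal(d2$record$displacements[seq_along(d1$record$displaced_indices), ],
               d1$record$displacements)
})

test_that("ground-truth record serialises to key-value text", {
  cube <- make_geometry("cube", size_mm = 20, resolution = 1)
  def <- random_deform(cube, deformation_spec(1, 1, 0.2, seed = 4))
  path <- withr::local_tempfile()
  write_deformation_record(def$record, path)
  lines <- readLines(path)
  expect_true(any(grepl("^V = 0.2", lines)))
  expect_true(any(grepl("^displaced_indices = ", lines)))
  got <- as.numeric(strsplit(sub("translation = ", "",
                                 grep("^translation = ", lines,
                                      value = TRUE)), " ")[[1]])
  expect_equal(got, def$record$translation, tolerance = 1e-15)
})
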
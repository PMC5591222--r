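test_that("objective matches a direct loop-summed oracle", {
  set.seed(1)
  p <- matrix(rnorm(150), ncol = 3)
  z <- matrix(rnorm(150), ncol = 3)
  R <- random_rotation()
  tr <- rigid_transform(R, c(1, -2, 0.5))
  obj <- icp_objective(list(test = p, ref = z), tr)
  direct <- 0
  for (i in 1:50)
    direct <- direct + sum((as.numeric(R %*% p[i, ]) + tr$translation -
                              z[i, ])^2)
  expect_equal(obj$sum, direct, tolerance = 1e-12)
  expect_equal(obj$mean, direct / 50, tolerance = 1e-12)

  # perfect match and a single 3-4-5 pair
  expect_equal(icp_objective(list(test = p, ref = p),
                             rigid_transform())$sum, 0)
  one <- list(test = matrix(0, 2, 3),
              ref = rbind(c(3, 4, 0), c(3, 4, 0)))
  expect_equal(icp_objective(one, rigid_transform())$sum, 50)
  expect_error(icp_objective(list(test = matrix(0, 0, 3),
                                  ref = matrix(0, 0, 3)),
                             rigid_transform()), "empty")
})

test_that("centroid is the arithmetic mean", {
  expect_equal(point_centroid(rbind(c(1, 0, 0), c(3, 0, 0))), c(2, 0, 0))
  cube <- make_geometry("cube", size_mm = 6, resolution = 1)
  expect_equal(point_centroid(cube$vertices), c(0, 0, 0))
  set.seed(2)
  x <- matrix(rnorm(300), ncol = 3)
  expect_equal(point_centroid(x), colSums(x) / 100, tolerance = 1e-12)
  expect_error(point_centroid(matrix(0, 0, 3)), "empty")
})

test_that("best_rotation recovers known rotations and the Horn oracle", {
  set.seed(3)
  for (i in 1:25) {
    P <- matrix(rnorm(600), ncol = 3)
    P <- sweep(P, 2, colMeans(P))
    R_true <- random_rotation()
    Z <- P %*% t(R_true)
    R_est <- best_rotation(P, Z)
    expect_lt(norm(R_est - R_true, "F"), 1e-9)
    expect_lt(norm(crossprod(R_est) - diag(3), "F"), 1e-9)
    expect_equal(det(R_est), 1, tolerance = 1e-9)
    # independent quaternion-method oracle agrees
    expect_lt(norm(R_est - oracle_best_rotation(P, Z), "F"), 1e-9)
  }
})

test_that("determinant correction branch returns a proper rotation", {
  # chiral 4-point set mirrored through z = 0: the unconstrained optimum
  # is a reflection, so the diag(1,1,-1) branch must fire
  P <- rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3), c(1, 1, 1))
  P <- sweep(P, 2, colMeans(P))
  Z <- P %*% diag(c(1, 1, -1))
  H <- crossprod(P, Z)
  s <- svd(H)
  expect_lt(det(s$v %*% t(s$u)), 0)        # branch is genuinely forced
  R <- best_rotation(P, Z)
  expect_equal(det(R), 1, tolerance = 1e-9)
  expect_lt(norm(crossprod(R) - diag(3), "F"), 1e-9)
  # constrained optimum beats random proper rotations on the objective
  score <- function(R) sum(diag(crossprod(Z, P %*% t(R))))
  set.seed(4)
  best_random <- max(replicate(200, score(random_rotation())))
  expect_gte(score(R), best_random)
  expect_error(best_rotation(P[1:2, ], Z[1:2, ]), "at least 3")
})

test_that("nearest-point lookup matches the exhaustive oracle", {
  set.seed(5)
  m <- make_geometry("cube", size_mm = 8, resolution = 1)  # 12 faces
  q <- matrix(runif(300, -8, 8), ncol = 3)
  fast <- closest_on_mesh(m, q)
  slow <- oracle_closest_on_mesh(m, q)
  expect_equal(fast$dist2, slow$dist2, tolerance = 1e-12)
  expect_equal(fast$point, slow$point, tolerance = 1e-9)
})

test_that("icp_step is a fixed point on perfect alignment and descends", {
  cube <- make_geometry("cube", size_mm = 10, resolution = 2)
  pts <- sample_surface(cube, 500, seed = 6)
  st <- icp_step(pts, cube, rigid_transform())
  expect_lt(st$objective$mean, 1e-24)
  expect_lt(norm(st$transform$rotation - diag(3), "F"), 1e-9)
  expect_lt(max(abs(st$transform$translation)), 1e-9)

  # translated start: one step strictly decreases the objective
  moved <- rigid_transform(diag(3), c(5, 0, 0))
  st2 <- icp_step(pts, cube, moved)
  expect_lt(st2$objective$mean, st2$objective_before$mean)
})

test_that("icp_align on a fixed point set matches the exhaustive ICP oracle", {
  cube <- make_geometry("cube", size_mm = 10, resolution = 1)
  pts <- sample_surface(cube, 60, seed = 7)$points
  start <- compose_transform(
    rotation_about(c(0, 0, 1), 0.3, center = c(0, 0, 0)),
    rigid_transform(diag(3), c(1.5, -1, 0.5)))
  pts_moved <- apply_transform(start, pts)

  # package inner loop on the fixed 60-point set
  current <- rigid_transform()
  for (it in 1:200) {
    st <- icp_step(pts_moved, cube, current)
    if (st$objective$mean >= st$objective_before$mean) break
    current <- st$transform
    if (st$objective_before$mean - st$objective$mean < 1e-9) break
  }
  ora <- oracle_icp(cube, pts_moved, rigid_transform(), 1e-9, 200)
  expect_lt(norm(current$rotation - ora$transform$rotation, "F"), 1e-9)
  expect_lt(max(abs(current$translation - ora$transform$translation)), 1e-9)
  # final pairings agree
  fast <- closest_on_mesh(cube, apply_transform(current, pts_moved))
  slow <- oracle_closest_on_mesh(cube, apply_transform(ora$transform,
                                                       pts_moved))
  expect_equal(fast$point, slow$point, tolerance = 1e-9)
})

test_that("icp_align recovers rigid motions and reports identity on self", {
  cube <- make_geometry("cube", size_mm = 20, resolution = 3)
  cfg <- icp_config(n_points = 2000, seed = 8)
  self <- icp_align(cube, cube, cfg)
  expect_true(self$trace$converged)
  expect_lt(norm(self$transform$rotation - diag(3), "F"), 1e-6)
  expect_lt(max(abs(self$transform$translation)), 1e-6)

  mv <- compose_transform(
    rigid_transform(diag(3), c(7, -3, 2)),
    rotation_about(c(1, 2, 0.5), 1.1, center = c(0, 0, 0)))

  # asymmetric shape: the recovered transform composed with the applied
  # one must be the identity (a symmetric shape may legitimately land on
  # any of its symmetry elements instead)
  blob <- make_geometry("blob", size_mm = 20, resolution = 8, seed = 4)
  al <- icp_align(blob, apply_transform(mv, blob), cfg)
  comp <- compose_transform(al$transform, mv)
  pts <- sample_surface(blob, 500, seed = 9)$points
  resid <- apply_transform(comp, pts) - pts
  expect_lt(mean(sqrt(rowSums(resid^2))), 1e-3)

  # symmetric shape: surface-level alignment must still be exact
  al2 <- icp_align(cube, apply_transform(mv, cube), cfg)
  dev <- signed_deviation(cube, apply_transform(mv, cube), al2$transform)
  expect_lt(max(abs(dev$deviation)), 5e-3)
})

test_that("accepted inner-loop objectives decrease strictly in every trace", {
  cube <- make_geometry("cube", size_mm = 20, resolution = 3)
  for (s in 1:5) {
    def <- random_deform(cube, deformation_spec(M = 1, R = 1, V = 0.2,
                                                seed = s))
    al <- icp_align(cube, def$mesh, icp_config(n_points = 1500, seed = s))
    for (rd in split(al$trace$steps, al$trace$steps$round))
      if (nrow(rd) > 1)
        expect_true(all(diff(rd$objective_mean) < 0))
    expect_lt(norm(crossprod(al$transform$rotation) - diag(3), "F"), 1e-9)
    expect_equal(det(al$transform$rotation), 1, tolerance = 1e-9)
  }
})

test_that("config validation and key-value config files work", {
  expect_error(icp_config(tau = 0), "tau")
  expect_error(icp_config(n_points = 2), "n_points")
  path <- withr::local_tempfile(lines = c("# comment", "N = 1234",
                                          "tau = 1e-7", "seed: 42"))
  cfg <- read_icp_config(path)
  expect_equal(cfg$n_points, 1234L)
  expect_equal(cfg$tau, 1e-7)
  expect_equal(cfg$seed, 42L)
})

test_that("transform file round-trips and invariants hold", {
  tr <- compose_transform(rotation_about(c(1, 1, 1), 0.7),
                          rigid_transform(diag(3), c(0.1, 2, -3)))
  path <- withr::local_tempfile()
  write_transform(tr, path)
  tr2 <- read_transform(path)
  expect_equal(tr2$rotation, tr$rotation, tolerance = 1e-12)
  expect_equal(tr2$translation, tr$translation, tolerance = 1e-12)
  inv <- invert_transform(tr)
  comp <- compose_transform(inv, tr)
  expect_lt(norm(comp$rotation - diag(3), "F"), 1e-12)
  expect_lt(max(abs(comp$translation)), 1e-12)
})
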
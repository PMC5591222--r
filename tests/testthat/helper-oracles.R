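# Independent brute-force oracles, deliberately implemented with different
# algorithms from the package internals (barycentric projection + edge
# clamping instead of Voronoi-region classification; Horn's quaternion
# method instead of the SVD construction).

# closest point on triangle (a,b,c) to p: project onto the plane, solve
# barycentrics; if outside, take the best of the three clamped edges
oracle_closest_on_triangle <- function(p, a, b, c) {
  seg <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d * d)
    u + min(1, max(0, t)) * d
  }
  e1 <- b - a
  e2 <- c - a
  A <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- c(sum((p - a) * e1), sum((p - a) * e2))
  uv <- solve(A, rhs)
  if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
    return(a + uv[1] * e1 + uv[2] * e2)
  cands <- rbind(seg(p, a, b), seg(p, b, c), seg(p, c, a))
  cands[which.min(rowSums(sweep(cands, 2, p)^2)), ]
}

# exhaustive nearest-surface-point search over all faces (lowest-index tie)
oracle_closest_on_mesh <- function(mesh, points) {
  points <- as.matrix(points)
  nq <- nrow(points)
  out_pt <- matrix(0, nq, 3)
  out_face <- integer(nq)
  out_d2 <- numeric(nq)
  for (i in seq_len(nq)) {
    best <- Inf
    for (f in seq_len(nrow(mesh$faces))) {
      q <- oracle_closest_on_triangle(points[i, ],
                                      mesh$vertices[mesh$faces[f, 1], ],
                                      mesh$vertices[mesh$faces[f, 2], ],
                                      mesh$vertices[mesh$faces[f, 3], ])
      d2 <- sum((q - points[i, ])^2)
      if (d2 < best - 1e-12) {
        best <- d2
        out_pt[i, ] <- q
        out_face[i] <- f
        out_d2[i] <- d2
      }
    }
  }
  list(point = out_pt, face = out_face, dist2 = out_d2)
}

# Horn's closed-form absolute orientation: rotation as the dominant
# eigenvector of the 4x4 quaternion matrix of the cross-covariance
oracle_best_rotation <- function(p_centered, z_centered) {
  S <- crossprod(as.matrix(p_centered), as.matrix(z_centered))
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), w^2 - x^2 - y^2 + z^2),
         3, 3)
}

# plain-loop exhaustive ICP on a fixed point set (no resampling): nearest
# point by full search, transform by the quaternion oracle
oracle_icp <- function(reference_mesh, test_points, start, tau, max_iters) {
  current <- start
  prev <- NULL
  corr <- NULL
  for (it in seq_len(max_iters)) {
    q <- apply_transform(current, test_points)
    cp <- oracle_closest_on_mesh(reference_mesh, q)
    f_before <- mean(cp$dist2)
    R <- oracle_best_rotation(sweep(test_points, 2, colMeans(test_points)),
                              sweep(cp$point, 2, colMeans(cp$point)))
    tr <- rigid_transform(R, colMeans(cp$point) -
                            as.numeric(R %*% colMeans(test_points)))
    resid <- apply_transform(tr, test_points) - cp$point
    f_new <- mean(rowSums(resid^2))
    if (f_new < f_before) {
      current <- tr
      corr <- cp
      if (f_before - f_new < tau) break
    } else break
  }
  list(transform = current, correspondences = corr)
}

# uniform random rotation matrix for test cases
random_rotation <- function() {
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  rotation_about(axis, runif(1, 0, pi))$rotation
}

expect_rounds_to_zero <- function(summ) {
  vals <- round(c(summ$mean_error, summ$upper_deviation,
                  summ$lower_deviation, summ$standard_deviation), 2)
  expect_true(all(vals == 0))
}
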
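test_that("axis_angle_to_matrix handles canonical cases and rejects bad input", {
  expect_equal(axis_angle_to_matrix(c(0, 0, 0)), diag(3))
  expect_equal(axis_angle_to_matrix(c(pi, 0, 0)), diag(c(1, -1, -1)),
               tolerance = 1e-14)
  expect_error(axis_angle_to_matrix(c(NA, 0, 0)), "finite")
  expect_error(axis_angle_to_matrix(c(Inf, 0, 0)), "finite")
})

test_that("axis_angle_to_matrix matches the quaternion oracle on random input", {
  set.seed(101)
  for (i in 1:100) {
    r <- rnorm(3, sd = runif(1, 0.01, 2))
    M <- axis_angle_to_matrix(r)
    expect_lt(max(abs(M - quat_rotation_oracle(r))), 1e-12)
    # orthonormality and orientation
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-12)
    expect_equal(det(M), 1, tolerance = 1e-12)
  }
})

test_that("canonicalisation wraps into [0, pi] and is idempotent", {
  set.seed(102)
  for (i in 1:50) {
    r <- rnorm(3) * runif(1, 0.1, 4)
    cr <- canonicalize_axis_angle(r)
    expect_lte(sqrt(sum(cr^2)), pi + 1e-12)
    # same rotation
    expect_lt(max(abs(axis_angle_to_matrix(r) - axis_angle_to_matrix(cr))),
              1e-9)
    # idempotent
    expect_equal(canonicalize_axis_angle(cr), cr, tolerance = 1e-12)
  }
  # tie at pi resolves to the lexicographically positive axis
  half_turn <- canonicalize_axis_angle(c(-pi, 0, 0))
  expect_gt(half_turn[1], 0)
})

test_that("sample_uniform_rotation is deterministic under a fixed seed", {
  set.seed(7)
  a <- sample_uniform_rotation()
  set.seed(7)
  b <- sample_uniform_rotation()
  expect_identical(a, b)
  set.seed(8)
  m <- sample_uniform_rotation(10)
  expect_equal(dim(m), c(10L, 3L))
  expect_true(all(sqrt(rowSums(m^2)) <= pi + 1e-12))
})

test_that("transform_project implements drop-z after rotation plus translation", {
  set.seed(103)
  v <- matrix(rnorm(30), 10, 3)
  cloud <- point_cloud(v)
  # identity pose returns the (x, y) columns
  expect_equal(transform_project(cloud, pose()), v[, 1:2])
  # pure translation shifts every point exactly
  p <- transform_project(cloud, pose(trans = c(0.1, -0.2)))
  expect_equal(p, cbind(v[, 1] + 0.1, v[, 2] - 0.2))
  # rotation about z commutes with the z-projection
  th <- 0.83
  pz <- transform_project(cloud, pose(rot = c(0, 0, th)))
  R2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(pz, v[, 1:2] %*% t(R2), tolerance = 1e-12)
})

test_that("pairwise 2D distances are invariant to a shared z-rotation", {
  set.seed(104)
  v <- matrix(rnorm(45), 15, 3)
  for (i in 1:5) {
    rot <- sample_uniform_rotation()
    tr <- runif(2, -0.2, 0.2)
    phi <- runif(1, 0, 2 * pi)
    p1 <- transform_project(v, pose(rot, tr))
    # z-rotate both the projected cloud's pose: Rz . R
    Rz <- axis_angle_to_matrix(c(0, 0, phi))
    rot2 <- splatfit:::matrix_to_axis_angle(Rz %*% axis_angle_to_matrix(rot))
    p2 <- transform_project(v, pose(rot2, tr))
    expect_equal(as.numeric(dist(p1)), as.numeric(dist(p2)),
                 tolerance = 1e-9)
  }
})

test_that("point_cloud and normalize_cloud enforce their invariants", {
  expect_error(point_cloud(matrix(1, 2, 2)), "3 columns")
  expect_error(point_cloud(matrix(c(1, NA, 3), 1, 3)), "finite")
  set.seed(105)
  nc <- normalize_cloud(matrix(rnorm(60, mean = 5, sd = 3), 20, 3))
  expect_equal(colMeans(nc$vertices), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(max(abs(nc$vertices)), 1, tolerance = 1e-12)
})
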
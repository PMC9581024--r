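test_that("icp_align: identical clouds converge immediately, rmsd monotone", {
  set.seed(501)
  A <- matrix(runif(60, -1, 1), 20, 3)
  res <- icp_align(A, A)
  expect_equal(res$rmsd, 0, tolerance = 1e-12)
  expect_equal(res$iterations, 1L)
  expect_error(icp_align(A[1:2, ], A), ">= 3")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(icp_align(line, A), "degenerate")
})

test_that("icp_align recovers a small known rotation", {
  set.seed(502)
  A <- matrix(runif(90, -1, 1), 30, 3)
  R <- axis_angle_to_matrix(c(0, 0, 10 * pi / 180))
  B <- A %*% t(R)
  res <- icp_align(A, B)
  expect_lt(res$rmsd, 1e-9)
  expect_lt(rotation_angle(res$rotation, R), 1e-6)
  # rmsd never increases across iterations: final <= first-iteration rmsd
  first <- icp_align(A, B, max_iter = 1L)
  expect_lte(res$rmsd, first$rmsd + 1e-15)
})

test_that("best_aligned_rmsd recovers random rigid transforms and chirality", {
  set.seed(503)
  A <- matrix(runif(120, -1, 1), 40, 3)
  for (i in 1:3) {
    R <- axis_angle_to_matrix(sample_uniform_rotation())
    t <- runif(3, -0.5, 0.5)
    B <- A %*% t(R) + rep(t, each = nrow(A))
    res <- best_aligned_rmsd(A, B)
    expect_lt(res$rmsd, 1e-6)
    expect_false(res$mirrored)
    # z-reflected source must be flagged as mirrored
    Bm <- (A %*% diag(c(1, 1, -1))) %*% t(R) + rep(t, each = nrow(A))
    resm <- best_aligned_rmsd(A, Bm)
    expect_lt(resm$rmsd, 1e-6)
    expect_true(resm$mirrored)
  }
})

test_that("best_aligned_rmsd is no worse than any single start", {
  set.seed(504)
  A <- matrix(runif(90, -1, 1), 30, 3)
  B <- matrix(runif(90, -1, 1), 30, 3)
  best <- best_aligned_rmsd(A, B)
  single <- icp_align(A, B)
  expect_lte(best$rmsd, single$rmsd + 1e-12)
  # invariance under a rigid pre-transform of the source
  R <- axis_angle_to_matrix(sample_uniform_rotation())
  A2 <- A %*% t(R) + rep(c(0.2, -0.1, 0.3), each = nrow(A))
  best2 <- best_aligned_rmsd(A2, B)
  expect_lt(abs(best2$rmsd - best$rmsd), 0.02)
})

test_that("rotation_grid24 is the proper octahedral group", {
  g <- rotation_grid24()
  expect_length(g, 24)
  for (R in g) {
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  }
  expect_equal(length(unique(lapply(g, as.numeric))), 24)
})

test_that("random_baseline is seed-reproducible and shrinks with cloud size", {
  set.seed(505)
  a <- random_baseline(40, n_trials = 3, n_starts = 6)
  set.seed(505)
  b <- random_baseline(40, n_trials = 3, n_starts = 6)
  expect_identical(a$rmsd, b$rmsd)
  # nearest-neighbour spacing shrinks as clouds densify
  set.seed(506)
  dense <- random_baseline(300, n_trials = 3, n_starts = 6)
  expect_lt(dense$mean, a$mean)
  expect_equal(a$se, sd(a$rmsd) / sqrt(3))
})
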
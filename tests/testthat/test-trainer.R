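test_that("sigma_at_epoch: boundaries, monotonicity, CEP152 floor", {
  sch <- sigma_schedule(10, 3.2, 40)   # the CEP152-style configuration
  expect_equal(sigma_at_epoch(sch, 0), 10)
  expect_lte(sigma_at_epoch(sch, 39), 3.2 * 1.01)
  expect_gte(sigma_at_epoch(sch, 39), 3.2)
  sigmas <- sigma_at_epoch(sch, 0:39)
  expect_true(all(diff(sigmas) < 0))
  expect_error(sigma_at_epoch(sch, 40), "out of range")
  expect_error(sigma_at_epoch(sch, -1), "out of range")
  expect_error(sigma_schedule(1, 2, 10), "sigma_start >= sigma_floor")
})

test_that("masked_l1 matches the hand-computed example and ignores off-mask", {
  target <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  pred <- matrix(c(0.5, 0.2, 0, 0), 2, 2, byrow = TRUE)
  # mask is the support of the target; the 0.2 lies outside it
  expect_equal(masked_l1(pred, target), 0.5)
  expect_equal(masked_l1(target, target), 0)
  # invariance to arbitrary prediction values outside the mask
  pred2 <- pred
  pred2[target == 0] <- rnorm(3) * 100
  expect_equal(masked_l1(pred2, target), 0.5)
  expect_error(masked_l1(matrix(0, 2, 3), target), "identical shapes")
})

test_that("loss gradient chain through splat and projection matches FD", {
  set.seed(701)
  cfg <- tiny_config(16)
  V <- matrix(runif(15, -0.5, 0.5), 5, 3)
  rot <- rnorm(3); tr <- c(0.05, -0.1); sig <- 1.6
  target <- splatfit:::target_image(
    list(fluorophores = matrix(runif(14, -0.6, 0.6), 7, 2)), 2, cfg, 100)
  g <- splatfit:::render_loss_grad(V, rot, tr, sig, target, cfg, 100, 0.01)
  f <- function(V) {
    P <- transform_project(V, pose(rot, tr))
    raw <- splat(P, sig, cfg)$pixels
    masked_l1(raw * (100 / sum(raw)), target)
  }
  fd <- fd_grad(f, V)
  expect_lt(rel_grad_err(g$dV, fd), 1e-5)
  fdr <- fd_grad(function(r) {
    P <- transform_project(V, pose(r, tr))
    raw <- splat(P, sig, cfg)$pixels
    masked_l1(raw * (100 / sum(raw)), target)
  }, rot)
  expect_lt(rel_grad_err(g$drot, fdr), 1e-5)
})

make_tiny_run <- function(seed = 11, epochs = 3L, n_base = 60L) {
  set.seed(seed)
  cfg <- tiny_config(16)
  ds <- make_dataset(tiny_model(), n_base = n_base, augment_factor = 1,
                     config = cfg)
  spec <- net_spec(16, base_channels = 4, max_channels = 16, n_conv = 5)
  tc <- train_config(epochs = epochs, n_points = 30, batch_size = 16,
                     seed = seed)
  sch <- sigma_schedule(2.5, 1, epochs)
  list(ds = ds, spec = spec, tc = tc, sch = sch)
}

test_that("train produces finite, decreasing losses and a full trace", {
  # constant sigma so per-epoch losses are directly comparable
  r <- make_tiny_run()
  r$sch <- sigma_schedule(1.5, 1.5, 3)
  fit <- train(r$ds, r$spec, r$tc, r$sch)
  expect_s3_class(fit$model, "point_cloud")
  expect_equal(nrow(fit$model$vertices), 30)
  expect_equal(nrow(fit$trace), 3)
  expect_true(all(is.finite(fit$trace$train_loss)))
  expect_true(all(is.finite(fit$trace$test_loss)))
  expect_lt(fit$trace$train_loss[3], fit$trace$train_loss[1])
})

test_that("train is exactly reproducible from its seed", {
  r <- make_tiny_run()
  fit1 <- train(r$ds, r$spec, r$tc, r$sch)
  fit2 <- train(r$ds, r$spec, r$tc, r$sch)
  expect_identical(fit1$model$vertices, fit2$model$vertices)
  expect_identical(fit1$trace, fit2$trace)
})

test_that("scaling all raw target intensities leaves the trajectory unchanged", {
  r <- make_tiny_run(seed = 12)
  ds_scaled <- r$ds
  ds_scaled$samples <- lapply(ds_scaled$samples, function(s) {
    s$intensity <- 7.3
    s
  })
  fit1 <- train(r$ds, r$spec, r$tc, r$sch)
  fit2 <- train(ds_scaled, r$spec, r$tc, r$sch)
  expect_equal(fit1$model$vertices, fit2$model$vertices, tolerance = 1e-12)
  expect_equal(fit1$trace$train_loss, fit2$trace$train_loss,
               tolerance = 1e-12)
})

test_that("model-matrix sizes 100/350/1000 all train on the same dataset", {
  r <- make_tiny_run(seed = 13, epochs = 1L, n_base = 24L)
  for (np in c(100L, 350L, 1000L)) {
    tc <- train_config(epochs = 1L, n_points = np, batch_size = 16,
                       seed = 13)
    fit <- train(r$ds, r$spec, tc, sigma_schedule(2.5, 1, 1))
    expect_equal(nrow(fit$model$vertices), np)
    expect_true(all(is.finite(fit$model$vertices)))
  }
})

test_that("train_direct: pose table shape, reproducibility, finite losses", {
  r <- make_tiny_run(seed = 14, epochs = 2L, n_base = 40L)
  fit <- train_direct(r$ds, r$tc <- train_config(epochs = 2L, n_points = 30,
                                                 batch_size = 16, seed = 14),
                      sigma_schedule(2.5, 1, 2))
  expect_equal(dim(fit$pose_table), c(5L, 40L))
  expect_true(all(is.finite(fit$trace$train_loss)))
  fit2 <- train_direct(r$ds, r$tc, sigma_schedule(2.5, 1, 2))
  expect_identical(fit$model$vertices, fit2$model$vertices)
})

test_that("partially trained network beats an untrained one on held-out data", {
  # information sharing through the CNN: after a short training run, the
  # masked loss on samples never seen in training drops below the loss of
  # an untrained network with the same architecture
  set.seed(15)
  cfg <- tiny_config(16)
  ds <- make_dataset(tiny_model(), n_base = 80, augment_factor = 1,
                     config = cfg)
  spec <- net_spec(16, base_channels = 4, max_channels = 16, n_conv = 5)
  tc <- train_config(epochs = 1L, n_points = 30, batch_size = 16, seed = 15,
                     test_fraction = 0.2)
  sch <- sigma_schedule(2.5, 1, 1)
  fit <- train(ds, spec, tc, sch)
  trained_test <- fit$trace$test_loss[1]
  # untrained reference: same split, same data, zero training steps
  set.seed(15)
  split <- local({
    set.seed(tc$seed)
    splatfit:::split_train_test(ds, tc$test_fraction)
  })
  set.seed(tc$seed)
  params0 <- init_network(spec)
  params0$model <- matrix(runif(30 * 3, -0.5, 0.5), 30, 3)
  untrained <- splatfit:::eval_loss(params0, spec, ds, split$test, 2.5, tc)
  expect_lt(trained_test, untrained)
})
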
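test_that("noise_config validates its fields, including the tested scatter grid", {
  expect_error(noise_config(scatter_sigma = -0.1), ">= 0")
  expect_error(noise_config(p_missing = 1.2), "\\[0, 1\\]")
  expect_error(noise_config(max_spawn = 0), ">= 1")
  # the scatter-sigma grid explored experimentally must all validate
  for (s in seq(0.03, 0.15, by = 0.03))
    expect_s3_class(noise_config(scatter_sigma = s), "noise_config")
})

test_that("apply_scatter: identity at zero, correct variance otherwise", {
  set.seed(301)
  p <- matrix(rnorm(300), 100, 3)
  expect_identical(apply_scatter(p, 0), p)
  # per-axis displacement variance equals (scatter_sigma * pixel_size)^2
  n <- 20000
  pts <- matrix(0, n, 3)
  sig <- 2.5; px <- 2 / 64
  d <- apply_scatter(pts, sig, pixel_size = px)
  v <- apply(d, 2, var)
  se <- (sig * px)^2 * sqrt(2 / (n - 1))  # SE of a Gaussian variance estimate
  expect_true(all(abs(v - (sig * px)^2) < 3 * se))
})

test_that("apply_missing: Bernoulli retention with degenerate-sample signal", {
  p <- matrix(rnorm(30), 10, 3)
  set.seed(302)
  expect_identical(apply_missing(p, 0), p)
  expect_error(apply_missing(p, 1), class = "splatfit_degenerate_sample")
  # mean retained count ~ Binomial(n, 1-p) mean (4 SE: ~6e-5 false-alarm)
  n <- 350; trials <- 1000; pm <- 0.3
  big <- matrix(0, n, 3)
  kept <- vapply(seq_len(trials),
                 function(i) nrow(apply_missing(big, pm)), numeric(1))
  se <- sqrt(n * pm * (1 - pm) / trials)
  expect_lt(abs(mean(kept) - n * (1 - pm)), 4 * se)
})

test_that("apply_spawn: 1 + Binomial(max_spawn - 1, rate) fluorophores per point", {
  p <- matrix(rnorm(30), 10, 3)
  set.seed(303)
  # rate 0 -> exactly one per point, exact positions
  expect_identical(apply_spawn(p, 0, 4), p)
  # expected counts: 1 + (m-1) r
  for (cse in list(c(4, 0.3, 1.9), c(8, 0.7, 5.9))) {
    n <- 3000
    out <- apply_spawn(matrix(0, n, 3), cse[2], cse[1])
    mean_k <- nrow(out) / n
    se <- sqrt((cse[1] - 1) * cse[2] * (1 - cse[2]) / n)
    expect_lt(abs(mean_k - cse[3]), 3 * se)
  }
})

test_that("the reference dataset arithmetic holds: 2000 base x 20 = 40,000", {
  set.seed(310)
  tiny <- point_cloud(matrix(rnorm(9), 3, 3))  # cheapest possible model
  ds <- make_dataset(tiny, n_base = 2000, augment_factor = 20,
                     config = tiny_config(16))
  expect_length(ds$samples, 40000L)
})

test_that("make_dataset: counts, determinism, self-consistency", {
  cfg <- tiny_config(16)
  model <- tiny_model()
  set.seed(304)
  ds <- make_dataset(model, n_base = 5, augment_factor = 4, config = cfg)
  expect_length(ds$samples, 20L)
  expect_equal(vapply(ds$samples, `[[`, integer(1), "base_id"),
               rep(1:5, each = 4))
  # determinism under a fixed seed
  set.seed(304)
  ds2 <- make_dataset(model, n_base = 5, augment_factor = 4, config = cfg)
  expect_identical(ds$samples, ds2$samples)
  # re-splatting stored fluorophores reproduces the image bit-exactly
  s <- ds$samples[[7]]
  img1 <- render_sample(s, 2.2, cfg)
  img2 <- splat(s$fluorophores, 2.2, cfg)
  expect_identical(img1$pixels, img2$pixels)
})

test_that("with noise disabled the pipeline equals transform_project + splat", {
  cfg <- tiny_config(16)
  model <- tiny_model()
  set.seed(305)
  ds <- make_dataset(model, n_base = 6, augment_factor = 1, config = cfg)
  for (s in ds$samples) {
    direct <- transform_project(model, s$pose)
    expect_equal(s$fluorophores, direct, tolerance = 1e-12)
  }
})

test_that("augmented samples carry a correctly composed true pose", {
  cfg <- tiny_config(16)
  model <- tiny_model()
  set.seed(306)
  ds <- make_dataset(model, n_base = 2, augment_factor = 5, config = cfg)
  for (s in ds$samples) {
    # stored fluorophores must equal the noise-free projection at the
    # stored pose even for augmented copies
    expect_equal(s$fluorophores, transform_project(model, s$pose),
                 tolerance = 1e-9)
  }
})

test_that("intensity varies with fluorophore count before normalisation, not after", {
  cfg <- tiny_config()
  model <- tiny_model()
  set.seed(307)
  noisy <- noise_config(spawn_rate = 0.7, max_spawn = 8)
  ds <- make_dataset(model, n_base = 8, augment_factor = 1, noise = noisy,
                     config = cfg)
  sums <- vapply(ds$samples,
                 function(s) sum(render_sample(s, 2, cfg)$pixels),
                 numeric(1))
  expect_gt(sd(sums) / mean(sums), 0.01)   # raw intensity really varies
  norms <- vapply(ds$samples, function(s)
    sum(normalise_image(render_sample(s, 2, cfg), 100)$pixels), numeric(1))
  expect_equal(norms, rep(100, 8), tolerance = 1e-9)
})

test_that("parametric models are deterministic and live on their surfaces", {
  m1 <- make_parametric_model("two_cylinder")
  m2 <- make_parametric_model("two_cylinder")
  expect_identical(m1$vertices, m2$vertices)
  # configured rings x points-per-ring arithmetic
  expect_equal(nrow(m1$vertices), 14 * 20 + 7 * 10)
  # distance-to-axis residuals vanish on both cylinders
  large <- m1$vertices[1:280, ]
  expect_lt(max(abs(sqrt(large[, 1]^2 + large[, 2]^2) - 0.5)), 1e-9)
  small <- m1$vertices[281:350, ]
  expect_lt(max(abs(sqrt(small[, 2]^2 + (small[, 3] - 0.3)^2) - 0.15)), 1e-9)
  # the small cylinder sits above the barrel mid-plane
  expect_gt(mean(small[, 3]), mean(large[, 3]))
  expect_error(make_parametric_model("teapot"), "arg")
  h <- make_parametric_model("helix", n_points = 120)
  expect_equal(nrow(h$vertices), 120)
})
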
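test_that("net_spec derives strides and channels from the input size", {
  s <- net_spec(128)
  expect_equal(s$n_conv, 10L)
  expect_equal(sum(s$strides == 2L), 7L)   # 128 -> 1 needs seven halvings
  expect_equal(s$channels[1], 16L)
  expect_equal(s$channels[10], 512L)
  expect_true(all(diff(s$channels) >= 0))
  expect_error(net_spec(100), "power of two")
  expect_error(net_spec(128, n_conv = 5), "at least 7")
})

test_that("forward pass has the 6-per-image shape contract and is deterministic", {
  set.seed(601)
  spec <- net_spec(16, base_channels = 4, max_channels = 16, n_conv = 5)
  params <- init_network(spec)
  x <- array(rnorm(16 * 16 * 1 * 3), c(16, 16, 1, 3))
  out1 <- net_forward(params, spec, x)$out
  expect_equal(dim(out1), c(6L, 3L))
  expect_true(all(is.finite(out1)))
  out2 <- net_forward(params, spec, x)$out
  expect_identical(out1, out2)
})

test_that("network gradients match finite differences", {
  set.seed(602)
  spec <- net_spec(8, base_channels = 3, max_channels = 8, n_conv = 4)
  params <- init_network(spec)
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  dout <- matrix(rnorm(12), 6, 2)
  fw <- net_forward(params, spec, x, keep_cache = TRUE)
  gr <- net_backward(params, spec, fw$cache, dout)
  loss <- function(p) sum(net_forward(p, spec, x)$out * dout)
  for (nm in names(params)) {
    # check a handful of coordinates per tensor
    idx <- seq(1, length(params[[nm]]),
               length.out = min(5, length(params[[nm]])))
    for (i in unique(round(idx))) {
      pp <- params
      h <- 1e-6
      pp[[nm]][i] <- params[[nm]][i] + h; lp <- loss(pp)
      pp[[nm]][i] <- params[[nm]][i] - h; lm <- loss(pp)
      fd <- (lp - lm) / (2 * h)
      expect_lt(abs(gr[[nm]][i] - fd) / (abs(fd) + 1e-8), 1e-5)
    }
  }
})

test_that("predict_pose returns valid poses and warns on unnormalised input", {
  set.seed(603)
  spec <- net_spec(16, base_channels = 4, max_channels = 16, n_conv = 5)
  net <- list(params = init_network(spec), spec = spec)
  img <- matrix(runif(256), 16, 16)
  img <- img * (100 / sum(img))
  preds <- predict_pose(net, list(img, img), scalar = 100)
  expect_length(preds, 2)
  p <- preds[[1]]
  expect_s3_class(p$pose, "pose")
  expect_gt(p$output_sigma, 0.1)
  expect_true(all(is.finite(c(p$pose$rot, p$pose$trans))))
  # eval-mode determinism: same image twice -> identical predictions
  expect_identical(preds[[1]], preds[[2]])
  expect_warning(predict_pose(net, list(img * 2), scalar = 100), "1%")
})

test_that("the sigma head is positive, centred on and bounded by the reference sigma", {
  # raw output 0 maps to sigma_ref (plus floor); extreme raw values stay
  # within the [ref/2, 2*ref] band so the blur cannot run away
  h0 <- splatfit:::head_transform(c(0, 0, 0, 0, 0, 0), 0.5, 3.2, 0.1)
  expect_equal(h0$sigma, 3.3, tolerance = 1e-9)
  hneg <- splatfit:::head_transform(c(0, 0, 0, 0, 0, -50), 0.5, 3.2, 0.1)
  expect_gte(hneg$sigma, 0.1)
  expect_equal(hneg$sigma, 3.2 / 2 + 0.1, tolerance = 1e-6)
  hpos <- splatfit:::head_transform(c(0, 0, 0, 0, 0, 50), 0.5, 3.2, 0.1)
  expect_lte(hpos$sigma, 2 * 3.2 + 0.1 + 1e-9)
  # translations bounded by the squash half-range
  hbig <- splatfit:::head_transform(c(0, 0, 0, 40, -40, 0), 0.5, 3.2, 0.1)
  expect_equal(as.numeric(hbig$trans), c(0.5, -0.5), tolerance = 1e-9)
})
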
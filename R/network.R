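#' Pose-regression network specification
#'
#' A compact convolutional network that maps a normalised single-channel
#' image to six outputs: three axis-angle rotation components, two in-plane
#' translations and one rendering sigma. The body is `n_conv` 3x3 strided
#' convolutions with leaky-rectifier activations; stride-2 layers halve the
#' spatial size until it reaches 1x1 (so a 128-pixel frame needs seven of
#' them, interleaved with three stride-1 layers), after which two fully
#' connected layers reduce to the six outputs. Channel width doubles every
#' other layer from `base_channels` up to `max_channels`.
#'
#' @param input_size image side in pixels; must be a power of two >= 8.
#' @param base_channels channels of the first convolution.
#' @param max_channels channel ceiling.
#' @param n_conv number of convolution layers (default 10).
#' @param leaky_slope negative-side slope of the leaky rectifier.
#' @param fc_size width of the hidden fully connected layer.
#' @return An object of class `net_spec`.
#' @export
net_spec <- function(input_size = 128L, base_channels = 16L,
                     max_channels = 512L, n_conv = 10L, leaky_slope = 0.1,
                     fc_size = 256L) {
  input_size <- as.integer(input_size)
  k <- log2(input_size)
  if (input_size < 8L || k != round(k))
    stop("`input_size` must be a power of two, at least 8")
  n_s2 <- as.integer(k)
  if (n_conv < n_s2)
    stop("need at least ", n_s2, " conv layers to reduce ", input_size,
         " -> 1")
  n_s1 <- n_conv - n_s2
  # interleave the stride-1 layers among the early stride-2 layers
  strides <- integer(0)
  s1_left <- n_s1
  s2_left <- n_s2
  while (s2_left > 0) {
    strides <- c(strides, 2L); s2_left <- s2_left - 1L
    if (s1_left > 0) { strides <- c(strides, 1L); s1_left <- s1_left - 1L }
  }
  strides <- c(strides, rep(1L, s1_left))
  channels <- pmin(as.integer(base_channels) * 2L^(floor((seq_len(n_conv)) / 2)),
                   as.integer(max_channels))
  structure(list(input_size = input_size, n_conv = as.integer(n_conv),
                 strides = strides, channels = channels,
                 leaky_slope = leaky_slope, fc_size = as.integer(fc_size),
                 n_out = 6L),
            class = "net_spec")
}

#' @export
print.net_spec <- function(x, ...) {
  cat(sprintf("<net_spec> %dx%d -> [%s conv, ch %s] -> fc %d -> 6\n",
              x$input_size, x$input_size,
              paste0("s", x$strides, collapse = ","),
              paste(x$channels, collapse = ","), x$fc_size))
  invisible(x)
}

#' Initialise network parameters
#'
#' He-style Gaussian initialisation scaled for the leaky rectifier; the
#' final layer starts near zero so initial pose predictions are close to
#' the identity pose. Draws from R's RNG stream.
#'
#' @param spec a [net_spec()].
#' @return Named list of parameter arrays (`convK.W`, `convK.b`, `fc1.*`,
#'   `fc2.*`).
#' @export
init_network <- function(spec) {
  params <- list()
  cin <- 1L
  gain2 <- 2 / (1 + spec$leaky_slope^2)
  for (l in seq_len(spec$n_conv)) {
    cout <- spec$channels[l]
    fan_in <- cin * 9L
    params[[sprintf("conv%d.W", l)]] <-
      matrix(stats::rnorm(cout * fan_in, sd = sqrt(gain2 / fan_in)),
             cout, fan_in)
    params[[sprintf("conv%d.b", l)]] <- numeric(cout)
    cin <- cout
  }
  params[["fc1.W"]] <- matrix(stats::rnorm(spec$fc_size * cin,
                                           sd = sqrt(gain2 / cin)),
                              spec$fc_size, cin)
  params[["fc1.b"]] <- numeric(spec$fc_size)
  params[["fc2.W"]] <- matrix(stats::rnorm(spec$n_out * spec$fc_size,
                                           sd = 0.01),
                              spec$n_out, spec$fc_size)
  params[["fc2.b"]] <- numeric(spec$n_out)
  params
}

leaky <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_grad <- function(x, slope) ifelse(x > 0, 1, slope)

#' Network forward pass
#'
#' @param params parameter list from [init_network()].
#' @param spec the matching [net_spec()].
#' @param x 4D array (H, W, 1, B) of normalised images.
#' @param keep_cache keep layer activations for [net_backward()].
#' @return List with `out` (6 x B matrix of raw head outputs) and, when
#'   requested, `cache`.
#' @export
net_forward <- function(params, spec, x, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", spec$n_conv + 2L) else NULL
  a <- x
  for (l in seq_len(spec$n_conv)) {
    z <- cpp_conv_forward(a, params[[sprintf("conv%d.W", l)]],
                          params[[sprintf("conv%d.b", l)]],
                          spec$strides[l])
    if (keep_cache) cache[[l]] <- list(x = a, z = z)
    a <- leaky(z, spec$leaky_slope)
    dim(a) <- dim(z)
  }
  d <- dim(a)
  if (d[1] != 1L || d[2] != 1L)
    stop("conv stack did not reduce to 1x1 (input size mismatch)")
  f <- matrix(a, d[3], d[4])           # C x B
  z1 <- params$fc1.W %*% f + params$fc1.b
  a1 <- leaky(z1, spec$leaky_slope)
  out <- params$fc2.W %*% a1 + params$fc2.b
  if (keep_cache) {
    cache[[spec$n_conv + 1L]] <- list(f = f, z1 = z1, a1 = a1)
    list(out = out, cache = cache)
  } else list(out = out)
}

#' Network backward pass
#'
#' @param params,spec as in [net_forward()].
#' @param cache cache returned by `net_forward(..., keep_cache = TRUE)`.
#' @param dout 6 x B upstream gradient.
#' @return Named list of parameter gradients (same shapes as `params`).
#' @export
net_backward <- function(params, spec, cache, dout) {
  grads <- list()
  fc <- cache[[spec$n_conv + 1L]]
  B <- ncol(dout)
  grads[["fc2.W"]] <- dout %*% t(fc$a1)
  grads[["fc2.b"]] <- rowSums(dout)
  da1 <- t(params$fc2.W) %*% dout
  dz1 <- da1 * leaky_grad(fc$z1, spec$leaky_slope)
  grads[["fc1.W"]] <- dz1 %*% t(fc$f)
  grads[["fc1.b"]] <- rowSums(dz1)
  df <- t(params$fc1.W) %*% dz1        # C x B
  da <- array(df, c(1L, 1L, nrow(df), B))
  for (l in rev(seq_len(spec$n_conv))) {
    cl <- cache[[l]]
    dz <- da * leaky_grad(cl$z, spec$leaky_slope)
    dim(dz) <- dim(cl$z)
    g <- cpp_conv_backward(cl$x, params[[sprintf("conv%d.W", l)]],
                           spec$strides[l], dz)
    grads[[sprintf("conv%d.W", l)]] <- g$dW
    grads[[sprintf("conv%d.b", l)]] <- as.numeric(g$db)
    da <- g$dx
  }
  grads
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(y)))

# Head transform: raw 6-vector -> pose + output sigma.
# Rotation components are unbounded axis-angle; translations are squashed
# by tanh to +/- trans_squash world units. The output-sigma is bounded to
# a band around the reference (input) sigma, sigma_ref * 2^tanh(raw), with
# a hard floor: an unbounded sigma head lets the network escape into a
# degenerate optimum where it blurs every render flat, which zeroes the
# pose and model gradients and stalls the fit. The band still lets the
# prediction absorb scatter-like blur (up to 2x) per image.
head_transform <- function(raw, trans_squash, sigma_ref, sigma_min) {
  th6 <- tanh(raw[6])
  list(rot = raw[1:3],
       trans = tanh(raw[4:5]) * trans_squash,
       sigma = max(sigma_ref, sigma_min) * 2^th6 + sigma_min,
       shift = NULL)
}

head_backward <- function(raw, drot, dtrans, dsigma, trans_squash, shift,
                          sigma_ref, sigma_min) {
  th <- tanh(raw[4:5])
  th6 <- tanh(raw[6])
  dsig_draw <- max(sigma_ref, sigma_min) * 2^th6 * log(2) * (1 - th6^2)
  c(drot, dtrans * (1 - th^2) * trans_squash, dsigma * dsig_draw)
}

#' Predict poses for a batch of images
#'
#' Runs the network in evaluation mode (the forward pass is deterministic)
#' and maps the six raw outputs to a pose and an output-sigma. Images whose
#' integrated intensity deviates by more than 1% from the normalisation
#' scalar trigger a warning: the network was trained on normalised input.
#'
#' @param net a trained network as returned by [train()] (list with
#'   `params` and `spec`), or a list with those fields.
#' @param images list of matrices, a 3D array (H, W, B), or a 4D array.
#' @param scalar normalisation scalar the images should sum to.
#' @param sigma_ref reference sigma the sigma head is centred on (pixels);
#'   predictions are bounded to `[sigma_ref/2, 2*sigma_ref]` plus the floor.
#' @param trans_squash translation squashing half-range (world units).
#' @param sigma_min hard floor on the predicted sigma (pixels).
#' @return List of `pose_prediction` objects (fields `pose`,
#'   `output_sigma`).
#' @export
predict_pose <- function(net, images, scalar = 100, sigma_ref = 2,
                         trans_squash = 0.5, sigma_min = 0.1) {
  x <- as_batch(images, net$spec$input_size)
  sums <- apply(x, 4, sum)
  if (any(abs(sums - scalar) > 0.01 * scalar))
    warning("input images deviate from the normalisation scalar by > 1%")
  out <- net_forward(net$params, net$spec, x)$out
  lapply(seq_len(ncol(out)), function(i) {
    h <- head_transform(out[, i], trans_squash, sigma_ref, sigma_min)
    structure(list(pose = pose(h$rot, h$trans), output_sigma = h$sigma),
              class = "pose_prediction")
  })
}

#' @export
print.pose_prediction <- function(x, ...) {
  cat(sprintf("<pose_prediction> rot (%.3f, %.3f, %.3f) trans (%.3f, %.3f) sigma %.3f px\n",
              x$pose$rot[1], x$pose$rot[2], x$pose$rot[3],
              x$pose$trans[1], x$pose$trans[2], x$output_sigma))
  invisible(x)
}

as_batch <- function(images, side) {
  if (is.list(images)) {
    images <- lapply(images, as_pixels)
    x <- array(0, c(side, side, 1L, length(images)))
    for (i in seq_along(images)) x[, , 1L, i] <- images[[i]]
    x
  } else if (length(dim(images)) == 2L) {
    array(images, c(dim(images), 1L, 1L))
  } else if (length(dim(images)) == 3L) {
    array(images, c(dim(images)[1:2], 1L, dim(images)[3]))
  } else images
}
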
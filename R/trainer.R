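#' Stepped coarse-to-fine input-sigma schedule
#'
#' The input-sigma controlling target-image blur starts high (around
#' diffraction-limited) and decays exponentially towards a floor, changing
#' only at epoch boundaries ("stepped curve"). Starting blurry smooths the
#' loss landscape so the model matrix can organise globally before fine
#' detail is asked for. The decay rate is chosen so the final epoch sits
#' within 1% of the floor.
#'
#' @param sigma_start initial sigma in pixels.
#' @param sigma_floor final sigma in pixels (e.g. ~3.2 px for the CEP152
#'   configuration, equivalent to 30 nm at that dataset's scale).
#' @param epochs number of training epochs.
#' @return An object of class `sigma_schedule`.
#' @export
sigma_schedule <- function(sigma_start = 10, sigma_floor = 1, epochs = 40L) {
  if (!(sigma_start >= sigma_floor) || sigma_floor <= 0)
    stop("need sigma_start >= sigma_floor > 0")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("`epochs` must be >= 1")
  decay <- if (sigma_start == sigma_floor || epochs == 1L) 0
    else log((sigma_start - sigma_floor) / (0.01 * sigma_floor))
  structure(list(sigma_start = sigma_start, sigma_floor = sigma_floor,
                 epochs = epochs, decay = decay, shape = "exponential-step"),
            class = "sigma_schedule")
}

#' Input-sigma for a given epoch
#'
#' Piecewise-constant within an epoch, non-increasing across epochs; epoch 0
#' is exactly `sigma_start` and the final epoch is within 1% of
#' `sigma_floor`.
#'
#' @param schedule a [sigma_schedule()].
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @return Sigma in pixels.
#' @export
sigma_at_epoch <- function(schedule, epoch) {
  if (any(epoch < 0) || any(epoch >= schedule$epochs))
    stop("`epoch` out of range [0, ", schedule$epochs - 1L, "]")
  if (schedule$epochs == 1L) return(rep(schedule$sigma_start, length(epoch)))
  schedule$sigma_floor + (schedule$sigma_start - schedule$sigma_floor) *
    exp(-schedule$decay * epoch / (schedule$epochs - 1L))
}

schedule_sigmas <- function(schedule) {
  sigma_at_epoch(schedule, seq_len(schedule$epochs) - 1L)
}

#' Masked L1 image loss
#'
#' Sum of absolute pixel differences restricted to the support of the
#' target: the mask is `target > threshold * max(target)`, and pixels
#' outside it are zeroed in both images, so the loss ignores anything the
#' prediction paints into empty background far from the structure.
#'
#' @param pred,target equal-shape numeric matrices.
#' @param threshold mask threshold as a fraction of the target maximum.
#' @return Non-negative scalar.
#' @export
masked_l1 <- function(pred, target, threshold = 0.01) {
  pred <- as_pixels(pred); target <- as_pixels(target)
  if (!identical(dim(pred), dim(target)))
    stop("`pred` and `target` must have identical shapes")
  mask <- target > threshold * max(target)
  sum(abs(pred[mask] - target[mask]))
}

# Gradient of masked_l1 w.r.t. pred (zero outside the mask).
masked_l1_grad <- function(pred, target, threshold = 0.01) {
  mask <- target > threshold * max(target)
  g <- sign(pred - target)
  g[!mask] <- 0
  g
}

#' Training configuration
#'
#' Defaults follow the reference protocol for simulated SMLM data: Adam at
#' learning rate 4e-4, batches of 32, 40 epochs, a 350-vertex model matrix,
#' image normalisation to a fixed integrated intensity, and a recorded seed.
#'
#' @param learning_rate Adam step size for the network (and, by default,
#'   the model matrix).
#' @param model_learning_rate Adam step size for the model matrix;
#'   `NULL` means `learning_rate`. Because Adam moves each coordinate by
#'   roughly the learning rate per step, the total distance a vertex can
#'   travel is about `lr * steps`; short (scaled-down) runs therefore need
#'   a larger matrix rate than the reference long-run value to cover the
#'   same world-space distance.
#' @param batch_size images per step.
#' @param epochs passes over the training set.
#' @param n_points rows of the model matrix (reconstruction vertices).
#' @param normalisation_scalar integrated intensity every image is scaled
#'   to before entering the network or the loss.
#' @param seed RNG seed; the whole run is reproducible from it.
#' @param test_fraction held-out fraction, split by base structure so that
#'   augmented copies of one structure never straddle the split.
#' @param trans_squash half-range of the tanh translation squash (world).
#' @param sigma_min floor of the predicted output-sigma (pixels).
#' @param mask_threshold loss mask threshold (fraction of target max).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 4e-4, batch_size = 32L,
                         epochs = 40L, n_points = 350L,
                         normalisation_scalar = 100, seed = 1L,
                         test_fraction = 0.1, trans_squash = 0.5,
                         sigma_min = 0.1, mask_threshold = 0.01,
                         model_learning_rate = NULL) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1, n_points >= 1,
            normalisation_scalar > 0, test_fraction >= 0, test_fraction < 1)
  if (is.null(model_learning_rate)) model_learning_rate <- learning_rate
  stopifnot(model_learning_rate > 0)
  structure(list(learning_rate = learning_rate,
                 model_learning_rate = model_learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_points = as.integer(n_points),
                 normalisation_scalar = normalisation_scalar,
                 seed = as.integer(seed), test_fraction = test_fraction,
                 trans_squash = trans_squash, sigma_min = sigma_min,
                 mask_threshold = mask_threshold),
            class = "train_config")
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, lr_overrides = list(),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    lr_k <- if (is.null(lr_overrides[[k]])) lr else lr_overrides[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr_k * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## ---- shared internals ----------------------------------------------------

# Render + normalise the target image of one sample at the epoch sigma.
target_image <- function(sample, sigma, config, scalar) {
  img <- splat(sample$fluorophores, sigma, config)$pixels
  intensity <- if (is.null(sample$intensity)) 1 else sample$intensity
  normalise_image(img * intensity, scalar)
}

# Gradient of image normalisation y = scalar * x / sum(x):
# dL/dx = (scalar/T) * (G - sum(G * x) / T)
normalise_backward <- function(x, G, scalar) {
  T <- sum(x)
  (scalar / T) * (G - sum(G * x) / T)
}

# Loss and gradients of one rendered model image against one target.
# Returns dV (N x 3), drot (3), dtrans (2), dsigma (scalar), loss.
render_loss_grad <- function(V, rot, trans, sigma_out, target, config,
                             scalar, mask_threshold) {
  P <- cpp_transform_project(V, rot, trans)
  raw <- splat(P, sigma_out, config)$pixels
  total <- sum(raw)
  if (total <= 0) {
    # model rendered entirely out of frame: no mask overlap, no gradient
    return(list(loss = sum(target), dV = V * 0, drot = numeric(3),
                dtrans = numeric(2), dsigma = 0))
  }
  pred <- raw * (scalar / total)
  loss <- masked_l1(pred, target, mask_threshold)
  G <- masked_l1_grad(pred, target, mask_threshold)
  Graw <- normalise_backward(raw, G, scalar)
  sg <- splat_grad(P, sigma_out, config, Graw)
  bk <- cpp_transform_project_backward(V, rot, sg$points)
  list(loss = loss, dV = bk$dV, drot = as.numeric(bk$drot),
       dtrans = as.numeric(bk$dtrans), dsigma = sg$sigma)
}

split_train_test <- function(dataset, test_fraction) {
  base_ids <- vapply(dataset$samples, `[[`, integer(1), "base_id")
  bases <- unique(base_ids)
  n_test <- floor(length(bases) * test_fraction)
  test_bases <- if (n_test > 0) sample(bases, n_test) else integer(0)
  list(train = which(!(base_ids %in% test_bases)),
       test = which(base_ids %in% test_bases))
}

## ---- CNN training --------------------------------------------------------

#' Fit a 3D model and a pose network to a dataset of 2D images
#'
#' The core fitting loop. Per step: render each sample's fluorophores at the
#' epoch's input-sigma and normalise; run the network to predict each
#' image's pose and output-sigma; render the shared model matrix under each
#' predicted pose at the predicted output-sigma through the differentiable
#' splatter; take the masked L1 loss against the target; and backpropagate
#' into both the network weights and the model-matrix coordinates, updating
#' both with Adam. The model matrix starts uniform in the centred cube of
#' half-side 0.5 and is the actual output of the procedure - the network is
#' discarded afterwards.
#'
#' @param dataset a `splat_dataset` from [make_dataset()].
#' @param spec a [net_spec()] matching the dataset frame size.
#' @param config a [train_config()].
#' @param schedule a [sigma_schedule()] with `epochs` matching `config`.
#' @param verbose print per-epoch losses.
#' @return List with `model` (the reconstructed `point_cloud`), `net`
#'   (params + spec), and `trace` (per-epoch data frame: sigma, mean train
#'   loss, mean test loss).
#' @export
train <- function(dataset, spec, config, schedule, verbose = FALSE) {
  if (schedule$epochs != config$epochs)
    stop("schedule and train_config disagree on `epochs`")
  if (spec$input_size != dataset$config$height ||
      spec$input_size != dataset$config$width)
    stop("network input size does not match the dataset frame")
  set.seed(config$seed)
  rcfg <- dataset$config
  scalar <- config$normalisation_scalar
  split <- split_train_test(dataset, config$test_fraction)
  params <- init_network(spec)
  params$model <- matrix(stats::runif(config$n_points * 3, -0.5, 0.5),
                         config$n_points, 3)
  state <- adam_init(params)
  trace <- data.frame(epoch = integer(0), sigma = numeric(0),
                      train_loss = numeric(0), test_loss = numeric(0))
  for (e in seq_len(config$epochs) - 1L) {
    sig_in <- sigma_at_epoch(schedule, e)
    ord <- sample(split$train)
    nb <- ceiling(length(ord) / config$batch_size)
    epoch_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * config$batch_size + 1L):
                   min(bi * config$batch_size, length(ord))]
      B <- length(idx)
      x <- array(0, c(rcfg$height, rcfg$width, 1L, B))
      targets <- vector("list", B)
      for (i in seq_len(B)) {
        targets[[i]] <- target_image(dataset$samples[[idx[i]]], sig_in,
                                     rcfg, scalar)
        x[, , 1L, i] <- targets[[i]]
      }
      fw <- net_forward(params, spec, x, keep_cache = TRUE)
      draw <- matrix(0, spec$n_out, B)
      dV <- params$model * 0
      batch_loss <- 0
      for (i in seq_len(B)) {
        h <- head_transform(fw$out[, i], config$trans_squash, sig_in,
                            config$sigma_min)
        g <- render_loss_grad(params$model, h$rot, h$trans, h$sigma,
                              targets[[i]], rcfg, scalar,
                              config$mask_threshold)
        batch_loss <- batch_loss + g$loss
        dV <- dV + g$dV / B
        draw[, i] <- head_backward(fw$out[, i], g$drot, g$dtrans, g$dsigma,
                                   config$trans_squash, h$shift, sig_in,
                                   config$sigma_min) / B
      }
      grads <- net_backward(params, spec, fw$cache, draw)
      grads$model <- dV
      if (!all(vapply(grads, function(g) all(is.finite(g)), logical(1))) ||
          !is.finite(batch_loss))
        stop("training diverged: non-finite loss/gradient at epoch ", e,
             ", batch ", bi)
      st <- adam_step(params, grads, state, config$learning_rate,
                      list(model = config$model_learning_rate))
      params <- st$params; state <- st$state
      epoch_loss <- epoch_loss + batch_loss / B
    }
    test_loss <- eval_loss(params, spec, dataset, split$test, sig_in, config)
    trace <- rbind(trace, data.frame(epoch = e, sigma = sig_in,
                                     train_loss = epoch_loss / nb,
                                     test_loss = test_loss))
    if (verbose)
      message(sprintf("epoch %2d  sigma %6.3f  train %10.4f  test %10.4f",
                      e, sig_in, epoch_loss / nb, test_loss))
  }
  net <- list(params = params[setdiff(names(params), "model")], spec = spec)
  list(model = point_cloud(params$model, "reconstruction"), net = net,
       trace = trace, config = config, schedule = schedule)
}

# Mean per-image masked loss of the current model/network on given indices.
eval_loss <- function(params, spec, dataset, idx, sig_in, config) {
  if (!length(idx)) return(NA_real_)
  rcfg <- dataset$config
  scalar <- config$normalisation_scalar
  total <- 0
  for (chunk in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
    B <- length(chunk)
    x <- array(0, c(rcfg$height, rcfg$width, 1L, B))
    targets <- vector("list", B)
    for (i in seq_len(B)) {
      targets[[i]] <- target_image(dataset$samples[[chunk[i]]], sig_in,
                                   rcfg, scalar)
      x[, , 1L, i] <- targets[[i]]
    }
    out <- net_forward(params, spec, x)$out
    for (i in seq_len(B)) {
      h <- head_transform(out[, i], config$trans_squash, sig_in,
                          config$sigma_min)
      P <- cpp_transform_project(params$model, h$rot, h$trans)
      raw <- splat(P, h$sigma, rcfg)$pixels
      pred <- if (sum(raw) > 0) raw * (scalar / sum(raw)) else raw
      total <- total + masked_l1(pred, targets[[i]], config$mask_threshold)
    }
  }
  total / length(idx)
}

## ---- direct-optimisation ablation ---------------------------------------

#' Direct pose-table optimisation (no network)
#'
#' Ablation of the pose network: the convolution stack is replaced by a
#' plain 5 x N table of free pose parameters (axis-angle rotation and
#' translation per training image), optimised jointly with the model matrix
#' through the same renderer and masked loss. The output-sigma is tied to
#' the epoch's input-sigma (there is no sigma head). Without the network's
#' ability to share pose information between similar images, this tends not
#' to recover the structure - which is the point of the comparison.
#'
#' @inheritParams train
#' @return List with `model`, `pose_table` (5 x N matrix), and `trace`.
#' @export
train_direct <- function(dataset, config, schedule, verbose = FALSE) {
  if (schedule$epochs != config$epochs)
    stop("schedule and train_config disagree on `epochs`")
  set.seed(config$seed)
  rcfg <- dataset$config
  scalar <- config$normalisation_scalar
  n <- length(dataset$samples)
  params <- list(
    pose_table = rbind(matrix(stats::rnorm(3 * n, sd = 0.3), 3, n),
                       matrix(0, 2, n)),
    model = matrix(stats::runif(config$n_points * 3, -0.5, 0.5),
                   config$n_points, 3))
  state <- adam_init(params)
  trace <- data.frame(epoch = integer(0), sigma = numeric(0),
                      train_loss = numeric(0))
  for (e in seq_len(config$epochs) - 1L) {
    sig_in <- sigma_at_epoch(schedule, e)
    ord <- sample(n)
    nb <- ceiling(n / config$batch_size)
    epoch_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * config$batch_size + 1L):
                   min(bi * config$batch_size, n)]
      B <- length(idx)
      dV <- params$model * 0
      dT <- params$pose_table * 0
      batch_loss <- 0
      for (i in seq_len(B)) {
        k <- idx[i]
        target <- target_image(dataset$samples[[k]], sig_in, rcfg, scalar)
        p5 <- params$pose_table[, k]
        trans <- tanh(p5[4:5]) * config$trans_squash
        g <- render_loss_grad(params$model, p5[1:3], trans, sig_in, target,
                              rcfg, scalar, config$mask_threshold)
        batch_loss <- batch_loss + g$loss
        dV <- dV + g$dV / B
        dT[1:3, k] <- g$drot / B
        dT[4:5, k] <- g$dtrans * (1 - tanh(p5[4:5])^2) *
          config$trans_squash / B
      }
      if (!is.finite(batch_loss))
        stop("training diverged: non-finite loss at epoch ", e)
      st <- adam_step(params, list(pose_table = dT, model = dV), state,
                      config$learning_rate,
                      list(model = config$model_learning_rate))
      params <- st$params; state <- st$state
      epoch_loss <- epoch_loss + batch_loss / B
    }
    trace <- rbind(trace, data.frame(epoch = e, sigma = sig_in,
                                     train_loss = epoch_loss / nb))
    if (verbose)
      message(sprintf("epoch %2d  sigma %6.3f  train %10.4f", e, sig_in,
                      epoch_loss / nb))
  }
  list(model = point_cloud(params$model, "reconstruction-direct"),
       pose_table = params$pose_table, trace = trace, config = config,
       schedule = schedule)
}
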
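#' Experimental-noise configuration
#'
#' Bundles the three noise processes observed in SMLM data: positional
#' scatter of fluorophores around their binding site (antibody offset plus
#' localisation error), incomplete labelling (missing fluorophores), and
#' multiple binding (one site emitting several fluorophores).
#'
#' @param scatter_sigma per-axis standard deviation of the positional
#'   scatter, in pixels (>= 0; converted to world units at the frame scale).
#' @param p_missing probability that a ground-truth point carries no
#'   fluorophore at all.
#' @param spawn_rate per-slot probability in the multiple-binding model:
#'   each point emits `1 + Binomial(max_spawn - 1, spawn_rate)` fluorophores.
#' @param max_spawn maximum fluorophores a single point may emit (>= 1).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(scatter_sigma = 0, p_missing = 0, spawn_rate = 0,
                         max_spawn = 1L) {
  if (scatter_sigma < 0) stop("`scatter_sigma` must be >= 0")
  if (p_missing < 0 || p_missing > 1) stop("`p_missing` must be in [0, 1]")
  if (spawn_rate < 0 || spawn_rate > 1) stop("`spawn_rate` must be in [0, 1]")
  max_spawn <- as.integer(max_spawn)
  if (is.na(max_spawn) || max_spawn < 1L) stop("`max_spawn` must be >= 1")
  structure(list(scatter_sigma = as.numeric(scatter_sigma),
                 p_missing = as.numeric(p_missing),
                 spawn_rate = as.numeric(spawn_rate),
                 max_spawn = max_spawn),
            class = "noise_config")
}

#' Scatter fluorophore positions
#'
#' Displaces every point by an independent isotropic 3D Gaussian with
#' per-axis standard deviation `scatter_sigma` pixels, converted to world
#' units through `pixel_size` (world units per pixel, 2/width for the
#' standard frame). Scatter is applied in 3D, before projection: the
#' physical label offset is three-dimensional.
#'
#' @param points N x 3 matrix.
#' @param scatter_sigma pixels, >= 0.
#' @param pixel_size world units per pixel.
#' @return Displaced N x 3 matrix.
#' @export
apply_scatter <- function(points, scatter_sigma, pixel_size = 2 / 128) {
  if (scatter_sigma < 0) stop("`scatter_sigma` must be >= 0")
  p <- as.matrix(points)
  if (scatter_sigma == 0 || nrow(p) == 0L) return(p)
  sd_world <- scatter_sigma * pixel_size
  p + matrix(stats::rnorm(length(p), sd = sd_world), nrow(p), ncol(p))
}

#' Remove unlabelled points
#'
#' Bernoulli dropout of ground-truth points: each is retained independently
#' with probability `1 - p_missing`. An empty result is a degenerate sample
#' and raises a condition of class `splatfit_degenerate_sample`; the dataset
#' generator catches it and redraws.
#'
#' @param points N x 3 matrix.
#' @param p_missing probability in \[0, 1\].
#' @return M x 3 matrix, M <= N.
#' @export
apply_missing <- function(points, p_missing) {
  if (p_missing < 0 || p_missing > 1) stop("`p_missing` must be in [0, 1]")
  p <- as.matrix(points)
  keep <- stats::runif(nrow(p)) >= p_missing
  if (!any(keep))
    stop(structure(class = c("splatfit_degenerate_sample", "error",
                             "condition"),
                   list(message = "all fluorophores missing (degenerate sample)",
                        call = sys.call(-1))))
  p[keep, , drop = FALSE]
}

#' Multiple-binding expansion with per-fluorophore scatter
#'
#' Each ground-truth point emits `k = 1 + Binomial(max_spawn - 1,
#' spawn_rate)` fluorophores, guaranteeing at least one per labelled point
#' (missing-ness is controlled solely by [apply_missing()]). Every emitted
#' fluorophore then receives an independent scatter displacement.
#'
#' @param points N x 3 matrix.
#' @inheritParams noise_config
#' @inheritParams apply_scatter
#' @return M x 3 matrix of fluorophores, M >= N.
#' @export
apply_spawn <- function(points, spawn_rate, max_spawn, scatter_sigma = 0,
                        pixel_size = 2 / 128) {
  max_spawn <- as.integer(max_spawn)
  if (max_spawn < 1L) stop("`max_spawn` must be >= 1")
  p <- as.matrix(points)
  n <- nrow(p)
  k <- if (max_spawn == 1L) rep(1L, n)
       else 1L + stats::rbinom(n, max_spawn - 1L, spawn_rate)
  out <- p[rep(seq_len(n), k), , drop = FALSE]
  apply_scatter(out, scatter_sigma, pixel_size)
}

# Full noise pipeline on 3D ground-truth vertices: dropout, then spawning
# (which includes the per-fluorophore scatter). With noise disabled this is
# the identity.
apply_noise <- function(vertices, noise, pixel_size) {
  v <- apply_missing(vertices, noise$p_missing)
  apply_spawn(v, noise$spawn_rate, noise$max_spawn, noise$scatter_sigma,
              pixel_size)
}

rot2d <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# One posed, noise-corrupted sample. Degenerate (empty) draws are retried.
simulate_sample <- function(vertices, noise, pixel_size, trans_range,
                            max_tries = 20L) {
  for (i in seq_len(max_tries)) {
    rot <- sample_uniform_rotation()
    trans <- stats::runif(2, -trans_range, trans_range)
    fl3 <- tryCatch(apply_noise(vertices, noise, pixel_size),
                    splatfit_degenerate_sample = function(e) NULL)
    if (is.null(fl3)) next
    ps <- pose(rot, trans)
    return(list(fluorophores = cpp_transform_project(fl3, rot, trans),
                pose = ps))
  }
  stop("could not draw a non-degenerate sample in ", max_tries, " tries")
}

#' Generate a synthetic training dataset
#'
#' Draws `n_base` independently posed samples of the model (Haar-uniform
#' rotations, in-plane translations uniform in `+/- trans_range`), corrupts
#' the 3D points with the configured noise, projects away z, and augments
#' each base sample `augment_factor` times by a uniform-random in-plane
#' rotation of the full fluorophore set about the frame centre (the same
#' augmentation applied to experimental localisation data). Samples store
#' their 2D fluorophores and true pose; images are rendered on demand at any
#' requested input-sigma via [render_sample()], which is what lets the
#' training loop anneal sigma per epoch.
#'
#' @param model ground-truth `point_cloud` (normalised to \[-1,1\]^3).
#' @param n_base number of independently posed base samples.
#' @param augment_factor in-plane augmentation multiplier (>= 1); the total
#'   dataset size is `n_base * augment_factor`.
#' @param noise a [noise_config()].
#' @param config a [render_config()] fixing the frame and pixel scale.
#' @param trans_range half-width of the uniform translation distribution in
#'   world units. The default 0.3 keeps a \[-1,1\]-normalised model inside a
#'   128 x 128 frame.
#' @return An object of class `splat_dataset`.
#' @export
make_dataset <- function(model, n_base, augment_factor = 1L,
                         noise = noise_config(), config = render_config(),
                         trans_range = 0.3) {
  if (n_base < 1L) stop("`n_base` must be >= 1")
  if (augment_factor < 1L) stop("`augment_factor` must be >= 1")
  vertices <- as_vertices(model)
  pixel_size <- 1 / pixel_scale(config)
  samples <- vector("list", n_base * augment_factor)
  k <- 0L
  for (b in seq_len(n_base)) {
    base <- simulate_sample(vertices, noise, pixel_size, trans_range)
    for (a in seq_len(augment_factor)) {
      k <- k + 1L
      if (a == 1L) {
        samples[[k]] <- c(base, list(base_id = b))
      } else {
        phi <- stats::runif(1, 0, 2 * pi)
        Rz <- rot2d(phi)
        fl <- base$fluorophores %*% t(Rz)
        # composed true pose: z-rotation after the base pose
        rot <- canonicalize_axis_angle(matrix_to_axis_angle(
          axis_angle_to_matrix(c(0, 0, phi)) %*%
            axis_angle_to_matrix(base$pose$rot)))
        trans <- drop(Rz %*% base$pose$trans)
        samples[[k]] <- list(fluorophores = fl, pose = pose(rot, trans),
                             base_id = b)
      }
    }
  }
  structure(list(samples = samples,
                 model = if (inherits(model, "point_cloud")) model
                         else point_cloud(vertices),
                 noise = noise, config = config,
                 n_base = as.integer(n_base),
                 augment_factor = as.integer(augment_factor),
                 trans_range = trans_range),
            class = "splat_dataset")
}

#' @export
print.splat_dataset <- function(x, ...) {
  cat(sprintf(
    "<splat_dataset> %d samples (%d base x %d augment), %d x %d frame\n",
    length(x$samples), x$n_base, x$augment_factor,
    x$config$height, x$config$width))
  invisible(x)
}

#' Render one dataset sample at a given input-sigma
#'
#' @param sample an element of `dataset$samples`.
#' @param sigma input-sigma in pixels.
#' @param config a [render_config()].
#' @return A `rendered_image`.
#' @export
render_sample <- function(sample, sigma, config) {
  splat(sample$fluorophores, sigma, config)
}

# Rotation matrix -> canonical axis-angle (used to compose augmentations).
matrix_to_axis_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (pi - th > 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(th))
  } else {
    # near half-turn: extract axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonals
    i <- which.max(ax)
    if (ax[i] > 0) {
      ax <- B[, i] / ax[i]
      ax <- ax / sqrt(sum(ax^2))
    }
  }
  canonicalize_axis_angle(th * ax)
}

cylinder_points <- function(radius, height, rings, per_ring, axis = "z",
                            centre = c(0, 0, 0), phase = 0) {
  z <- if (rings == 1L) 0 else seq(-height / 2, height / 2, length.out = rings)
  ang <- seq(0, 2 * pi, length.out = per_ring + 1L)[seq_len(per_ring)] + phase
  g <- expand.grid(a = ang, h = z)
  pts <- cbind(radius * cos(g$a), radius * sin(g$a), g$h)
  perm <- switch(axis, z = c(1, 2, 3), x = c(3, 1, 2), y = c(1, 3, 2),
                 stop("axis must be x, y or z"))
  pts <- pts[, perm, drop = FALSE]
  sweep(pts, 2, centre, `+`)
}

#' Built-in parametric ground-truth models
#'
#' `two_cylinder` approximates the CEP152/HsSAS-6 complex: a large cylinder
#' (the CEP152 toroid barrel) with a smaller cylinder (the HsSAS-6
#' cartwheel stem) perpendicular to it and offset towards the top of the
#' larger structure. `helix` is a single helical curve; `random_blob` is an
#' isotropic Gaussian cluster (drawn from R's RNG stream).
#'
#' @param name one of `"two_cylinder"`, `"helix"`, `"random_blob"`.
#' @param ... shape parameters. `two_cylinder`: `r_large` (0.5), `h_large`
#'   (1.0), `rings_large` (14), `per_ring_large` (20), `r_small` (0.15),
#'   `h_small` (0.5), `rings_small` (7), `per_ring_small` (10), `z_offset`
#'   (0.3). `helix`: `n_points` (350), `turns` (3), `radius` (0.7),
#'   `height` (1.2). `random_blob`: `n_points` (350), `sd` (0.4).
#' @return A `point_cloud` (not yet normalised; pass through
#'   [normalize_cloud()] before simulation).
#' @export
make_parametric_model <- function(name = c("two_cylinder", "helix",
                                           "random_blob"), ...) {
  name <- match.arg(name)
  args <- list(...)
  take <- function(nm, default) if (!is.null(args[[nm]])) args[[nm]] else default
  v <- switch(name,
    two_cylinder = {
      large <- cylinder_points(take("r_large", 0.5), take("h_large", 1.0),
                               take("rings_large", 14L),
                               take("per_ring_large", 20L), axis = "z")
      # small cylinder sticks out along +x, perpendicular to the barrel
      # axis, centred above the mid-plane ("towards the top")
      r_l <- take("r_large", 0.5); h_s <- take("h_small", 0.5)
      small <- cylinder_points(take("r_small", 0.15), h_s,
                               take("rings_small", 7L),
                               take("per_ring_small", 10L), axis = "x",
                               centre = c(r_l + h_s / 2,
                                          0, take("z_offset", 0.3)))
      rbind(large, small)
    },
    helix = {
      n <- take("n_points", 350L)
      t <- seq(0, 1, length.out = n)
      turns <- take("turns", 3); rad <- take("radius", 0.7)
      h <- take("height", 1.2)
      cbind(rad * cos(2 * pi * turns * t), rad * sin(2 * pi * turns * t),
            h * (t - 0.5))
    },
    random_blob = {
      n <- take("n_points", 350L)
      matrix(stats::rnorm(3 * n, sd = take("sd", 0.4)), n, 3)
    })
  point_cloud(v, name)
}

#' Write a dataset to disk as a reusable fixture
#'
#' Emits per-sample TIFF images rendered at `sigma`, a tab-delimited
#' manifest (sample id, base id, pose, sigma, relative image path) and the
#' ground-truth model as PLY.
#'
#' @param dataset a `splat_dataset`.
#' @param dir output directory (created if needed).
#' @param sigma input-sigma at which to render the images.
#' @param seed optional seed to record in the manifest for provenance.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir, sigma, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  n <- length(dataset$samples)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- dataset$samples[[i]]
    rel <- file.path("images", sprintf("sample_%05d.tif", i))
    img <- render_sample(s, sigma, dataset$config)
    write_tiff(img$pixels, file.path(dir, rel))
    rows[[i]] <- data.frame(id = i, base_id = s$base_id,
                            rx = s$pose$rot[1], ry = s$pose$rot[2],
                            rz = s$pose$rot[3], tx = s$pose$trans[1],
                            ty = s$pose$trans[2], sigma = sigma, path = rel)
  }
  manifest <- file.path(dir, "manifest.tsv")
  df <- do.call(rbind, rows)
  attr(df, "seed") <- seed
  writeLines(sprintf("# seed: %s", seed), manifest)
  suppressWarnings(utils::write.table(df, manifest, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  write_pointcloud(dataset$model, file.path(dir, "ground_truth.ply"), "PLY")
  invisible(manifest)
}
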
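#' Rendering configuration
#'
#' Fixes the image geometry: pixel grid size, the affine world-to-pixel map
#' (world \[-1, 1\] spans the full frame, pixel centres at half-integers,
#' y down, 0-based) and the truncation radius of each splatted Gaussian in
#' multiples of sigma.
#'
#' @param height,width image size in pixels (>= 8).
#' @param truncation_radius cutoff radius in sigmas (>= 3). Beyond 4 sigma
#'   the neglected tail mass is below 3.4e-4 of the peak.
#' @return An object of class `render_config`.
#' @export
render_config <- function(height = 128L, width = 128L, truncation_radius = 4) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 8L || width < 8L) stop("image size must be at least 8 x 8")
  if (truncation_radius < 3) stop("`truncation_radius` must be >= 3")
  structure(list(height = height, width = width,
                 truncation_radius = as.numeric(truncation_radius)),
            class = "render_config")
}

#' Map world coordinates to pixel coordinates
#'
#' u = (x + 1) / 2 * width, v = (y + 1) / 2 * height. The inverse of the
#' map used when interpreting rendered images.
#'
#' @param points2d N x 2 matrix of world (x, y).
#' @param config a [render_config()].
#' @return N x 2 matrix of pixel (u, v).
#' @export
world_to_pixel <- function(points2d, config) {
  p <- as.matrix(points2d)
  cbind((p[, 1] + 1) / 2 * config$width,
        (p[, 2] + 1) / 2 * config$height)
}

#' @rdname world_to_pixel
#' @param pixels N x 2 matrix of pixel (u, v).
#' @export
pixel_to_world <- function(pixels, config) {
  p <- as.matrix(pixels)
  cbind(p[, 1] / config$width * 2 - 1,
        p[, 2] / config$height * 2 - 1)
}

#' Pixels per world unit (isotropic for square frames).
#' @param config a [render_config()].
#' @return Scalar scale factor, pixels per world unit.
#' @export
pixel_scale <- function(config) config$width / 2

new_rendered_image <- function(pixels, sigma) {
  structure(list(pixels = pixels, sigma = sigma), class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image> %d x %d, sigma = %.3f px, sum = %.4g\n",
              nrow(x$pixels), ncol(x$pixels), x$sigma, sum(x$pixels)))
  invisible(x)
}

as_pixels <- function(img) {
  if (inherits(img, "rendered_image")) img$pixels else as.matrix(img)
}

#' Render a 2D point set as a sum of Gaussians
#'
#' The image-formation model: every point contributes an isotropic Gaussian
#' of width `sigma` (pixels) and unit peak amplitude, evaluated at pixel
#' centres and truncated beyond `truncation_radius * sigma`. Amplitudes are
#' unnormalised so integrated intensity scales with the number of
#' fluorophores, as in real SMLM reconstructions; intensity normalisation is
#' applied afterwards at image level (see [normalise_image()]). Points
#' outside the frame are kept and contribute their in-frame tails, so
#' gradients can pull them back into view. The result is differentiable in
#' every point coordinate and in sigma (see [splat_grad()]).
#'
#' @param points2d N x 2 matrix of world coordinates (may be 0-row).
#' @param sigma Gaussian width in pixels, > 0.
#' @param config a [render_config()].
#' @return A `rendered_image` (pixels matrix `height` x `width`, plus the
#'   generating sigma).
#' @export
splat <- function(points2d, sigma, config) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single positive number")
  p <- as.matrix(points2d)
  if (nrow(p) == 0L)
    return(new_rendered_image(matrix(0, config$height, config$width), sigma))
  if (!all(is.finite(p))) stop("points must be finite")
  px <- world_to_pixel(p, config)
  img <- cpp_splat(px, sigma, config$height, config$width,
                   config$truncation_radius)
  new_rendered_image(img, sigma)
}

#' Gradients of the splat renderer
#'
#' Given the upstream gradient of a scalar loss with respect to every pixel,
#' returns the analytic gradient with respect to each world point coordinate
#' and with respect to sigma.
#'
#' @param points2d N x 2 matrix of world coordinates.
#' @param sigma Gaussian width in pixels.
#' @param config a [render_config()].
#' @param grad_pixels `height` x `width` matrix, dLoss/dpixels.
#' @return List with `points` (N x 2, dLoss/dworld-coords) and `sigma`
#'   (scalar dLoss/dsigma).
#' @export
splat_grad <- function(points2d, sigma, config, grad_pixels) {
  p <- as.matrix(points2d)
  if (nrow(p) == 0L) return(list(points = p, sigma = 0))
  px <- world_to_pixel(p, config)
  g <- cpp_splat_backward(px, sigma, config$height, config$width,
                          config$truncation_radius, as_pixels(grad_pixels))
  # chain through the world->pixel affine map
  gp <- cbind(g$dpoints[, 1] * config$width / 2,
              g$dpoints[, 2] * config$height / 2)
  list(points = gp, sigma = g$dsigma)
}

#' Normalise a rendered image to a fixed integrated intensity
#'
#' Divides by the integrated intensity and multiplies by a fixed scalar, so
#' the output sums exactly to `scalar` regardless of how many fluorophores
#' produced it. This is what makes datasets with 5,000-30,000 localisations
#' per structure comparable inside one network.
#'
#' @param img a `rendered_image` or plain matrix.
#' @param scalar target integrated intensity.
#' @return Same type as `img`, rescaled.
#' @export
normalise_image <- function(img, scalar = 100) {
  px <- as_pixels(img)
  tot <- sum(px)
  if (tot <= 0) stop("cannot normalise an all-zero image (degenerate input)")
  out <- px * (scalar / tot)
  if (inherits(img, "rendered_image")) new_rendered_image(out, img$sigma)
  else out
}
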
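#' Construct a 3D point cloud
#'
#' The basic container shared by ground-truth models, simulator output and
#' the learned reconstruction: an N x 3 matrix of vertex coordinates in
#' world units (nominal extent \[-1, 1\] per axis) plus a label.
#'
#' @param vertices numeric N x 3 matrix (or coercible) of finite coordinates.
#' @param label character tag carried through for bookkeeping.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(vertices, label = "cloud") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L)
    stop("`vertices` must have exactly 3 columns")
  if (nrow(vertices) < 1L)
    stop("a point cloud needs at least one vertex")
  if (!all(is.finite(vertices)))
    stop("all vertex coordinates must be finite")
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, label = as.character(label)[1]),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> '%s': %d vertices, extent [%.3f, %.3f]\n",
              x$label, nrow(x$vertices), min(x$vertices), max(x$vertices)))
  invisible(x)
}

# Accept either a point_cloud or a bare matrix.
as_vertices <- function(x) {
  if (inherits(x, "point_cloud")) x$vertices else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

#' Rescale a cloud to the canonical world cube
#'
#' Centres the vertices on their centroid and rescales isotropically so the
#' largest absolute coordinate is 1, i.e. the model fits in \[-1, 1\]^3.
#' All ground-truth models are normalised this way at load time, which fixes
#' the world space in which RMSD values (and the random-cloud baseline) are
#' expressed.
#'
#' @param cloud a `point_cloud` or N x 3 matrix.
#' @return A `point_cloud` with normalised vertices.
#' @export
normalize_cloud <- function(cloud) {
  v <- as_vertices(cloud)
  lab <- if (inherits(cloud, "point_cloud")) cloud$label else "cloud"
  v <- sweep(v, 2, colMeans(v))
  s <- max(abs(v))
  if (s > 0) v <- v / s
  point_cloud(v, lab)
}

#' Construct a pose
#'
#' A rigid placement of the model for one image: an axis-angle rotation
#' (direction = axis, norm = angle in radians) and an in-plane translation.
#' There is no z-translation: the images are orthographic z-projections.
#'
#' @param rot numeric length-3 axis-angle vector.
#' @param trans numeric length-2 translation (Tx, Ty) in world units.
#' @return An object of class `pose`.
#' @export
pose <- function(rot = c(0, 0, 0), trans = c(0, 0)) {
  rot <- as.numeric(rot); trans <- as.numeric(trans)
  if (length(rot) != 3L || !all(is.finite(rot)))
    stop("`rot` must be 3 finite numbers (axis-angle)")
  if (length(trans) != 2L || !all(is.finite(trans)))
    stop("`trans` must be 2 finite numbers (Tx, Ty)")
  structure(list(rot = rot, trans = trans), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> rot = (%.4f, %.4f, %.4f), trans = (%.4f, %.4f)\n",
              x$rot[1], x$rot[2], x$rot[3], x$trans[1], x$trans[2]))
  invisible(x)
}

#' Convert an axis-angle vector to a rotation matrix
#'
#' Rodrigues' formula with series-safe coefficients near zero angle.
#'
#' @param rot numeric length-3 axis-angle vector (radians * unit axis).
#' @return A 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @export
axis_angle_to_matrix <- function(rot) {
  rot <- as.numeric(rot)
  if (length(rot) != 3L || !all(is.finite(rot)))
    stop("`rot` must be 3 finite numbers")
  cpp_axis_angle_to_matrix(rot)
}

#' Canonicalise an axis-angle vector
#'
#' Wraps the rotation angle into \[0, pi\]. Angles above pi are replaced by
#' the equivalent rotation of 2*pi - theta about the flipped axis. The tie
#' at exactly pi (where w and -w encode the same rotation) is resolved in
#' favour of the lexicographically positive axis. Idempotent.
#'
#' @param rot numeric length-3 axis-angle vector.
#' @return Canonical axis-angle vector with norm in \[0, pi\].
#' @export
canonicalize_axis_angle <- function(rot) {
  rot <- as.numeric(rot)
  th <- sqrt(sum(rot^2))
  if (th == 0) return(rot)
  axis <- rot / th
  th <- th %% (2 * pi)
  if (th > pi) {
    th <- 2 * pi - th
    axis <- -axis
  }
  if (abs(th - pi) < 1e-12) {
    # w and -w are the same half-turn: pick the lexicographically positive axis
    nz <- which(abs(axis) > 1e-12)
    if (length(nz) && axis[nz[1]] < 0) axis <- -axis
  }
  th * axis
}

#' Draw Haar-uniform random rotations
#'
#' Samples uniformly from SO(3) by normalising 4D standard Gaussian draws
#' into unit quaternions (provably Haar-uniform) and converting to canonical
#' axis-angle form. Uses R's global RNG stream, so results are reproducible
#' under [set.seed()].
#'
#' @param n number of rotations to draw.
#' @return If `n == 1` a length-3 axis-angle vector, otherwise an n x 3
#'   matrix with one rotation per row.
#' @export
sample_uniform_rotation <- function(n = 1L) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  # q = (w, x, y, z); angle = 2*acos(|w|), axis = sign(w)*(x,y,z)/sin(th/2)
  w <- q[, 1]
  s <- sign(w + (w == 0))            # map w=0 to +1
  w <- abs(w)
  w <- pmin(w, 1)
  half <- acos(w)
  sinh_ <- sqrt(pmax(1 - w^2, 0))
  axis <- q[, 2:4, drop = FALSE] * s
  scale <- ifelse(sinh_ < 1e-12, 2, 2 * half / sinh_)
  out <- axis * scale
  out <- t(apply(out, 1, canonicalize_axis_angle))
  if (n == 1L) drop(out) else out
}

#' Rotate, project away z, and translate in-plane
#'
#' Applies the pose rotation to the vertices, drops the z coordinate
#' (orthographic projection along the optical axis) and adds the in-plane
#' translation. Vertex order is preserved.
#'
#' @param points a `point_cloud` or N x 3 matrix.
#' @param pose a [pose()].
#' @return N x 2 matrix of projected world coordinates.
#' @export
transform_project <- function(points, pose) {
  v <- as_vertices(points)
  cpp_transform_project(v, pose$rot, pose$trans)
}
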
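# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the quaternion conversion checks the Rodrigues
# implementation, and central finite differences check every analytic
# gradient.

# Axis-angle -> rotation matrix via unit quaternion (independent of the
# package's Rodrigues formula).
quat_rotation_oracle <- function(rot) {
  th <- sqrt(sum(rot^2))
  if (th < 1e-14) return(diag(3))
  ax <- rot / th
  q <- c(cos(th / 2), sin(th / 2) * ax)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Central finite difference of a scalar function of a vector/matrix.
fd_grad <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Max relative error between analytic and FD gradients, ignoring entries
# whose FD gradient is negligible relative to the largest one.
rel_grad_err <- function(analytic, fd) {
  big <- abs(fd) > 1e-6 * max(abs(fd), 1e-12)
  if (!any(big)) return(0)
  max(abs(analytic[big] - fd[big]) / abs(fd[big]))
}

# Small shared fixtures.
tiny_config <- function(side = 32L) render_config(side, side)

tiny_model <- function() {
  normalize_cloud(make_parametric_model(
    "two_cylinder", rings_large = 5L, per_ring_large = 4L,
    rings_small = 2L, per_ring_small = 5L))  # 30 vertices
}

# Geodesic angle (radians) between two rotation matrices.
rotation_angle <- function(R1, R2) {
  ct <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(min(1, max(-1, ct)))
}
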
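# Small 3D vector helpers used by template construction and Monte Carlo moves.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# Rotation matrix for a right-handed rotation by `angle` degrees about `axis`.
rotation_matrix <- function(axis, angle) {
  u <- unit(axis)
  th <- angle * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c1 + s1 * K + (1 - c1) * (u %o% u)
}

# Rotate rows of `xyz` by `angle` degrees about the axis through `origin`
# with direction `axis`.
rotate_about_axis <- function(xyz, origin, axis, angle) {
  R <- rotation_matrix(axis, angle)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
}

# Uniformly random rotation matrix (from a random axis and angle via
# quaternion construction); consumes 4 uniforms from R's RNG stream.
random_rotation_matrix <- function() {
  repeat {
    q <- runif(4, -1, 1)
    n2 <- sum(q^2)
    if (n2 > 1e-6 && n2 <= 1) break
  }
  q <- q / sqrt(n2)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Orthonormal frame with first axis along `d` (arbitrary but deterministic
# perpendicular pair).
local_frame <- function(d) {
  e1 <- unit(d)
  ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- unit(ref - sum(ref * e1) * e1)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}
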
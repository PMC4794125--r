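# Rigid transforms and the two needle pose compositions.
#
# World frame Sigma: origin at needle 1's target, z vertical-up, units mm,
# right-handed.  A rigid_transform maps local coordinates to world:
# p_world = R p_local + t.

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector \[mm\].
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            all(is.finite(rotation)), all(is.finite(translation)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation block is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation block has determinant -1 (reflection)")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("  translation [mm]:", format(x$t, digits = 6), "\n")
  print(x$R, digits = 6)
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `rt_compose(A, B)` returns the transform applying `B` first, then `A`.
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param x A `rigid_transform`.
#' @return A `rigid_transform` with `rt_compose(x, rt_inverse(x))` = identity.
#' @export
rt_inverse <- function(x) {
  rigid_transform(t(x$R), as.numeric(-crossprod(x$R, x$t)))
}

#' Apply a rigid transform to points
#' @param x A `rigid_transform`.
#' @param p length-3 vector or 3-row matrix of points (columns are points).
#' @return Transformed points, same shape as `p`.
#' @export
rt_apply <- function(x, p) {
  if (is.matrix(p)) x$R %*% p + x$t else as.numeric(x$R %*% p) + x$t
}

# Elementary rotations (world-frame conventions used by the pose formulas).
rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}
rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}
rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}
drot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(-s_, 0, -c_, 0, 0, 0, c_, 0, -s_), 3, 3)
}
drot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(-s_, c_, 0, -c_, -s_, 0, 0, 0, 0), 3, 3)
}

# Unit quaternion (w, x, y, z) <-> rotation matrix; used by the JSON schema.
quat_to_rot <- function(q) {
  q <- as.numeric(q)
  stopifnot(length(q) == 4L, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero quaternion")
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Polar/azimuth angles of an insertion trajectory
#'
#' The needle axis points from the (compensated) target to the entry point.
#' `theta` is the polar angle from the +z axis, `phi` the azimuth measured
#' with a full-quadrant two-argument arctangent.
#'
#' @param entry length-3 entry point \[mm\].
#' @param target length-3 (compensated) target point \[mm\].
#' @return Named numeric vector `c(theta =, phi =)` in radians.
#' @export
trajectory_angles <- function(entry, target) {
  d <- as.numeric(entry) - as.numeric(target)
  len <- sqrt(sum(d^2))
  if (!is.finite(len) || len < 1e-12)
    stop("zero-length trajectory: entry coincides with target")
  theta <- atan2(sqrt(d[1]^2 + d[2]^2), d[3])
  phi <- if (sqrt(d[1]^2 + d[2]^2) < 1e-12) 0 else atan2(d[2], d[1])
  c(theta = theta, phi = phi)
}

# Rotation part shared by the needle-head poses: Rz(phi) Ry(theta) Ry(pi/2).
needle_rotation <- function(theta, phi) {
  rot_z(phi) %*% rot_y(theta) %*% rot_y(pi / 2)
}

#' Pose of an inserted needle's head (obstacle transform)
#'
#' Homogeneous transform from the head-local frame of an already inserted
#' needle to the world frame: a translation to the head centre
#' `o' = target + (l/2) (sin th cos ph, sin th sin ph, cos th)`, followed by
#' Rz(phi), Ry(theta) and a fixed Ry(pi/2) aligning the head's long local
#' x-axis with the needle axis.
#'
#' @param inserted A `trajectory` (see [trajectory()]) of the inserted needle.
#' @param geom A [needle_geometry()].
#' @return A `rigid_transform`.
#' @export
obstacle_transform <- function(inserted, geom) {
  tgt <- target_position(inserted$target)
  ang <- trajectory_angles(inserted$entry, tgt)
  th <- ang[["theta"]]; ph <- ang[["phi"]]
  l2 <- geom$head_length / 2
  o_prime <- tgt + l2 * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  rigid_transform(needle_rotation(th, ph), o_prime)
}

#' Pose of the moving needle's head for candidate angles
#'
#' Same composition as [obstacle_transform()] but parameterised by the
#' candidate rotation angles of the needle being planned:
#' Trans(target') Rz(phi) Ry(theta) Trans(0,0,l/2) Ry(pi/2).
#'
#' @param q_angles numeric `c(theta, phi)` in radians.
#' @param target A [target_point()] (its compensated position is used).
#' @param geom A [needle_geometry()].
#' @return A `rigid_transform`.
#' @export
needle_transform <- function(q_angles, target, geom) {
  th <- q_angles[[1]]; ph <- q_angles[[2]]
  stopifnot(is.finite(th), is.finite(ph))
  tgt <- target_position(target)
  rzy <- rot_z(ph) %*% rot_y(th)
  tr <- tgt + as.numeric(rzy %*% c(0, 0, geom$head_length / 2))
  rigid_transform(rzy %*% rot_y(pi / 2), tr)
}
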
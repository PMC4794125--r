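# Super-quadric implicit surfaces.
#
# Canonical form in the local frame:
#   f(p) = sum_i (p_i / a_i)^{e_i} - c
# with scales a, even integer exponents e >= 2 and level constant c > 0.
# f < 0 strictly inside, f = 0 on the surface, f > 0 outside.  Even
# exponents make f polynomial, hence smooth to any order, which the
# boundary criterion needs (it differentiates f twice).

#' Super-quadric obstacle / needle-part surface
#'
#' @param scales length-3 positive scales \[mm\] `(a1, a2, a3)`.
#' @param exponents length-3 even integers >= 2.
#' @param level positive right-hand constant `c` of the implicit equation.
#' @param rotation 3x3 rotation matrix of the pose (local -> world).
#' @param translation length-3 translation of the pose \[mm\].
#' @param label obstacle identifier (free text).
#' @return An object of class `superquadric`.
#' @examples
#' sq <- superquadric(c(1, 1, 1), c(2, 2, 2), level = 1)  # unit sphere
#' sq_value(sq, c(2, 0, 0))
#' @export
superquadric <- function(scales, exponents = c(2, 2, 2), level = 1,
                         rotation = diag(3), translation = c(0, 0, 0),
                         label = "") {
  scales <- as.numeric(scales); exponents <- as.numeric(exponents)
  stopifnot(length(scales) == 3L, length(exponents) == 3L,
            all(is.finite(scales)), all(scales > 0),
            is.numeric(level), length(level) == 1L, level > 0)
  if (any(exponents < 2) || any(exponents %% 2 != 0))
    stop("exponents must be even integers >= 2")
  pose <- rigid_transform(rotation, translation)
  structure(list(scales = scales, exponents = exponents, level = level,
                 pose = pose, label = as.character(label)),
            class = "superquadric")
}

#' @export
print.superquadric <- function(x, ...) {
  cat(sprintf("<superquadric '%s'> scales (%s) mm, exponents (%s), level %g\n",
              x$label, paste(format(x$scales, digits = 4), collapse = ", "),
              paste(format(x$exponents), collapse = ", "), x$level))
  cat("  half-extents [mm]:",
      format(sq_half_extents(x), digits = 4), "\n")
  invisible(x)
}

#' Axial half-extents of a super-quadric
#'
#' Distance from the local origin to the surface along each local axis,
#' `a_i * c^(1/e_i)`.
#' @param sq A `superquadric`.
#' @return length-3 numeric \[mm\].
#' @export
sq_half_extents <- function(sq) sq$scales * sq$level^(1 / sq$exponents)

# canonical value/gradient/hessian at a local point (3-vector)
sq_canonical <- function(sq, pl) {
  sum((pl / sq$scales)^sq$exponents) - sq$level
}
sq_canonical_grad <- function(sq, pl) {
  sq$exponents * pl^(sq$exponents - 1) / sq$scales^sq$exponents
}
sq_canonical_hess <- function(sq, pl) {
  diag(sq$exponents * (sq$exponents - 1) * pl^(sq$exponents - 2) /
         sq$scales^sq$exponents, nrow = 3L)
}

#' Evaluate a super-quadric implicit function at world points
#'
#' @param sq A [superquadric()].
#' @param p length-3 world point, or a 3-row matrix of points.
#' @return Scalar (or vector) value of `f`: negative strictly inside, zero on
#'   the surface, positive outside.
#' @export
sq_value <- function(sq, p) {
  if (is.matrix(p)) {
    if (!all(is.finite(p))) stop("non-finite point passed to sq_value")
    pl <- crossprod(sq$pose$R, p - sq$pose$t)
    colSums((pl / sq$scales)^sq$exponents) - sq$level
  } else {
    p <- as.numeric(p)
    if (length(p) != 3L || !all(is.finite(p)))
      stop("non-finite point passed to sq_value")
    sq_canonical(sq, as.numeric(crossprod(sq$pose$R, p - sq$pose$t)))
  }
}

#' First and second world-frame derivatives of a super-quadric
#'
#' Closed-form chain rule through the pose: with `p_l = R^T (p - t)`,
#' the world gradient is `R g_l(p_l)` and the world Hessian `R H_l R^T`.
#'
#' @param sq A [superquadric()].
#' @param p length-3 world point.
#' @return `sq_gradient`: length-3 gradient; `sq_hessian`: 3x3 matrix.
#' @export
sq_gradient <- function(sq, p) {
  p <- as.numeric(p)
  if (!all(is.finite(p))) stop("non-finite point passed to sq_gradient")
  pl <- as.numeric(crossprod(sq$pose$R, p - sq$pose$t))
  as.numeric(sq$pose$R %*% sq_canonical_grad(sq, pl))
}

#' @rdname sq_gradient
#' @export
sq_hessian <- function(sq, p) {
  p <- as.numeric(p)
  if (!all(is.finite(p))) stop("non-finite point passed to sq_hessian")
  pl <- as.numeric(crossprod(sq$pose$R, p - sq$pose$t))
  sq$pose$R %*% sq_canonical_hess(sq, pl) %*% t(sq$pose$R)
}

# value+gradient+hessian in one sweep (hot path of the KKT system)
sq_eval_all <- function(sq, p) {
  pl <- as.numeric(crossprod(sq$pose$R, p - sq$pose$t))
  list(f = sq_canonical(sq, pl),
       g = as.numeric(sq$pose$R %*% sq_canonical_grad(sq, pl)),
       H = sq$pose$R %*% sq_canonical_hess(sq, pl) %*% t(sq$pose$R))
}

# re-pose a canonical superquadric
sq_with_pose <- function(sq, rotation, translation, label = sq$label) {
  superquadric(sq$scales, sq$exponents, sq$level, rotation, translation, label)
}
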
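# Scene-level domain types: targets, trajectories, angle limits, needle
# geometry and the assembled scene object.

#' Tumor target point with deformation compensation
#'
#' @param position length-3 target position \[mm\] in the world frame.
#' @param displacement length-3 displacement \[mm\] caused by liver
#'   deformation (default zero).  The compensated position used for planning
#'   is `position + displacement`.
#' @return An object of class `target_point`.
#' @export
target_point <- function(position, displacement = c(0, 0, 0)) {
  position <- as.numeric(position); displacement <- as.numeric(displacement)
  stopifnot(length(position) == 3L, length(displacement) == 3L,
            all(is.finite(position)), all(is.finite(displacement)))
  structure(list(position = position, displacement = displacement),
            class = "target_point")
}

#' Compensated target position
#' @param target A [target_point()].
#' @return length-3 numeric, `position + displacement`.
#' @export
target_position <- function(target) {
  if (is.numeric(target)) return(as.numeric(target))
  target$position + target$displacement
}

#' Needle insertion trajectory
#'
#' The line from the compensated target to the entry point on the skin.
#' The stored angle pair is always recomputed from entry and target so the
#' three fields stay mutually consistent.
#'
#' @param target A [target_point()] (or bare length-3 position).
#' @param entry length-3 entry point \[mm\].
#' @return An object of class `trajectory` with fields `target`, `entry`,
#'   `angles` (named `theta`, `phi`).
#' @export
trajectory <- function(target, entry) {
  if (is.numeric(target)) target <- target_point(target)
  entry <- as.numeric(entry)
  stopifnot(length(entry) == 3L, all(is.finite(entry)))
  ang <- trajectory_angles(entry, target_position(target))
  structure(list(target = target, entry = entry, angles = ang),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> target (%s) -> entry (%s) mm; theta %.4f, phi %.4f rad\n",
    paste(format(target_position(x$target), digits = 5), collapse = ", "),
    paste(format(x$entry, digits = 5), collapse = ", "),
    x$angles[["theta"]], x$angles[["phi"]]))
  invisible(x)
}

#' Needle rotation-angle limits
#'
#' @param theta_min,theta_max polar-angle bounds \[rad\].
#' @param phi_min,phi_max azimuth bounds \[rad\].
#' @return An object of class `angle_limits`.
#' @export
angle_limits <- function(theta_min = 0, theta_max = 0.9,
                         phi_min = -pi, phi_max = pi) {
  stopifnot(theta_min < theta_max, phi_min < phi_max)
  structure(list(theta_min = theta_min, theta_max = theta_max,
                 phi_min = phi_min, phi_max = phi_max),
            class = "angle_limits")
}

#' Needle geometry: head and tube super-quadrics
#'
#' The canonical (unposed) head and tube surfaces share the needle's local
#' axis (local x after the fixed Ry(pi/2) in the pose composition).  The
#' head length `l` defaults to the head's own axial extent
#' `2 a1 c^(1/e1)`, so the posed head spans exactly `[0, l]` above the tip.
#'
#' @param head_sq canonical [superquadric()] of the needle head.
#' @param tube_sq canonical [superquadric()] of the needle tube (optional).
#' @param head_length head length `l` \[mm\]; default derived from `head_sq`.
#' @param radius nominal tube radius \[mm\] (metadata; default 0.9).
#' @return An object of class `needle_geometry`.
#' @export
needle_geometry <- function(head_sq = superquadric(c(60, 0.1, 0.1),
                                                   c(8, 2, 2), 1000,
                                                   label = "needle-head"),
                            tube_sq = NULL, head_length = NULL,
                            radius = 0.9) {
  stopifnot(inherits(head_sq, "superquadric"))
  if (is.null(head_length)) head_length <- 2 * sq_half_extents(head_sq)[1]
  stopifnot(head_length > 0)
  if (is.null(tube_sq)) {
    # tube defaults: same family as the head, cross-section from the radius
    half_len <- 30
    tube_sq <- superquadric(
      c(half_len / 1000^(1 / 8), radius / sqrt(1000), radius / sqrt(1000)),
      c(8, 2, 2), 1000, label = "needle-tube")
  }
  structure(list(head_sq = head_sq, tube_sq = tube_sq,
                 head_length = head_length, radius = radius),
            class = "needle_geometry")
}

#' @export
print.needle_geometry <- function(x, ...) {
  cat(sprintf("<needle_geometry> head length %.2f mm, head cross radius %.3f mm\n",
              x$head_length, sq_half_extents(x$head_sq)[2]))
  invisible(x)
}

#' Assemble a planning scene
#'
#' @param obstacles list of posed [superquadric()] obstacles (vessels, ribs).
#' @param skin a [skin_surface()].
#' @param targets list of [target_point()]s, in insertion order.
#' @param needle a [needle_geometry()].
#' @param limits an [angle_limits()].
#' @param planning named list of planner parameters: `gamma` \[mm\], `mu`,
#'   `z_layers` \[mm\], `h_max` \[mm\], `delta_tol`, `eps_tol`, `step_u` \[mm\].
#' @param name,seed scene metadata.
#' @return An object of class `cfrw_scene`.
#' @export
scene <- function(obstacles, skin, targets, needle = needle_geometry(),
                  limits = angle_limits(),
                  planning = list(), name = "scene", seed = NULL) {
  defaults <- list(gamma = 1.5, mu = 0.1, z_layers = c(150, 160, 170),
                   h_max = 200, delta_tol = 1e-5, eps_tol = 1e-4,
                   step_u = 0.5, newton_tol = 1e-10, max_steps = 1e5,
                   seed_grid = 5)
  planning <- utils::modifyList(defaults, planning)
  sc <- structure(list(name = name, seed = seed, obstacles = obstacles,
                       skin = skin, targets = targets, needle = needle,
                       limits = limits, planning = planning),
                  class = "cfrw_scene")
  validate_scene(sc)
  sc
}

#' @export
print.cfrw_scene <- function(x, ...) {
  cat(sprintf("<cfrw_scene '%s'> %d target(s), %d obstacle(s), skin kind '%s'\n",
              x$name, length(x$targets), length(x$obstacles), x$skin$kind))
  cat(sprintf("  gamma %.3g mm, mu %.3g, z-layers {%s} mm\n",
              x$planning$gamma, x$planning$mu,
              paste(format(x$planning$z_layers), collapse = ", ")))
  invisible(x)
}

#' Validate a scene against the schema invariants
#'
#' Errors name the offending field and constraint.  Implausible geometry
#' (for instance a needle head longer than 250 mm, as the printed default
#' head parameters imply) is reported as a message, not an error.
#'
#' @param sc A [scene()].
#' @param quiet suppress plausibility messages.
#' @return Invisibly `TRUE` on success.
#' @export
validate_scene <- function(sc, quiet = TRUE) {
  p <- sc$planning
  if (!is.numeric(p$gamma) || p$gamma <= 0)
    stop("planning$gamma: must be > 0")
  if (!is.numeric(p$mu) || p$mu <= 0)
    stop("planning$mu: must be > 0")
  if (!is.numeric(p$delta_tol) || p$delta_tol <= 0)
    stop("planning$delta_tol: must be > 0")
  if (!is.numeric(p$eps_tol) || p$eps_tol <= 0)
    stop("planning$eps_tol: must be > 0")
  if (any(p$z_layers < 0 | p$z_layers > p$h_max))
    stop("planning$z_layers: must lie within [0, h_max]")
  if (!inherits(sc$skin, "skin_surface")) stop("skin: not a skin_surface")
  if (!inherits(sc$needle, "needle_geometry"))
    stop("needle: not a needle_geometry")
  if (!inherits(sc$limits, "angle_limits")) stop("limits: not angle_limits")
  for (i in seq_along(sc$obstacles))
    if (!inherits(sc$obstacles[[i]], "superquadric"))
      stop(sprintf("obstacles[[%d]]: not a superquadric", i))
  for (i in seq_along(sc$targets))
    if (!inherits(sc$targets[[i]], "target_point"))
      stop(sprintf("targets[[%d]]: not a target_point", i))
  if (!quiet) {
    he <- sq_half_extents(sc$needle$head_sq)
    if (2 * he[1] > 250)
      message(sprintf(
        "note: needle head spans %.1f mm along its axis; check head_sq scales",
        2 * he[1]))
  }
  invisible(TRUE)
}
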
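# Deterministic synthetic scene generators.
#
# These emulate the abdominal simulation environment at configurable
# scale: three collinear tumor targets, elongated vessel obstacles between
# tumor and skin, and a cylindrical abdominal-wall patch.  They also build
# the sphere-obstacle oracle scenes whose CFRW boundary has a closed form
# (tangent cone), used throughout the tests.

#' Three-needle demonstration scene
#'
#' Three collinear targets at (0, 0, 0), (0, -15, 0) and (0, -30, 0) mm,
#' three elongated vessel super-quadrics between the tumor and the skin,
#' and an elliptic-cylinder skin patch spanning z of roughly 150-180 mm.
#' Defaults: gamma = 1.5 mm, mu = 0.1, z-layers {150, 160, 170} mm.
#'
#' @param gamma,mu,z_layers planner parameter overrides.
#' @return A [scene()].
#' @export
make_three_needle_scene <- function(gamma = 1.5, mu = 0.1,
                                    z_layers = c(150, 160, 170)) {
  vessel <- function(x, y, z, along, half_len, radius, label) {
    R <- if (along == "y") rot_z(pi / 2) else diag(3)
    superquadric(c(half_len, radius, radius), c(2, 2, 2), 1,
                 rotation = R, translation = c(x, y, z), label = label)
  }
  obstacles <- list(
    vessel(25, -15, 70, "y", 60, 4, "vessel1"),
    vessel(-25, -15, 70, "y", 60, 4, "vessel2"),
    vessel(0, 20, 60, "x", 60, 3.5, "vessel3"))
  skin <- skin_surface("cylinder",
                       list(center = c(0, 0, 0), a = 180, b = 180),
                       u_bounds = c(-0.58, 0.58), v_bounds = c(-80, 50))
  targets <- list(target_point(c(0, 0, 0)), target_point(c(0, -15, 0)),
                  target_point(c(0, -30, 0)))
  scene(obstacles, skin, targets,
        needle = needle_geometry(),
        limits = angle_limits(0, 0.9, -pi, pi),
        planning = list(gamma = gamma, mu = mu, z_layers = z_layers),
        name = "three-needle-demo")
}

#' Sphere-obstacle oracle scene with closed-form boundary
#'
#' One spherical obstacle of radius `r` centred a distance `D` directly
#' above a single target, probed by a near-line needle (rod radius
#' ~0.03 mm).  The CFRW boundary is then the tangent cone to the sphere
#' inflated by `gamma`: half-angle `asin((r + gamma) / D)`, a circle of
#' radius `(h - z_target) tan(half_angle)` in each layer.
#'
#' @param r sphere radius \[mm\].
#' @param D distance from target to sphere centre \[mm\].
#' @param gamma safe distance \[mm\].
#' @param mu barrier parameter (default 0.01 for a tight boundary).
#' @param z_layers layer heights \[mm\].
#' @return list with `scene` (a [scene()]), `half_angle` \[rad\], and
#'   `circle_radius(h)`, the analytic boundary radius at height `h`.
#' @export
make_sphere_oracle_scene <- function(r, D, gamma = 1.5, mu = 0.01,
                                     z_layers = c(150, 160, 170)) {
  if (D <= r + gamma)
    stop("D <= r + gamma: target lies inside the inflated obstacle")
  obs <- superquadric(rep(r, 3), c(2, 2, 2), 1, translation = c(0, 0, D),
                      label = "sphere")
  thin_head <- superquadric(c(142.3, 0.0316, 0.0316), c(8, 2, 2), 1,
                            label = "needle-head")
  skin <- skin_surface("cylinder",
                       list(center = c(0, 0, 0), a = 180, b = 180),
                       u_bounds = c(-0.58, 0.58), v_bounds = c(-60, 60))
  sc <- scene(list(obs), skin, list(target_point(c(0, 0, 0))),
              needle = needle_geometry(head_sq = thin_head, radius = 0.03),
              limits = angle_limits(0, 0.9, -pi, pi),
              planning = list(gamma = gamma, mu = mu, z_layers = z_layers),
              name = sprintf("sphere-oracle-r%g-D%g", r, D))
  half_angle <- asin((r + gamma) / D)
  list(scene = sc, half_angle = half_angle,
       circle_radius = function(h) h * tan(half_angle))
}

#' Randomised vessel scene
#'
#' `n_vessels` elongated vessel super-quadrics (ellipsoids) with seeded
#' pseudo-random poses, guaranteed to lie in the axial slab between the
#' target and the skin and on the +x side of the target (so their layer
#' shadows stay away from the azimuth branch cut).  Identical
#' `(seed, n_vessels, bounds)` give bit-identical scenes.
#'
#' @param seed integer RNG seed, recorded in the scene.
#' @param n_vessels number of vessels (>= 0).
#' @param bounds named list of ranges: `z` (vessel centre heights \[mm\]),
#'   `offset` (lateral distance from the target \[mm\]), `radius` and
#'   `half_len` \[mm\].
#' @param thin_needle use the near-line needle (as in the oracle scenes)
#'   instead of the standard head.
#' @param gamma,mu,z_layers planner parameter overrides.
#' @return A [scene()].
#' @export
make_random_vessel_scene <- function(seed, n_vessels = 2,
                                     bounds = list(z = c(55, 110),
                                                   offset = c(18, 45),
                                                   radius = c(2.5, 5),
                                                   half_len = c(40, 70)),
                                     thin_needle = FALSE,
                                     gamma = 1.5, mu = 0.1,
                                     z_layers = c(150, 160, 170)) {
  stopifnot(n_vessels >= 0)
  rng <- make_lcg(seed)
  obstacles <- list()
  if (n_vessels > 0) for (i in seq_len(n_vessels)) {
    z <- runif_lcg(rng, bounds$z[1], bounds$z[2])
    off <- runif_lcg(rng, bounds$offset[1], bounds$offset[2])
    az <- runif_lcg(rng, -pi / 3, pi / 3)  # +x side only
    radius <- runif_lcg(rng, bounds$radius[1], bounds$radius[2])
    half_len <- runif_lcg(rng, bounds$half_len[1], bounds$half_len[2])
    yaw <- runif_lcg(rng, 0, pi)
    ctr <- c(off * cos(az), off * sin(az), z)
    obstacles[[i]] <- superquadric(
      c(half_len, radius, radius), c(2, 2, 2), 1,
      rotation = rot_z(yaw), translation = ctr,
      label = sprintf("vessel%d", i))
  }
  head_sq <- if (thin_needle)
    superquadric(c(142.3, 0.0316, 0.0316), c(8, 2, 2), 1,
                 label = "needle-head")
  else superquadric(c(60, 0.1, 0.1), c(8, 2, 2), 1000, label = "needle-head")
  skin <- skin_surface("cylinder",
                       list(center = c(0, 0, 0), a = 180, b = 180),
                       u_bounds = c(-0.58, 0.58), v_bounds = c(-60, 60))
  scene(obstacles, skin, list(target_point(c(0, 0, 0))),
        needle = needle_geometry(head_sq = head_sq),
        limits = angle_limits(0, 0.9, -pi, pi),
        planning = list(gamma = gamma, mu = mu, z_layers = z_layers),
        name = sprintf("random-vessels-seed%d", seed), seed = seed)
}

# Small deterministic linear-congruential generator so scene construction
# never touches R's global RNG stream.
make_lcg <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- (as.numeric(seed) %% 2147483647) + 1
  env
}
runif_lcg <- function(rng, lo = 0, hi = 1) {
  rng$state <- (16807 * rng$state) %% 2147483647
  lo + (hi - lo) * (rng$state / 2147483647)
}
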
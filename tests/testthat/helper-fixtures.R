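# Shared fixtures, built in code, with lazy caches for the expensive
# traced boundaries so several test files can reuse one computation.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# sphere-oracle scene, one layer, traced boundary
sphere_fixture <- function() {
  cached("sphere_fixture", function() {
    osc <- make_sphere_oracle_scene(r = 6, D = 40, gamma = 1.5, mu = 0.01,
                                    z_layers = 150)
    bnd <- cfrw_for_needle(osc$scene, 1)
    list(oracle = osc, scene = osc$scene, boundary = bnd)
  })
}

# thin needle part and a posed sphere obstacle for direct system tests
thin_part <- function() {
  cfrwplan:::needle_part(
    superquadric(c(142.3, 0.0316, 0.0316), c(8, 2, 2), 1), 142.3)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  cfrwplan:::quat_to_rot(q / sqrt(sum(q^2)))
}

rot_z_mat <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
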
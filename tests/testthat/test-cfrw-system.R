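# Constraint-system assembly: angle substitution, kinematics, KKT rows,
# Jacobians, and the two-sphere closest-pair benchmark.

lims <- angle_limits(0.1, 0.9, -1, 1)

test_that("angle substitution maps the real line into the limits", {
  mid <- angle_substitution(c(0, 0), lims)
  expect_equal(mid[["theta"]], 0.5)
  expect_equal(mid[["phi"]], 0)
  expect_equal(angle_substitution(c(pi / 2, pi / 2), lims),
               c(theta = 0.9, phi = 1))
  expect_equal(angle_substitution(c(-pi / 2, -pi / 2), lims),
               c(theta = 0.1, phi = -1))
  set.seed(31)
  w <- matrix(stats::rnorm(2e4, sd = 20), ncol = 2)
  ang <- apply(w, 1, angle_substitution, limits = lims)
  expect_true(all(ang["theta", ] >= 0.1 - 1e-12 & ang["theta", ] <= 0.9 + 1e-12))
  expect_true(all(ang["phi", ] >= -1 - 1e-12 & ang["phi", ] <= 1 + 1e-12))
})

test_that("kinematic residual vanishes exactly on consistent states", {
  tgt <- target_point(c(2, -1, 0))
  # vertical needle: theta = 0 -> residual zero iff u is above the target
  lv <- angle_limits(-0.5, 0.5, -1, 1)
  st <- list(u = c(2, -1), w = c(0, 0), h = 150)
  expect_equal(kinematic_residual(st, tgt, lv), c(0, 0), tolerance = 1e-12)
  st$u <- c(3, -1)
  expect_equal(kinematic_residual(st, tgt, lv), c(1, 0), tolerance = 1e-12)
  # theta = pi/4, phi = 0, target at origin, h = 150 -> x = 150
  l2 <- angle_limits(0, pi / 2 - 0.01, -1, 1)
  w1 <- asin((pi / 4 - (pi / 2 - 0.01) / 2) / ((pi / 2 - 0.01) / 2))
  st2 <- list(u = c(150, 0), w = c(w1, 0), h = 150)
  expect_equal(kinematic_residual(st2, target_point(c(0, 0, 0)), l2),
               c(0, 0), tolerance = 1e-9)
})

test_that("system row counts are 11 / 13 / 27 over 11 / 15 / 28 unknowns", {
  part <- thin_part()
  obs <- superquadric(rep(10, 3), c(2, 2, 2), 1, translation = c(0, 0, 40))
  nsq <- cfrwplan:::posed_part(part, c(0, 0, 0), 0.3, 0)
  kkt <- as.numeric(1:11)
  expect_length(collision_free_residual(kkt, nsq, obs, 1.5, 0.1), 11L)
  z <- as.numeric(1:13)
  expect_length(extended_residual(c(1, 2), z, target_point(c(0, 0, 0)), 150,
                                  angle_limits(0, 0.9, -pi, pi), part, obs,
                                  1.5, 0.1), 13L)
  x <- as.numeric(1:28)
  expect_length(criterion_residual(x, target_point(c(0, 0, 0)), 150,
                                   angle_limits(0, 0.9, -pi, pi), part, obs,
                                   1.5, 0.1), 27L)
})

test_that("extended Jacobian matches finite differences", {
  part <- thin_part()
  obs <- superquadric(c(20, 5, 5), c(2, 2, 2), 1,
                      rotation = rot_z_mat(0.6),
                      translation = c(-30, 20, 60))
  par <- cfrwplan:::cfrw_par(target_point(c(0, 0, 0)), 150,
                             angle_limits(0, 0.9, -pi, pi), part, obs,
                             1.5, 0.1)
  sol <- cfrwplan:::solve_extended_at(c(60, 10), par)
  expect_true(sol$converged)
  set.seed(33)
  z <- sol$z + stats::rnorm(13, sd = 1e-3)
  J <- cfrwplan:::ext_jacobian(c(60, 10), z, par)
  for (k in 1:13) {
    h <- 1e-6 * max(1, abs(z[k]))
    zp <- z; zp[k] <- zp[k] + h
    zm <- z; zm[k] <- zm[k] - h
    col_fd <- (cfrwplan:::ext_residual(c(60, 10), zp, par) -
                 cfrwplan:::ext_residual(c(60, 10), zm, par)) / (2 * h)
    expect_equal(J[, k], col_fd, tolerance = 1e-4)
  }
})

test_that("solved barrier states satisfy complementarity exactly", {
  part <- thin_part()
  obs <- superquadric(rep(8, 3), c(2, 2, 2), 1, translation = c(0, 0, 45))
  par <- cfrwplan:::cfrw_par(target_point(c(0, 0, 0)), 150,
                             angle_limits(0, 0.9, -pi, pi), part, obs,
                             1.5, 0.1)
  sol <- cfrwplan:::solve_extended_at(c(70, -5), par)
  expect_true(sol$converged)
  z <- sol$z
  expect_equal(z[7] * z[9], 0.1, tolerance = 1e-9)
  expect_equal(z[8] * z[10], 0.1, tolerance = 1e-9)
  # clearance row ties ||a-b||^2 to gamma^2 + s_d^2
  expect_equal(sum((z[1:3] - z[4:6])^2), 1.5^2 + z[11]^2, tolerance = 1e-8)
})

test_that("two spheres 5 apart: closest pair approaches the centre line", {
  # needle part degenerates to a unit sphere at the target (offset 0), the
  # obstacle is a unit sphere 5 above: true surface distance is 3
  part <- cfrwplan:::needle_part(superquadric(c(1, 1, 1), c(2, 2, 2), 1), 0)
  obs <- superquadric(c(1, 1, 1), c(2, 2, 2), 1, translation = c(0, 0, 5))
  lims0 <- angle_limits(-0.2, 0.2, -pi, pi)
  for (mu in c(1e-2, 1e-3)) {
    par <- cfrwplan:::cfrw_par(target_point(c(0, 0, 0)), 150, lims0, part,
                               obs, 1, mu)
    # u slightly off-axis: at u = 0 the azimuth is undefined and the
    # kinematic Jacobian block is singular
    sol <- cfrwplan:::solve_extended_at(c(1, 0), par)
    expect_true(sol$converged)
    a <- sol$z[1:3]; b <- sol$z[4:6]
    # both points on the centre line (z-axis)
    expect_lt(max(abs(a[1:2])), 1e-6)
    expect_lt(max(abs(b[1:2])), 1e-6)
    gap <- sqrt(sum((a - b)^2))
    expect_gt(gap, 3)                       # barrier keeps points interior
    expect_lt(gap - 3, 60 * mu)             # and the bias vanishes with mu
    # clearance row then forces s_d^2 -> gap^2 - gamma^2 ~ 8
    expect_equal(sol$z[11]^2, gap^2 - 1, tolerance = 1e-8)
  }
  # independent brute-force check of the true distance
  nsq <- cfrwplan:::posed_part(part, c(0, 0, 0), 0, 0)
  expect_equal(oracle_surface_pair_distance(nsq, obs), 3, tolerance = 1e-3)
})

test_that("criterion rows are symmetric under xi -> -xi", {
  fx <- sphere_fixture()
  st <- fx$boundary$layers[[1]]$obstacles[[1]]$states[[1]]
  x <- st[5, ]
  tgt <- target_point(c(0, 0, 0))
  lims_s <- fx$scene$limits
  part <- thin_part()
  obs <- fx$scene$obstacles[[1]]
  r1 <- criterion_residual(x, tgt, 150, lims_s, part, obs, 1.5, 0.01)
  x2 <- x; x2[16:28] <- -x2[16:28]
  r2 <- criterion_residual(x2, tgt, 150, lims_s, part, obs, 1.5, 0.01)
  expect_equal(abs(r1), abs(r2), tolerance = 1e-7)
  expect_lt(max(abs(r1[1:26])), 1e-6)
})
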
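# Boundary location and continuation tracing, against the tangent-cone
# closed form of the sphere-obstacle scene.

test_that("boundary point search finds the clearance singularity", {
  fx <- sphere_fixture()
  sc <- fx$scene
  part <- thin_part()
  obs <- sc$obstacles[[1]]
  tgt <- sc$targets[[1]]
  R_an <- fx$oracle$circle_radius(150)
  st <- find_boundary_point(c(60, 0), c(-1, 0), 150, tgt, sc$limits, part,
                            obs, 1.5, 0.01)
  expect_true(st$converged)
  expect_equal(st$active, "clearance")
  expect_lt(st$residual, 1e-8)
  expect_equal(sqrt(sum(st$u^2)), R_an, tolerance = 0.01)
  # opposite directions from one interior point give two distinct points
  # of the same closed curve
  st2 <- find_boundary_point(c(60, 20), c(-1, -0.33), 150, tgt, sc$limits,
                             part, obs, 1.5, 0.01)
  expect_gt(sqrt(sum((st$u - st2$u)^2)), 1)
  expect_equal(sqrt(sum(st2$u^2)), R_an, tolerance = 0.01)
  expect_error(
    find_boundary_point(c(5, 0), c(1, 0), 150, tgt, sc$limits, part, obs,
                        1.5, 0.01),
    "not inside")
})

test_that("traced sphere boundary is closed and matches the tangent cone", {
  fx <- sphere_fixture()
  cv <- fx$boundary$layers[[1]]$obstacles[[1]]$curves[[1]]
  n <- nrow(cv)
  expect_gt(n, 100)
  expect_lt(sqrt(sum((cv[1, ] - cv[n, ])^2)), 0.51)
  R_an <- fx$oracle$circle_radius(150)
  th <- seq(0, 2 * pi, length.out = 1440)
  circle <- cbind(R_an * cos(th), R_an * sin(th))
  expect_lt(cfrwplan:::hausdorff_xy(cv, circle), 0.5)
})

test_that("boundary trajectories clear the obstacle by gamma (mu bias shrinks)", {
  fx <- sphere_fixture()
  sc <- fx$scene
  obs <- sc$obstacles[[1]]
  gamma <- 1.5
  rod_r <- sq_half_extents(sc$needle$head_sq)[2]
  bias <- function(mu) {
    part <- thin_part()
    st <- find_boundary_point(c(60, 0), c(-1, 0), 150, sc$targets[[1]],
                              sc$limits, part, obs, gamma, mu)
    u <- st$u
    dir <- c(u, 150) / sqrt(sum(c(u, 150)^2))
    # independent distance: line to sphere via the centre closed form,
    # less the rod's own cross radius to get the surface clearance
    ctr <- obs$pose$t
    t_c <- sum(ctr * dir)
    d_line <- sqrt(sum((t_c * dir - ctr)^2)) - 6 - rod_r
    abs(d_line - gamma)
  }
  b1 <- bias(0.1); b2 <- bias(0.01)
  expect_lt(b1, 3 * 0.1 / (2 * gamma) + 0.04)   # within the mu-bias bound
  expect_lt(b2, b1)                             # and shrinking with mu
})

test_that("angle-limit folds are recognised as such", {
  # march outward where no obstacle blocks: the theta-limit circle is hit
  fx <- sphere_fixture()
  sc <- fx$scene
  st <- suppressWarnings(
    find_boundary_point(c(60, 0), c(1, 0), 150, sc$targets[[1]],
                        sc$limits, thin_part(), sc$obstacles[[1]],
                        1.5, 0.01))
  expect_equal(st$active, "angle")
  expect_equal(sqrt(sum(st$u^2)), 150 * tan(0.9), tolerance = 0.1)
})
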
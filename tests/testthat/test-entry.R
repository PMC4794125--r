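# Grid-refinement entry search.

# boundary object with no obstacles: everything inside the angle limits
free_boundary <- function(tgt, lims = angle_limits(0, 0.9, -pi, pi),
                          z_layers = 150) {
  sc <- scene(list(), skin_surface("poly", list(coef = matrix(160, 1, 1)),
                                   c(-80, 80), c(-80, 80)),
              list(target_point(tgt)), limits = lims,
              planning = list(z_layers = z_layers))
  cfrw_for_needle(sc, 1)
}

test_that("spherical skin centred on the target returns d_min = R", {
  tgt <- c(0, 0, 0)
  skin <- skin_surface("sphere", list(center = tgt, radius = 170),
                       c(-pi / 4, pi / 4), c(0.9, 1.4))
  res <- optimal_entry(skin, target_point(tgt), free_boundary(tgt))
  expect_equal(res$d_min, 170, tolerance = 1e-9)
  expect_equal(sqrt(sum((res$entry - tgt)^2)), 170, tolerance = 1e-9)
})

test_that("planar skin converges to the foot of the perpendicular", {
  tgt <- c(12, -7, 0)
  skin <- skin_surface("poly", list(coef = matrix(160, 1, 1)),
                       c(-80, 80), c(-80, 80))
  res <- optimal_entry(skin, target_point(tgt), free_boundary(tgt))
  expect_equal(res$d_min, 160, tolerance = 1e-4)
  expect_equal(res$entry[1:2], tgt[1:2], tolerance = 0.2)
  expect_equal(res$termination, "normal_alignment")
  # dense-grid oracle over the same domain
  us <- seq(-80, 80, length.out = 801)
  d2 <- outer((us - tgt[1])^2, (us - tgt[2])^2, "+") + 160^2
  expect_lt(res$d_min, sqrt(min(d2)) + 1e-6)
})

test_that("best distance never increases across refinement iterations", {
  tgt <- c(12, -7, 0)
  skin <- skin_surface("poly", list(coef = matrix(160, 1, 1)),
                       c(-80, 80), c(-80, 80))
  bnd <- free_boundary(tgt)
  prev <- Inf
  for (it in 1:8) {
    r <- optimal_entry(skin, target_point(tgt), bnd, eps_tol = 1e-4,
                       delta_tol = 0, max_iter = it)
    expect_lte(r$d_min, prev + 1e-12)
    prev <- r$d_min
  }
})

test_that("an obstacle over the perpendicular forces a feasible detour", {
  osc <- make_sphere_oracle_scene(r = 6, D = 40, gamma = 1.5, mu = 0.01,
                                  z_layers = 150)
  fx <- sphere_fixture()
  bnd <- fx$boundary
  tgt <- target_point(c(0, 0, 0))
  skin <- skin_surface("poly", list(coef = matrix(160, 1, 1)),
                       c(-80, 80), c(-80, 80))
  res <- optimal_entry(skin, tgt, bnd)
  # returned entry is feasible
  expect_true(trajectory_in_cfrw(trajectory(tgt, res$entry), bnd))
  # constrained dense-grid oracle: entry feasible iff the line clears the
  # sphere by gamma (closed form), minimise distance over the feasible grid
  us <- seq(-60, 60, length.out = 601)
  ctr <- c(0, 0, 40)
  best <- Inf
  for (u in us) for (v in us) {
    p <- c(u, v, 160)
    dir <- p / sqrt(sum(p^2))
    d_line <- sqrt(sum((sum(ctr * dir) * dir - ctr)^2))
    if (d_line >= 6 + 1.5) best <- min(best, sqrt(sum(p^2)))
  }
  expect_gt(res$d_min, 160)               # perpendicular is blocked
  expect_equal(res$d_min, best, tolerance = 0.5)
})

test_that("search errors when no feasible candidate exists", {
  # obstacle so large that it covers the whole layer
  sc <- scene(list(superquadric(rep(60, 3), c(2, 2, 2), 1,
                                translation = c(0, 0, 75), label = "wall")),
              skin_surface("poly", list(coef = matrix(160, 1, 1)),
                           c(-40, 40), c(-40, 40)),
              list(target_point(c(0, 0, 0))),
              limits = angle_limits(0, 0.35, -pi, pi),
              planning = list(z_layers = 150))
  bnd <- cfrw_for_needle(sc, 1)
  expect_true(bnd$layers[[1]]$obstacles[[1]]$covers_layer)
  expect_error(optimal_entry(sc$skin, sc$targets[[1]], bnd), "CFRW|feasible")
})
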
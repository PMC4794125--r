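# Super-quadric evaluation and derivatives.

test_that("canonical values: centre, printed on-surface point, level", {
  head <- superquadric(c(60, 0.1, 0.1), c(8, 2, 2), 1000)
  expect_equal(sq_value(head, c(0, 0, 0)), -1000)
  # (ay / 0.1)^2 = 1000 at ay = 0.1 * sqrt(1000)
  expect_equal(sq_value(head, c(0, 0.1 * sqrt(1000), 0)), 0, tolerance = 1e-12)
  sph <- superquadric(c(1, 1, 1), c(2, 2, 2), 1)
  expect_equal(sq_value(sph, c(2, 0, 0)), 3)
})

test_that("sign of posed evaluation agrees with an independent oracle", {
  set.seed(11)
  for (rep in 1:5) {
    R <- random_rotation()
    tr <- stats::rnorm(3, sd = 20)
    scales <- stats::runif(3, 2, 15)
    sq <- superquadric(scales, c(2, 2, 2), 1, rotation = R, translation = tr)
    P <- matrix(stats::rnorm(3 * 200, sd = 15), 3) + tr
    v1 <- sq_value(sq, P)
    v2 <- apply(P, 2, function(p)
      oracle_sq_value(scales, c(2, 2, 2), 1, R, tr, p))
    expect_equal(sign(v1), sign(v2))
    expect_equal(v1, v2, tolerance = 1e-9)
  }
})

test_that("gradients match central finite differences", {
  set.seed(12)
  sqs <- list(
    superquadric(c(1, 1, 1), c(2, 2, 2), 1),
    superquadric(c(60, 0.1, 0.1), c(8, 2, 2), 1000),
    superquadric(c(10, 4, 4), c(2, 2, 2), 1, rotation = random_rotation(),
                 translation = c(5, -3, 12)))
  for (sq in sqs) {
    for (k in 1:60) {
      p <- sq$pose$t + stats::rnorm(3, sd = 5)
      g <- sq_gradient(sq, p)
      gfd <- fd_gradient(function(x) sq_value(sq, x), p)
      expect_equal(g, gfd, tolerance = 1e-5)
    }
  }
})

test_that("unit-sphere derivatives have their closed forms", {
  sph <- superquadric(c(1, 1, 1), c(2, 2, 2), 1)
  expect_equal(sq_gradient(sph, c(2, 0, 0)), c(4, 0, 0))
  for (p in list(c(0.3, -1, 2), c(5, 5, 5), c(0, 0, 0.1)))
    expect_equal(sq_hessian(sph, p), 2 * diag(3))
})

# apply a world-frame motion to a posed super-quadric
sq_with_pose_public <- function(sq, M) {
  superquadric(sq$scales, sq$exponents, sq$level,
               rotation = M$R %*% sq$pose$R,
               translation = rt_apply(M, sq$pose$t), label = sq$label)
}

test_that("value is invariant under simultaneous rigid motion", {
  set.seed(13)
  sq <- superquadric(c(8, 3, 2), c(4, 2, 2), 10,
                     rotation = random_rotation(), translation = c(1, 2, 3))
  for (k in 1:50) {
    p <- stats::rnorm(3, sd = 10)
    M <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 30))
    moved <- sq_with_pose_public(sq, M)
    expect_equal(sq_value(moved, rt_apply(M, p)), sq_value(sq, p),
                 tolerance = 1e-10)
  }
})

test_that("non-finite points are rejected", {
  sph <- superquadric(c(1, 1, 1), c(2, 2, 2), 1)
  expect_error(sq_value(sph, c(NA, 0, 0)), "non-finite")
  expect_error(sq_gradient(sph, c(Inf, 0, 0)), "non-finite")
  expect_error(superquadric(c(1, 1, 1), c(3, 2, 2)), "even")
})
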
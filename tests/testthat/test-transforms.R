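# Rigid transforms and the needle pose compositions.

test_that("compose/inverse round-trips to the identity", {
  set.seed(21)
  for (k in 1:20) {
    A <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 50))
    I <- rt_compose(A, rt_inverse(A))
    expect_equal(I$R, diag(3), tolerance = 1e-12)
    expect_equal(I$t, c(0, 0, 0), tolerance = 1e-10)
    B <- rigid_transform(random_rotation(), stats::rnorm(3))
    C <- rigid_transform(random_rotation(), stats::rnorm(3))
    p <- stats::rnorm(3)
    expect_equal(rt_apply(rt_compose(rt_compose(A, B), C), p),
                 rt_apply(A, rt_apply(B, rt_apply(C, p))),
                 tolerance = 1e-9)
  }
})

test_that("quaternion representation round-trips", {
  set.seed(22)
  for (k in 1:30) {
    R <- random_rotation()
    expect_equal(cfrwplan:::quat_to_rot(cfrwplan:::rot_to_quat(R)), R,
                 tolerance = 1e-10)
  }
})

test_that("obstacle transform places the head centre per the pose formula", {
  geom <- needle_geometry()
  l <- geom$head_length
  # vertical insertion: head centre l/2 straight above the target
  tr <- trajectory(target_point(c(3, -2, 1)), c(3, -2, 101))
  T1 <- obstacle_transform(tr, geom)
  expect_equal(T1$t, c(3, -2, 1 + l / 2), tolerance = 1e-12)
  # 45-degree insertion in the xz-plane, checked by direct substitution
  geom2 <- needle_geometry(head_length = 2)
  tr2 <- trajectory(target_point(c(0, 0, 0)), c(1, 0, 1))
  T2 <- obstacle_transform(tr2, geom2)
  th <- pi / 4; ph <- 0
  expect_equal(trajectory_angles(c(1, 0, 1), c(0, 0, 0)),
               c(theta = th, phi = ph))
  expect_equal(T2$t, c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)),
               tolerance = 1e-12)
})

test_that("head local x-axis maps parallel to the needle axis", {
  set.seed(23)
  geom <- needle_geometry()
  for (k in 1:100) {
    tgt <- stats::rnorm(3, sd = 10)
    ent <- tgt + stats::rnorm(3, sd = 60)
    tr <- tryCatch(trajectory(target_point(tgt), ent),
                   error = function(e) NULL)
    if (is.null(tr)) next
    Tb <- obstacle_transform(tr, geom)
    axis_world <- as.numeric(Tb$R %*% c(1, 0, 0))
    dir <- (ent - tgt) / sqrt(sum((ent - tgt)^2))
    expect_equal(abs(sum(axis_world * dir)), 1, tolerance = 1e-9)
  }
})

test_that("moving-needle and inserted-needle poses agree for equal angles", {
  set.seed(24)
  geom <- needle_geometry()
  for (k in 1:100) {
    th <- stats::runif(1, 0.01, 1.2)
    ph <- stats::runif(1, -pi, pi)
    tgt <- target_point(stats::rnorm(3, sd = 10))
    Tn <- needle_transform(c(th, ph), tgt, geom)
    dir <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    ent <- target_position(tgt) + 120 * dir
    To <- obstacle_transform(trajectory(tgt, ent), geom)
    expect_lt(max(abs(Tn$R - To$R)), 1e-10)
    expect_lt(max(abs(Tn$t - To$t)), 1e-10)
    expect_equal(crossprod(Tn$R), diag(3), tolerance = 1e-12)
    expect_equal(det(Tn$R), 1, tolerance = 1e-12)
  }
})

test_that("vertical needle pose maps the local origin to target + l/2 e_z", {
  geom <- needle_geometry()
  tgt <- target_point(c(1, 2, 3), displacement = c(0, 0, 0))
  Tn <- needle_transform(c(0, 0), tgt, geom)
  expect_equal(rt_apply(Tn, c(0, 0, 0)), c(1, 2, 3 + geom$head_length / 2))
})

test_that("trajectory stores consistent angles and rejects degenerate input", {
  tr <- trajectory(target_point(c(0, 0, 0)), c(10, 10, 10))
  d <- c(sin(tr$angles[["theta"]]) * cos(tr$angles[["phi"]]),
         sin(tr$angles[["theta"]]) * sin(tr$angles[["phi"]]),
         cos(tr$angles[["theta"]]))
  expect_equal(d * sqrt(300), c(10, 10, 10), tolerance = 1e-9)
  expect_error(trajectory(target_point(c(1, 1, 1)), c(1, 1, 1)),
               "zero-length")
  # compensated position shifts the line
  tr2 <- trajectory(target_point(c(0, 0, 0), displacement = c(0, 0, 5)),
                    c(0, 0, 10))
  expect_equal(target_position(tr2$target), c(0, 0, 5))
})
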
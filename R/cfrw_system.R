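# Constraint systems of the collision-free reachable workspace (CFRW).
#
# Unknowns of the extended system, for one needle / one obstacle / one
# z-layer at height h:
#   u  = (x, y)                  — intersection of the needle axis with the
#                                  z = h plane [mm]
#   z~ = (a, b, lambda1, lambda2, s1, s2, s_d, v1, v2)   (13 entries)
#        a — candidate closest point on the obstacle surface [mm]
#        b — candidate closest point on the needle surface [mm]
#        lambda — Lagrange multipliers, s — membership slacks
#        s_d — clearance slack, v1/v2 — unconstrained angle parameters
#
# Rows (13): 2 kinematic + 11 collision-free KKT rows
#   1-2   x - (h - z_t) tan(theta) cos(phi) - x_t   (and the y analogue)
#   3-5   2(a - b) + lambda2 grad f_obs(a)
#   6-8  -2(a - b) + lambda1 grad f_n(b; v)
#   9     f_n(b; v) + s1
#   10    f_obs(a) + s2
#   11-12 lambda_i s_i - mu          (barrier complementarity)
#   13    ||a - b||^2 - gamma^2 - s_d^2
#
# The boundary criterion stacks the extended system, its transposed
# Jacobian applied to a unit null direction xi (13 rows), and the
# normalisation xi'xi - 1: 27 equations in the 28 unknowns (u, z~, xi).

IDX_A <- 1:3; IDX_B <- 4:6; IDX_L <- 7:8; IDX_S <- 9:10
IDX_SD <- 11L; IDX_V <- 12:13

#' Sine substitution mapping unconstrained parameters to bounded angles
#'
#' `theta = (max+min)/2 + (max-min)/2 sin(w1)` and the analogue for `phi`
#' with `w2`, so any real `(w1, w2)` yields angles within the limits.
#'
#' @param w numeric pair `(w1, w2)`.
#' @param limits an [angle_limits()].
#' @return named numeric `c(theta =, phi =)` \[rad\].
#' @export
angle_substitution <- function(w, limits) {
  c(theta = (limits$theta_max + limits$theta_min) / 2 +
      (limits$theta_max - limits$theta_min) / 2 * sin(w[[1]]),
    phi = (limits$phi_max + limits$phi_min) / 2 +
      (limits$phi_max - limits$phi_min) / 2 * sin(w[[2]]))
}

#' Kinematic constraint residual of a planar needle state
#'
#' Residual of the two kinematic rows tying the axis/layer intersection
#' `(x, y)` to the angles obtained from `(w1, w2)` through
#' [angle_substitution()].
#'
#' @param state list with fields `u` (length-2, \[mm\]), `w` (length-2) and
#'   `h` (layer height \[mm\]).
#' @param target a [target_point()] (compensated position is used).
#' @param limits an [angle_limits()].
#' @return length-2 residual \[mm\]; zero iff the state is consistent.
#' @export
kinematic_residual <- function(state, target, limits) {
  tgt <- target_position(target)
  ang <- angle_substitution(state$w, limits)
  th <- ang[["theta"]]; ph <- ang[["phi"]]
  if (abs(abs(th) - pi / 2) < 1e-9)
    stop("tan singularity: |theta| = pi/2")
  H <- state$h - tgt[3]
  c(state$u[1] - H * tan(th) * cos(ph) - tgt[1],
    state$u[2] - H * tan(th) * sin(ph) - tgt[2])
}

# A needle part: canonical super-quadric plus the axial offset of its
# centre from the needle tip (head: l/2).
needle_part <- function(sq, offset) list(sq = sq, offset = offset)

moving_parts <- function(geom, use_tube = FALSE) {
  parts <- list(head = needle_part(geom$head_sq, geom$head_length / 2))
  if (use_tube)
    parts$tube <- needle_part(
      geom$tube_sq,
      geom$head_length + sq_half_extents(geom$tube_sq)[1])
  parts
}

# Evaluate a moving needle part's implicit surface at world point b for
# angles (theta, phi), with the angle derivatives the Jacobian needs.
needle_part_eval <- function(part, tgt, th, ph, b, derivs = TRUE) {
  sq <- part$sq
  Rz <- rot_z(ph); Ry <- rot_y(th); R90 <- rot_y(pi / 2)
  Rzy <- Rz %*% Ry
  R <- Rzy %*% R90
  off <- c(0, 0, part$offset)
  tr <- tgt + as.numeric(Rzy %*% off)
  d <- b - tr
  pl <- as.numeric(crossprod(R, d))
  gl <- sq_canonical_grad(sq, pl)
  out <- list(f = sq_canonical(sq, pl),
              g = as.numeric(R %*% gl),
              H = R %*% sq_canonical_hess(sq, pl) %*% t(R))
  if (derivs) {
    Hl <- sq_canonical_hess(sq, pl)
    dRth <- Rz %*% drot_y(th) %*% R90
    dRph <- drot_z(ph) %*% Ry %*% R90
    dtth <- as.numeric(Rz %*% drot_y(th) %*% off)
    dtph <- as.numeric(drot_z(ph) %*% Ry %*% off)
    dpl_th <- as.numeric(crossprod(dRth, d)) - as.numeric(crossprod(R, dtth))
    dpl_ph <- as.numeric(crossprod(dRph, d)) - as.numeric(crossprod(R, dtph))
    out$df_th <- sum(gl * dpl_th)
    out$df_ph <- sum(gl * dpl_ph)
    out$dg_th <- as.numeric(dRth %*% gl) + as.numeric(R %*% (Hl %*% dpl_th))
    out$dg_ph <- as.numeric(dRph %*% gl) + as.numeric(R %*% (Hl %*% dpl_ph))
  }
  out
}

# posed superquadric of a moving part at fixed angles (for clearance checks)
posed_part <- function(part, tgt, th, ph) {
  Rzy <- rot_z(ph) %*% rot_y(th)
  sq_with_pose(part$sq, Rzy %*% rot_y(pi / 2),
               tgt + as.numeric(Rzy %*% c(0, 0, part$offset)))
}

# Parameter bundle shared by the residual/Jacobian evaluators.  When the
# azimuth limits span the full circle, phi is periodic rather than
# constrained, and the sine substitution would introduce an artificial
# fold at the range ends; phi is then parameterised freely (phi = cp + w2),
# optionally rebased so the branch cut sits away from the region of
# interest.
cfrw_par <- function(target, h, limits, part, obs, gamma, mu,
                     phi_center = NULL) {
  tgt <- target_position(target)
  stopifnot(h > tgt[3], gamma > 0, mu > 0)
  rp <- (limits$phi_max - limits$phi_min) / 2
  phi_free <- rp >= pi - 1e-9
  cp <- if (phi_free && !is.null(phi_center)) phi_center else
    (limits$phi_max + limits$phi_min) / 2
  list(tgt = tgt, h = h, limits = limits, part = part, obs = obs,
       gamma = gamma, mu = mu,
       ct = (limits$theta_max + limits$theta_min) / 2,
       rt = (limits$theta_max - limits$theta_min) / 2,
       cp = cp, rp = rp, phi_free = phi_free)
}

# angles and their w-derivatives under the active parameterisation
par_angles <- function(v, par) {
  th <- par$ct + par$rt * sin(v[1])
  if (par$phi_free) {
    list(th = th, ph = par$cp + v[2],
         dth = par$rt * cos(v[1]), dph = 1)
  } else {
    list(th = th, ph = par$cp + par$rp * sin(v[2]),
         dth = par$rt * cos(v[1]), dph = par$rp * cos(v[2]))
  }
}

# inverse parameterisation; NULL when the angles are outside the limits
par_w_from_angles <- function(th, ph, par) {
  st <- if (par$rt > 0) (th - par$ct) / par$rt else 0
  if (abs(st) > 1 + 1e-12) return(NULL)
  w1 <- asin(max(-1, min(1, st)))
  if (par$phi_free) {
    d <- (ph - par$cp) %% (2 * pi)
    if (d > pi) d <- d - 2 * pi
    c(w1, d)
  } else {
    sp <- if (par$rp > 0) (ph - par$cp) / par$rp else 0
    if (abs(sp) > 1 + 1e-12) return(NULL)
    c(w1, asin(max(-1, min(1, sp))))
  }
}

#' Collision-free (barrier KKT) residual between a needle and an obstacle
#'
#' The 11 rows of the interior-point closest-pair system for one posed
#' needle surface and one obstacle surface: 6 stationarity rows, 2 surface
#' membership rows with slacks, 2 barrier complementarity rows
#' `lambda_i s_i - mu`, and the clearance row
#' `||a - b||^2 - gamma^2 - s_d^2`.
#'
#' @param kkt list with fields `eta` (length-6, `c(a, b)` \[mm\]), `lambda`
#'   (length 2), `slacks` (length 2) and `s_d` (scalar); or a bare numeric
#'   vector of length 11 in that order.
#' @param needle_sq posed [superquadric()] of the needle part.
#' @param obs_sq posed [superquadric()] of the obstacle.
#' @param gamma safe-distance parameter \[mm\], > 0.
#' @param mu barrier parameter, > 0.
#' @return length-11 numeric residual.
#' @export
collision_free_residual <- function(kkt, needle_sq, obs_sq, gamma, mu) {
  if (is.numeric(kkt)) {
    stopifnot(length(kkt) == 11L)
    kkt <- list(eta = kkt[1:6], lambda = kkt[7:8], slacks = kkt[9:10],
                s_d = kkt[11])
  }
  stopifnot(length(kkt$eta) == 6L, length(kkt$lambda) == 2L,
            length(kkt$slacks) == 2L, length(kkt$s_d) == 1L,
            gamma > 0, mu > 0)
  a <- kkt$eta[1:3]; b <- kkt$eta[4:6]
  ob <- sq_eval_all(obs_sq, a)
  ne <- sq_eval_all(needle_sq, b)
  d <- a - b
  c(2 * d + kkt$lambda[2] * ob$g,
    -2 * d + kkt$lambda[1] * ne$g,
    ne$f + kkt$slacks[1],
    ob$f + kkt$slacks[2],
    kkt$lambda * kkt$slacks - mu,
    sum(d^2) - gamma^2 - kkt$s_d^2)
}

# --- internal evaluators on the (u, z) coordinates -------------------------

ext_residual <- function(u, z, par) {
  a <- z[IDX_A]; b <- z[IDX_B]; lam <- z[IDX_L]; s <- z[IDX_S]
  sdv <- z[IDX_SD]; v <- z[IDX_V]
  ang <- par_angles(v, par)
  th <- ang$th; ph <- ang$ph
  H <- par$h - par$tgt[3]
  ne <- needle_part_eval(par$part, par$tgt, th, ph, b, derivs = FALSE)
  ob <- sq_eval_all(par$obs, a)
  d <- a - b
  c(u[1] - H * tan(th) * cos(ph) - par$tgt[1],
    u[2] - H * tan(th) * sin(ph) - par$tgt[2],
    2 * d + lam[2] * ob$g,
    -2 * d + lam[1] * ne$g,
    ne$f + s[1],
    ob$f + s[2],
    lam * s - par$mu,
    sum(d^2) - par$gamma^2 - sdv^2)
}

# 13x13 Jacobian of the extended residual with respect to z~ (u enters the
# first two rows only through the identity block, handled separately).
ext_jacobian <- function(u, z, par) {
  a <- z[IDX_A]; b <- z[IDX_B]; lam <- z[IDX_L]; s <- z[IDX_S]
  sdv <- z[IDX_SD]; v <- z[IDX_V]
  ang <- par_angles(v, par)
  th <- ang$th; ph <- ang$ph; dth <- ang$dth; dph <- ang$dph
  H <- par$h - par$tgt[3]
  ne <- needle_part_eval(par$part, par$tgt, th, ph, b, derivs = TRUE)
  ob <- sq_eval_all(par$obs, a)
  d <- a - b
  J <- matrix(0, 13, 13)
  sec2 <- 1 / cos(th)^2
  J[1, 12] <- -H * sec2 * cos(ph) * dth
  J[1, 13] <- H * tan(th) * sin(ph) * dph
  J[2, 12] <- -H * sec2 * sin(ph) * dth
  J[2, 13] <- -H * tan(th) * cos(ph) * dph
  # stationarity wrt a
  J[3:5, IDX_A] <- 2 * diag(3) + lam[2] * ob$H
  J[3:5, IDX_B] <- -2 * diag(3)
  J[3:5, 8] <- ob$g
  # stationarity wrt b
  J[6:8, IDX_A] <- -2 * diag(3)
  J[6:8, IDX_B] <- 2 * diag(3) + lam[1] * ne$H
  J[6:8, 7] <- ne$g
  J[6:8, 12] <- lam[1] * ne$dg_th * dth
  J[6:8, 13] <- lam[1] * ne$dg_ph * dph
  # membership rows
  J[9, IDX_B] <- ne$g
  J[9, 9] <- 1
  J[9, 12] <- ne$df_th * dth
  J[9, 13] <- ne$df_ph * dph
  J[10, IDX_A] <- ob$g
  J[10, 10] <- 1
  # complementarity
  J[11, 7] <- s[1]; J[11, 9] <- lam[1]
  J[12, 8] <- s[2]; J[12, 10] <- lam[2]
  # clearance
  J[13, IDX_A] <- 2 * d
  J[13, IDX_B] <- -2 * d
  J[13, IDX_SD] <- -2 * sdv
  J
}

#' Extended constraint residual (kinematic + collision-free rows)
#'
#' Stacks the two kinematic rows of [kinematic_residual()] on the eleven
#' collision-free rows: 13 equations in the 15 unknowns `(u, z~)`.
#'
#' @param u length-2 axis/layer intersection \[mm\].
#' @param z length-13 state `(a, b, lambda, s, s_d, v1, v2)`.
#' @param target a [target_point()].
#' @param h layer height \[mm\].
#' @param limits an [angle_limits()].
#' @param part a needle part (see [needle_geometry()]; the head by default).
#' @param obs_sq posed obstacle [superquadric()].
#' @param gamma,mu safe distance \[mm\] and barrier parameter.
#' @return length-13 numeric residual.
#' @export
extended_residual <- function(u, z, target, h, limits, part, obs_sq,
                              gamma, mu) {
  stopifnot(length(u) == 2L, length(z) == 13L)
  par <- cfrw_par(target, h, limits, part, obs_sq, gamma, mu)
  ext_residual(as.numeric(u), as.numeric(z), par)
}

# --- boundary criterion ----------------------------------------------------

crit_residual <- function(x, par) {
  u <- x[1:2]; z <- x[3:15]; xi <- x[16:28]
  c(ext_residual(u, z, par),
    as.numeric(crossprod(ext_jacobian(u, z, par), xi)),
    sum(xi^2) - 1)
}

# 27x28 Jacobian of the criterion.  The only block without closed form is
# d(J' xi)/dz, obtained by forward differences of the analytic Jacobian
# (the base Jacobian is reused; FD accuracy only affects the Newton
# contraction rate, not the attainable residual).
crit_jacobian <- function(x, par, fd_step = 1e-7) {
  u <- x[1:2]; z <- x[3:15]; xi <- x[16:28]
  J <- ext_jacobian(u, z, par)
  Jt_xi <- as.numeric(crossprod(J, xi))
  D <- matrix(0, 27, 28)
  D[1:2, 1:2] <- diag(2)           # d(kinematic)/du
  D[1:13, 3:15] <- J
  for (k in 1:13) {
    hk <- fd_step * max(1, abs(z[k]))
    zp <- z; zp[k] <- z[k] + hk
    D[14:26, 2 + k] <- (as.numeric(crossprod(ext_jacobian(u, zp, par), xi)) -
                          Jt_xi) / hk
  }
  D[14:26, 16:28] <- t(J)
  D[27, 16:28] <- 2 * xi
  D
}

#' Boundary criterion residual of the CFRW
#'
#' The workspace boundary is characterised by a rank deficiency of the
#' extended system's Jacobian: the criterion stacks the 13 extended rows,
#' the 13 rows of that Jacobian's transpose applied to a unit null
#' direction `xi`, and the normalisation `xi'xi - 1` — 27 equations over
#' the 28 unknowns `(u, z~, xi)`, whose solution set is a 1D curve.
#'
#' @param x length-28 state `c(u, z, xi)`.
#' @inheritParams extended_residual
#' @return length-27 numeric residual.
#' @export
criterion_residual <- function(x, target, h, limits, part, obs_sq,
                               gamma, mu) {
  stopifnot(length(x) == 28L)
  par <- cfrw_par(target, h, limits, part, obs_sq, gamma, mu)
  r <- crit_residual(as.numeric(x), par)
  if (any(!is.finite(r)))
    stop(sprintf("non-finite criterion residual at row(s) %s",
                 paste(which(!is.finite(r)), collapse = ", ")))
  r
}
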
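# Newton solvers, surface projections and closest-pair utilities.

# Damped (Armijo backtracking) Newton for square systems.
newton_damped <- function(res_fn, jac_fn, x0, tol = 1e-10, maxit = 50L) {
  x <- x0
  r <- res_fn(x)
  nr <- max(abs(r))
  if (!is.finite(nr)) return(list(x = x, converged = FALSE, res = Inf))
  for (it in seq_len(maxit)) {
    if (nr < tol) return(list(x = x, converged = TRUE, res = nr, iter = it))
    J <- jac_fn(x)
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(x = x, converged = FALSE, res = nr))
    alpha <- 1
    improved <- FALSE
    while (alpha >= 1e-4) {
      xn <- x - alpha * step
      rn <- res_fn(xn)
      nrn <- max(abs(rn))
      if (is.finite(nrn) && (nrn < (1 - 1e-4 * alpha) * nr || nrn < tol)) {
        x <- xn; r <- rn; nr <- nrn; improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) return(list(x = x, converged = nr < tol, res = nr))
  }
  list(x = x, converged = nr < tol, res = nr, iter = maxit)
}

# Closest point on a super-quadric surface to a world point p.
# Start from the radial surface intersection (f is monotone along rays from
# the centre for even exponents), then polish the 4x4 closest-point KKT.
project_to_surface <- function(sq, p) {
  ctr <- sq$pose$t
  dir <- p - ctr
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-9) dir <- c(1, 0, 0) else dir <- dir / nd
  # bracket f = 0 along the ray
  lo <- 0; hi <- max(nd, max(sq_half_extents(sq)) * 2)
  while (sq_value(sq, ctr + hi * dir) < 0) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sq_value(sq, ctr + mid * dir) < 0) lo <- mid else hi <- mid
  }
  x0 <- ctr + ((lo + hi) / 2) * dir
  g0 <- sq_gradient(sq, x0)
  nu0 <- sum((p - x0) * g0) / sum(g0^2)
  res_fn <- function(y) {
    x <- y[1:3]; nu <- y[4]
    e <- sq_eval_all(sq, x)
    c(x - p + nu * e$g, e$f)
  }
  jac_fn <- function(y) {
    x <- y[1:3]; nu <- y[4]
    e <- sq_eval_all(sq, x)
    rbind(cbind(diag(3) + nu * e$H, e$g), c(e$g, 0))
  }
  sol <- newton_damped(res_fn, jac_fn, c(x0, -nu0), tol = 1e-11, maxit = 40L)
  if (sol$converged) sol$x[1:3] else x0
}

#' Minimum distance between two super-quadric surfaces
#'
#' Alternating closest-point projection between the two surfaces (convergent
#' for the convex members of the family used here).  Returns 0 when the
#' bodies overlap.
#'
#' @param sq1,sq2 posed [superquadric()]s.
#' @param max_iter,tol iteration cap and movement tolerance \[mm\].
#' @return list with `distance` \[mm\], the closest pair `p1`, `p2`, and
#'   `overlap` (logical).
#' @export
sq_surface_distance <- function(sq1, sq2, max_iter = 60L, tol = 1e-9) {
  p <- sq2$pose$t
  x1 <- project_to_surface(sq1, p)
  x2 <- project_to_surface(sq2, x1)
  if (sq_value(sq1, sq2$pose$t) <= 0 || sq_value(sq2, sq1$pose$t) <= 0)
    return(list(distance = 0, p1 = x1, p2 = x2, overlap = TRUE))
  for (i in seq_len(max_iter)) {
    x1n <- project_to_surface(sq1, x2)
    x2n <- project_to_surface(sq2, x1n)
    move <- max(abs(x1n - x1), abs(x2n - x2))
    x1 <- x1n; x2 <- x2n
    if (move < tol) break
  }
  overlap <- sq_value(sq1, x2) < 0 || sq_value(sq2, x1) < 0
  list(distance = if (overlap) 0 else sqrt(sum((x1 - x2)^2)),
       p1 = x1, p2 = x2, overlap = overlap)
}

#' Clearance of a candidate trajectory to one obstacle
#'
#' Minimum surface-to-surface distance between the needle part posed along
#' the trajectory and the obstacle.
#'
#' @param traj a [trajectory()].
#' @param geom a [needle_geometry()].
#' @param obs_sq posed obstacle [superquadric()].
#' @param use_tube include the tube part as well as the head.
#' @return minimum distance \[mm\] over the needle parts (0 on overlap).
#' @export
trajectory_clearance <- function(traj, geom, obs_sq, use_tube = FALSE) {
  tgt <- target_position(traj$target)
  th <- traj$angles[["theta"]]; ph <- traj$angles[["phi"]]
  parts <- moving_parts(geom, use_tube)
  min(vapply(parts, function(pt) {
    sq_surface_distance(posed_part(pt, tgt, th, ph), obs_sq)$distance
  }, numeric(1)))
}

# angles (theta, phi) of the trajectory through layer point u at height h
u_to_angles <- function(u, tgt, h) {
  H <- h - tgt[3]
  rho <- sqrt((u[1] - tgt[1])^2 + (u[2] - tgt[2])^2)
  th <- atan2(rho, H)
  ph <- if (rho < 1e-12) 0 else atan2(u[2] - tgt[2], u[1] - tgt[1])
  c(th, ph)
}

# quick feasibility probe for a layer point: angles within limits and
# direct needle/obstacle clearance above gamma
quick_feasible <- function(u, par) {
  ang <- u_to_angles(u, par$tgt, par$h)
  if (is.null(par_w_from_angles(ang[1], ang[2], par))) return(FALSE)
  d <- sq_surface_distance(posed_part(par$part, par$tgt, ang[1], ang[2]),
                           par$obs)$distance
  d > par$gamma
}

# Initial extended state for a layer point u strictly inside the CFRW:
# angles from the kinematics, closest pair from alternating projection,
# multipliers from the stationarity rows, slacks from the barrier.
interior_guess <- function(u, par) {
  ang <- u_to_angles(u, par$tgt, par$h)
  w <- par_w_from_angles(ang[1], ang[2], par)
  if (is.null(w)) return(NULL)
  nsq <- posed_part(par$part, par$tgt, ang[1], ang[2])
  cp <- sq_surface_distance(par$obs, nsq)
  if (cp$overlap) return(NULL)
  a <- cp$p1; b <- cp$p2
  d <- sqrt(sum((a - b)^2))
  g_o <- sq_gradient(par$obs, a)
  g_n <- sq_gradient(nsq, b)
  lam2 <- 2 * d / max(sqrt(sum(g_o^2)), 1e-12)
  lam1 <- 2 * d / max(sqrt(sum(g_n^2)), 1e-12)
  s1 <- min(par$mu / max(lam1, 1e-12), 0.9 * par$part$sq$level)
  s2 <- min(par$mu / max(lam2, 1e-12), 0.9 * par$obs$level)
  sd2 <- d^2 - par$gamma^2
  c(a, b, lam1, lam2, s1, s2, sqrt(max(sd2, 1e-8)), w)
}

# Solve the 13x13 extended system at fixed u.  z0 = NULL builds a fresh
# interior guess; otherwise warm-starts.  Falls back to a short barrier
# continuation (large mu -> target mu) when the direct solve stalls.
solve_extended_at <- function(u, par, z0 = NULL, tol = 1e-10,
                              fallback = is.null(z0)) {
  if (is.null(z0)) {
    z0 <- interior_guess(u, par)
    if (is.null(z0)) return(list(converged = FALSE))
  }
  res_fn <- function(z) ext_residual(u, z, par)
  jac_fn <- function(z) ext_jacobian(u, z, par)
  sol <- newton_damped(res_fn, jac_fn, z0, tol = tol)
  if (!sol$converged && fallback) {
    g0 <- interior_guess(u, par)
    if (!is.null(g0)) {
      z <- g0
      ok <- TRUE
      for (mu_k in exp(seq(log(max(1, par$mu)), log(par$mu), length.out = 4))) {
        par_k <- par; par_k$mu <- mu_k
        sk <- newton_damped(function(z) ext_residual(u, z, par_k),
                            function(z) ext_jacobian(u, z, par_k),
                            z, tol = tol)
        if (!sk$converged) { ok <- FALSE; break }
        z <- sk$x
      }
      if (ok) sol <- list(x = z, converged = TRUE, res = 0)
    }
  }
  if (sol$converged) list(converged = TRUE, z = sol$x) else
    list(converged = FALSE)
}
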
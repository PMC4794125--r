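# Boundary location and pseudo-arclength continuation.

# Gauss-Newton (minimum-norm) polish onto the underdetermined criterion
# curve G(x) = 0, 27 equations / 28 unknowns.
polish_criterion <- function(x, par, tol = 1e-9, maxit = 25L) {
  for (it in seq_len(maxit)) {
    G <- crit_residual(x, par)
    nG <- max(abs(G))
    if (!is.finite(nG)) return(list(x = x, converged = FALSE, res = Inf))
    if (nG < tol) return(list(x = x, converged = TRUE, res = nG))
    D <- crit_jacobian(x, par)
    step <- tryCatch(
      as.numeric(crossprod(D, solve(tcrossprod(D), G))),
      error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(x = x, converged = FALSE, res = nG))
    alpha <- 1
    repeat {
      xn <- x - alpha * step
      nGn <- max(abs(crit_residual(xn, par)))
      if (is.finite(nGn) && nGn < nG) { x <- xn; break }
      alpha <- alpha / 2
      if (alpha < 1e-4) return(list(x = x, converged = nG < tol, res = nG))
    }
  }
  nG <- max(abs(crit_residual(x, par)))
  list(x = x, converged = nG < tol, res = nG)
}

# unit tangent of the criterion curve: null direction of the 27x28 Jacobian
crit_tangent <- function(D) {
  qr_ <- qr(t(D))
  tau <- qr.Q(qr_, complete = TRUE)[, 28]
  tau / sqrt(sum(tau^2))
}

# classify which singularity the criterion point sits on
active_constraint <- function(x, par) {
  sdv <- x[13]  # s_d is z index 11 -> x index 2 + 11
  v <- x[14:15]
  angle_fold <- abs(cos(v[1])) < 1e-3 ||
    (!par$phi_free && abs(cos(v[2])) < 1e-3)
  if (angle_fold) "angle" else if (abs(sdv) < 1e-3) "clearance" else "other"
}

#' Locate one point of the CFRW boundary by directional marching
#'
#' From an interior layer point, march along a fixed in-plane direction,
#' re-solving the extended system with warm starts; the boundary is
#' bracketed where the solve first fails and refined by bisection, then the
#' full criterion state (including the unit null direction of the Jacobian
#' transpose) is polished onto the boundary curve.
#'
#' @param start_u length-2 interior layer point \[mm\].
#' @param direction length-2 march direction (normalised internally).
#' @param h layer height \[mm\].
#' @inheritParams extended_residual
#' @param t_step march step \[mm\].
#' @param t_max maximum march distance \[mm\].
#' @return An object of class `criterion_state`: list with `x` (length-28),
#'   `u`, `z`, `xi`, `h`, `residual`, and `active` (`"clearance"` or
#'   `"angle"`, the singularity type).
#' @export
find_boundary_point <- function(start_u, direction, h, target, limits, part,
                                obs_sq, gamma, mu, t_step = 1, t_max = 400) {
  par <- cfrw_par(target, h, limits, part, obs_sq, gamma, mu)
  direction <- direction / sqrt(sum(direction^2))
  sol <- solve_extended_at(start_u, par)
  if (!sol$converged) stop("start point not inside CFRW")
  t_in <- 0; z_in <- sol$z
  t <- t_step
  repeat {
    s <- solve_extended_at(start_u + t * direction, par, z0 = z_in)
    if (!s$converged) break
    t_in <- t; z_in <- s$z
    t <- t + t_step
    if (t > t_max) stop("no boundary within max march distance")
  }
  t_out <- t
  while (t_out - t_in > 1e-8) {
    tm <- (t_in + t_out) / 2
    s <- solve_extended_at(start_u + tm * direction, par, z0 = z_in)
    if (s$converged) { t_in <- tm; z_in <- s$z } else t_out <- tm
  }
  u_b <- start_u + t_in * direction
  J <- ext_jacobian(u_b, z_in, par)
  xi <- svd(J)$u[, 13]
  pol <- polish_criterion(c(u_b, z_in, xi), par)
  st <- structure(list(x = pol$x, u = pol$x[1:2], z = pol$x[3:15],
                       xi = pol$x[16:28], h = h, residual = pol$res,
                       converged = pol$converged,
                       active = active_constraint(pol$x, par)),
                  class = "criterion_state")
  if (!pol$converged)
    warning(sprintf("criterion polish stalled at residual %.2e", pol$res))
  st
}

#' Trace a closed CFRW boundary curve by pseudo-arclength continuation
#'
#' Predictor-corrector continuation of the 1D solution curve of the
#' boundary criterion, with an adaptive step targeted at a fixed in-plane
#' displacement.  Tracing stops when the curve closes on its seed, leaves
#' the layer domain, or reaches an angle-limit fold; in the open cases the
#' second half of the curve is traced from the seed in the opposite
#' direction and prepended.
#'
#' @param seed a `criterion_state` from [find_boundary_point()].
#' @inheritParams extended_residual
#' @param step_u target in-plane step \[mm\].
#' @param h_max half-width of the layer domain \[mm\].
#' @param max_steps hard cap on continuation steps.
#' @param tol corrector residual tolerance.
#' @return list with `u` (n x 2 matrix of ordered boundary points, first
#'   row repeated at the end when closed), `states` (matrix of the full
#'   28-vectors), `closed`, and `end_reason`.
#' @export
trace_boundary <- function(seed, target, limits, part, obs_sq, gamma, mu,
                           step_u = 0.5, h_max = 200, max_steps = 1e5,
                           tol = 1e-9) {
  par <- cfrw_par(target, seed$h, limits, part, obs_sq, gamma, mu)
  half1 <- trace_half(seed$x, par, +1, step_u, h_max, max_steps, tol)
  if (half1$end_reason == "closed") {
    u <- rbind(half1$u, half1$u[1, ])
    return(list(u = u, states = half1$states, closed = TRUE,
                end_reason = "closed", h = seed$h))
  }
  half2 <- trace_half(seed$x, par, -1, step_u, h_max, max_steps, tol)
  n2 <- nrow(half2$u)
  u <- rbind(half2$u[n2:1, , drop = FALSE], half1$u[-1, , drop = FALSE])
  states <- rbind(half2$states[n2:1, , drop = FALSE],
                  half1$states[-1, , drop = FALSE])
  list(u = u, states = states, closed = FALSE,
       end_reason = paste(half2$end_reason, half1$end_reason, sep = "/"),
       h = seed$h)
}

trace_half <- function(x_seed, par, orient, step_u, h_max, max_steps, tol) {
  D <- crit_jacobian(x_seed, par)
  tau <- crit_tangent(D) * orient
  u_seed <- x_seed[1:2]
  x <- x_seed
  us <- matrix(x[1:2], 1, 2)
  states <- matrix(x, 1, 28)
  # step length is controlled by the in-plane displacement: h_arc is chosen
  # so the predictor moves ~step_u mm in u, with a hard cap on the 28-space
  # arclength for curve sections where u barely moves
  arc_cap <- 100
  u_speed <- max(sqrt(sum(tau[1:2]^2)), 1e-4)
  h_arc <- min(step_u / u_speed, arc_cap)
  end_reason <- "max_steps"
  steps <- 0L
  while (steps < max_steps) {
    steps <- steps + 1L
    ok <- FALSE
    for (try in 1:10) {
      pred <- x + h_arc * tau
      corr <- correct_step(pred, tau, par, tol)
      if (corr$converged) { ok <- TRUE; break }
      h_arc <- h_arc / 2
      if (h_arc < 1e-5) break
    }
    if (!ok) { end_reason <- "stalled"; break }
    x_new <- corr$x
    # angle-limit fold: the criterion curve continues through v = pi/2
    # onto a mirror branch that retraces u backwards, so stop both when a
    # sampled point sits on the fold and when a step jumps across it
    # (sign change of cos v between accepted points)
    fold <- cos(x[14]) * cos(x_new[14]) < 0 ||
      (!par$phi_free && cos(x[15]) * cos(x_new[15]) < 0)
    D <- crit_jacobian(x_new, par)
    tau_new <- crit_tangent(D)
    if (sum(tau_new * tau) < 0) tau_new <- -tau_new
    x <- x_new; tau <- tau_new
    us <- rbind(us, x[1:2])
    states <- rbind(states, x)
    # stop conditions
    if (fold || active_constraint(x, par) == "angle") {
      end_reason <- "angle_fold"; break
    }
    if (max(abs(x[1:2])) > h_max) { end_reason <- "domain_exit"; break }
    du <- sqrt(sum((x[1:2] - u_seed)^2))
    last_step <- sqrt(sum((us[nrow(us), ] - us[nrow(us) - 1, ])^2))
    if (steps > 8 && du < max(1.2 * last_step, step_u)) {
      end_reason <- "closed"; break
    }
    u_speed <- max(sqrt(sum(tau[1:2]^2)), 1e-4)
    grow <- if (corr$iter <= 5) 1.6 else 1.1
    h_arc <- min(h_arc * grow, step_u / u_speed, arc_cap)
  }
  list(u = us, states = states, end_reason = end_reason)
}

# one pseudo-arclength corrector: Newton on [G(x); tau'(x - pred)] = 0.
# The Jacobian is built at the predictor and reused (chord iterations),
# with one rebuild if the contraction is slow.
correct_step <- function(pred, tau, par, tol, maxit = 9L) {
  x <- pred
  A <- rbind(crit_jacobian(x, par), tau)
  dec <- tryCatch(qr(A), error = function(e) NULL)
  if (is.null(dec)) return(list(converged = FALSE))
  for (it in seq_len(maxit)) {
    G <- crit_residual(x, par)
    nG <- max(abs(G))
    if (!is.finite(nG)) return(list(converged = FALSE))
    if (nG < tol) return(list(x = x, converged = TRUE, iter = it))
    if (it == 5L) {
      A <- rbind(crit_jacobian(x, par), tau)
      dec <- tryCatch(qr(A), error = function(e) NULL)
      if (is.null(dec)) return(list(converged = FALSE))
    }
    rhs <- c(G, sum(tau * (x - pred)))
    step <- tryCatch(qr.coef(dec, rhs), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(converged = FALSE))
    x <- x - step
  }
  list(converged = FALSE)
}

# symmetric (discrete) Hausdorff distance between two polylines' vertices
hausdorff_xy <- function(P, Q) {
  d2 <- outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}
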
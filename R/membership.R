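# Layer-region bookkeeping: angle-limit polygons, ray-casting parity,
# per-needle CFRW assembly and trajectory membership.

# Closed polygon(s) of the reachable region in the z = h plane implied by
# the angle limits: an annulus (or disk) around the target's xy-projection,
# cut to a sector when the azimuth range is a strict subset of the circle.
reachable_polygons <- function(limits, tgt, h, n = 360L) {
  H <- h - tgt[3]
  r_out <- H * tan(limits$theta_max)
  r_in <- if (limits$theta_min > 1e-9) H * tan(limits$theta_min) else 0
  full_phi <- (limits$phi_max - limits$phi_min) >= 2 * pi - 1e-9
  ctr <- tgt[1:2]
  circle <- function(r, a0, a1, n) {
    ang <- seq(a0, a1, length.out = n)
    cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
  }
  if (full_phi) {
    polys <- list(circle(r_out, 0, 2 * pi, n))
    if (r_in > 0) polys <- c(polys, list(circle(r_in, 0, 2 * pi, n)))
    polys
  } else {
    # sector annulus: outer arc, radial edge, inner arc (reversed), back
    outer_arc <- circle(r_out, limits$phi_min, limits$phi_max, n)
    inner_arc <- if (r_in > 0)
      circle(r_in, limits$phi_max, limits$phi_min, n)
    else matrix(ctr, 1, 2)
    list(rbind(outer_arc, inner_arc, outer_arc[1, , drop = FALSE]))
  }
}

# Even-odd ray casting over a list of closed polylines.  The ray direction
# is +x; if a vertex sits on the ray the whole configuration is rotated by
# a fixed irrational angle and retried (deterministic, no RNG).
point_in_curves <- function(pt, polys, max_retry = 5L) {
  rot <- 0
  for (k in seq_len(max_retry + 1L)) {
    crossings <- 0L
    degenerate <- FALSE
    cr <- cos(rot); sr <- sin(rot)
    for (P in polys) {
      if (is.null(P) || nrow(P) < 3) next
      x <- cr * (P[, 1] - pt[1]) + sr * (P[, 2] - pt[2])
      y <- -sr * (P[, 1] - pt[1]) + cr * (P[, 2] - pt[2])
      n <- length(x)
      if (abs(x[1] - x[n]) > 1e-12 || abs(y[1] - y[n]) > 1e-12) {
        x <- c(x, x[1]); y <- c(y, y[1]); n <- n + 1L
      }
      if (any(abs(y) < 1e-9 & x > 0)) { degenerate <- TRUE; break }
      i <- seq_len(n - 1L)
      upward <- (y[i] > 0) != (y[i + 1L] > 0)
      if (any(upward)) {
        xi <- x[i][upward] - y[i][upward] *
          (x[i + 1L][upward] - x[i][upward]) /
          (y[i + 1L][upward] - y[i][upward])
        crossings <- crossings + sum(xi > 0)
      }
    }
    if (!degenerate) return(crossings %% 2L == 1L)
    rot <- rot + 0.3819660112501051  # fixed irrational offset
  }
  stop("ray casting failed: degenerate configuration after retries")
}

# Close an open traced curve.  Ends that both sit near the angle-limit
# circle are joined along a slightly inflated arc (side chosen by probing
# which side of the circle is infeasible); otherwise — a trace that
# stalled mid-domain, e.g. at a high-curvature rod end — the ends are
# joined by the direct chord, which is the conservative small closure.
close_curve_on_outer <- function(u_poly, par) {
  ctr <- par$tgt[1:2]
  H <- par$h - par$tgt[3]
  r_out <- H * tan(par$limits$theta_max)
  e1 <- u_poly[1, ]; e2 <- u_poly[nrow(u_poly), ]
  r1 <- sqrt(sum((e1 - ctr)^2)); r2 <- sqrt(sum((e2 - ctr)^2))
  if (r1 < 0.9 * r_out || r2 < 0.9 * r_out)
    return(rbind(u_poly, u_poly[1, , drop = FALSE]))
  a1 <- atan2(e1[2] - ctr[2], e1[1] - ctr[1])
  a2 <- atan2(e2[2] - ctr[2], e2[1] - ctr[1])
  ccw <- (a1 - a2) %% (2 * pi)          # arc sweep e2 -> e1 going ccw
  cw <- ccw - 2 * pi                     # the complementary (cw) sweep
  pick <- NULL
  for (sweep in list(ccw, cw)) {
    mid <- a2 + sweep / 2
    probe <- ctr + 0.995 * r_out * c(cos(mid), sin(mid))
    if (!quick_feasible(probe, par)) { pick <- sweep; break }
  }
  if (is.null(pick)) pick <- if (abs(ccw) < abs(cw)) ccw else cw
  n_arc <- max(8L, ceiling(abs(pick) / (pi / 90)))
  ang <- a2 + seq(0, pick, length.out = n_arc)
  arc <- cbind(ctr[1] + 1.03 * r_out * cos(ang),
               ctr[2] + 1.03 * r_out * sin(ang))
  rbind(u_poly, arc, u_poly[1, , drop = FALSE])
}

#' Compute the layered CFRW boundary of one needle
#'
#' For every obstacle and every z-layer, locates and traces the closed
#' clearance curves (where the needle/obstacle distance equals the safe
#' distance) and assembles them with the angle-limit region into a
#' queryable boundary object.  Curves are seeded from each obstacle's
#' central projection onto the layer and from a coarse interior grid, and
#' de-duplicated by Hausdorff distance.
#'
#' @param sc a [scene()].
#' @param needle_id index of the needle (into `sc$targets`).
#' @param obstacles list of posed obstacle [superquadric()]s (defaults to
#'   the scene's anatomy).
#' @param z_layers,gamma,mu override the scene's planning parameters.
#' @param target optional [target_point()] overriding the scene target
#'   (used by the sequential planner after displacement compensation).
#' @param step_u continuation step \[mm\].
#' @param seed_grid interior seed-grid resolution per axis.
#' @param max_curves cap on distinct curves per obstacle and layer.
#' @return An object of class `cfrw_boundary`.
#' @export
cfrw_for_needle <- function(sc, needle_id, obstacles = sc$obstacles,
                            z_layers = NULL, gamma = NULL, mu = NULL,
                            target = NULL, step_u = NULL,
                            seed_grid = NULL, max_curves = 4L) {
  p <- sc$planning
  if (is.null(z_layers)) z_layers <- p$z_layers
  if (is.null(gamma)) gamma <- p$gamma
  if (is.null(mu)) mu <- p$mu
  if (is.null(step_u)) step_u <- p$step_u
  if (is.null(seed_grid)) seed_grid <- p$seed_grid
  if (is.null(target)) target <- sc$targets[[needle_id]]
  tgt <- target_position(target)
  limits <- sc$limits
  part <- moving_parts(sc$needle)$head
  layers <- lapply(z_layers, function(h) {
    outer <- reachable_polygons(limits, tgt, h)
    obs_records <- lapply(seq_along(obstacles), function(oi) {
      layer_curves(obstacles[[oi]], tgt, target, h, limits, part,
                   gamma, mu, step_u, seed_grid, max_curves, p$h_max)
    })
    names(obs_records) <- vapply(seq_along(obstacles), function(oi) {
      lb <- obstacles[[oi]]$label
      if (nzchar(lb)) lb else paste0("obstacle", oi)
    }, character(1))
    list(h = h, outer = outer, obstacles = obs_records)
  })
  structure(list(needle_id = needle_id, gamma = gamma, mu = mu,
                 h_max = p$h_max, target = tgt, limits = limits,
                 z_layers = z_layers, layers = layers),
            class = "cfrw_boundary")
}

# curves of one obstacle in one layer
layer_curves <- function(obs, tgt, target, h, limits, part, gamma, mu,
                         step_u, seed_grid, max_curves, h_max) {
  phi_c <- {
    dxy <- obs$pose$t[1:2] - tgt[1:2]
    if (sqrt(sum(dxy^2)) > 1e-9) atan2(dxy[2], dxy[1]) else 0
  }
  par <- cfrw_par(target, h, limits, part, obs, gamma, mu,
                  phi_center = phi_c)
  H <- h - tgt[3]
  r_out <- H * tan(limits$theta_max)
  # seed points: obstacle centre projected through the target + coarse grid
  seeds <- list()
  if (obs$pose$t[3] > tgt[3] + 1e-9) {
    sc_ <- H / (obs$pose$t[3] - tgt[3])
    seeds <- c(seeds, list(tgt[1:2] + sc_ * (obs$pose$t[1:2] - tgt[1:2])))
  }
  g <- seq(-0.9 * r_out, 0.9 * r_out, length.out = seed_grid)
  for (gx in g) for (gy in g) {
    pt <- tgt[1:2] + c(gx, gy)
    if (sqrt(gx^2 + gy^2) < 0.95 * r_out) seeds <- c(seeds, list(pt))
  }
  feas <- vapply(seeds, function(s) quick_feasible(s, par), logical(1))
  if (!any(feas))
    return(list(label = obs$label, covers_layer = TRUE, curves = list(),
                states = list()))
  if (all(feas))
    return(list(label = obs$label, covers_layer = FALSE, curves = list(),
                states = list()))
  feas_pts <- seeds[feas]
  curves <- list(); states <- list()
  for (p_inf in seeds[!feas]) {
    if (length(curves) >= max_curves) break
    inside_existing <- any(vapply(curves, function(cv)
      point_in_curves(p_inf, list(cv)), logical(1)))
    if (inside_existing) next
    dists <- vapply(feas_pts, function(pf) sum((pf - p_inf)^2), numeric(1))
    p_f <- feas_pts[[which.min(dists)]]
    dir <- p_inf - p_f
    if (sqrt(sum(dir^2)) < 1e-9) next
    seed_state <- tryCatch(
      find_boundary_point(p_f, dir, h, target, limits, part, obs,
                          gamma, mu),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(seed_state) || seed_state$active != "clearance") next
    cv <- tryCatch(
      trace_boundary(seed_state, target, limits, part, obs, gamma, mu,
                     step_u = step_u, h_max = h_max),
      error = function(e) NULL)
    if (is.null(cv) || nrow(cv$u) < 8) next
    poly <- if (cv$closed) cv$u else close_curve_on_outer(cv$u, par)
    # duplicate if close in Hausdorff distance or mostly contained in an
    # already-kept curve (partial re-traces of the same shadow)
    dup <- any(vapply(curves, function(ex) {
      if (hausdorff_xy(ex, poly) < 4 * step_u) return(TRUE)
      idx <- unique(round(seq(1, nrow(poly), length.out = 25)))
      frac <- mean(vapply(idx, function(i)
        point_in_curves(poly[i, ], list(ex)), logical(1)))
      frac > 0.6
    }, logical(1)))
    if (!dup) {
      curves <- c(curves, list(poly))
      states <- c(states, list(cv$states))
    }
  }
  list(label = obs$label, covers_layer = FALSE, curves = curves,
       states = states)
}

#' @export
print.cfrw_boundary <- function(x, ...) {
  cat(sprintf("<cfrw_boundary> needle %s, gamma %.3g mm, mu %.3g\n",
              x$needle_id, x$gamma, x$mu))
  for (ly in x$layers) {
    ncv <- sum(vapply(ly$obstacles, function(o) length(o$curves), integer(1)))
    cov <- sum(vapply(ly$obstacles, function(o) o$covers_layer, logical(1)))
    cat(sprintf("  z = %g mm: %d clearance curve(s)%s\n", ly$h, ncv,
                if (cov) sprintf(", %d obstacle(s) cover the layer", cov)
                else ""))
  }
  invisible(x)
}

#' Test whether a trajectory lies inside the CFRW
#'
#' For every stored layer the trajectory crosses, the axis/layer
#' intersection point is tested by even-odd ray casting against each
#' obstacle's curve set (angle-limit region plus clearance curves); the
#' trajectory is a member iff it is inside for every obstacle on every
#' crossed layer, and its angles lie within the limits.
#'
#' @param traj a [trajectory()].
#' @param boundary a `cfrw_boundary` from [cfrw_for_needle()].
#' @return logical.
#' @export
trajectory_in_cfrw <- function(traj, boundary) {
  tgt <- target_position(traj$target)
  ez <- traj$entry[3]
  if (abs(ez - tgt[3]) < 1e-9)
    stop("trajectory parallel to the z-layers")
  hs <- vapply(boundary$layers, function(l) l$h, numeric(1))
  crossed <- which(hs >= min(tgt[3], ez) - 1e-9 & hs <= max(tgt[3], ez) + 1e-9)
  if (!length(crossed))
    stop("trajectory does not cross any stored z-layer")
  lim <- boundary$limits
  th <- traj$angles[["theta"]]; ph <- traj$angles[["phi"]]
  if (th < lim$theta_min - 1e-12 || th > lim$theta_max + 1e-12) return(FALSE)
  if ((lim$phi_max - lim$phi_min) < 2 * pi - 1e-9) {
    d <- (ph - (lim$phi_max + lim$phi_min) / 2) %% (2 * pi)
    if (d > pi) d <- d - 2 * pi
    if (abs(d) > (lim$phi_max - lim$phi_min) / 2 + 1e-12) return(FALSE)
  }
  for (li in crossed) {
    ly <- boundary$layers[[li]]
    s <- (ly$h - tgt[3]) / (ez - tgt[3])
    u_pt <- tgt[1:2] + s * (traj$entry[1:2] - tgt[1:2])
    if (!point_in_curves(u_pt, ly$outer)) return(FALSE)
    for (ob in ly$obstacles) {
      if (ob$covers_layer) return(FALSE)
      # each closed clearance curve encloses an infeasible pocket of this
      # obstacle; a point inside any of them is out of the CFRW (robust
      # even when partial re-traces of one shadow overlap)
      for (cv in ob$curves)
        if (point_in_curves(u_pt, list(cv))) return(FALSE)
    }
  }
  TRUE
}
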
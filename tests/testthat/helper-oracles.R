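# Independent oracles used across the test suite.  These deliberately
# re-derive every quantity with their own transform / optimisation code so
# they never share a path with the implementation they check.

# Super-quadric value computed from scratch: own rotation application.
oracle_sq_value <- function(scales, exponents, level, R, t, p) {
  pl <- solve(R) %*% (p - t)      # inverse, not transpose, on purpose
  sum(abs(pl / scales)^exponents) - level
}

# Central finite differences of a scalar field.
fd_gradient <- function(f, p, h = 1e-6) {
  vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (f(p + e) - f(p - e)) / (2 * h)
  }, numeric(1))
}

# Distance from a line (point p0, unit direction dir) to the surface of a
# posed super-quadric with exponents (2,2,2) (an ellipsoid), by multi-start
# quasi-Newton over the line parameter and the ellipsoid's spherical
# parameterisation.  Negative -> line intersects the ellipsoid.
oracle_line_ellipsoid_distance <- function(p0, dir, sq,
                                           t_range = c(0, 300),
                                           n_starts = 8L) {
  stopifnot(all(sq$exponents == 2))
  A <- sq$scales * sqrt(sq$level)
  R <- sq$pose$R; ctr <- sq$pose$t
  dir <- dir / sqrt(sum(dir^2))
  surf <- function(al, be) {
    as.numeric(R %*% (A * c(cos(al) * cos(be), sin(al) * cos(be),
                            sin(be)))) + ctr
  }
  obj <- function(x) {
    p <- p0 + x[1] * dir
    sqrt(sum((p - surf(x[2], x[3]))^2))
  }
  # does the line hit the inflated body?  check centre distance first
  w <- ctr - p0
  t_c <- sum(w * dir)
  inside <- sum((p0 + t_c * dir - ctr)^2) < max(A)^2
  best <- Inf
  set.seed(42)
  for (s in seq_len(n_starts)) {
    x0 <- c(stats::runif(1, t_range[1], t_range[2]),
            stats::runif(1, -pi, pi), stats::runif(1, -pi / 2, pi / 2))
    o <- stats::optim(x0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (o$value < best) best <- o$value
  }
  # sign: negative if some line point is inside the implicit surface
  ts <- seq(t_range[1], t_range[2], length.out = 400)
  vals <- vapply(ts, function(tt) sq_value(sq, p0 + tt * dir), numeric(1))
  if (any(vals < 0)) -best else best
}

# Winding-number point-in-polygon (independent of the ray-parity code).
oracle_winding_inside <- function(pt, polys) {
  total <- 0
  for (P in polys) {
    n <- nrow(P)
    if (sqrt(sum((P[1, ] - P[n, ])^2)) > 1e-9) P <- rbind(P, P[1, ])
    a <- atan2(P[, 2] - pt[2], P[, 1] - pt[1])
    d <- diff(a)
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    total <- total + round(sum(d) / (2 * pi))
  }
  total %% 2 != 0
}

# Brute-force closest pair between two posed super-quadric surfaces by
# penalised multi-start optimisation (independent of the alternating
# projection used in the package).
oracle_surface_pair_distance <- function(sq1, sq2, n_starts = 6L) {
  obj <- function(x, rho) {
    p1 <- x[1:3]; p2 <- x[4:6]
    sqrt(sum((p1 - p2)^2)) + rho * (sq_value(sq1, p1)^2 + sq_value(sq2, p2)^2)
  }
  # retract a point exactly onto a surface along the ray from the centre
  # (independent 1-D root find; f is monotone along such rays)
  retract <- function(sq, p) {
    ctr <- sq$pose$t
    g <- function(s) sq_value(sq, ctr + s * (p - ctr))
    hi <- 1
    while (g(hi) < 0) hi <- hi * 2
    s <- stats::uniroot(g, c(0, hi), tol = 1e-12)$root
    ctr + s * (p - ctr)
  }
  set.seed(7)
  best <- Inf
  c1 <- sq1$pose$t; c2 <- sq2$pose$t
  for (s in seq_len(n_starts)) {
    x <- c(c1 + stats::rnorm(3, 0, 2), c2 + stats::rnorm(3, 0, 2))
    for (rho in c(1, 10, 100, 1000)) {
      o <- stats::optim(x, obj, rho = rho, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
      x <- o$par
    }
    p1 <- retract(sq1, x[1:3]); p2 <- retract(sq2, x[4:6])
    best <- min(best, sqrt(sum((p1 - p2)^2)))
  }
  best
}
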
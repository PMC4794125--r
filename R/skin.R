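# Parametric skin surfaces S(u, v).
#
# Kinds:
#   "cylinder" — elliptic-cylinder patch around an axis parallel to y:
#       S(u,v) = center + (a sin u, v, b cos u); u is the angular parameter,
#       v runs along the axis [mm].
#   "poly"     — polynomial height patch S(u,v) = (u, v, poly(u, v)).
#   "sphere"   — spherical patch of radius R about a center.
#   "grid"     — gridded bilinear interpolant of tabulated x/y/z node values.

#' Parametric skin surface
#'
#' @param kind one of `"cylinder"`, `"poly"`, `"sphere"`, `"grid"`.
#' @param params kind-specific parameter list:
#'   cylinder: `center` (3), `a`, `b` \[mm\];
#'   poly: `coef` matrix of polynomial coefficients, `z = sum coef[i,j] u^(i-1) v^(j-1)`;
#'   sphere: `center` (3), `radius` \[mm\];
#'   grid: `u_nodes`, `v_nodes`, and `x`, `y`, `z` matrices of node coordinates.
#' @param u_bounds,v_bounds parameter intervals `c(min, max)`.
#' @return An object of class `skin_surface`.
#' @export
skin_surface <- function(kind, params, u_bounds, v_bounds) {
  kind <- match.arg(kind, c("cylinder", "poly", "sphere", "grid"))
  u_bounds <- as.numeric(u_bounds); v_bounds <- as.numeric(v_bounds)
  stopifnot(length(u_bounds) == 2L, length(v_bounds) == 2L,
            u_bounds[1] < u_bounds[2], v_bounds[1] < v_bounds[2])
  need <- switch(kind,
                 cylinder = c("center", "a", "b"),
                 poly = "coef",
                 sphere = c("center", "radius"),
                 grid = c("u_nodes", "v_nodes", "x", "y", "z"))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop(sprintf("skin params: missing field(s) %s for kind '%s'",
                 paste(missing, collapse = ", "), kind))
  structure(list(kind = kind, params = params,
                 u_bounds = u_bounds, v_bounds = v_bounds),
            class = "skin_surface")
}

check_uv <- function(surface, u, v) {
  if (u < surface$u_bounds[1] - 1e-12 || u > surface$u_bounds[2] + 1e-12)
    stop(sprintf("u = %g outside u_bounds [%g, %g]",
                 u, surface$u_bounds[1], surface$u_bounds[2]))
  if (v < surface$v_bounds[1] - 1e-12 || v > surface$v_bounds[2] + 1e-12)
    stop(sprintf("v = %g outside v_bounds [%g, %g]",
                 v, surface$v_bounds[1], surface$v_bounds[2]))
}

poly_eval <- function(coef, u, v) {
  iu <- seq_len(nrow(coef)) - 1
  iv <- seq_len(ncol(coef)) - 1
  sum(outer(u^iu, v^iv) * coef)
}
poly_du <- function(coef, u, v) {
  if (nrow(coef) == 1) return(0)
  d <- coef[-1, , drop = FALSE] * seq_len(nrow(coef) - 1)
  poly_eval(d, u, v)
}
poly_dv <- function(coef, u, v) {
  if (ncol(coef) == 1) return(0)
  d <- t(t(coef[, -1, drop = FALSE]) * seq_len(ncol(coef) - 1))
  poly_eval(d, u, v)
}

# bilinear interpolation of one node matrix, with derivative selection
grid_interp <- function(nodes_u, nodes_v, M, u, v, deriv = "none") {
  i <- findInterval(u, nodes_u, rightmost.closed = TRUE, all.inside = TRUE)
  j <- findInterval(v, nodes_v, rightmost.closed = TRUE, all.inside = TRUE)
  du <- nodes_u[i + 1] - nodes_u[i]; dv <- nodes_v[j + 1] - nodes_v[j]
  su <- (u - nodes_u[i]) / du; sv <- (v - nodes_v[j]) / dv
  f00 <- M[i, j]; f10 <- M[i + 1, j]; f01 <- M[i, j + 1]; f11 <- M[i + 1, j + 1]
  switch(deriv,
         none = (1 - su) * (1 - sv) * f00 + su * (1 - sv) * f10 +
           (1 - su) * sv * f01 + su * sv * f11,
         u = ((1 - sv) * (f10 - f00) + sv * (f11 - f01)) / du,
         v = ((1 - su) * (f01 - f00) + su * (f11 - f10)) / dv)
}

#' Evaluate a skin surface and its unit normal
#'
#' @param surface A [skin_surface()].
#' @param u,v parameters within the surface bounds.
#' @return `skin_eval`: length-3 surface point \[mm\]; `skin_normal`: unit
#'   normal `S_u x S_v / ||.||`.
#' @export
skin_eval <- function(surface, u, v) {
  check_uv(surface, u, v)
  p <- surface$params
  switch(surface$kind,
         cylinder = p$center + c(p$a * sin(u), v, p$b * cos(u)),
         poly = c(u, v, poly_eval(p$coef, u, v)),
         sphere = p$center + p$radius *
           c(cos(v) * cos(u), cos(v) * sin(u), sin(v)),
         grid = c(grid_interp(p$u_nodes, p$v_nodes, p$x, u, v),
                  grid_interp(p$u_nodes, p$v_nodes, p$y, u, v),
                  grid_interp(p$u_nodes, p$v_nodes, p$z, u, v)))
}

# partial derivatives S_u, S_v as columns of a 3x2 matrix
skin_deriv <- function(surface, u, v) {
  check_uv(surface, u, v)
  p <- surface$params
  switch(surface$kind,
         cylinder = cbind(c(p$a * cos(u), 0, -p$b * sin(u)), c(0, 1, 0)),
         poly = cbind(c(1, 0, poly_du(p$coef, u, v)),
                      c(0, 1, poly_dv(p$coef, u, v))),
         sphere = p$radius * cbind(
           c(-cos(v) * sin(u), cos(v) * cos(u), 0),
           c(-sin(v) * cos(u), -sin(v) * sin(u), cos(v))),
         grid = cbind(
           c(grid_interp(p$u_nodes, p$v_nodes, p$x, u, v, "u"),
             grid_interp(p$u_nodes, p$v_nodes, p$y, u, v, "u"),
             grid_interp(p$u_nodes, p$v_nodes, p$z, u, v, "u")),
           c(grid_interp(p$u_nodes, p$v_nodes, p$x, u, v, "v"),
             grid_interp(p$u_nodes, p$v_nodes, p$y, u, v, "v"),
             grid_interp(p$u_nodes, p$v_nodes, p$z, u, v, "v"))))
}

#' @rdname skin_eval
#' @export
skin_normal <- function(surface, u, v) {
  d <- skin_deriv(surface, u, v)
  n <- c(d[2, 1] * d[3, 2] - d[3, 1] * d[2, 2],
         d[3, 1] * d[1, 2] - d[1, 1] * d[3, 2],
         d[1, 1] * d[2, 2] - d[2, 1] * d[1, 2])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate surface normal (S_u x S_v = 0)")
  n / nn
}
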
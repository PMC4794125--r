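# Optimal entry point on the skin by four-quadrant grid refinement.

#' Optimal needle entry point on the skin surface
#'
#' Four-quadrant grid-refinement search for the feasible entry point
#' minimising the trajectory length `||S(u,v) - target'||`.  Starting at
#' the parameter-domain midpoint, the four quadrant centres at
#' half-interval offsets are evaluated each iteration, candidates whose
#' trajectory leaves the CFRW are discarded, the best feasible candidate
#' becomes the new centre, and the intervals are halved.  The search
#' terminates when the sine of the angle between the trajectory and the
#' surface normal drops to `delta_tol`, or when the largest interval drops
#' to `eps_tol`.
#'
#' @param surface a [skin_surface()].
#' @param target a [target_point()].
#' @param boundary a `cfrw_boundary` for this needle.
#' @param delta_tol convergence precision on the normal-alignment sine.
#' @param eps_tol step precision on the parameter intervals.
#' @param start optional `(u, v)` start (defaults to the domain midpoint).
#' @param multi_start optional m: also try an m x m coarse seed grid and
#'   keep the best result (off by default; the base procedure is a local
#'   search).
#' @param max_iter iteration cap.
#' @return list with `entry` \[mm\], `uv`, `d_min` \[mm\], `angles`,
#'   `iterations`, `termination` (`"normal_alignment"` or `"step_precision"`).
#' @export
optimal_entry <- function(surface, target, boundary,
                          delta_tol = 1e-5, eps_tol = 1e-4,
                          start = NULL, multi_start = NULL,
                          max_iter = 200L) {
  if (!is.null(multi_start) && multi_start >= 2) {
    us <- seq(surface$u_bounds[1], surface$u_bounds[2],
              length.out = multi_start + 2L)[-c(1L, multi_start + 2L)]
    vs <- seq(surface$v_bounds[1], surface$v_bounds[2],
              length.out = multi_start + 2L)[-c(1L, multi_start + 2L)]
    best <- NULL
    for (u0 in us) for (v0 in vs) {
      res <- tryCatch(
        optimal_entry(surface, target, boundary, delta_tol, eps_tol,
                      start = c(u0, v0)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$d_min < best$d_min))
        best <- res
    }
    if (is.null(best)) stop("no feasible entry point from any start")
    return(best)
  }

  tgt <- target_position(target)
  L1 <- (surface$u_bounds[2] - surface$u_bounds[1]) / 2
  L2 <- (surface$v_bounds[2] - surface$v_bounds[1]) / 2
  uv <- if (is.null(start))
    c(mean(surface$u_bounds), mean(surface$v_bounds)) else as.numeric(start)

  eval_candidate <- function(uv) {
    if (uv[1] < surface$u_bounds[1] || uv[1] > surface$u_bounds[2] ||
        uv[2] < surface$v_bounds[1] || uv[2] > surface$v_bounds[2])
      return(NULL)
    p <- skin_eval(surface, uv[1], uv[2])
    tr <- tryCatch(trajectory(target, p), error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    ok <- tryCatch(trajectory_in_cfrw(tr, boundary), error = function(e) FALSE)
    if (!ok) return(NULL)
    list(uv = uv, p = p, d = sqrt(sum((p - tgt)^2)))
  }

  best <- eval_candidate(uv)
  iter <- 0L
  termination <- "step_precision"
  repeat {
    iter <- iter + 1L
    offs <- list(c(0.5 * L1, 0.5 * L2), c(-0.5 * L1, 0.5 * L2),
                 c(-0.5 * L1, -0.5 * L2), c(0.5 * L1, -0.5 * L2))
    cands <- Filter(Negate(is.null),
                    lapply(offs, function(o) eval_candidate(uv + o)))
    if (iter == 1L && is.null(best) && !length(cands))
      stop("initial point outside CFRW; supply alternative start")
    if (length(cands)) {
      ds <- vapply(cands, `[[`, numeric(1), "d")
      ties <- which(abs(ds - min(ds)) < 1e-12)
      if (length(ties) > 1L) {
        key <- vapply(cands[ties], function(cn) cn$uv[1] * 1e9 + cn$uv[2],
                      numeric(1))
        pick <- cands[[ties[which.min(key)]]]
      } else pick <- cands[[which.min(ds)]]
      if (is.null(best) || pick$d < best$d) best <- pick
    }
    if (is.null(best)) stop("no feasible candidate survives the search")
    uv <- best$uv
    L1 <- L1 / 2; L2 <- L2 / 2
    # termination: trajectory aligned with the surface normal, or grid
    # refined to the step precision
    w <- best$p - tgt
    n <- skin_normal(surface, best$uv[1], best$uv[2])
    cr <- c(w[2] * n[3] - w[3] * n[2], w[3] * n[1] - w[1] * n[3],
            w[1] * n[2] - w[2] * n[1])
    sine <- sqrt(sum(cr^2)) / (sqrt(sum(w^2)) * sqrt(sum(n^2)))
    if (sine <= delta_tol) { termination <- "normal_alignment"; break }
    if (max(L1, L2) <= eps_tol) { termination <- "step_precision"; break }
    if (iter >= max_iter) { termination <- "max_iter"; break }
  }
  ang <- trajectory_angles(best$p, tgt)
  list(entry = best$p, uv = best$uv, d_min = best$d, angles = ang,
       iterations = iter, termination = termination)
}
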
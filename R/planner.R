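# Sequential multi-needle planning: per-needle CFRW, optimal entry,
# obstacle update with the inserted needle, displacement compensation.

#' Zero displacement provider
#'
#' The default deformation model: every insertion displaces every
#' subsequent target by zero.  A real provider is a
#' `function(inserted_idx, target_idx)` returning a length-3 displacement
#' \[mm\] of target `target_idx` caused by inserting needle `inserted_idx`;
#' displacements accumulate over insertions.
#'
#' @return A displacement provider function.
#' @export
zero_displacements <- function() {
  function(inserted_idx, target_idx) c(0, 0, 0)
}

# posed obstacle super-quadrics representing an inserted needle, truncated
# at the skin entry point (the inserted portion is the obstacle)
inserted_needle_obstacles <- function(traj, geom, needle_id,
                                      truncate = TRUE) {
  tgt <- target_position(traj$target)
  th <- traj$angles[["theta"]]; ph <- traj$angles[["phi"]]
  dir <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  head <- geom$head_sq
  if (truncate) {
    L_ins <- sqrt(sum((traj$entry - tgt)^2))
    half <- L_ins / 2
    rod <- superquadric(
      c(half / head$level^(1 / head$exponents[1]), head$scales[2],
        head$scales[3]),
      head$exponents, head$level,
      rotation = needle_rotation(th, ph),
      translation = tgt + half * dir,
      label = sprintf("needle%d", needle_id))
    list(rod)
  } else {
    tr <- obstacle_transform(traj, geom)
    list(sq_with_pose(head, tr$R, tr$t, label = sprintf("needle%d", needle_id)))
  }
}

#' Plan all needle-insertion trajectories sequentially
#'
#' Implements the sequential loop: for each target in insertion order,
#' compensate the target by the accumulated displacement, build the
#' obstacle set (anatomy plus previously inserted needles), compute the
#' CFRW boundary, select the optimal entry point, and register the
#' inserted needle as a new obstacle for its successors.
#'
#' @param sc a [scene()].
#' @param config named list overriding `sc$planning` entries.
#' @param displacements a displacement provider (see [zero_displacements()]).
#' @param order insertion order (default: scene target order).
#' @param truncate_needles treat inserted needles as rods truncated at the
#'   entry point (default) rather than the full printed head.
#' @param verbose print per-needle progress.
#' @return An object of class `plan_result`: list of per-needle records
#'   (`trajectory`, `d_min`, `entry`, `uv`, `angles`, `clearances`,
#'   `termination`, `iterations`, `boundary`) plus the settings used.
#' @export
plan_all <- function(sc, config = list(), displacements = zero_displacements(),
                     order = seq_along(sc$targets), truncate_needles = TRUE,
                     verbose = FALSE) {
  p <- utils::modifyList(sc$planning, config)
  obstacles <- sc$obstacles
  n <- length(sc$targets)
  disp_acc <- matrix(0, nrow = max(n, 1L), ncol = 3)
  needles <- list()
  for (j in order) {
    base_t <- sc$targets[[j]]
    tgt_j <- target_point(base_t$position,
                          base_t$displacement + disp_acc[j, ])
    if (verbose)
      message(sprintf("planning needle %d: target (%s) mm, %d obstacle(s)",
                      j, paste(format(target_position(tgt_j), digits = 5),
                               collapse = ", "), length(obstacles)))
    bnd <- cfrw_for_needle(sc, j, obstacles = obstacles,
                           z_layers = p$z_layers, gamma = p$gamma,
                           mu = p$mu, target = tgt_j, step_u = p$step_u,
                           seed_grid = p$seed_grid)
    empty <- length(bnd$layers) &&
      all(vapply(bnd$layers, function(ly)
        any(vapply(ly$obstacles, function(o) o$covers_layer, logical(1))),
        logical(1)))
    if (empty) {
      blockers <- unique(unlist(lapply(bnd$layers, function(ly)
        names(Filter(function(o) o$covers_layer, ly$obstacles)))))
      stop(sprintf("needle %d has an empty CFRW on every layer (blocking: %s)",
                   j, paste(blockers, collapse = ", ")))
    }
    # local grid search first; if the domain midpoint and its quadrant
    # offsets are all blocked (crowded scenes), retry from a coarse
    # multi-start seed grid
    ent <- tryCatch(
      optimal_entry(sc$skin, tgt_j, bnd,
                    delta_tol = p$delta_tol, eps_tol = p$eps_tol),
      error = function(e) {
        if (!grepl("outside CFRW|feasible", conditionMessage(e))) stop(e)
        optimal_entry(sc$skin, tgt_j, bnd, delta_tol = p$delta_tol,
                      eps_tol = p$eps_tol, multi_start = 4)
      })
    traj <- trajectory(tgt_j, ent$entry)
    clear <- vapply(obstacles, function(ob)
      trajectory_clearance(traj, sc$needle, ob), numeric(1))
    names(clear) <- vapply(seq_along(obstacles), function(oi) {
      lb <- obstacles[[oi]]$label
      if (nzchar(lb)) lb else paste0("obstacle", oi)
    }, character(1))
    needles[[length(needles) + 1L]] <- list(
      needle_id = j, trajectory = traj, entry = ent$entry, uv = ent$uv,
      d_min = ent$d_min, angles = ent$angles, clearances = clear,
      iterations = ent$iterations, termination = ent$termination,
      boundary = bnd)
    obstacles <- c(obstacles,
                   inserted_needle_obstacles(traj, sc$needle, j,
                                             truncate = truncate_needles))
    for (k in setdiff(order, order[seq_len(match(j, order))]))
      disp_acc[k, ] <- disp_acc[k, ] + displacements(j, k)
  }
  structure(list(scene_name = sc$name, needles = needles,
                 settings = p, final_obstacles = obstacles),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("<plan_result '%s'> %d needle(s)\n", x$scene_name,
              length(x$needles)))
  for (nd in x$needles) {
    cat(sprintf(
      "  needle %d: entry (%s) mm, d_min %.3f mm, min clearance %s mm\n",
      nd$needle_id, paste(format(nd$entry, digits = 5), collapse = ", "),
      nd$d_min,
      if (length(nd$clearances)) format(min(nd$clearances), digits = 4)
      else "-"))
  }
  invisible(x)
}

#' Pairwise clearances between planned needle shafts
#'
#' For each ordered pair i < j, the minimum surface distance between
#' needle i's inserted rod (truncated at its entry, as the planner
#' represented it) and needle j's planning body (the posed head) — i.e.
#' exactly the quantity the sequential CFRW constrained to stay above
#' gamma.
#'
#' @param plan a `plan_result`.
#' @param geom the [needle_geometry()] used for planning.
#' @return symmetric matrix of clearances \[mm\] (diagonal NA).
#' @export
plan_pairwise_clearances <- function(plan, geom) {
  n <- length(plan$needles)
  M <- matrix(NA_real_, n, n)
  rods <- lapply(plan$needles, function(nd)
    inserted_needle_obstacles(nd$trajectory, geom, nd$needle_id)[[1]])
  part <- moving_parts(geom)$head
  heads <- lapply(plan$needles, function(nd) {
    posed_part(part, target_position(nd$trajectory$target),
               nd$trajectory$angles[["theta"]], nd$trajectory$angles[["phi"]])
  })
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sq_surface_distance(rods[[i]], heads[[j]])$distance
    M[i, j] <- M[j, i] <- d
  }
  M
}
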
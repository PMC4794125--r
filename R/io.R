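# Scene / plan serialization (JSON) and boundary export (CSV).

sq_to_list <- function(sq) {
  list(label = sq$label, scales = sq$scales, exponents = sq$exponents,
       level = sq$level, rotation = rot_to_quat(sq$pose$R),
       translation = sq$pose$t)
}
sq_from_list <- function(x) {
  superquadric(x$scales, x$exponents, x$level,
               rotation = quat_to_rot(x$rotation),
               translation = x$translation,
               label = if (is.null(x$label)) "" else x$label)
}

scene_to_list <- function(sc) {
  list(
    name = sc$name,
    seed = sc$seed,
    obstacles = lapply(sc$obstacles, sq_to_list),
    skin = list(kind = sc$skin$kind, params = sc$skin$params,
                u_bounds = sc$skin$u_bounds, v_bounds = sc$skin$v_bounds),
    targets = lapply(sc$targets, function(t)
      list(position = t$position, displacement = t$displacement)),
    needle = list(head_length = sc$needle$head_length,
                  radius = sc$needle$radius,
                  head_sq = sq_to_list(sc$needle$head_sq),
                  tube_sq = sq_to_list(sc$needle$tube_sq)),
    angle_limits = list(theta = c(sc$limits$theta_min, sc$limits$theta_max),
                        phi = c(sc$limits$phi_min, sc$limits$phi_max)),
    planning = sc$planning)
}

scene_from_list <- function(x) {
  sk <- x$skin
  params <- sk$params
  for (nm in c("x", "y", "z", "coef"))   # matrix-valued params: a single
    if (!is.null(params[[nm]])) {        # row deserialises as a vector
      if (is.list(params[[nm]]))
        params[[nm]] <- do.call(rbind, lapply(params[[nm]], as.numeric))
      else if (!is.matrix(params[[nm]]))
        params[[nm]] <- matrix(params[[nm]], nrow = 1)
    }
  scene(
    obstacles = lapply(x$obstacles, sq_from_list),
    skin = skin_surface(sk$kind, params, sk$u_bounds, sk$v_bounds),
    targets = lapply(x$targets, function(t)
      target_point(t$position, t$displacement)),
    needle = needle_geometry(head_sq = sq_from_list(x$needle$head_sq),
                             tube_sq = sq_from_list(x$needle$tube_sq),
                             head_length = x$needle$head_length,
                             radius = x$needle$radius),
    limits = angle_limits(x$angle_limits$theta[1], x$angle_limits$theta[2],
                          x$angle_limits$phi[1], x$angle_limits$phi[2]),
    planning = x$planning, name = x$name, seed = x$seed)
}

#' Save / load a scene as JSON
#'
#' Numeric fields are written at full precision so that
#' `load_scene(save_scene(x))` round-trips exactly.
#'
#' @param sc a [scene()].
#' @param path file path of the JSON document.
#' @return `load_scene` returns the [scene()]; `save_scene` the path,
#'   invisibly.
#' @export
save_scene <- function(sc, path) {
  jsonlite::write_json(scene_to_list(sc), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_scene
#' @export
load_scene <- function(path) {
  if (!file.exists(path)) stop(sprintf("scene file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  scene_from_list(x)
}

#' Flatten a CFRW boundary into a data frame
#'
#' One row per sampled boundary point, with columns `needle_id`,
#' `obstacle_id`, `z_mm`, `curve_index`, `point_index`, `x_mm`, `y_mm`.
#'
#' @param boundary a `cfrw_boundary`.
#' @return A data.frame.
#' @export
boundaries_to_df <- function(boundary) {
  rows <- list()
  for (ly in boundary$layers) {
    for (on in names(ly$obstacles)) {
      ob <- ly$obstacles[[on]]
      for (ci in seq_along(ob$curves)) {
        P <- ob$curves[[ci]]
        rows[[length(rows) + 1L]] <- data.frame(
          needle_id = boundary$needle_id, obstacle_id = on, z_mm = ly$h,
          curve_index = ci, point_index = seq_len(nrow(P)),
          x_mm = P[, 1], y_mm = P[, 2])
      }
    }
  }
  if (!length(rows))
    return(data.frame(needle_id = integer(), obstacle_id = character(),
                      z_mm = numeric(), curve_index = integer(),
                      point_index = integer(), x_mm = numeric(),
                      y_mm = numeric()))
  do.call(rbind, rows)
}

plan_to_list <- function(plan) {
  list(
    scene = plan$scene_name,
    settings = plan$settings,
    needles = lapply(plan$needles, function(nd) list(
      needle_id = nd$needle_id,
      target = target_position(nd$trajectory$target),
      entry = nd$entry,
      uv = nd$uv,
      d_min = nd$d_min,
      theta = nd$angles[["theta"]],
      phi = nd$angles[["phi"]],
      clearances = as.list(nd$clearances),
      iterations = nd$iterations,
      termination = nd$termination)))
}

#' Save a plan result
#'
#' Writes `plan.json` (trajectories, distances, clearance diagnostics) and
#' `boundaries.csv` (all traced boundary points) into a directory.
#'
#' @param plan a `plan_result` from [plan_all()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
save_plan <- function(plan, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plan_path <- file.path(dir, "plan.json")
  jsonlite::write_json(plan_to_list(plan), plan_path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  bnd <- do.call(rbind, lapply(plan$needles, function(nd)
    boundaries_to_df(nd$boundary)))
  csv_path <- file.path(dir, "boundaries.csv")
  utils::write.csv(bnd, csv_path, row.names = FALSE)
  invisible(c(plan = plan_path, boundaries = csv_path))
}

#' Plot the layered boundary curves and planned trajectories
#'
#' Draws, for each stored layer, the angle-limit region and every
#' obstacle's clearance curves in the xy-plane, with the axis/layer
#' intersection of each planned trajectory overlaid.
#'
#' @param boundary a `cfrw_boundary`.
#' @param plan optional `plan_result` whose trajectories to overlay.
#' @param layers which stored layers to draw (default all).
#' @export
plot_layers <- function(boundary, plan = NULL, layers = NULL) {
  if (is.null(layers)) layers <- seq_along(boundary$layers)
  old <- graphics::par(mfrow = c(1, length(layers)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (li in layers) {
    ly <- boundary$layers[[li]]
    lim <- max(vapply(ly$outer, function(P) max(abs(P)), numeric(1)))
    graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                   xlab = "x [mm]", ylab = "y [mm]",
                   main = sprintf("z = %g mm", ly$h))
    for (P in ly$outer)
      graphics::lines(P[, 1], P[, 2], col = "grey50", lty = 2)
    cols <- grDevices::hcl.colors(max(1L, length(ly$obstacles)), "Dark 3")
    for (oi in seq_along(ly$obstacles))
      for (P in ly$obstacles[[oi]]$curves)
        graphics::lines(P[, 1], P[, 2], col = cols[oi], lwd = 1.5)
    if (!is.null(plan)) for (nd in plan$needles) {
      tgt <- target_position(nd$trajectory$target)
      ez <- nd$entry[3]
      if (ly$h <= max(tgt[3], ez) && ly$h >= min(tgt[3], ez)) {
        s <- (ly$h - tgt[3]) / (ez - tgt[3])
        u <- tgt[1:2] + s * (nd$entry[1:2] - tgt[1:2])
        graphics::points(u[1], u[2], pch = 4, lwd = 2)
        graphics::text(u[1], u[2], labels = nd$needle_id, pos = 3)
      }
    }
  }
  invisible(NULL)
}
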
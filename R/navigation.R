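# Obstacle-aware shortest paths on a rasterized floor plan.
#
# The planner is a deterministic 8-connected grid search: straight moves cost
# one cell size, diagonal moves sqrt(2) cell sizes (octile metric). Distances
# are computed by repeated vectorized relaxation of the whole grid (a
# label-correcting Dijkstra fixed point), which yields exactly the optimal
# costs; paths are then extracted by backtracking the distance field with a
# fixed neighbour order, so results are reproducible bit for bit.

DIRS <- cbind(
  dx = c(1L, -1L, 0L, 0L, 1L, 1L, -1L, -1L),
  dy = c(0L, 0L, 1L, -1L, 1L, -1L, 1L, -1L)
)

#' Construct a navigation grid
#'
#' Usually produced by [rasterize()]; the direct constructor is useful for
#' synthetic occupancy maps.
#'
#' @param occupancy logical matrix, `TRUE` = blocked; rows index x cells,
#'   columns index y cells.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin `c(x, y)` of the grid's south-west corner.
#' @return an object of class `nav_grid`.
#' @export
nav_grid <- function(occupancy, cell_size, origin = c(0, 0)) {
  if (!is.matrix(occupancy) || !is.logical(occupancy)) {
    stop("'occupancy' must be a logical matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop("'cell_size' must be positive", call. = FALSE)
  }
  structure(list(occupancy = occupancy, cell_size = cell_size,
                 origin = as_point(origin, "origin")),
            class = "nav_grid")
}

#' Rasterize a layout into a navigation grid
#'
#' Cells whose area intersects any floor-plan obstacle or furniture footprint,
#' inflated on all sides by `agent_radius`, are marked blocked. Inflation by
#' the walking agent's body radius turns the planning problem into a point
#' search while keeping the agent clear of solids.
#'
#' @param layout an `or_layout`.
#' @param cell_size grid resolution in metres; default 0.10 m.
#' @param agent_radius inflation radius in metres; default 0.30 m (torso
#'   half-width of a walking adult).
#' @return a [nav_grid()]. A warning is raised when `cell_size` exceeds the
#'   narrowest gap between inflated solids, since passages may then be
#'   spuriously closed.
#' @export
rasterize <- function(layout, cell_size = 0.10, agent_radius = 0.30) {
  if (cell_size <= 0) stop("'cell_size' must be positive", call. = FALSE)
  if (agent_radius < 0) stop("'agent_radius' must be non-negative", call. = FALSE)
  nx <- as.integer(ceiling(layout$plan$width / cell_size))
  ny <- as.integer(ceiling(layout$plan$height / cell_size))
  occ <- matrix(FALSE, nrow = nx, ncol = ny)

  rects <- c(unname(layout$plan$obstacles),
             lapply(layout$furniture, furniture_rect))
  inflated <- lapply(rects, grow_rect, margin = agent_radius)
  eps <- 1e-9
  for (r in inflated) {
    b <- rect_bounds(r)
    ix0 <- max(1L, floor(b[1] / cell_size + eps) + 1L)
    ix1 <- min(nx, ceiling(b[3] / cell_size - eps))
    iy0 <- max(1L, floor(b[2] / cell_size + eps) + 1L)
    iy1 <- min(ny, ceiling(b[4] / cell_size - eps))
    if (ix0 <= ix1 && iy0 <= iy1) occ[ix0:ix1, iy0:iy1] <- TRUE
  }

  # A passage of physical width w admits the agent iff w > 2 * agent_radius;
  # rasterization may still close it when fewer than one free cell remains.
  gap <- min_rect_separation(rects, above = 2 * agent_radius)
  if (is.finite(gap) && gap <= 2 * agent_radius + cell_size) {
    warning(sprintf(paste0("narrowest passable gap (%.2f m) may close at this ",
                           "resolution (cell_size %.2f m, agent_radius %.2f m); ",
                           "paths may be spuriously blocked"),
                    gap, cell_size, agent_radius), call. = FALSE)
  }
  nav_grid(occ, cell_size)
}

# smallest pairwise separation strictly greater than `above` (gaps at or
# below `above` are impassable anyway and not a resolution concern)
min_rect_separation <- function(rects, above = 0) {
  n <- length(rects)
  if (n < 2L) return(Inf)
  best <- Inf
  for (i in seq_len(n - 1L)) {
    a <- rect_bounds(rects[[i]])
    for (j in seq.int(i + 1L, n)) {
      b <- rect_bounds(rects[[j]])
      dx <- max(a[1] - b[3], b[1] - a[3], 0)
      dy <- max(a[2] - b[4], b[2] - a[4], 0)
      d <- sqrt(dx^2 + dy^2)
      if (d > above + 1e-9 && d < best) best <- d
    }
  }
  best
}

point_to_cell <- function(grid, p) {
  rel <- (p - grid$origin) / grid$cell_size
  nx <- nrow(grid$occupancy); ny <- ncol(grid$occupancy)
  ix <- min(nx, max(1L, as.integer(floor(rel[1])) + 1L))
  iy <- min(ny, max(1L, as.integer(floor(rel[2])) + 1L))
  c(ix, iy)
}

cell_center <- function(grid, cell) {
  grid$origin + (cell - 0.5) * grid$cell_size
}

# Matrix shifted by one cell in direction (dx, dy), padded with Inf.
shift_inf <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(Inf, nx, ny)
  xs <- seq_len(nx) - dx
  ys <- seq_len(ny) - dy
  okx <- xs >= 1L & xs <= nx
  oky <- ys >= 1L & ys <= ny
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

# Optimal octile cost from `start_cell` to every cell (Inf where unreachable
# or blocked). Vectorized Bellman relaxation to the Dijkstra fixed point.
distance_field <- function(grid, start_cell) {
  occ <- grid$occupancy
  nx <- nrow(occ); ny <- ncol(occ)
  d <- matrix(Inf, nx, ny)
  if (occ[start_cell[1], start_cell[2]]) {
    stop("start lies in a blocked cell", call. = FALSE)
  }
  d[start_cell[1], start_cell[2]] <- 0
  step <- grid$cell_size
  costs <- c(rep(step, 4), rep(sqrt(2) * step, 4))
  repeat {
    new <- d
    for (k in seq_len(8L)) {
      new <- pmin(new, shift_inf(d, DIRS[k, 1], DIRS[k, 2]) + costs[k])
    }
    new[occ] <- Inf
    if (all(new >= d - 1e-12)) break
    d <- new
  }
  d
}

backtrack_path <- function(grid, d, start_cell, goal_cell) {
  step <- grid$cell_size
  costs <- c(rep(step, 4), rep(sqrt(2) * step, 4))
  cells <- list(goal_cell)
  cur <- goal_cell
  nx <- nrow(d); ny <- ncol(d)
  while (!(cur[1] == start_cell[1] && cur[2] == start_cell[2])) {
    found <- FALSE
    for (k in seq_len(8L)) {
      nb <- cur + DIRS[k, ]
      if (nb[1] < 1L || nb[1] > nx || nb[2] < 1L || nb[2] > ny) next
      if (is.finite(d[nb[1], nb[2]]) &&
          abs(d[nb[1], nb[2]] + costs[k] - d[cur[1], cur[2]]) < 1e-9) {
        cells <- c(cells, list(nb))
        cur <- nb
        found <- TRUE
        break
      }
    }
    if (!found) stop("internal error: backtracking failed", call. = FALSE)
  }
  rev(cells)
}

#' Shortest obstacle-avoiding path between two points
#'
#' Computes the minimal-length 8-connected grid path (straight moves cost one
#' cell, diagonal moves `sqrt(2)` cells). Grid paths overestimate the true
#' Euclidean shortest path by at most ~8.3 % (the octile bound).
#'
#' @param grid a [nav_grid()].
#' @param start,goal `c(x, y)` points in metres; both must fall in unblocked
#'   cells.
#' @param goal_name optional label used in the "unreachable" error message.
#' @return an object of class `nav_path`: list with `waypoints` (n x 2 matrix
#'   of cell-centre coordinates) and `length` (metres, the sum of consecutive
#'   waypoint distances).
#' @export
shortest_path <- function(grid, start, goal, goal_name = NULL) {
  start <- as_point(start, "start"); goal <- as_point(goal, "goal")
  s <- point_to_cell(grid, start)
  g <- point_to_cell(grid, goal)
  if (grid$occupancy[s[1], s[2]]) stop("start lies in a blocked cell", call. = FALSE)
  if (grid$occupancy[g[1], g[2]]) {
    stop(sprintf("goal%s lies in a blocked cell",
                 if (is.null(goal_name)) "" else paste0(" '", goal_name, "'")),
         call. = FALSE)
  }
  d <- distance_field(grid, s)
  path_from_field(grid, d, s, g, goal_name)
}

# shared by shortest_path and the travel simulation (which reuses one field)
path_from_field <- function(grid, d, start_cell, goal_cell, goal_name = NULL) {
  if (!is.finite(d[goal_cell[1], goal_cell[2]])) {
    stop(sprintf("goal%s is unreachable from start",
                 if (is.null(goal_name)) "" else paste0(" '", goal_name, "'")),
         call. = FALSE)
  }
  cells <- backtrack_path(grid, d, start_cell, goal_cell)
  wp <- t(vapply(cells, function(cl) cell_center(grid, cl), numeric(2)))
  colnames(wp) <- c("x", "y")
  len <- if (nrow(wp) < 2L) 0 else
    sum(sqrt(rowSums((wp[-1L, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2)))
  structure(list(waypoints = wp, length = len), class = "nav_path")
}

#' @export
print.nav_path <- function(x, ...) {
  cat(sprintf("<nav_path> %d waypoints, length %.3f m\n", nrow(x$waypoints), x$length))
  invisible(x)
}
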
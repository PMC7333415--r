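# Circulator travel: round trips from the main working place to supply
# destinations, on the rasterized floor plan.

#' Per-surgery circulator trip profile
#'
#' @param counts named numeric vector or list: round trips per surgery to each
#'   destination. Standard destinations are the supply racks `R1`/`R2`, supply
#'   stocks `ST1` (outside the OR) and `ST2` (sterile room), the anesthesia
#'   room `AR`, and `SN` (walking up to the scrub nurse). Counts may be
#'   fractional (per-surgery means).
#' @param origin name of the circulator's base destination; default `"WP1"`,
#'   the main working place.
#' @return an object of class `trip_profile`.
#' @export
trip_profile <- function(counts, origin = "WP1") {
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("trip counts must be named by destination", call. = FALSE)
  }
  if (any(counts < 0)) stop("trip counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, origin = origin), class = "trip_profile")
}

resolve_destination <- function(layout, name) {
  if (name == "SN") return(get_agent(layout, "SN")$position)
  p <- layout$plan$destinations[[name]]
  if (is.null(p)) {
    stop(sprintf("destination '%s' is not defined in layout '%s'",
                 name, layout$id), call. = FALSE)
  }
  p
}

#' Total distance traveled by the circulator during one surgery
#'
#' Each trip is a round trip from the origin working place to the destination
#' and back along the shortest obstacle-avoiding path; per-destination
#' distance is `count * 2 * path_length`. The supply stock `ST1` lies outside
#' the OR proper: its trips are routed to the OR door and extended by a fixed
#' corridor allowance each way. A destination with no collision-free path
#' raises an error naming it.
#'
#' @param layout an `or_layout`.
#' @param trips a [trip_profile()].
#' @param cell_size,agent_radius grid parameters passed to [rasterize()].
#' @param st1_corridor one-way corridor allowance in metres added to `ST1`
#'   trips beyond the door point (default 4 m).
#' @return list of class `travel_result` with `per_destination` (metres),
#'   `total_distance` (their sum) and `paths` (named list of `nav_path`s,
#'   one way out).
#' @export
total_travel_distance <- function(layout, trips, cell_size = 0.10,
                                  agent_radius = 0.30, st1_corridor = 4) {
  stopifnot(inherits(trips, "trip_profile"))
  grid <- rasterize(layout, cell_size, agent_radius)
  origin <- resolve_destination(layout, trips$origin)
  start_cell <- point_to_cell(grid, origin)
  if (grid$occupancy[start_cell[1], start_cell[2]]) {
    stop(sprintf("trip origin '%s' lies in a blocked cell", trips$origin),
         call. = FALSE)
  }
  d <- distance_field(grid, start_cell)

  per <- numeric(0)
  paths <- list()
  for (dest in names(trips$counts)) {
    target <- resolve_destination(layout, dest)
    goal_cell <- point_to_cell(grid, target)
    if (grid$occupancy[goal_cell[1], goal_cell[2]]) {
      stop(sprintf("destination '%s' lies in a blocked cell", dest), call. = FALSE)
    }
    path <- path_from_field(grid, d, start_cell, goal_cell, goal_name = dest)
    one_way <- path$length + if (dest == "ST1") st1_corridor else 0
    per[dest] <- trips$counts[[dest]] * 2 * one_way
    paths[[dest]] <- path
  }
  structure(list(per_destination = per, total_distance = sum(per),
                 paths = paths),
            class = "travel_result")
}

#' @export
print.travel_result <- function(x, ...) {
  cat(sprintf("<travel_result> total %.1f m\n", x$total_distance))
  if (length(x$per_destination)) {
    cat(paste(sprintf("  %s: %.1f m", names(x$per_destination),
                      x$per_destination), collapse = "\n"), "\n")
  }
  invisible(x)
}
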
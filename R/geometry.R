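# Planar OR geometry: floor plans, furniture, staff poses, layout setups.
# All coordinates are metres in 2D, origin at the room's south-west corner.

## ---- small geometric helpers -------------------------------------------

as_point <- function(p, what = "point") {
  p <- as.numeric(unlist(p, use.names = FALSE))
  if (length(p) != 2L || any(!is.finite(p))) {
    stop(sprintf("%s must be two finite coordinates (x, y)", what), call. = FALSE)
  }
  p
}

# rectangles are stored as c(cx, cy, w, h); bounds as c(x0, y0, x1, y1)
rect_bounds <- function(r) {
  c(r[1] - r[3] / 2, r[2] - r[4] / 2, r[1] + r[3] / 2, r[2] + r[4] / 2)
}

rect_contains <- function(r, p) {
  b <- rect_bounds(r)
  p[1] >= b[1] && p[1] <= b[3] && p[2] >= b[2] && p[2] <= b[4]
}

# strict interior overlap: rectangles that merely touch do not overlap
rects_overlap <- function(r1, r2) {
  a <- rect_bounds(r1); b <- rect_bounds(r2)
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

# shortest distance from a point to an axis-aligned rectangle (0 if inside)
rect_point_distance <- function(r, p) {
  b <- rect_bounds(r)
  dx <- max(b[1] - p[1], 0, p[1] - b[3])
  dy <- max(b[2] - p[2], 0, p[2] - b[4])
  sqrt(dx^2 + dy^2)
}

grow_rect <- function(r, margin) c(r[1], r[2], r[3] + 2 * margin, r[4] + 2 * margin)

## ---- constructors -------------------------------------------------------

#' Construct an OR floor plan
#'
#' A floor plan holds the fixed, room-bound part of an operating-room model:
#' outer dimensions, solid obstacle regions (wall desks, racks, anesthesia
#' equipment) and named destination points used by the circulator (supply
#' racks `R1`/`R2`, stocks `ST1`/`ST2`, anesthesia room `AR`, working places
#' `WP1`/`WP2`, doors). Obstacles are axis-aligned rectangles given by centre
#' and size. Floor-plan elements never move when a layout is mirrored; only
#' furniture and staff do.
#'
#' @param width,height room extent in metres (must be positive).
#' @param obstacles named list; each element `c(cx, cy, w, h)` in metres.
#' @param destinations named list of `c(x, y)` points. Names must be unique,
#'   and every point must lie inside the room and outside all obstacles.
#' @return an object of class `or_floor_plan`.
#' @export
floor_plan <- function(width, height, obstacles = list(), destinations = list()) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0) {
    stop("floor plan 'width' and 'height' must be positive", call. = FALSE)
  }
  obstacles <- lapply(obstacles, function(o) as.numeric(unlist(o, use.names = FALSE)))
  for (nm in names(obstacles)) {
    o <- obstacles[[nm]]
    if (length(o) != 4L || o[3] <= 0 || o[4] <= 0) {
      stop(sprintf("obstacle '%s' must be c(cx, cy, w, h) with positive size", nm),
           call. = FALSE)
    }
  }
  destinations <- lapply(destinations, as_point, what = "destination")
  if (anyDuplicated(names(destinations))) {
    stop("destination names must be unique", call. = FALSE)
  }
  plan <- structure(
    list(width = width, height = height,
         obstacles = obstacles, destinations = destinations),
    class = "or_floor_plan"
  )
  for (nm in names(destinations)) {
    p <- destinations[[nm]]
    if (p[1] < 0 || p[1] > width || p[2] < 0 || p[2] > height) {
      stop(sprintf("destination '%s' lies outside the floor plan", nm), call. = FALSE)
    }
    for (ob in names(obstacles)) {
      if (rect_contains(obstacles[[ob]], p)) {
        stop(sprintf("destination '%s' lies inside obstacle '%s'", nm, ob),
             call. = FALSE)
      }
    }
  }
  plan
}

#' Construct a piece of OR furniture
#'
#' @param id label, unique within a layout.
#' @param kind one of `"or_table"`, `"instrument_table"`, `"equipment"`.
#' @param center `c(x, y)` footprint centre in metres.
#' @param footprint `c(width, height)` in metres (axis-aligned).
#' @param table_angle for instrument tables only: the table's angular position
#'   relative to the scrub nurse's neutral facing direction, degrees in
#'   `[0, 360)`. The conventional positions in arthroplasty setups are 0, 45,
#'   90 and 180 degrees.
#' @return an object of class `or_furniture`.
#' @export
furniture <- function(id, kind = c("instrument_table", "or_table", "equipment"),
                      center, footprint, table_angle = NULL) {
  kind <- match.arg(kind)
  center <- as_point(center, sprintf("furniture '%s' center", id))
  footprint <- as.numeric(footprint)
  if (length(footprint) != 2L || any(footprint <= 0)) {
    stop(sprintf("furniture '%s' footprint must have positive area", id), call. = FALSE)
  }
  if (kind == "instrument_table") {
    if (is.null(table_angle) || !is.numeric(table_angle) ||
        table_angle < 0 || table_angle >= 360) {
      stop(sprintf("instrument table '%s' needs a table_angle in [0, 360)", id),
           call. = FALSE)
    }
  } else {
    table_angle <- NULL
  }
  structure(list(id = as.character(id), kind = kind, center = center,
                 footprint = footprint, table_angle = table_angle),
            class = "or_furniture")
}

furniture_rect <- function(f) c(f$center, f$footprint)

#' Construct a staff pose
#'
#' @param role one of `"SU"` (surgeon), `"SN"` (scrub nurse), `"A1"`, `"A2"`
#'   (assistants), `"AN"` (anesthesiologist), `"CIRC"` (circulator).
#' @param position `c(x, y)` in metres.
#' @param facing direction vector; normalized to unit length on construction.
#' @return an object of class `or_agent`.
#' @export
agent_pose <- function(role = c("SU", "SN", "A1", "A2", "AN", "CIRC"),
                       position, facing) {
  role <- match.arg(role)
  position <- as_point(position, sprintf("agent '%s' position", role))
  facing <- as_point(facing, sprintf("agent '%s' facing", role))
  n <- sqrt(sum(facing^2))
  if (n == 0) stop(sprintf("agent '%s' facing must be non-zero", role), call. = FALSE)
  structure(list(role = role, position = position, facing = facing / n),
            class = "or_agent")
}

#' Construct (and validate) an OR layout setup
#'
#' A layout setup is one named operating-room configuration: a floor plan,
#' the movable furniture (the OR table, three or four instrument tables,
#' optional equipment) and the staff poses for one side (left or right limb)
#' of a THA or TKA procedure.
#'
#' @param id setup label, e.g. `"TKA1"` or `"THA3"`.
#' @param procedure `"THA"` or `"TKA"`.
#' @param side `"left"` or `"right"` (the operated side).
#' @param plan an [floor_plan()].
#' @param furniture list of [furniture()] objects; exactly one must be the
#'   OR table, and 3 or 4 must be instrument tables. Footprints must not
#'   overlap.
#' @param agents list of [agent_pose()] objects; exactly one scrub nurse
#'   (`SN`) and one surgeon (`SU`).
#' @return an object of class `or_layout`.
#' @export
layout_setup <- function(id, procedure = c("THA", "TKA"),
                         side = c("left", "right"), plan, furniture, agents) {
  procedure <- match.arg(procedure)
  side <- match.arg(side)
  stopifnot(inherits(plan, "or_floor_plan"))
  layout <- structure(
    list(id = as.character(id), procedure = procedure, side = side,
         plan = plan, furniture = furniture, agents = agents),
    class = "or_layout"
  )
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  fids <- vapply(layout$furniture, function(f) f$id, character(1))
  if (anyDuplicated(fids)) {
    stop("furniture ids must be unique", call. = FALSE)
  }
  kinds <- vapply(layout$furniture, function(f) f$kind, character(1))
  if (sum(kinds == "or_table") != 1L) {
    stop("layout must contain exactly one or_table", call. = FALSE)
  }
  n_tables <- sum(kinds == "instrument_table")
  if (!n_tables %in% c(3L, 4L)) {
    stop(sprintf("layout must have 3 or 4 instrument tables, found %d", n_tables),
         call. = FALSE)
  }
  n <- length(layout$furniture)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (rects_overlap(furniture_rect(layout$furniture[[i]]),
                          furniture_rect(layout$furniture[[j]]))) {
          stop(sprintf("furniture footprints overlap: '%s' and '%s'",
                       fids[i], fids[j]), call. = FALSE)
        }
      }
    }
  }
  roles <- vapply(layout$agents, function(a) a$role, character(1))
  if (sum(roles == "SN") != 1L) stop("layout must have exactly one SN", call. = FALSE)
  if (sum(roles == "SU") != 1L) stop("layout must have exactly one SU", call. = FALSE)
  for (a in layout$agents) {
    p <- a$position
    if (p[1] < 0 || p[1] > layout$plan$width || p[2] < 0 || p[2] > layout$plan$height) {
      stop(sprintf("agent '%s' position lies outside the floor plan", a$role),
           call. = FALSE)
    }
    for (ob in names(layout$plan$obstacles)) {
      if (rect_contains(layout$plan$obstacles[[ob]], p)) {
        stop(sprintf("agent '%s' position lies inside obstacle '%s'", a$role, ob),
             call. = FALSE)
      }
    }
    if (abs(sqrt(sum(a$facing^2)) - 1) > 1e-9) {
      stop(sprintf("agent '%s' facing is not unit length", a$role), call. = FALSE)
    }
  }
  invisible(layout)
}

## ---- accessors ----------------------------------------------------------

get_agent <- function(layout, role) {
  for (a in layout$agents) if (a$role == role) return(a)
  stop(sprintf("layout '%s' has no agent with role '%s'", layout$id, role),
       call. = FALSE)
}

get_furniture <- function(layout, id) {
  for (f in layout$furniture) if (f$id == id) return(f)
  stop(sprintf("layout '%s' has no furniture '%s'", layout$id, id), call. = FALSE)
}

or_table <- function(layout) {
  for (f in layout$furniture) if (f$kind == "or_table") return(f)
  stop("layout has no or_table", call. = FALSE)
}

#' List the instrument tables of a layout
#'
#' @param layout an [layout_setup()] object.
#' @return list of `or_furniture` objects of kind `instrument_table`, in
#'   layout order.
#' @export
instrument_tables <- function(layout) {
  Filter(function(f) f$kind == "instrument_table", layout$furniture)
}

#' @export
print.or_layout <- function(x, ...) {
  tabs <- instrument_tables(x)
  cat(sprintf("<or_layout> %s (%s, %s side)\n", x$id, x$procedure, x$side))
  cat(sprintf("  room: %.1f x %.1f m, %d obstacles, %d destinations\n",
              x$plan$width, x$plan$height,
              length(x$plan$obstacles), length(x$plan$destinations)))
  cat(sprintf("  instrument tables: %s\n",
              paste(sprintf("%s(%g°)", vapply(tabs, `[[`, "", "id"),
                            vapply(tabs, `[[`, 0, "table_angle")),
                    collapse = ", ")))
  cat(sprintf("  staff: %s\n",
              paste(vapply(x$agents, `[[`, "", "role"), collapse = ", ")))
  invisible(x)
}

## ---- angles and mirroring ----------------------------------------------

#' Unsigned viewing angle from a staff pose to a target point
#'
#' Returns the angle, in degrees within `[0, 180]`, between the observer's
#' facing direction and the direction from the observer to the target. This
#' is the torso rotation a person must perform to face the target, the
#' elementary quantity of the rotational-movement ergonomics model.
#'
#' @param observer an [agent_pose()].
#' @param target `c(x, y)` target point; must differ from the observer's
#'   position.
#' @return angle in degrees, in `[0, 180]`.
#' @export
relative_angle <- function(observer, target) {
  target <- as_point(target, "target")
  v <- target - observer$position
  n <- sqrt(sum(v^2))
  if (n == 0) stop("target coincides with the observer's position", call. = FALSE)
  cosang <- sum(observer$facing * v) / n
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Mirror a layout across the OR-table long axis
#'
#' Produces the contralateral variant of a setup: all furniture centres and
#' staff positions are reflected across the long axis of the OR table, facing
#' directions are reflected, and the `side` flag is toggled. Room-fixed
#' elements (floor-plan obstacles and destinations) do not move: the
#' operating room itself stays put when the team switches sides, which is
#' what creates left-versus-right asymmetries in circulator travel.
#'
#' Mirroring is an involution: `mirror_layout(mirror_layout(x))` equals `x`.
#'
#' @param layout an [layout_setup()] object.
#' @return the mirrored `or_layout`.
#' @export
mirror_layout <- function(layout) {
  ot <- or_table(layout)
  # the long axis of the OR table defines the mirror line
  vertical_axis <- ot$footprint[2] >= ot$footprint[1]
  axis_coord <- if (vertical_axis) ot$center[1] else ot$center[2]
  reflect_point <- function(p) {
    if (vertical_axis) c(2 * axis_coord - p[1], p[2]) else c(p[1], 2 * axis_coord - p[2])
  }
  reflect_dir <- function(d) {
    if (vertical_axis) c(-d[1], d[2]) else c(d[1], -d[2])
  }
  layout$furniture <- lapply(layout$furniture, function(f) {
    f$center <- reflect_point(f$center)
    f
  })
  layout$agents <- lapply(layout$agents, function(a) {
    a$position <- reflect_point(a$position)
    a$facing <- reflect_dir(a$facing)
    a
  })
  layout$side <- if (layout$side == "left") "right" else "left"
  validate_layout(layout)
  layout
}
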
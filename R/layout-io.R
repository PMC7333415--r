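# Reading and writing the layout schema (YAML or JSON).

#' Load a layout setup from a YAML/JSON document
#'
#' The schema mirrors the schematic top views the package works from:
#' top-level keys `id`, `procedure`, `side`, `room: {width, height}`,
#' `obstacles` (list of `{id, x, y, width, height}`, centre coordinates),
#' `destinations` (map of name to `[x, y]`), `furniture` (list of
#' `{id, kind, x, y, width, height, table_angle}`) and `agents` (list of
#' `{role, x, y, facing: [dx, dy]}`). Lengths are metres, angles degrees.
#' All [layout_setup()] invariants are checked; violations raise an error
#' naming the offending field.
#'
#' @param source path to a `.yaml`/`.yml`/`.json` file, or an already-parsed
#'   list with the same structure.
#' @return a validated `or_layout`.
#' @seealso [layout_fixture()] for the bundled setups.
#' @export
load_layout <- function(source) {
  if (is.character(source)) {
    if (!file.exists(source)) stop(sprintf("no such layout file: %s", source), call. = FALSE)
    doc <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::read_json(source, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(source)
    }
  } else if (is.list(source)) {
    doc <- source
  } else {
    stop("'source' must be a file path or a list", call. = FALSE)
  }

  need <- function(x, field, where) {
    if (is.null(x[[field]])) {
      stop(sprintf("layout schema: missing field '%s' in %s", field, where),
           call. = FALSE)
    }
    x[[field]]
  }

  room <- need(doc, "room", "document")
  obstacles <- list()
  for (ob in doc$obstacles %||% list()) {
    obstacles[[need(ob, "id", "obstacle")]] <-
      c(need(ob, "x", "obstacle"), need(ob, "y", "obstacle"),
        need(ob, "width", "obstacle"), need(ob, "height", "obstacle"))
  }
  destinations <- lapply(doc$destinations %||% list(), function(p) unlist(p))
  plan <- floor_plan(need(room, "width", "room"), need(room, "height", "room"),
                     obstacles, destinations)

  furn <- lapply(doc$furniture %||% list(), function(f) {
    furniture(id = need(f, "id", "furniture"),
              kind = need(f, "kind", "furniture"),
              center = c(need(f, "x", "furniture"), need(f, "y", "furniture")),
              footprint = c(need(f, "width", "furniture"), need(f, "height", "furniture")),
              table_angle = f$table_angle)
  })
  agents <- lapply(doc$agents %||% list(), function(a) {
    agent_pose(role = need(a, "role", "agent"),
               position = c(need(a, "x", "agent"), need(a, "y", "agent")),
               facing = unlist(need(a, "facing", "agent")))
  })

  layout_setup(id = need(doc, "id", "document"),
               procedure = need(doc, "procedure", "document"),
               side = need(doc, "side", "document"),
               plan = plan, furniture = furn, agents = agents)
}

#' Write a layout setup to a YAML file
#'
#' Inverse of [load_layout()]: serializes the layout in the documented
#' schema so that `load_layout(write_layout(x, f))` round-trips.
#'
#' @param layout an `or_layout`.
#' @param path output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  doc <- list(
    id = layout$id,
    procedure = layout$procedure,
    side = layout$side,
    room = list(width = layout$plan$width, height = layout$plan$height),
    obstacles = lapply(names(layout$plan$obstacles), function(nm) {
      o <- layout$plan$obstacles[[nm]]
      list(id = nm, x = o[1], y = o[2], width = o[3], height = o[4])
    }),
    destinations = lapply(layout$plan$destinations, function(p) as.list(round(p, 6))),
    furniture = lapply(layout$furniture, function(f) {
      out <- list(id = f$id, kind = f$kind,
                  x = round(f$center[1], 6), y = round(f$center[2], 6),
                  width = f$footprint[1], height = f$footprint[2])
      if (!is.null(f$table_angle)) out$table_angle <- f$table_angle
      out
    }),
    agents = lapply(layout$agents, function(a) {
      list(role = a$role, x = round(a$position[1], 6), y = round(a$position[2], 6),
           facing = as.list(round(a$facing, 9)))
    })
  )
  yaml::write_yaml(doc, path, precision = 9L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled OR setup fixtures
#'
#' The package bundles fourteen layout files: seven arthroplasty setups
#' (`TKA1`--`TKA4`, `THA1`--`THA3`), each in a left-side and a right-side
#' variant (the right-side variant is the exact mirror of the left one).
#' `TKA1`, `THA1` and `THA2` are the historically used setups; the others are
#' redesigned alternatives. Coordinates are scale reconstructions of the
#' published schematic top views: absolute distances are reconstruction
#' choices, while the relative geometry (table angles, blocked passages,
#' adjacencies) follows the published descriptions.
#'
#' @param id setup label: `"TKA1"`, `"TKA2"`, `"TKA3"`, `"TKA4"`, `"THA1"`,
#'   `"THA2"` or `"THA3"`.
#' @param side `"left"` or `"right"`.
#' @return for `layout_fixture`, a validated `or_layout`; for
#'   `layout_fixture_ids`, the character vector of bundled setup labels.
#' @export
layout_fixture <- function(id, side = c("left", "right")) {
  side <- match.arg(side)
  id <- toupper(id)
  if (!id %in% layout_fixture_ids()) {
    stop(sprintf("unknown setup '%s'; bundled setups: %s", id,
                 paste(layout_fixture_ids(), collapse = ", ")), call. = FALSE)
  }
  path <- system.file("extdata", "layouts",
                      sprintf("%s_%s.yaml", tolower(id), side),
                      package = "orsim", mustWork = TRUE)
  load_layout(path)
}

#' @rdname layout_fixture
#' @export
layout_fixture_ids <- function() {
  c("TKA1", "TKA2", "TKA3", "TKA4", "THA1", "THA2", "THA3")
}
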
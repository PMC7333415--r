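# Machine-checkable layout requirements.
#
# Of the design requirements collected for arthroplasty OR setups (view lines,
# reach, pathways, hygiene clearances, ergonomics), four are geometric enough
# to lint automatically:
#   req2 - at least one instrument table within arm's reach of the surgeon
#   req6 - no instrument table behind the surgeon (hygiene: the back of the
#          gown is the least sterile surface)
#   req7 - circulator paths keep a clearance margin from instrument tables
#          (airflow and accidental contact threaten sterility)
#   req8 - instrument tables stay inside the laminar-airflow proximity of the
#          OR table

rect_rect_distance <- function(r1, r2) {
  a <- rect_bounds(r1); b <- rect_bounds(r2)
  dx <- max(a[1] - b[3], b[1] - a[3], 0)
  dy <- max(a[2] - b[4], b[2] - a[4], 0)
  sqrt(dx^2 + dy^2)
}

#' Check a layout against the machine-checkable setup requirements
#'
#' Produces one pass/warn finding per requirement with the measured value and
#' the threshold it was compared against. Warnings are advisory: the
#' historically used setups violate several requirements by design.
#'
#' @param layout an `or_layout`.
#' @param reach_threshold req2: maximum surgeon-to-nearest-table distance in
#'   metres (default 1.0).
#' @param behind_tolerance req6: degrees beyond 90 that still count as "next
#'   to" the surgeon (default 10).
#' @param clearance_margin req7: minimum circulator-path clearance from
#'   instrument tables in metres (default 1.0).
#' @param proximity_radius req8: maximum table distance from the OR table in
#'   metres (default 2.5).
#' @param cell_size,agent_radius grid parameters for the req7 path check.
#' @return data.frame with columns `requirement_id`, `status` (`"pass"` or
#'   `"warn"`), `measured_value`, `threshold`, `detail`.
#' @export
lint_layout <- function(layout, reach_threshold = 1.0, behind_tolerance = 10,
                        clearance_margin = 1.0, proximity_radius = 2.5,
                        cell_size = 0.10, agent_radius = 0.30) {
  su <- get_agent(layout, "SU")
  tabs <- instrument_tables(layout)
  tab_ids <- vapply(tabs, `[[`, "", "id")

  # req2: nearest table within the surgeon's reach
  dist_su <- vapply(tabs, function(tb) rect_point_distance(furniture_rect(tb),
                                                           su$position), numeric(1))
  req2 <- list(measured = min(dist_su), detail = tab_ids[which.min(dist_su)],
               ok = min(dist_su) <= reach_threshold, threshold = reach_threshold)

  # req6: no table behind the surgeon
  ang_su <- vapply(tabs, function(tb) relative_angle(su, tb$center), numeric(1))
  req6 <- list(measured = max(ang_su), detail = tab_ids[which.max(ang_su)],
               ok = max(ang_su) <= 90 + behind_tolerance,
               threshold = 90 + behind_tolerance)

  # req7: circulator paths vs table clearance. Supply/equipment corridors
  # only: the walk up to the scrub nurse is excluded, since handing supplies
  # to her is necessarily close to her tables.
  dests <- intersect(c("R1", "R2", "ST1", "ST2", "AR"),
                     names(layout$plan$destinations))
  travel <- total_travel_distance(
    layout, trip_profile(stats::setNames(rep(1, length(dests)), dests)),
    cell_size = cell_size, agent_radius = agent_radius
  )
  min_clear <- Inf; worst_tab <- NA_character_
  for (p in travel$paths) {
    for (tb in tabs) {
      d <- min(apply(p$waypoints, 1L, function(w)
        rect_point_distance(furniture_rect(tb), w)))
      if (d < min_clear) { min_clear <- d; worst_tab <- tb$id }
    }
  }
  req7 <- list(measured = min_clear, detail = worst_tab,
               ok = min_clear >= clearance_margin, threshold = clearance_margin)

  # req8: tables within the protected proximity of the OR table
  ot <- furniture_rect(or_table(layout))
  dist_ot <- vapply(tabs, function(tb) rect_rect_distance(furniture_rect(tb), ot),
                    numeric(1))
  req8 <- list(measured = max(dist_ot), detail = tab_ids[which.max(dist_ot)],
               ok = max(dist_ot) <= proximity_radius, threshold = proximity_radius)

  reqs <- list(req2 = req2, req6 = req6, req7 = req7, req8 = req8)
  data.frame(
    requirement_id = names(reqs),
    status = vapply(reqs, function(r) if (r$ok) "pass" else "warn", character(1)),
    measured_value = vapply(reqs, function(r) unname(r$measured), numeric(1)),
    threshold = vapply(reqs, function(r) r$threshold, numeric(1)),
    detail = vapply(reqs, function(r) r$detail, character(1)),
    row.names = NULL
  )
}

#' Write lint findings as JSON
#'
#' @param findings data.frame from [lint_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_findings <- function(findings, path) {
  jsonlite::write_json(findings, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reference instrument handover times for the final setups
#'
#' Published per-table handover times for the final redesigned TKA and THA
#' setups: the values predicted by the commercial human-motion simulation used
#' in the original evaluation study side by side with the intraoperative
#' measurements, in seconds. Their per-table absolute deviations (via
#' [compare_sim_measured()]) quantify how closely a motion simulation can
#' track the real OR.
#'
#' @return data.frame with columns `procedure`, `table`, `sim`, `measured`.
#' @export
iht_reference <- function() {
  data.frame(
    procedure = rep(c("TKA", "THA"), each = 3L),
    table = rep(c("T1", "T2", "T3"), 2L),
    sim = c(0.70, 1.24, 1.66, 0.79, 1.42, 1.20),
    measured = c(0.65, 1.14, 1.46, 0.72, 1.44, 1.86)
  )
}
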
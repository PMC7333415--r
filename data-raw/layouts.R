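# Authoring script for the bundled layout fixtures.
#
# The seven left-side setups are defined here to scale from the published
# schematic top views (6.5 m x 6.5 m room, origin at the south-west corner,
# OR table fixed with its long axis vertical at x = 3.25). Right-side variants
# are generated as exact mirrors via mirror_layout(). Run from the package
# root after loading the package:
#
#   Rscript -e 'pkgload::load_all(); source("data-raw/layouts.R")'

out_dir <- file.path("inst", "extdata", "layouts")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# ---- room: shared floor plan ---------------------------------------------
# Room-fixed elements: anesthesia equipment at the head end (north), the
# circulator's main working place WP1 at the south-west wall, the second
# working place WP2 at the south-east wall, supply racks R1 (west) and R2
# (east), the sterile-room door on the west wall (ST2 behind it), the
# anesthesia-room door on the east wall, and the OR door (south) through
# which the outside stock ST1 is reached.
room_plan <- function() {
  floor_plan(
    width = 6.5, height = 6.5,
    obstacles = list(
      anesthesia_gear = c(3.25, 5.9, 1.2, 0.8),
      wp1_desk = c(0.3, 1.2, 0.6, 1.2),
      wp2_desk = c(6.3, 0.7, 0.4, 1.4),
      rack_r1 = c(0.15, 4.1, 0.3, 1.0),
      rack_r2 = c(6.35, 4.1, 0.3, 1.0)
    ),
    destinations = list(
      WP1 = c(1.05, 0.65), WP2 = c(5.65, 1.15),
      R1 = c(0.75, 4.05), R2 = c(5.75, 4.45),
      ST1 = c(3.35, 0.25), ST2 = c(0.55, 3.05),
      AR = c(6.15, 5.35),
      sterile_room_door = c(0.45, 2.75),
      anesthesia_room_door = c(6.3, 5.5)
    )
  )
}

ORT <- function() furniture("OR", "or_table", c(3.25, 3.3), c(0.64, 2.0))
tbl <- function(id, x, y, angle, w = 0.8, h = 0.5) {
  furniture(id, "instrument_table", c(x, y), c(w, h), table_angle = angle)
}
ag <- function(role, x, y, fx, fy) agent_pose(role, c(x, y), c(fx, fy))

common_agents <- list(
  AN = ag("AN", 3.25, 5.0, 0, -1),
  CIRC = ag("CIRC", 1.05, 0.65, 1, 0)
)

mk <- function(id, procedure, furn, agents) {
  layout_setup(id, procedure, "left", room_plan(), c(list(ORT()), furn),
               c(agents, unname(common_agents)))
}

layouts <- list(
  # Initial TKA setup: tables in a U at the foot end around the nurse, who
  # stands beside the surgeon; she must turn around for tables 2-4.
  mk("TKA1", "TKA",
     list(tbl("T1", 4.25, 2.75, 0, 0.6, 0.4),
          tbl("T2", 5.00, 2.75, 45),
          tbl("T3", 5.30, 1.90, 90),
          tbl("T4", 4.25, 1.25, 180)),
     list(ag("SU", 3.75, 3.0, -0.6, -0.8),
          ag("SN", 4.25, 2.1, 0, 1),
          ag("A1", 3.75, 2.3, -1, 0),
          ag("A2", 2.70, 3.0, 1, 0))),

  # Redesigned: compact U behind the surgeon; nurse stands at the surgeon's
  # back, one table squeezed against WP2.
  mk("TKA2", "TKA",
     list(tbl("T1", 4.25, 3.00, 0, 0.6, 0.4),
          tbl("T2", 4.15, 3.80, 45),
          tbl("T3", 5.00, 3.60, 90),
          tbl("T4", 5.70, 1.60, 90)),
     list(ag("SU", 3.75, 3.0, -0.6, -0.8),
          ag("SN", 5.00, 2.9, -1.25, 0.1),
          ag("A1", 3.60, 3.9, -1, 0),
          ag("A2", 2.70, 3.0, 1, 0))),

  # Redesigned: U around the nurse at the foot end, nurse facing the surgeon
  # and the operating area; near-symmetric about the table axis.
  mk("TKA3", "TKA",
     list(tbl("T1", 3.95, 2.35, 0, 0.6, 0.4),
          tbl("T2", 4.65, 1.70, 45),
          tbl("T3", 2.45, 1.75, 90),
          tbl("T4", 4.00, 1.05, 90)),
     list(ag("SU", 3.75, 3.0, -0.6, -0.8),
          ag("SN", 3.30, 1.8, 0.45, 1.2),
          ag("A1", 3.70, 3.6, -1, 0),
          ag("A2", 2.70, 3.0, 1, 0))),

  # Redesigned: the TKA1 table arrangement with the nurse moved to the
  # opposite side of the OR table, facing the surgeon.
  mk("TKA4", "TKA",
     list(tbl("T1", 2.80, 1.90, 0, 0.6, 0.4),
          tbl("T2", 1.70, 2.95, 45),
          tbl("T3", 1.85, 1.65, 90),
          tbl("T4", 1.15, 2.35, 180)),
     list(ag("SU", 3.75, 3.0, -0.6, -0.8),
          ag("SN", 2.55, 2.55, 1.2, 0.45),
          ag("A1", 3.75, 2.3, -1, 0),
          ag("A2", 2.70, 3.9, 1, 0))),

  # Initial THA setup: J-shape, one table in front of the nurse, one to her
  # left, two behind; surgeon at the hip.
  mk("THA1", "THA",
     list(tbl("T1", 4.20, 2.95, 0, 0.6, 0.4),
          tbl("T2", 3.10, 1.85, 90),
          tbl("T3", 3.90, 1.20, 180),
          tbl("T4", 4.70, 1.70, 180)),
     list(ag("SU", 3.90, 3.5, -0.8, -0.6),
          ag("SN", 4.20, 2.35, 0, 1),
          ag("A1", 3.70, 4.1, -1, 0),
          ag("A2", 2.70, 3.5, 1, 0))),

  # Initial three-table THA setup: U around the nurse behind the surgeon,
  # who must turn around for every handover.
  mk("THA2", "THA",
     list(tbl("T1", 4.40, 3.50, 0, 0.6, 0.4),
          tbl("T2", 4.90, 4.30, 90),
          tbl("T3", 4.90, 2.70, 90)),
     list(ag("SU", 3.90, 3.5, -0.8, -0.6),
          ag("SN", 5.05, 3.5, -1, 0),
          ag("A1", 3.70, 4.1, -1, 0),
          ag("A2", 2.70, 3.5, 1, 0))),

  # Redesigned three-table THA setup: U around the nurse at the foot end,
  # nurse facing the surgeon; table 2 directly at the bottom of the OR table.
  mk("THA3", "THA",
     list(tbl("T1", 3.95, 2.85, 0, 0.6, 0.4),
          tbl("T2", 3.10, 2.00, 90),
          tbl("T3", 4.95, 2.00, 90)),
     list(ag("SU", 3.90, 3.5, -0.8, -0.6),
          ag("SN", 4.00, 2.2, -0.1, 1.3),
          ag("A1", 3.70, 4.1, -1, 0),
          ag("A2", 2.70, 3.5, 1, 0)))
)

for (ly in layouts) {
  write_layout(ly, file.path(out_dir, sprintf("%s_left.yaml", tolower(ly$id))))
  write_layout(mirror_layout(ly),
               file.path(out_dir, sprintf("%s_right.yaml", tolower(ly$id))))
}
message("wrote ", 2L * length(layouts), " fixtures to ", out_dir)
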
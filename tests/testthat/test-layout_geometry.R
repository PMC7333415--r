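test_that("layout schema round-trips and validates invariants", {
  doc <- toy_layout_doc()
  ly <- load_layout(doc)
  expect_s3_class(ly, "or_layout")
  expect_length(instrument_tables(ly), 3L)

  # round-trip through the YAML writer
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_layout(ly, tmp)
  ly2 <- load_layout(tmp)
  expect_equal(vapply(ly2$furniture, `[[`, numeric(2), "center"),
               vapply(ly$furniture, `[[`, numeric(2), "center"))
  expect_equal(ly2$plan$destinations, ly$plan$destinations)

  # invariant violations are named
  doc2 <- doc
  doc2$agents <- c(doc2$agents,
                   list(list(role = "SN", x = 4, y = 2.5, facing = c(0, 1))))
  expect_error(load_layout(doc2), "exactly one SN")

  doc3 <- doc
  doc3$furniture[[2]]$table_angle <- NULL
  expect_error(load_layout(doc3), "table_angle")

  doc4 <- doc
  doc4$destinations$R1 <- c(9, 9)
  expect_error(load_layout(doc4), "outside the floor plan")

  doc5 <- doc
  doc5$furniture[[3]]$x <- 3.0  # collide with T1
  expect_error(load_layout(doc5), "overlap")
})

test_that("all bundled fixtures validate; TKA1 has tables at 0/45/90/180", {
  for (id in layout_fixture_ids()) {
    for (side in c("left", "right")) {
      expect_s3_class(layout_fixture(id, side), "or_layout")
    }
  }
  tka1 <- layout_fixture("TKA1", "left")
  angles <- sort(vapply(instrument_tables(tka1), `[[`, 0, "table_angle"))
  expect_equal(angles, c(0, 45, 90, 180))
  expect_length(instrument_tables(layout_fixture("THA3", "left")), 3L)
})

test_that("mirroring is an involution and matches the bundled right sides", {
  for (pair in fixture_pairs()) {
    m <- mirror_layout(pair$left)
    expect_equal(m$side, "right")
    # bundled right fixture is the exact mirror of the left
    expect_equal(vapply(m$furniture, `[[`, numeric(2), "center"),
                 vapply(pair$right$furniture, `[[`, numeric(2), "center"),
                 tolerance = 1e-9)
    expect_equal(vapply(m$agents, `[[`, numeric(2), "position"),
                 vapply(pair$right$agents, `[[`, numeric(2), "position"),
                 tolerance = 1e-9)
    # involution
    mm <- mirror_layout(m)
    expect_equal(vapply(mm$furniture, `[[`, numeric(2), "center"),
                 vapply(pair$left$furniture, `[[`, numeric(2), "center"),
                 tolerance = 1e-9)
    expect_equal(vapply(mm$agents, `[[`, numeric(2), "facing"),
                 vapply(pair$left$agents, `[[`, numeric(2), "facing"),
                 tolerance = 1e-9)
    # destinations are room-fixed
    expect_identical(m$plan$destinations, pair$left$plan$destinations)
  }
})

test_that("mirroring reflects points across the OR-table long axis", {
  ly <- layout_fixture("THA3", "left")
  axis_x <- 3.25  # OR table centre
  m <- mirror_layout(ly)
  for (i in seq_along(ly$agents)) {
    p <- ly$agents[[i]]$position
    q <- m$agents[[i]]$position
    expect_equal(q[1], 2 * axis_x - p[1], tolerance = 1e-12)
    expect_equal(q[2], p[2], tolerance = 1e-12)
  }
})

test_that("relative_angle matches hand geometry and is rotation invariant", {
  obs <- agent_pose("SU", c(0, 0), c(1, 0))
  expect_equal(relative_angle(obs, c(2, 0)), 0)
  expect_equal(relative_angle(obs, c(-3, 0)), 180)
  expect_equal(relative_angle(obs, c(1, 1)), 45)
  expect_error(relative_angle(obs, c(0, 0)), "coincides")

  # invariance under rigid rotation of observer + target about the origin
  set.seed(42)
  for (rep in 1:25) {
    pos <- runif(2, -2, 2); fac <- runif(2, -1, 1)
    if (all(fac == 0)) fac <- c(1, 0)
    tgt <- pos + runif(2, 0.1, 2)
    base <- relative_angle(agent_pose("SU", pos, fac), tgt)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rot <- relative_angle(agent_pose("SU", as.vector(R %*% pos),
                                     as.vector(R %*% fac)),
                          as.vector(R %*% tgt))
    expect_equal(rot, base, tolerance = 1e-9)
  }
})

test_that("constructors reject degenerate inputs", {
  expect_error(floor_plan(-1, 5), "positive")
  expect_error(floor_plan(5, 5, destinations = list(A = c(1, 1), A = c(2, 2))),
               "unique")
  expect_error(furniture("T1", "instrument_table", c(1, 1), c(0.5, 0)),
               "positive area")
  expect_error(furniture("T1", "instrument_table", c(1, 1), c(0.5, 0.5),
                         table_angle = 400), "table_angle")
  expect_error(agent_pose("SN", c(1, 1), c(0, 0)), "non-zero")
})
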
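empty_grid <- function(n = 50, cell = 0.1) {
  nav_grid(matrix(FALSE, n, n), cell)
}

test_that("rasterize blocks inflated footprints and nothing else", {
  # empty room: no blocked interior cells
  g0 <- rasterize(structure(list(plan = floor_plan(5, 5), furniture = list()),
                            class = "or_layout"),
                  cell_size = 0.1, agent_radius = 0.3)
  expect_false(any(g0$occupancy))

  # 1 m x 1 m table, radius 0.3, cell 0.1: blocked region at least 1.6 m wide
  ly1 <- structure(list(
    plan = floor_plan(5, 5),
    furniture = list(furniture("T", "instrument_table", c(2.5, 2.5), c(1, 1),
                               table_angle = 0))), class = "or_layout")
  g1 <- rasterize(ly1, cell_size = 0.1, agent_radius = 0.3)
  blocked_x <- range(which(apply(g1$occupancy, 1, any)))
  span <- (blocked_x[2] - blocked_x[1] + 1) * 0.1
  expect_gte(span, 1.6)

  # the second working place is walled in by an instrument table in the
  # redesigned compact TKA setup (left side)
  tka2 <- layout_fixture("TKA2", "left")
  g2 <- rasterize(tka2)
  wp2 <- tka2$plan$destinations$WP2
  cc <- c(floor((wp2[1]) / 0.1) + 1, floor((wp2[2]) / 0.1) + 1)
  nbs <- expand.grid(dx = -1:1, dy = -1:1)
  blocked <- mapply(function(dx, dy) g2$occupancy[cc[1] + dx, cc[2] + dy],
                    nbs$dx, nbs$dy)
  expect_gte(sum(blocked), 5)
})

test_that("a too-coarse grid for a barely passable gap warns", {
  # two tables leaving a 0.65 m gap: passable for radius 0.3 but may close
  ly <- structure(list(
    plan = floor_plan(5, 5),
    furniture = list(
      furniture("A", "equipment", c(1.0, 2.5), c(1, 1)),
      furniture("B", "equipment", c(2.8, 2.5), c(1.3, 1)))),
    class = "or_layout")
  expect_warning(rasterize(ly, cell_size = 0.2, agent_radius = 0.3),
                 "spuriously blocked")
})

test_that("shortest paths are straight in the open and fail loudly when sealed", {
  g <- empty_grid()
  p <- shortest_path(g, c(1, 1), c(4, 1))
  expect_equal(p$length, 3.0, tolerance = 0.1)  # cell quantization
  expect_equal(p$length,
               sum(sqrt(rowSums(diff(p$waypoints)^2))), tolerance = 1e-12)

  # enclosed goal
  occ <- matrix(FALSE, 30, 30)
  occ[14:18, 14] <- TRUE; occ[14:18, 18] <- TRUE
  occ[14, 14:18] <- TRUE; occ[18, 14:18] <- TRUE
  g2 <- nav_grid(occ, 0.1)
  expect_error(shortest_path(g2, c(0.5, 0.5), c(1.55, 1.55), goal_name = "box"),
               "'box' is unreachable")
  expect_error(shortest_path(g2, c(1.35, 1.35), c(0.5, 0.5)), "blocked cell")
})

test_that("path length is symmetric, bounded below by Euclid, monotone in obstacles", {
  set.seed(7)
  for (rep in 1:20) {
    occ <- matrix(runif(400) < 0.2, 20, 20)
    free <- which(!occ, arr.ind = TRUE)
    pick <- free[sample(nrow(free), 2), , drop = FALSE]
    s <- (pick[1, ] - 0.5) * 0.1
    t <- (pick[2, ] - 0.5) * 0.1
    g <- nav_grid(occ, 0.1)
    len_st <- tryCatch(shortest_path(g, s, t)$length, error = function(e) Inf)
    len_ts <- tryCatch(shortest_path(g, t, s)$length, error = function(e) Inf)
    expect_equal(len_st, len_ts, tolerance = 1e-9)
    if (is.finite(len_st)) {
      expect_gte(len_st + 1e-12, sqrt(sum((s - t)^2)) - 0.1 * sqrt(2))
      # removing an obstacle never lengthens the path
      blocked <- which(occ)
      if (length(blocked)) {
        occ2 <- occ
        occ2[sample(blocked, 1)] <- FALSE
        len2 <- shortest_path(nav_grid(occ2, 0.1), s, t)$length
        expect_lte(len2, len_st + 1e-9)
      }
    }
  }
})

test_that("planner costs equal the brute-force uniform-cost oracle", {
  set.seed(11)
  for (rep in 1:20) {
    occ <- matrix(runif(400) < 0.25, 20, 20)
    free <- which(!occ, arr.ind = TRUE)
    pick <- free[sample(nrow(free), 2), , drop = FALSE]
    oracle <- ucs_oracle(occ, 0.1, pick[1, ], pick[2, ])
    g <- nav_grid(occ, 0.1)
    mine <- tryCatch(
      shortest_path(g, (pick[1, ] - 0.5) * 0.1, (pick[2, ] - 0.5) * 0.1)$length,
      error = function(e) Inf)
    if (is.finite(oracle)) {
      expect_equal(mine, oracle, tolerance = 1e-9)
    } else {
      expect_identical(mine, Inf)
    }
  }
})
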
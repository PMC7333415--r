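# Independent oracles and small layout builders used across the test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force uniform-cost search (plain O(V^2) Dijkstra, no heuristic, no
# heap) over an 8-connected occupancy grid. Returns the optimal cost from
# start_cell to goal_cell in metres, or Inf when unreachable. Written
# independently of the package's planner.
ucs_oracle <- function(occ, cell_size, start_cell, goal_cell) {
  nx <- nrow(occ); ny <- ncol(occ)
  idx <- function(c) (c[2] - 1L) * nx + c[1]
  n <- nx * ny
  dist <- rep(Inf, n)
  done <- as.vector(occ)  # blocked cells are never expanded
  if (occ[start_cell[1], start_cell[2]] || occ[goal_cell[1], goal_cell[2]]) {
    return(Inf)
  }
  dist[idx(start_cell)] <- 0
  moves <- cbind(dx = c(1, -1, 0, 0, 1, 1, -1, -1),
                 dy = c(0, 0, 1, -1, 1, -1, 1, -1))
  w <- c(rep(cell_size, 4), rep(sqrt(2) * cell_size, 4))
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || done[u]) break
    done[u] <- TRUE
    ux <- (u - 1L) %% nx + 1L
    uy <- (u - 1L) %/% nx + 1L
    for (k in 1:8) {
      vx <- ux + moves[k, 1]; vy <- uy + moves[k, 2]
      if (vx < 1 || vx > nx || vy < 1 || vy > ny) next
      if (occ[vx, vy]) next
      v <- (vy - 1L) * nx + vx
      if (dist[u] + w[k] < dist[v]) dist[v] <- dist[u] + w[k]
    }
    if (all(done | !is.finite(dist))) break
  }
  dist[idx(goal_cell)]
}

# Textbook two-sample t-test formulas, coded independently of stats::t.test.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

student_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# exhaustive enumeration of the rotational-movement formula over all
# movement-count combinations dominated by (i, j, k)
trm_enumeration_oracle <- function(alpha, beta, gamma, i, j, k) {
  best <- -Inf
  for (ii in 0:i) for (jj in 0:j) for (kk in 0:k) {
    best <- max(best, ii * alpha + jj * beta + kk * gamma)
  }
  best
}

# Minimal valid layout: 6 x 6 room, OR table, three instrument tables at the
# given angles, nurse/surgeon poses chosen by the caller.
toy_layout <- function(angles = c(0, 90, 90),
                       sn_pos = c(3, 2.5), sn_facing = c(0, 1),
                       su_pos = c(3, 3.0), su_facing = c(0, -1),
                       destinations = list()) {
  plan <- floor_plan(6, 6, obstacles = list(), destinations = destinations)
  tabs <- list(
    furniture("T1", "instrument_table", c(3.0, 1.6), c(0.6, 0.4),
              table_angle = angles[1]),
    furniture("T2", "instrument_table", c(1.6, 1.6), c(0.6, 0.4),
              table_angle = angles[2]),
    furniture("T3", "instrument_table", c(4.4, 1.6), c(0.6, 0.4),
              table_angle = angles[3])
  )
  layout_setup("TOY1", "TKA", "left", plan,
               c(list(furniture("OR", "or_table", c(3, 4.2), c(0.6, 1.6))), tabs),
               list(agent_pose("SN", sn_pos, sn_facing),
                    agent_pose("SU", su_pos, su_facing)))
}

# schema document (as a list) for load_layout tests
toy_layout_doc <- function() {
  list(
    id = "DOC1", procedure = "THA", side = "left",
    room = list(width = 6, height = 6),
    obstacles = list(list(id = "shelf", x = 0.3, y = 3, width = 0.6, height = 2)),
    destinations = list(WP1 = c(1.5, 0.5), R1 = c(5.5, 5.5)),
    furniture = list(
      list(id = "OR", kind = "or_table", x = 3, y = 4.2, width = 0.6, height = 1.6),
      list(id = "T1", kind = "instrument_table", x = 3, y = 1.6, width = 0.6,
           height = 0.4, table_angle = 0),
      list(id = "T2", kind = "instrument_table", x = 1.6, y = 1.6, width = 0.6,
           height = 0.4, table_angle = 45),
      list(id = "T3", kind = "instrument_table", x = 4.4, y = 1.6, width = 0.6,
           height = 0.4, table_angle = 90)
    ),
    agents = list(
      list(role = "SN", x = 3, y = 2.5, facing = c(0, 1)),
      list(role = "SU", x = 3, y = 3.2, facing = c(0, -1))
    )
  )
}

fixture_pairs <- function() {
  lapply(layout_fixture_ids(), function(id) {
    list(id = id, left = layout_fixture(id, "left"),
         right = layout_fixture(id, "right"))
  })
}
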
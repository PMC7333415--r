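test_that("handover time decomposes into rotations, pass, grasp and transfer", {
  # alpha = beta = gamma = 90 deg at 180 deg/s, 0.5 m pass at 1 m/s,
  # 0.3 s grasp + 0.2 s transfer: 1.5 + 0.5 + 0.5 = 2.5 s
  ly <- toy_layout(angles = c(90, 45, 90),
                   sn_pos = c(3, 2.5), sn_facing = c(1, 0),
                   su_pos = c(3, 3.0), su_facing = c(1, 0))
  # facing checks: beta = angle((1,0) -> (0,+1)) = 90; gamma likewise
  p <- motion_params(rotation_speed = 180, arm_speed = 1, grasp_time = 0.3,
                     transfer_time = 0.2, arm_reach = 0.8)
  expect_equal(iht(ly, "T1", p), 2.5)
  expect_equal(iht(ly, "T2", p), 2.25)  # 45 deg less of alpha
  expect_error(iht(ly, "T9", p), "no furniture")
  expect_error(iht(ly, "OR", p), "not an instrument table")

  # nurse-surgeon distance is clipped to arm reach
  ly_far <- toy_layout(angles = c(90, 45, 90),
                       sn_pos = c(1.0, 2.5), sn_facing = c(0, 1),
                       su_pos = c(5.0, 2.5), su_facing = c(0, 1))
  base <- iht(ly_far, "T1", p)
  ly_near <- toy_layout(angles = c(90, 45, 90),
                        sn_pos = c(4.3, 2.5), sn_facing = c(0, 1),
                        su_pos = c(5.0, 2.5), su_facing = c(0, 1))
  near <- iht(ly_near, "T1", p)
  expect_equal(base - near, (0.8 - 0.7) / p$arm_speed)

  # strictly increasing in grasp time
  p2 <- motion_params(grasp_time = 0.9)
  expect_gt(iht(ly, "T1", p2), iht(ly, "T1", motion_params(grasp_time = 0.3)))
})

test_that("per-fixture handover times rise with the table angle and mirror", {
  for (pair in fixture_pairs()) {
    tabs <- instrument_tables(pair$left)
    angles <- vapply(tabs, `[[`, 0, "table_angle")
    ihts <- vapply(tabs, function(tb) iht(pair$left, tb$id), numeric(1))
    expect_equal(order(ihts), order(angles))  # non-decreasing in angle
    ihts_r <- vapply(instrument_tables(pair$right),
                     function(tb) iht(pair$right, tb$id), numeric(1))
    expect_equal(ihts_r, ihts, tolerance = 1e-9)
  }
})

test_that("total handover time is the count-weighted sum with a monotone clock", {
  ly <- layout_fixture("TKA1", "left")
  expect_equal(total_handover_time(ly, c(T1 = 0, T2 = 0))$total_handover_time, 0)

  one <- iht(ly, "T1")
  expect_equal(total_handover_time(ly, c(T1 = 2))$total_handover_time, 2 * one)

  # recorded mean counts: total equals the hand-computed dot product
  counts <- c(T1 = 108.3, T2 = 5.7, T3 = 5.0, T4 = 2.7)
  ihts <- vapply(names(counts), function(id) iht(ly, id), numeric(1))
  sim <- total_handover_time(ly, counts)
  expect_equal(sim$total_handover_time, sum(counts * ihts), tolerance = 1e-12)

  # linearity in counts
  sim2 <- total_handover_time(ly, 2 * counts)
  expect_equal(sim2$total_handover_time, 2 * sim$total_handover_time,
               tolerance = 1e-12)

  # event log: one event per rounded count, cumulative start times
  expect_equal(nrow(sim$event_log), sum(round(counts)))
  expect_true(all(diff(sim$event_log$time) >= 0))
  expect_equal(sim$event_log$time[-1],
               cumsum(sim$event_log$duration)[-nrow(sim$event_log)])

  expect_error(total_handover_time(ly, c(T9 = 1)), "unknown table")
  expect_error(total_handover_time(ly, c(T1 = -1)), "non-negative")
})

test_that("calibration recovers parameters that generated the data", {
  ly <- layout_fixture("THA3", "left")
  truth <- motion_params(rotation_speed = 150, arm_speed = 1, grasp_time = 0.45,
                         transfer_time = 0.2)
  ids <- vapply(instrument_tables(ly), `[[`, "", "id")
  measured <- vapply(ids, function(id) iht(ly, id, truth), numeric(1))

  fit <- calibrate_motion(motion_params(), ly, measured)
  refit <- vapply(ids, function(id) iht(ly, id, fit), numeric(1))
  expect_lt(max(abs(refit - measured)), 1e-6)

  expect_error(calibrate_motion(motion_params(), ly, measured[1]),
               "at least two")

  # all tables at the same angle: nothing to identify
  ly_flat <- toy_layout(angles = c(90, 90, 90))
  flat <- c(T1 = 1, T2 = 1.1, T3 = 0.9)
  expect_error(calibrate_motion(motion_params(), ly_flat, flat), "degenerate")
})

test_that("calibrating to the recorded THA handover times improves the fit", {
  ly <- layout_fixture("THA3", "left")
  measured <- c(T1 = 0.72, T2 = 1.44, T3 = 1.86)
  init <- motion_params()
  ids <- names(measured)
  rss <- function(p) {
    sum((vapply(ids, function(id) iht(ly, id, p), numeric(1)) - measured)^2)
  }
  fit <- calibrate_motion(init, ly, measured)
  expect_lte(rss(fit), rss(init))
})

test_that("sim-vs-measured deviations reproduce the published comparison", {
  ref <- iht_reference()
  tka <- ref[ref$procedure == "TKA", ]
  deltas <- compare_sim_measured(stats::setNames(tka$sim, tka$table),
                                 stats::setNames(tka$measured, tka$table))
  expect_equal(unname(deltas), c(0.05, 0.10, 0.20))
  tha <- ref[ref$procedure == "THA", ]
  deltas2 <- compare_sim_measured(stats::setNames(tha$sim, tha$table),
                                  stats::setNames(tha$measured, tha$table))
  expect_equal(unname(deltas2), c(0.07, 0.02, 0.66))
  expect_equal(unname(compare_sim_measured(c(A = 1.2), c(A = 1.2))), 0)
  expect_error(compare_sim_measured(c(A = 1), c(B = 1)), "same table ids")
})
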
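test_that("bundled presets carry the recorded means and SDs", {
  tka <- surgery_log_preset("TKA", "TKA1")
  expect_equal(tka$handover_count_params$mean, c(108.3, 5.7, 5.0, 2.7))
  expect_equal(tka$handover_count_params$sd, c(32.2, 7.3, 4.2, 2.3))
  expect_equal(tka$trip_params$mean[tka$trip_params$destination == "R1"], 4.0)
  expect_equal(tka$ibct_params, c(71.1, 20.7))

  tha3 <- surgery_log_preset("THA", "THA3")
  expect_equal(tha3$ibct_params, c(49.7, 12.2))
  expect_equal(nrow(tha3$handover_count_params), 3L)  # three-table setup
  expect_identical(attr(tha3$trip_params, "suspect"), "ST1")

  expect_error(surgery_log_preset("TKA", "THA1"), "does not belong")
  expect_error(surgery_log_preset("TKA", "TKA9"), "no preset")
})

test_that("cohort generation is seed-deterministic and leaves the RNG alone", {
  cfg <- surgery_log_preset("TKA", "TKA1", n_surgeries = 25, seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(surgery_log_preset("TKA", "TKA1", n_surgeries = 25,
                                           seed = 8L))
  expect_false(identical(a$ibct, c2$ibct))

  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_cohort(cfg)); after <- rnorm(1)
  expect_identical(before, after)

  # counts are integers >= 0, IBCT floored at 10 minutes
  expect_true(all(a$handovers_T1 == round(a$handovers_T1)))
  expect_true(all(a$handovers_T4 >= 0))
  expect_true(all(a$ibct >= 10))
})

test_that("zero-spread presets are reproduced exactly", {
  cfg <- generator_config(
    "TKA", "TKA1", n_surgeries = 10,
    handover_count_params = data.frame(table = "T1", mean = 108.3, sd = 0),
    trip_params = data.frame(destination = "R1", mean = 4, sd = 0),
    ibct_params = c(71.1, 0), seed = 1L)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$handovers_T1 == 108))
  expect_true(all(coh$trips_R1 == 4))
  expect_true(all(coh$ibct == 71.1))
  rec <- recover_params(coh)
  expect_equal(rec$handover_count_params$sd, 0)
  expect_equal(unname(rec$ibct_params), c(71.1, 0))
})

test_that("a large cohort recovers the generator's parameters", {
  for (case in list(c("TKA", "TKA1"), c("THA", "THA3"))) {
    cfg <- surgery_log_preset(case[1], case[2], n_surgeries = 5000, seed = 42L)
    rec <- recover_params(generate_cohort(cfg))

    hp <- cfg$handover_count_params
    expect_equal(rec$handover_count_params$table, hp$table)
    se <- hp$sd / sqrt(cfg$n_surgeries)
    expect_true(all(abs(rec$handover_count_params$mean - hp$mean) <=
                      3 * se + 1e-9))

    tp <- cfg$trip_params
    keep <- tp$destination != (attr(tp, "suspect") %||% "")
    se_t <- tp$sd[keep] / sqrt(cfg$n_surgeries)
    expect_true(all(abs(rec$trip_params$mean[keep] - tp$mean[keep]) <=
                      3 * se_t + 0.05))  # rounding/truncation slack

    expect_lt(abs(rec$ibct_params[["mean"]] - cfg$ibct_params[1]),
              3 * cfg$ibct_params[2] / sqrt(cfg$n_surgeries))
  }
})

test_that("recovered mean counts drive the handover totals linearly", {
  cfg <- surgery_log_preset("TKA", "TKA1", n_surgeries = 200, seed = 5L)
  rec <- recover_params(generate_cohort(cfg))
  counts <- stats::setNames(rec$handover_count_params$mean,
                            rec$handover_count_params$table)
  ly <- layout_fixture("TKA1", "left")
  total <- total_handover_time(ly, counts)$total_handover_time
  ihts <- vapply(names(counts), function(id) iht(ly, id), numeric(1))
  expect_equal(total, sum(counts * ihts), tolerance = 1e-12)

  expect_error(recover_params(generate_cohort(cfg)[1, ]), "at least two")
})

test_that("surgery logs round-trip through the CSV format", {
  cfg <- surgery_log_preset("THA", "THA2", n_surgeries = 6, seed = 2L)
  coh <- generate_cohort(cfg)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_surgery_log(coh, tmp, side = "left")
  back <- read_surgery_log(tmp)
  expect_equal(back$ibct, coh$ibct)
  expect_equal(back$handovers_T1, coh$handovers_T1)
  expect_equal(back$trips_SN, coh$trips_SN)
  header <- readLines(tmp, n = 1)
  expect_match(header,
               "surgery_id.*setup_id.*side.*table_or_dest.*kind.*count_or_value")
})
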
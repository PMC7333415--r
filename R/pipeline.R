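# End-to-end setup comparison: geometry -> ergonomics -> simulation -> stats.

#' Run the full setup-comparison pipeline
#'
#' For a set of same-procedure OR setups this reproduces the complete analysis
#' shape of a simulation-based setup study: the scenario inventory (setups x
#' sides), per-table instrument handover times, per-surgery total handover
#' times, TRM ergonomics totals, circulator travel distances, IBCT summaries,
#' pairwise two-tailed t-tests between setups, requirement lint findings, and
#' (when reference measurements are supplied) simulated-versus-measured
#' deviations.
#'
#' @param setups either a character vector of bundled setup ids (both sides
#'   are loaded via [layout_fixture()]) or a list of `or_layout` objects.
#'   All must belong to one procedure; mixing THA and TKA is an error.
#' @param cohorts optional named list (setup id -> `surgery_cohort`). Missing
#'   cohorts are generated from [surgery_log_preset()] with the given `seed`.
#' @param params a [motion_params()].
#' @param seed seed for generated cohorts.
#' @param measured optional named list (setup id -> named vector of measured
#'   per-table IHTs in seconds) for sim-vs-measured deltas.
#' @param cell_size,agent_radius,st1_corridor navigation parameters, see
#'   [total_travel_distance()].
#' @param lint logical; include requirement findings (default `TRUE`).
#' @return an object of class `comparison_report`; see Details.
#' @details The report is a list with elements `procedure`, `scenarios` (the
#'   inventory with per-scenario TRM, total handover time and travel
#'   distance), `per_table_iht`, `ibct_summary`, `handover_time_summary`
#'   (per-surgery totals from cohort counts), `t_tests` (pairwise Welch tests
#'   on IBCT and per-surgery total handover time; empty with a single setup),
#'   `deltas`, `lint` and `ranking` (setups ordered by TRM ergonomics total,
#'   with simulated total handover time as tie-break; TRM depends only on the
#'   layout geometry, so the ranking is not confounded by each setup's
#'   historical handover-count profile).
#' @export
run_pipeline <- function(setups, cohorts = NULL, params = motion_params(),
                         seed = 1L, measured = NULL, cell_size = 0.10,
                         agent_radius = 0.30, st1_corridor = 4, lint = TRUE) {
  layouts <- if (is.character(setups)) {
    unlist(lapply(setups, function(id) {
      list(layout_fixture(id, "left"), layout_fixture(id, "right"))
    }), recursive = FALSE)
  } else {
    setups
  }
  if (!length(layouts)) stop("no layouts supplied", call. = FALSE)
  procedures <- unique(vapply(layouts, `[[`, "", "procedure"))
  if (length(procedures) != 1L) {
    stop("cannot compare mixed procedures in one report: ",
         paste(procedures, collapse = ", "), call. = FALSE)
  }
  setup_ids <- unique(vapply(layouts, `[[`, "", "id"))

  # cohorts: supplied or generated from the recorded presets
  cohorts <- cohorts %||% list()
  for (id in setup_ids) {
    if (is.null(cohorts[[id]])) {
      cohorts[[id]] <- generate_cohort(
        surgery_log_preset(procedures, id, seed = seed))
    }
  }

  scen_rows <- list(); iht_rows <- list(); lint_rows <- list()
  per_surgery_totals <- list()
  for (ly in layouts) {
    coh <- cohorts[[ly$id]]
    hcols <- grep("^handovers_", names(coh), value = TRUE)
    mean_counts <- vapply(coh[hcols], mean, numeric(1))
    names(mean_counts) <- sub("^handovers_", "", hcols)
    tab_ids <- vapply(instrument_tables(ly), `[[`, "", "id")
    mean_counts <- mean_counts[names(mean_counts) %in% tab_ids]

    sim <- total_handover_time(ly, mean_counts, params)
    trm <- trm_setup(derive_rotation_specs(ly))

    tcols <- grep("^trips_", names(coh), value = TRUE)
    mean_trips <- vapply(coh[tcols], mean, numeric(1))
    names(mean_trips) <- sub("^trips_", "", tcols)
    travel <- total_travel_distance(ly, trip_profile(mean_trips),
                                    cell_size = cell_size,
                                    agent_radius = agent_radius,
                                    st1_corridor = st1_corridor)

    scen_rows[[length(scen_rows) + 1L]] <- data.frame(
      setup_id = ly$id, side = ly$side,
      n_tables = length(tab_ids),
      trm_total = trm$total,
      total_handover_time = sim$total_handover_time,
      travel_total = travel$total_distance
    )
    iht_rows[[length(iht_rows) + 1L]] <- data.frame(
      setup_id = ly$id, side = ly$side,
      table = names(sim$per_table_iht), iht = unname(sim$per_table_iht),
      row.names = NULL
    )
    if (lint) {
      lf <- lint_layout(ly, cell_size = cell_size, agent_radius = agent_radius)
      lf$setup_id <- ly$id; lf$side <- ly$side
      lint_rows[[length(lint_rows) + 1L]] <- lf
    }
    if (ly$side == "left") {
      # per-surgery totals for the between-setup test, computed once per setup
      counts_mat <- as.matrix(coh[paste0("handovers_", names(sim$per_table_iht))])
      per_surgery_totals[[ly$id]] <- as.numeric(counts_mat %*% sim$per_table_iht)
    }
  }

  scenarios <- do.call(rbind, scen_rows)
  per_table_iht <- do.call(rbind, iht_rows)

  ibct_summary <- do.call(rbind, lapply(setup_ids, function(id) {
    s <- summarize_sample(cohorts[[id]]$ibct)
    data.frame(setup_id = id, n = s$n, mean = s$mean, sd = s$sd)
  }))
  handover_time_summary <- do.call(rbind, lapply(setup_ids, function(id) {
    s <- summarize_sample(per_surgery_totals[[id]])
    data.frame(setup_id = id, n = s$n, mean = s$mean, sd = s$sd)
  }))

  t_rows <- list()
  if (length(setup_ids) >= 2L) {
    pairs <- utils::combn(setup_ids, 2L, simplify = FALSE)
    for (pr in pairs) {
      for (metric in c("ibct", "total_handover_time")) {
        a <- if (metric == "ibct") cohorts[[pr[1]]]$ibct else per_surgery_totals[[pr[1]]]
        b <- if (metric == "ibct") cohorts[[pr[2]]]$ibct else per_surgery_totals[[pr[2]]]
        tt <- t_test_two_tailed(a, b)
        t_rows[[length(t_rows) + 1L]] <- data.frame(
          metric = metric, setup_a = pr[1], setup_b = pr[2],
          t_statistic = tt$t_statistic, df = tt$degrees_of_freedom,
          p_two_tailed = tt$p_two_tailed
        )
      }
    }
  }

  deltas <- NULL
  if (!is.null(measured)) {
    deltas <- lapply(names(measured), function(id) {
      left <- Filter(function(l) l$id == id && l$side == "left", layouts)[[1]]
      sim_iht <- vapply(names(measured[[id]]),
                        function(tb) iht(left, tb, params), numeric(1))
      compare_sim_measured(sim_iht, measured[[id]])
    })
    names(deltas) <- names(measured)
  }

  # Ranking uses the TRM total: it depends only on the layouts, whereas
  # per-surgery handover totals also inherit each setup's recorded count
  # profile, which would mix layout quality with historical case mix.
  left_scen <- scenarios[scenarios$side == "left", ]
  ranking <- rank_setups(stats::setNames(
    left_scen$trm_total + 1e-6 * left_scen$total_handover_time,
    left_scen$setup_id))

  structure(list(
    procedure = procedures,
    scenarios = scenarios,
    per_table_iht = per_table_iht,
    ibct_summary = ibct_summary,
    handover_time_summary = handover_time_summary,
    t_tests = if (length(t_rows)) do.call(rbind, t_rows) else NULL,
    deltas = deltas,
    lint = if (length(lint_rows)) do.call(rbind, lint_rows) else NULL,
    ranking = ranking
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s: %d scenarios (%d setups x 2 sides)\n",
              x$procedure, nrow(x$scenarios),
              length(unique(x$scenarios$setup_id))))
  cat("  ranking (best first):", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Write a comparison report to JSON
#'
#' @param report a `comparison_report` from [run_pipeline()].
#' @param path output JSON path.
#' @param tables optional path for a human-readable text dump.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, tables = NULL) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!is.null(tables)) {
    con <- file(tables, "w"); on.exit(close(con))
    writeLines(sprintf("Comparison report (%s)", report$procedure), con)
    writeLines("\n== Scenarios ==", con)
    utils::capture.output(print(report$scenarios), file = con, append = TRUE)
    writeLines("\n== IBCT ==", con)
    utils::capture.output(print(report$ibct_summary), file = con, append = TRUE)
    if (!is.null(report$t_tests)) {
      writeLines("\n== Pairwise t-tests ==", con)
      utils::capture.output(print(report$t_tests), file = con, append = TRUE)
    }
    writeLines(paste("\nRanking:", paste(report$ranking, collapse = " > ")), con)
  }
  invisible(path)
}
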
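# Instrument handover time (IHT) model and per-surgery totals.
#
# One handover from a given instrument table decomposes into: the nurse turns
# to the table (alpha), turns back towards the surgeon (beta), the surgeon
# turns to the nurse (gamma), the instrument is passed over the gap between
# the two (arm motion), plus fixed grasp and transfer components:
#
#   iht = alpha/omega + beta/omega + gamma/omega + d_pass/v + t_grasp + t_transfer
#
# where omega is torso rotation speed (deg/s), v arm speed (m/s) and d_pass
# the nurse-surgeon distance clipped to arm reach. The decomposition is this
# package's own reconstruction of a human-motion simulation; its constants are
# calibratable against measured per-table handover times.

#' Motion parameters of the handover model
#'
#' @param rotation_speed torso rotation speed, degrees/second (default 180:
#'   a half turn per second, a comfortable standing rotation pace).
#' @param arm_speed instrument-passing arm speed, metres/second (default 1.0).
#' @param grasp_time seconds to pick the instrument off the table
#'   (default 0.3).
#' @param transfer_time seconds for the hand-to-hand transfer itself
#'   (default 0.2).
#' @param arm_reach maximum passing distance in metres; the nurse-surgeon
#'   distance is clipped to this before dividing by `arm_speed` (default 0.8).
#' @return an object of class `motion_params`.
#' @export
motion_params <- function(rotation_speed = 180, arm_speed = 1.0,
                          grasp_time = 0.3, transfer_time = 0.2,
                          arm_reach = 0.8) {
  vals <- c(rotation_speed = rotation_speed, arm_speed = arm_speed,
            grasp_time = grasp_time, transfer_time = transfer_time,
            arm_reach = arm_reach)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all motion parameters must be strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "motion_params")
}

#' Simulated instrument handover time for one table
#'
#' @param layout an `or_layout` with scrub nurse and surgeon present.
#' @param table_id id of an instrument table in the layout.
#' @param params a [motion_params()].
#' @param turn rotation-direction convention, see [derive_rotation_specs()].
#' @return handover duration in seconds (strictly positive).
#' @export
iht <- function(layout, table_id, params = motion_params(),
                turn = "shorter") {
  tab <- get_furniture(layout, table_id)
  if (tab$kind != "instrument_table") {
    stop(sprintf("'%s' is not an instrument table", table_id), call. = FALSE)
  }
  specs <- derive_rotation_specs(layout, turn = turn)
  spec <- specs[[match(table_id, vapply(specs, `[[`, "", "table_id"))]]
  sn <- get_agent(layout, "SN"); su <- get_agent(layout, "SU")
  d_pass <- min(sqrt(sum((sn$position - su$position)^2)), params$arm_reach)
  (spec$alpha + spec$beta + spec$gamma) / params$rotation_speed +
    d_pass / params$arm_speed + params$grasp_time + params$transfer_time
}

#' Total instrument handover time of a surgery
#'
#' Schedules the given number of handovers per table sequentially on a
#' monotone clock (handovers never overlap in recorded surgeries) and sums
#' their durations. Counts may be fractional: recorded logs report per-surgery
#' means, in which case the total is an expected value and the event log
#' rounds counts to whole events.
#'
#' @param layout an `or_layout`.
#' @param counts named numeric vector or list, handovers per instrument table.
#' @param params a [motion_params()].
#' @param turn rotation-direction convention, see [derive_rotation_specs()].
#' @return list of class `handover_sim` with `per_table_iht` (seconds),
#'   `total_handover_time` (seconds, `sum(counts * per_table_iht)`) and
#'   `event_log` (data.frame with `time`, `table_id`, `duration`; `time` is
#'   the cumulative start of each handover).
#' @export
total_handover_time <- function(layout, counts, params = motion_params(),
                                turn = "shorter") {
  counts <- unlist(counts)
  if (any(counts < 0)) stop("handover counts must be non-negative", call. = FALSE)
  table_ids <- vapply(instrument_tables(layout), `[[`, "", "id")
  unknown <- setdiff(names(counts), table_ids)
  if (length(unknown)) {
    stop(sprintf("counts given for unknown table(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  per_iht <- vapply(names(counts), function(id) iht(layout, id, params, turn),
                    numeric(1))
  total <- sum(counts * per_iht)

  n_events <- round(counts)
  tab <- rep(names(counts), n_events)
  dur <- rep(per_iht, n_events)
  event_log <- data.frame(
    time = if (length(dur)) cumsum(c(0, dur[-length(dur)])) else numeric(0),
    table_id = tab, duration = dur, row.names = NULL
  )
  structure(list(per_table_iht = per_iht, total_handover_time = total,
                 event_log = event_log),
            class = "handover_sim")
}

#' @export
print.handover_sim <- function(x, ...) {
  cat(sprintf("<handover_sim> total %.1f s over %d events\n",
              x$total_handover_time, nrow(x$event_log)))
  invisible(x)
}

#' Calibrate motion parameters against measured handover times
#'
#' Fits the handover decomposition to measured per-table IHTs by least
#' squares. Within one layout the model is linear: every table shares the same
#' nurse-surgeon rotation angles (beta, gamma) and passing distance, so
#' `iht_t = S_t / omega + c` with `S_t = alpha_t + beta + gamma` and a common
#' offset `c`. The fit first solves this line in closed form (recovering
#' `rotation_speed` from the slope and reallocating the intercept to
#' `grasp_time`, holding `arm_speed` and `transfer_time` at their initial
#' values), then falls back to bounded numerical least squares whenever the
#' closed-form solution leaves the feasible (all-positive) region. The
#' returned parameters never fit worse than `params_init`.
#'
#' @param params_init starting [motion_params()].
#' @param layout an `or_layout`.
#' @param measured_iht named numeric vector of measured per-table handover
#'   times in seconds; at least two tables with distinct rotation geometry.
#' @return a [motion_params()] with residual sum of squares no larger than at
#'   `params_init`.
#' @export
calibrate_motion <- function(params_init, layout, measured_iht) {
  measured_iht <- unlist(measured_iht)
  if (length(measured_iht) < 2L) {
    stop("calibration needs measurements for at least two tables", call. = FALSE)
  }
  specs <- derive_rotation_specs(layout)
  ids <- vapply(specs, `[[`, "", "table_id")
  if (!all(names(measured_iht) %in% ids)) {
    stop("measured_iht names must match the layout's instrument tables",
         call. = FALSE)
  }
  S <- vapply(names(measured_iht), function(id) {
    sp <- specs[[match(id, ids)]]
    sp$alpha + sp$beta + sp$gamma
  }, numeric(1))
  if (diff(range(S)) < 1e-9) {
    stop("degenerate calibration: all tables have identical rotation geometry",
         call. = FALSE)
  }
  sn <- get_agent(layout, "SN"); su <- get_agent(layout, "SU")
  d_pass <- min(sqrt(sum((sn$position - su$position)^2)), params_init$arm_reach)

  rss <- function(p) {
    pred <- S / p$rotation_speed + d_pass / p$arm_speed +
      p$grasp_time + p$transfer_time
    sum((pred - measured_iht)^2)
  }

  best <- params_init
  fit <- stats::lm.fit(cbind(1, S), measured_iht)
  slope <- fit$coefficients[2]; intercept <- fit$coefficients[1]
  if (is.finite(slope) && slope > 0) {
    grasp <- intercept - d_pass / params_init$arm_speed - params_init$transfer_time
    if (grasp > 0) {
      cand <- motion_params(rotation_speed = 1 / slope,
                            arm_speed = params_init$arm_speed,
                            grasp_time = grasp,
                            transfer_time = params_init$transfer_time,
                            arm_reach = params_init$arm_reach)
      if (rss(cand) <= rss(best)) best <- cand
    }
  }
  if (rss(best) > 1e-12) {
    # closed form infeasible or imperfect: bounded numerical polish
    obj <- function(theta) {
      rss(motion_params(rotation_speed = theta[1], arm_speed = params_init$arm_speed,
                        grasp_time = theta[2], transfer_time = params_init$transfer_time,
                        arm_reach = params_init$arm_reach))
    }
    start <- c(best$rotation_speed, best$grasp_time)
    opt <- stats::optim(start, obj, method = "L-BFGS-B",
                        lower = c(1e-3, 1e-6), upper = c(1e4, 60))
    cand <- motion_params(rotation_speed = opt$par[1],
                          arm_speed = params_init$arm_speed,
                          grasp_time = opt$par[2],
                          transfer_time = params_init$transfer_time,
                          arm_reach = params_init$arm_reach)
    if (rss(cand) <= rss(best)) best <- cand
  }
  best
}

#' Per-table deviation between simulated and measured handover times
#'
#' @param sim,measured named numeric vectors (seconds) over the same table
#'   ids.
#' @return named numeric vector of absolute deviations `|sim - measured|`,
#'   rounded to 2 decimals.
#' @export
compare_sim_measured <- function(sim, measured) {
  sim <- unlist(sim); measured <- unlist(measured)
  if (!setequal(names(sim), names(measured)) ||
      length(sim) != length(measured)) {
    stop("'sim' and 'measured' must cover the same table ids", call. = FALSE)
  }
  measured <- measured[names(sim)]
  round(abs(sim - measured), 2)
}
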
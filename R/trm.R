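# Total Rotational Movement (TRM): a simplified ergonomics score for OR
# setups. For each instrument table, one handover cycle involves three torso
# rotations: the scrub nurse turns to the table to grab an instrument
# (angle alpha), turns to the surgeon to hand it over (beta), and the surgeon
# turns to the nurse to receive it (gamma). Each rotation is performed
# i, j or k times (0, 1 or 2; two in the usual case: towards the target and
# back). The table score is i*alpha + j*beta + k*gamma and the setup score is
# the sum over its instrument tables; lower is ergonomically better.

#' Rotation specification for one instrument table
#'
#' @param table_id table label.
#' @param alpha scrub-nurse rotation to grab from the table, degrees in
#'   `[0, 360)`.
#' @param beta scrub-nurse rotation to hand the instrument to the surgeon,
#'   degrees.
#' @param gamma surgeon rotation to grab the instrument from the nurse,
#'   degrees.
#' @param i,j,k movement counts for the three rotations; integers in
#'   `{0, 1, 2}` (default 2: turn towards the target and back).
#' @return an object of class `rotation_spec`.
#' @export
rotation_spec <- function(table_id, alpha, beta, gamma, i = 2L, j = 2L, k = 2L) {
  for (cnt in list(i = i, j = j, k = k)) {
    if (!is.numeric(cnt) || length(cnt) != 1L || cnt != round(cnt) ||
        cnt < 0 || cnt > 2) {
      stop("movement counts i, j, k must be integers in {0, 1, 2}", call. = FALSE)
    }
  }
  for (ang in list(alpha = alpha, beta = beta, gamma = gamma)) {
    if (!is.numeric(ang) || length(ang) != 1L || ang < 0 || ang >= 360) {
      stop("angles alpha, beta, gamma must lie in [0, 360)", call. = FALSE)
    }
  }
  structure(list(table_id = as.character(table_id),
                 alpha = alpha, beta = beta, gamma = gamma,
                 i = as.integer(i), j = as.integer(j), k = as.integer(k)),
            class = "rotation_spec")
}

#' Rotational movement of one instrument table
#'
#' @param spec a [rotation_spec()].
#' @return `i*alpha + j*beta + k*gamma`, in degrees.
#' @export
trm_table <- function(spec) {
  stopifnot(inherits(spec, "rotation_spec"))
  spec$i * spec$alpha + spec$j * spec$beta + spec$k * spec$gamma
}

#' Total Rotational Movement of an OR setup
#'
#' @param specs list of [rotation_spec()] with unique `table_id`s.
#' @return list with `per_table` (named numeric, degrees) and `total` (their
#'   sum), of class `trm_result`.
#' @export
trm_setup <- function(specs) {
  ids <- vapply(specs, function(s) s$table_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate table_id in rotation specs", call. = FALSE)
  per_table <- vapply(specs, trm_table, numeric(1))
  names(per_table) <- ids
  structure(list(per_table = per_table, total = sum(per_table)),
            class = "trm_result")
}

#' @export
print.trm_result <- function(x, ...) {
  cat(sprintf("<trm_result> total %.0f deg\n", x$total))
  if (length(x$per_table)) {
    cat(paste(sprintf("  %s: %.0f deg", names(x$per_table), x$per_table),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Derive rotation specs from a layout's geometry
#'
#' Applies the model's simplifying assumption that the scrub nurse rotates her
#' torso according to each instrument table's angular position: `alpha` is the
#' table's `table_angle` (folded to the unsigned magnitude in `[0, 180]`),
#' `beta` is the nurse's viewing angle to the surgeon and `gamma` the
#' surgeon's viewing angle to the nurse (both via [relative_angle()], hence
#' unsigned and mirror-invariant).
#'
#' Off-axis tables (anything but 0 or 180 degrees) can be reached by turning
#' either way around; `turn` selects the convention. With `"shorter"` the
#' unsigned magnitude is used. `"right"`/`"left"` model a nurse who always
#' turns over the named shoulder: a table at a clockwise angular position `a`
#' costs `a` degrees over the right shoulder but `360 - a` over the left.
#'
#' @param layout an `or_layout`.
#' @param movement_counts `c(i, j, k)`, passed to [rotation_spec()];
#'   default `c(2, 2, 2)`.
#' @param turn `"shorter"` (default), `"right"` or `"left"`.
#' @return list of [rotation_spec()], one per instrument table.
#' @export
derive_rotation_specs <- function(layout, movement_counts = c(2L, 2L, 2L),
                                  turn = c("shorter", "right", "left")) {
  turn <- match.arg(turn)
  stopifnot(length(movement_counts) == 3L)
  sn <- get_agent(layout, "SN")
  su <- get_agent(layout, "SU")
  beta <- relative_angle(sn, su$position)
  gamma <- relative_angle(su, sn$position)
  lapply(instrument_tables(layout), function(tab) {
    a <- tab$table_angle %% 360
    alpha <- switch(turn,
      shorter = min(a, 360 - a),
      right   = a,
      left    = (360 - a) %% 360
    )
    rotation_spec(tab$id, alpha = alpha, beta = beta, gamma = gamma,
                  i = movement_counts[1], j = movement_counts[2],
                  k = movement_counts[3])
  })
}
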
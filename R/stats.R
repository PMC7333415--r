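# Summary statistics and two-sample comparisons used to evaluate setups.

#' Mean and sample standard deviation of a metric
#'
#' Follows the mean +/- SD reporting convention of surgical-workflow studies
#' (sample SD, n-1 denominator).
#'
#' @param sample numeric vector, length >= 2.
#' @return list of class `sample_summary` with `n`, `mean`, `sd`.
#' @export
summarize_sample <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 2L) {
    stop("need at least two observations for a mean +/- SD summary", call. = FALSE)
  }
  structure(list(n = length(sample), mean = mean(sample), sd = stats::sd(sample)),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> n = %d, %.2f +/- %.2f\n", x$n, x$mean, x$sd))
  invisible(x)
}

#' Two-tailed two-sample t-test
#'
#' Compares a metric between two setups. The default is Welch's test (unequal
#' variances; the evaluated cohorts have unequal sizes), with Student's pooled
#' test selectable. Degenerate inputs follow a documented convention instead
#' of failing: when both samples have zero variance, `p = 1` if the means are
#' equal (`t = 0`) and `p = 0` if they are not (`t = +/-Inf`).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant `"welch"` (default) or `"student"`.
#' @return list of class `t_test_result` with `t_statistic`,
#'   `degrees_of_freedom`, `p_two_tailed`.
#' @export
t_test_two_tailed <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need at least two observations", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(structure(list(
      t_statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
      degrees_of_freedom = length(a) + length(b) - 2,
      p_two_tailed = if (equal) 1 else 0
    ), class = "t_test_result"))
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"),
                      alternative = "two.sided")
  structure(list(t_statistic = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_two_tailed = ht$p.value),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test> t = %.3f, df = %.2f, p = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_two_tailed))
  invisible(x)
}

#' Rank setups by a scalar metric
#'
#' Stable sort: ties keep their input order.
#'
#' @param metric named numeric vector (setup id -> value).
#' @param lower_is_better logical; default `TRUE` (times, distances and TRM
#'   are all the-lower-the-better).
#' @return character vector of setup ids, best first.
#' @export
rank_setups <- function(metric, lower_is_better = TRUE) {
  metric <- unlist(metric)
  if (!length(metric)) stop("'metric' must be non-empty", call. = FALSE)
  ord <- order(if (lower_is_better) metric else -metric)
  names(metric)[ord]
}
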
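# Condition-level summaries and significance calls: mean +/- SEM per
# condition and two-sided Student's t-tests against a no-activity control.

#' Summarize replicate activity scores for one condition
#'
#' @param scores numeric activity values (one per replicate).
#' @param condition_value the condition (temperature in degrees C or pH).
#' @return a one-row data frame: `condition`, `mean`, `sem` (sd/sqrt(n);
#'   0 with a `single_replicate` attribute when n = 1), `n`.
#' @export
summarize_activity <- function(scores, condition_value) {
  scores <- as.numeric(scores)
  if (!length(scores)) stop("empty score list", call. = FALSE)
  n <- length(scores)
  sem <- if (n > 1) stats::sd(scores) / sqrt(n) else 0
  out <- data.frame(condition = condition_value, mean = mean(scores),
                    sem = sem, n = n)
  if (n == 1L) {
    attr(out, "single_replicate") <- TRUE
    warning("single replicate: SEM reported as 0", call. = FALSE)
  }
  out
}

#' Two-sided Student's t-test against the control
#'
#' Equal-variance (pooled) two-sample t-test, the classical Student form.
#' Degenerate groups with zero pooled variance return p = 1 when the means
#' are equal and p = 0 otherwise.
#'
#' @param group activity values for the condition (n >= 2).
#' @param control activity values for the control condition (n >= 2).
#' @param welch use the Welch unequal-variance form instead (default FALSE).
#' @return list with elements `t` and `p`.
#' @export
t_test_vs_control <- function(group, control, welch = FALSE) {
  if (length(group) < 2L || length(control) < 2L) {
    stop("insufficient data: both groups need n >= 2", call. = FALSE)
  }
  if (stats::sd(group) == 0 && stats::sd(control) == 0) {
    same <- isTRUE(all.equal(mean(group), mean(control)))
    return(list(t = if (same) 0 else Inf * sign(mean(group) - mean(control)),
                p = if (same) 1 else 0))
  }
  ht <- stats::t.test(group, control, var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

significance_symbol <- function(p) {
  if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Condition profile with significance vs control
#'
#' One summary row per condition, each compared against the control
#' condition with a two-sided pooled t-test; the control's own p is set
#' to 1. Significance symbols follow the fixed thresholds: `*` for
#' p < 0.05, `**` for p < 0.01. No multiple-testing correction is applied
#' (per-condition comparisons against a single control).
#'
#' @param values condition label per score (same length as `scores`).
#' @param scores numeric activity values.
#' @param control_value the control condition label (e.g. 10 for 10 degrees
#'   C, 2 for pH 2); must be present in `values`.
#' @param welch passed to [t_test_vs_control()].
#' @return data frame `condition, mean, sem, n, t, p, significance`, ordered
#'   by condition.
#' @export
condition_profile <- function(values, scores, control_value, welch = FALSE) {
  stopifnot(length(values) == length(scores))
  if (!control_value %in% values) {
    stop("control condition ", control_value, " not present", call. = FALSE)
  }
  ctrl <- scores[values == control_value]
  conds <- sort(unique(values))
  rows <- lapply(conds, function(cv) {
    sc <- scores[values == cv]
    s <- suppressWarnings(summarize_activity(sc, cv))
    if (identical(cv, control_value)) {
      s$t <- 0; s$p <- 1
    } else {
      tt <- t_test_vs_control(sc, ctrl, welch)
      s$t <- tt$t; s$p <- tt$p
    }
    s$significance <- significance_symbol(s$p)
    s
  })
  do.call(rbind, rows)
}

#' Condition profile straight from a synthetic condition series
#'
#' Runs [analyze_recording()] on every waveform of a
#' [generate_condition_series()] result and builds the condition profile
#' against the stated control.
#'
#' @param series a `condition_series`.
#' @param control_value control condition (defaults to the first grid value,
#'   the no-activity anchor).
#' @param ... passed to [analyze_recording()].
#' @return list with `profile` (see [condition_profile()]) and `scores`
#'   (long table `condition, replicate, activity`).
#' @export
profile_condition_series <- function(series, control_value = NULL, ...) {
  stopifnot(inherits(series, "condition_series"))
  control_value <- control_value %||% attr(series, "grid")[1]
  scores <- do.call(rbind, lapply(series, function(w) {
    an <- analyze_recording(w, ...)
    data.frame(condition = w$metadata$condition_value,
               replicate = w$metadata$replicate,
               activity = as.numeric(an$activity))
  }))
  list(profile = condition_profile(scores$condition, scores$activity,
                                   control_value),
       scores = scores)
}
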
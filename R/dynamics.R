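# Emotion-dynamics statistics.
#
# All four metrics operate on a composite panel (compute_composites output)
# and a polarity ("positive"/"negative"). Group subsetting is the caller's
# job (dynamics_table does it for all groups); the metric functions
# themselves are group-agnostic.
#
# Conventions, fixed package-wide:
#  * between-person variance is the population variance (divisor n) of
#    subject mean ratings;
#  * within-person variance pools squared deviations of a subject's
#    unit-level means (unit = two-hour slot for "daily", weekday for
#    "weekly") around the subject's grand mean (the mean of the unit-level
#    means), divided by the total number of observed (subject, unit) cells
#    -- this reduces to the textbook n*m denominator in the balanced case
#    and is the only well-defined reading when unit counts differ by
#    subject;
#  * instability is the mean absolute difference between successive
#    answered prompts within the same day (square-rooted successive squared
#    differences), pooled over all pairs of all subjects by default.

#' Per-subject mean composite rating
#'
#' Arithmetic mean of each subject's answered-prompt composite ratings
#' (the subject-level "emotional intensity").
#'
#' @param panel an `esm_panel` from [compute_composites()]
#' @param polarity `"positive"` or `"negative"`
#' @return named numeric vector, one mean per subject present in the panel
#' @export
subject_means <- function(panel, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  v <- tapply(panel[[polarity]], panel$subject_id, mean)
  setNames(as.numeric(v), names(v))
}

#' Between-person variance of subject means
#'
#' Population variance (divisor n, not n-1) of the subject-level mean
#' ratings: sum_i (Xbar_i - Xbar)^2 / n, where Xbar is the group average of
#' the subject means.
#'
#' @param means named numeric vector of subject means (one group), e.g. from
#'   [subject_means()] on a group-subset panel
#' @return numeric point estimate (squared-rating units)
#' @export
between_person_variance <- function(means) {
  means <- means[!is.na(means)]
  n <- length(means)
  if (n < 2) stop("insufficient subjects (n < 2)", call. = FALSE)
  mean((means - mean(means))^2)
}

# Per-subject within-person components: sum of squared deviations of
# unit-level means around the subject grand mean, and the unit cell count.
# Subjects with < 2 observed units are dropped (with a warning upstream).
.within_components <- function(panel, polarity, unit) {
  ucol <- switch(unit, slot = "slot_index", weekday = "weekday",
                 stop("unit must be 'slot' or 'weekday'", call. = FALSE))
  um <- aggregate(panel[[polarity]],
                  by = list(subject_id = panel$subject_id,
                            unit = panel[[ucol]]),
                  FUN = mean)
  spl <- split(um$x, um$subject_id)
  data.frame(subject_id = names(spl),
             ss = vapply(spl, function(x) sum((x - mean(x))^2), 0),
             cells = vapply(spl, length, 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Within-person (daily or weekly) variance
#'
#' For each subject, unit-level means are computed (mean of the subject's
#' answered composites in each two-hour slot for `unit = "slot"`, or on
#' each weekday for `unit = "weekday"`), squared deviations from the
#' subject's grand mean (the mean of those unit-level means) are formed,
#' and the deviations are pooled over subjects and divided by the total
#' number of observed (subject, unit) cells. Subjects with fewer than two
#' observed units carry no information about within-person spread and are
#' dropped with a warning.
#'
#' @inheritParams subject_means
#' @param unit `"slot"` (daily variability across the eight time slots) or
#'   `"weekday"` (weekly variability across Monday..Sunday)
#' @return numeric point estimate (squared-rating units), with attributes
#'   `n_subjects` and `n_cells`
#' @export
within_person_variance <- function(panel,
                                   polarity = c("positive", "negative"),
                                   unit = c("slot", "weekday")) {
  polarity <- match.arg(polarity)
  unit <- match.arg(unit)
  comp <- .within_components(panel, polarity, unit)
  drop <- comp$cells < 2
  if (any(drop))
    warning(sum(drop), " subject(s) with < 2 observed units dropped from ",
            "within-person (", unit, ") variance", call. = FALSE)
  comp <- comp[!drop, , drop = FALSE]
  if (nrow(comp) == 0) stop("no subject has >= 2 observed units",
                            call. = FALSE)
  structure(sum(comp$ss) / sum(comp$cells),
            n_subjects = nrow(comp), n_cells = sum(comp$cells))
}

# Per-subject instability components: sum of |successive difference| over
# same-day successive answered prompts (ordered by slot), and pair count.
.instability_components <- function(panel, polarity) {
  p <- panel[order(panel$subject_id, panel$day_index, panel$slot_index), ]
  spl <- split(p[, c("day_index", polarity)], p$subject_id)
  res <- lapply(spl, function(d) {
    dif <- abs(diff(d[[polarity]]))
    same_day <- diff(d$day_index) == 0
    c(s = sum(dif[same_day]), k = sum(same_day))
  })
  m <- do.call(rbind, res)
  data.frame(subject_id = rownames(m), s = m[, "s"], k = as.integer(m[, "k"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Emotion instability (mean absolute successive difference)
#'
#' Successive squared differences between assessments are formed only
#' within the same day (prompts ordered by slot; the overnight pair between
#' the last prompt of one day and the first of the next is excluded) and
#' square-root transformed per pair, i.e. each pair contributes the
#' absolute change |x_(t+1) - x_t|. By default all pairs of all subjects
#' are pooled into one mean; `per_subject_first = TRUE` instead averages
#' each subject's mean absolute change.
#'
#' @inheritParams subject_means
#' @param per_subject_first average subject-level means instead of pooling
#'   pairs (default `FALSE`)
#' @return numeric point estimate (rating units), with attributes
#'   `n_subjects` and `n_pairs`
#' @export
instability <- function(panel, polarity = c("positive", "negative"),
                        per_subject_first = FALSE) {
  polarity <- match.arg(polarity)
  comp <- .instability_components(panel, polarity)
  comp <- comp[comp$k > 0, , drop = FALSE]
  if (nrow(comp) == 0 || sum(comp$k) == 0)
    stop("no successive assessments (no same-day pairs)", call. = FALSE)
  point <- if (per_subject_first) mean(comp$s / comp$k)
  else sum(comp$s) / sum(comp$k)
  structure(point, n_subjects = nrow(comp), n_pairs = sum(comp$k))
}

# ---- bootstrap ------------------------------------------------------------

DYNAMICS_METRICS <- c("between_person", "within_daily", "within_weekly",
                      "instability")

# Per-subject sufficient statistics for one metric. Resampling subjects and
# recomputing the metric on the materialized resample is equivalent to
# aggregating these components, which is what the bootstrap loop does.
.metric_components <- function(panel, metric, polarity, per_subject_first) {
  switch(metric,
    between_person = {
      m <- subject_means(panel, polarity)
      data.frame(subject_id = names(m), value = as.numeric(m),
                 stringsAsFactors = FALSE)
    },
    within_daily = .within_components(panel, polarity, "slot"),
    within_weekly = .within_components(panel, polarity, "weekday"),
    instability = .instability_components(panel, polarity),
    stop("unknown metric: ", metric, call. = FALSE))
}

.metric_from_components <- function(comp, metric, per_subject_first) {
  switch(metric,
    between_person = {
      if (nrow(comp) < 2) stop("insufficient subjects (n < 2)",
                               call. = FALSE)
      mean((comp$value - mean(comp$value))^2)
    },
    within_daily = ,
    within_weekly = {
      ok <- comp$cells >= 2
      if (!any(ok)) stop("no subject has >= 2 observed units",
                         call. = FALSE)
      sum(comp$ss[ok]) / sum(comp$cells[ok])
    },
    instability = {
      ok <- comp$k > 0
      if (!any(ok)) stop("no successive assessments (no same-day pairs)",
                         call. = FALSE)
      if (per_subject_first) mean(comp$s[ok] / comp$k[ok])
      else sum(comp$s[ok]) / sum(comp$k[ok])
    })
}

#' Subject-resampling bootstrap confidence interval for a dynamics metric
#'
#' Resamples subjects (the exchangeable unit in this design) with
#' replacement `B` times within the supplied panel, recomputes the metric
#' on each resample, and returns the percentile interval. Deterministic
#' given `seed`. Degenerate resamples (all subjects identical) simply yield
#' the degenerate value.
#'
#' @inheritParams subject_means
#' @param metric one of `"between_person"`, `"within_daily"`,
#'   `"within_weekly"`, `"instability"`
#' @param B number of bootstrap resamples (>= 100; default 2000)
#' @param level confidence level (default 0.95)
#' @param seed integer RNG seed (required, for reproducibility)
#' @param per_subject_first passed to [instability()]
#' @return object of class `esm_estimate`: list with `metric`, `polarity`,
#'   `point`, `ci_low`, `ci_high`, `n_subjects`, `B`, `level`, `seed`
#' @export
bootstrap_ci <- function(panel, metric = DYNAMICS_METRICS,
                         polarity = c("positive", "negative"),
                         B = 2000, level = 0.95, seed,
                         per_subject_first = FALSE) {
  metric <- match.arg(metric)
  polarity <- match.arg(polarity)
  stopifnot(B >= 100, level > 0, level < 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  comp <- .metric_components(panel, metric, polarity, per_subject_first)
  # resample only subjects that can contribute to this metric
  comp <- switch(metric,
                 between_person = comp,
                 within_daily = ,
                 within_weekly = comp[comp$cells >= 2, , drop = FALSE],
                 instability = comp[comp$k > 0, , drop = FALSE])
  n <- nrow(comp)
  if (n < 2) stop("insufficient subjects (n < 2)", call. = FALSE)
  point <- .metric_from_components(comp, metric, per_subject_first)
  stat <- numeric(B)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old), add = TRUE)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    stat[b] <- .metric_from_components(comp[idx, , drop = FALSE],
                                       metric, per_subject_first)
  }
  alpha <- (1 - level) / 2
  ci <- unname(quantile(stat, c(alpha, 1 - alpha), type = 7))
  structure(list(metric = metric, polarity = polarity,
                 point = as.numeric(point),
                 ci_low = ci[1], ci_high = ci[2],
                 n_subjects = n, B = B, level = level, seed = seed),
            class = "esm_estimate")
}

#' @export
print.esm_estimate <- function(x, ...) {
  cat(sprintf("<esm_estimate> %s (%s): %.2f [%g%% CI %.2f; %.2f], n=%d, B=%d\n",
              x$metric, x$polarity, x$point, 100 * x$level, x$ci_low,
              x$ci_high, x$n_subjects, x$B))
  invisible(x)
}

# set.seed without clobbering the caller's RNG stream
.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Full dynamics table (metric x group x polarity, with bootstrap CIs)
#'
#' Computes all four dynamics metrics for every group and polarity present
#' in the panel, each with a subject-resampling percentile bootstrap CI.
#' Per-cell seeds are derived deterministically from `seed`.
#'
#' @inheritParams bootstrap_ci
#' @return data.frame with columns `metric`, `group`, `polarity`, `point`,
#'   `ci_low`, `ci_high`, `n_subjects`
#' @export
dynamics_table <- function(panel, B = 2000, level = 0.95, seed,
                           per_subject_first = FALSE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  groups <- intersect(ESM_GROUPS, unique(panel$group))
  rows <- list()
  i <- 0L
  for (metric in DYNAMICS_METRICS)
    for (g in groups)
      for (pol in c("positive", "negative")) {
        i <- i + 1L
        sub <- panel[panel$group == g, , drop = FALSE]
        est <- bootstrap_ci(sub, metric, pol, B = B, level = level,
                            seed = (seed + 7L * i) %% .Machine$integer.max,
                            per_subject_first = per_subject_first)
        rows[[i]] <- data.frame(metric = metric, group = g, polarity = pol,
                                point = est$point, ci_low = est$ci_low,
                                ci_high = est$ci_high,
                                n_subjects = est$n_subjects,
                                stringsAsFactors = FALSE)
      }
  do.call(rbind, rows)
}

#' Per-subject dynamics measures
#'
#' Subject-level versions of the within-person variability and instability
#' statistics (the outcomes correlated with clinical scores and modelled by
#' backward elimination): for each subject, intraday and intraweek variance
#' of unit-level means around the subject grand mean, mean absolute
#' successive same-day difference, and the subject mean (intensity), for
#' both polarities. `NA` where a subject lacks the required structure
#' (< 2 units, or no same-day pair).
#'
#' @param panel an `esm_panel`
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   `mean_positive`, `mean_negative`, `intraday_var_positive`,
#'   `intraday_var_negative`, `intraweek_var_positive`,
#'   `intraweek_var_negative`, `instability_positive`,
#'   `instability_negative`
#' @export
subject_dynamics <- function(panel) {
  ids <- sort(unique(panel$subject_id))
  grp <- panel$group[match(ids, panel$subject_id)]
  out <- data.frame(subject_id = ids, group = grp,
                    stringsAsFactors = FALSE)
  for (pol in c("positive", "negative")) {
    m <- subject_means(panel, pol)
    out[[paste0("mean_", pol)]] <- as.numeric(m[ids])
    for (unit in c("slot", "weekday")) {
      comp <- .within_components(panel, pol, unit)
      v <- ifelse(comp$cells >= 2, comp$ss / comp$cells, NA_real_)
      key <- if (unit == "slot") "intraday_var_" else "intraweek_var_"
      out[[paste0(key, pol)]] <- v[match(ids, comp$subject_id)]
    }
    comp <- .instability_components(panel, pol)
    v <- ifelse(comp$k > 0, comp$s / comp$k, NA_real_)
    out[[paste0("instability_", pol)]] <- v[match(ids, comp$subject_id)]
  }
  out
}
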
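test_that("between-person variance is the population variance of means", {
  expect_equal(between_person_variance(c(a = 0, b = 10)), 25)
  expect_equal(between_person_variance(c(a = 5, b = 5, c = 5)), 0)
  # frozen from the brute-force oracle: sum((x - mean(x))^2) / n
  expect_equal(between_person_variance(c(1, 2, 3, 4)), 1.25)
  expect_equal(oracle_between(c(1, 2, 3, 4)), 1.25)
  expect_error(between_person_variance(c(a = 1)), "insufficient subjects")
})

test_that("subject means are arithmetic means over answered prompts", {
  panel <- panel_from_values(list(A = list(`1` = c(10, 20, 30)),
                                  B = list(`2` = 42),
                                  C = list(`1` = c(0, 100))))
  m <- subject_means(panel, "positive")
  expect_equal(unname(m[c("A", "B", "C")]), c(20, 42, 50))
})

test_that("within-person variance pools squared deviations over cells", {
  # one subject, slot means {10, 20} -> 25
  p1 <- panel_from_values(list(A = list(`1` = c(10, 20))))
  expect_equal(as.numeric(within_person_variance(p1, "positive", "slot")),
               25)
  # A slot means {10, 20}, B slot means {0, 0} -> (25+25+0+0)/4 = 12.5
  p2 <- panel_from_values(list(A = list(`1` = c(10, 20)),
                               B = list(`1` = c(0, 0))))
  expect_equal(as.numeric(within_person_variance(p2, "positive", "slot")),
               12.5)
  expect_equal(oracle_within(p2, "positive", "slot"), 12.5)
  # all ratings constant -> 0
  p3 <- panel_from_values(list(A = list(`1` = c(7, 7, 7),
                                        `2` = c(7, 7, 7))))
  expect_equal(as.numeric(within_person_variance(p3, "positive", "slot")), 0)
  expect_equal(as.numeric(within_person_variance(p3, "positive",
                                                 "weekday")), 0)
  # subject with a single observed unit is dropped with a warning
  p4 <- rbind(p2, panel_from_values(list(C = list(`1` = 50))))
  class(p4) <- c("esm_panel", "data.frame")
  expect_warning(v <- within_person_variance(p4, "positive", "slot"),
                 "dropped")
  expect_equal(as.numeric(v), 12.5)
  expect_equal(attr(v, "n_subjects"), 2)
})

test_that("weekly unit is the weekday, not the day index", {
  # same composite per day; weekday differs from day_index (starts Thursday)
  rows <- subject_prompts("A", days = 1:2, start_weekday = 4)
  ds <- esm_dataset(blank_subject("A"), rows)
  panel <- compute_composites(ds)
  expect_setequal(unique(panel$weekday), c(4, 5))
  comp <- within_person_variance(panel, "positive", "weekday")
  expect_equal(as.numeric(comp), oracle_within(panel, "positive", "weekday"))
})

test_that("instability is the mean absolute same-day successive difference", {
  # one day [10, 20, 15] -> |10|, |-5| -> 7.5
  p1 <- panel_from_values(list(A = list(`1` = c(10, 20, 15))))
  i1 <- instability(p1, "positive")
  expect_equal(as.numeric(i1), 7.5)
  expect_equal(attr(i1, "n_pairs"), 2L)
  # day1 [0, 10], day2 [50, 50]: overnight 10 -> 50 excluded -> mean 5
  p2 <- panel_from_values(list(A = list(`1` = c(0, 10), `2` = c(50, 50))))
  expect_equal(as.numeric(instability(p2, "positive")), 5)
  expect_equal(oracle_instability(p2, "positive"), 5)
  # constant series -> 0
  p3 <- panel_from_values(list(A = list(`1` = c(9, 9, 9, 9))))
  expect_equal(as.numeric(instability(p3, "positive")), 0)
  # no same-day pairs -> error
  p4 <- panel_from_values(list(A = list(`1` = 1, `2` = 2, `3` = 3)))
  expect_error(instability(p4, "positive"), "no successive assessments")
})

test_that("instability orders prompts by slot within day", {
  p <- panel_from_values(list(A = list(`1` = c(0, 100, 0))))
  shuffled <- p[c(2, 3, 1), ]
  class(shuffled) <- c("esm_panel", "data.frame")
  expect_equal(as.numeric(instability(shuffled, "positive")), 100)
})

test_that("per-subject-first instability averages subject means of pairs", {
  # A pairs {10, 10} mean 10; B pairs {0} mean 0
  p <- panel_from_values(list(A = list(`1` = c(0, 10, 20)),
                              B = list(`1` = c(5, 5))))
  expect_equal(as.numeric(instability(p, "positive")), 20 / 3)
  expect_equal(as.numeric(instability(p, "positive",
                                      per_subject_first = TRUE)), 5)
})

test_that("all four metrics equal brute-force oracles on random micro-data", {
  for (seed in 1:60) {
    panel <- random_micro_panel(seed)
    for (pol in c("positive", "negative")) {
      om <- oracle_subject_means(panel, pol)
      expect_equal(subject_means(panel, pol)[names(om)], om)
      if (length(om) >= 2)
        expect_equal(between_person_variance(subject_means(panel, pol)),
                     oracle_between(om))
      ow <- oracle_within(panel, pol, "slot")
      if (!is.na(ow))
        expect_equal(as.numeric(
          suppressWarnings(within_person_variance(panel, pol, "slot"))), ow)
      oi <- oracle_instability(panel, pol)
      if (!is.na(oi))
        expect_equal(as.numeric(instability(panel, pol)), oi)
    }
  }
})

test_that("bootstrap CIs are deterministic and degenerate correctly", {
  ds <- generate_dataset(small_config(n = 15), seed = 5)
  panel <- compute_composites(ds)
  a <- bootstrap_ci(panel, "between_person", "positive", B = 200, seed = 42)
  b <- bootstrap_ci(panel, "between_person", "positive", B = 200, seed = 42)
  expect_identical(a[c("point", "ci_low", "ci_high")],
                   b[c("point", "ci_low", "ci_high")])
  c2 <- bootstrap_ci(panel, "between_person", "positive", B = 200, seed = 43)
  expect_false(identical(a$ci_low, c2$ci_low))

  # all subjects identical -> CI width 0
  ident <- panel_from_values(list(A = list(`1` = c(10, 20)),
                                  B = list(`1` = c(10, 20)),
                                  C = list(`1` = c(10, 20))))
  for (metric in c("between_person", "within_daily", "instability")) {
    est <- bootstrap_ci(ident, metric, "positive", B = 200, seed = 1)
    expect_equal(est$ci_low, est$ci_high)
    expect_equal(est$ci_low, est$point)
  }
})

test_that("sufficient-statistic bootstrap equals materialized resampling", {
  ds <- generate_dataset(small_config(n = 8), seed = 9)
  panel <- compute_composites(ds)
  B <- 150
  for (metric in c("between_person", "within_daily", "within_weekly",
                   "instability")) {
    fn <- switch(metric,
      between_person = function(p)
        between_person_variance(subject_means(p, "positive")),
      within_daily = function(p)
        as.numeric(within_person_variance(p, "positive", "slot")),
      within_weekly = function(p)
        as.numeric(within_person_variance(p, "positive", "weekday")),
      instability = function(p) as.numeric(instability(p, "positive")))
    ids <- sort(unique(panel$subject_id))
    n <- length(ids)
    set.seed(77)
    stat <- numeric(B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      resampled <- do.call(rbind, lapply(seq_along(idx), function(j) {
        rows <- panel[panel$subject_id == ids[idx[j]], ]
        rows$subject_id <- sprintf("bs%03d", j)
        rows
      }))
      class(resampled) <- c("esm_panel", "data.frame")
      stat[b] <- suppressWarnings(fn(resampled))
    }
    expected <- unname(quantile(stat, c(0.025, 0.975), type = 7))
    est <- bootstrap_ci(panel, metric, "positive", B = B, seed = 77)
    expect_equal(c(est$ci_low, est$ci_high), expected,
                 info = metric)
  }
})

test_that("bootstrap CI covers a known between-person variance ~95% of the
           time", {
  # subject means drawn N(50, 15) => true population variance 225
  cover <- 0
  for (r in 1:200) {
    set.seed(1000 + r)
    m <- rnorm(100, 50, 15)
    panel <- data.frame(subject_id = sprintf("s%03d", 1:100),
                        group = "control", day_index = 1L, weekday = 1L,
                        slot_index = 1L, positive = m, negative = 0)
    class(panel) <- c("esm_panel", "data.frame")
    est <- bootstrap_ci(panel, "between_person", "positive", B = 2000,
                        seed = r)
    if (est$ci_low <= 225 && 225 <= est$ci_high) cover <- cover + 1
  }
  # oracle simulation gave 189/200 (94.5%)
  expect_gte(cover, 176)   # >= 88%
})

test_that("dynamics metrics are translation invariant and scale
           equivariant", {
  for (seed in c(3, 14)) {
    panel <- random_micro_panel(seed)
    if (length(unique(panel$subject_id)) < 2) next
    shifted <- panel
    shifted$positive <- shifted$positive + 11.5
    scaled <- panel
    scaled$positive <- scaled$positive * 3
    for (variant in list(list(p = shifted, vf = 1, ifc = 1, off = TRUE),
                         list(p = scaled, vf = 9, ifc = 3, off = FALSE))) {
      expect_equal(
        between_person_variance(subject_means(variant$p, "positive")),
        variant$vf *
          between_person_variance(subject_means(panel, "positive")))
      ow <- oracle_within(panel, "positive", "slot")
      if (!is.na(ow))
        expect_equal(as.numeric(suppressWarnings(
          within_person_variance(variant$p, "positive", "slot"))),
          variant$vf * ow)
      oi <- oracle_instability(panel, "positive")
      if (!is.na(oi))
        expect_equal(as.numeric(instability(variant$p, "positive")),
                     variant$ifc * oi)
    }
  }
})

test_that("subject_dynamics matches the per-subject oracles", {
  panel <- random_micro_panel(8)
  sd_tab <- subject_dynamics(panel)
  for (i in seq_len(nrow(sd_tab))) {
    sub <- panel[panel$subject_id == sd_tab$subject_id[i], ]
    class(sub) <- c("esm_panel", "data.frame")
    expect_equal(sd_tab$mean_positive[i], mean(sub$positive))
    ow <- oracle_within(sub, "positive", "slot")
    expect_equal(sd_tab$intraday_var_positive[i],
                 if (is.na(ow)) NA_real_ else ow)
    oi <- oracle_instability(sub, "negative")
    expect_equal(sd_tab$instability_negative[i],
                 if (is.na(oi)) NA_real_ else oi)
  }
})
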
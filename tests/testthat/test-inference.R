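test_that("identical groups give a null omnibus test and no posthoc", {
  vals <- rep(c(1, 3, 5, 7, 9, 11, 14, 18, 23, 29), 3)
  grp <- rep(c("residential", "outpatient", "control"), each = 10)
  res <- compare_groups(vals, grp)
  expect_gt(res$p_value, 0.9)
  expect_equal(nrow(res$posthoc), 0)
})

test_that("a separated group is detected and only its pairs flagged", {
  hits <- 0
  for (seed in 1:40) {
    set.seed(200 + seed)
    vals <- c(rnorm(200, 0), rnorm(200, 0), rnorm(200, 2))
    grp <- rep(c("g1", "g2", "g3"), each = 200)
    res <- compare_groups(vals, grp)
    ok <- res$p_value < 0.001 && nrow(res$posthoc) == 3
    if (ok) {
      sig <- res$posthoc$p_adjusted < 0.05
      with3 <- grepl("g3", res$posthoc$pair)
      ok <- all(sig[with3]) && !any(sig[!with3])
    }
    hits <- hits + ok
  }
  expect_gte(hits, 36)   # >= 90% of 40 seeds (expected ~98%)
})

test_that("posthoc adjustment is Bonferroni: p_adj = min(1, p_raw * pairs)", {
  set.seed(4)
  vals <- c(rnorm(40, 0), rnorm(40, 0.8), rnorm(40, 1.6))
  grp <- rep(c("a", "b", "c"), each = 40)
  res <- compare_groups(vals, grp)
  expect_equal(nrow(res$posthoc), 3)
  expect_equal(res$posthoc$p_adjusted,
               pmin(1, res$posthoc$p_raw * 3))
  expect_equal(min(1, 0.02 * 3), 0.06)  # the contract, in numbers
})

test_that("compare_groups is permutation-safe within groups", {
  set.seed(9)
  vals <- rnorm(90)
  grp <- rep(c("a", "b", "c"), each = 30)
  perm <- unlist(lapply(split(seq_along(vals), grp), sample))
  r1 <- compare_groups(vals, grp)
  r2 <- compare_groups(vals[perm], grp[perm])
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$normality_p, r2$normality_p)
})

test_that("categorical outcomes use a chi-square test", {
  set.seed(2)
  vals <- sample(c("single", "married"), 120, replace = TRUE,
                 prob = c(0.7, 0.3))
  grp <- rep(c("a", "b", "c"), each = 40)
  res <- compare_groups(vals, grp)
  expect_equal(res$test, "chi_square")
  expect_true(is.numeric(res$p_value))
})

test_that("Spearman cells match a rank-then-Pearson oracle", {
  expect_equal(cor(1:5, c(1, 3, 2, 5, 4), method = "spearman"), 0.8)
  set.seed(31)
  for (rep in 1:10) {
    x <- sample(seq(0.01, 1, by = 0.01), 25)   # ties-free
    y <- sample(seq(0.01, 1, by = 0.01), 25)
    expect_equal(cor(x, y, method = "spearman"),
                 cor(rank(x), rank(y), method = "pearson"),
                 tolerance = 1e-12)
  }
})

test_that("clinical_correlations recovers monotone relations per subset", {
  sdyn <- data.frame(
    subject_id = sprintf("p%02d", 1:20),
    group = rep(c("residential", "outpatient"), each = 10),
    mean_positive = 50, mean_negative = 30,
    intraday_var_positive = 1:20,
    intraday_var_negative = 20:1,
    intraweek_var_positive = 1:20,
    intraweek_var_negative = 1:20,
    instability_positive = 1:20,
    instability_negative = 1:20,
    stringsAsFactors = FALSE)
  subjects <- do.call(rbind, lapply(1:20, function(i)
    blank_subject(sprintf("p%02d", i),
                  group = if (i <= 10) "residential" else "outpatient",
                  bprs_total = 24 + i, bnss_total = 78 - i,
                  slof_total = 100 + i)))
  cm <- clinical_correlations(sdyn, subjects)
  expect_setequal(unique(cm$subset),
                  c("patients", "residential", "outpatient"))
  up <- cm[cm$subset == "patients" &
             cm$measure == "intraday_var_positive" &
             cm$clinical == "bprs_total", ]
  expect_equal(up$rho, 1)
  down <- cm[cm$subset == "patients" &
               cm$measure == "intraday_var_negative" &
               cm$clinical == "bprs_total", ]
  expect_equal(down$rho, -1)
  expect_true(all(abs(cm$rho[!cm$insufficient]) <= 1))

  # < 3 complete pairs -> flagged missing
  subjects$bnss_total <- NA_real_
  cm2 <- clinical_correlations(sdyn, subjects)
  expect_true(all(cm2$insufficient[cm2$clinical == "bnss_total"]))
  expect_true(all(is.na(cm2$rho[cm2$clinical == "bnss_total"])))
})

test_that("backward elimination retains a true predictor and drops the
           worst term first", {
  set.seed(6)
  n <- 100
  d <- data.frame(x1 = rnorm(n))
  d$y <- d$x1 + rnorm(n, sd = 0.1)
  sel <- backward_eliminate(d, "y", "x1")
  expect_equal(sel$retained$term, "x1")
  expect_lt(abs(sel$retained$beta - 1), 0.1)

  # contract: the first dropped term is the argmax-p term of the full fit
  set.seed(7)
  d2 <- data.frame(x1 = rnorm(80), x2 = rnorm(80), x3 = rnorm(80))
  d2$y <- 0.8 * d2$x1 + rnorm(80)
  full <- glm(y ~ x1 + x2 + x3, data = d2, family = gaussian())
  pv <- drop1(full, test = "F")[["Pr(>F)"]][-1]
  names(pv) <- c("x1", "x2", "x3")
  sel2 <- backward_eliminate(d2, "y", c("x1", "x2", "x3"))
  if (max(pv) >= 0.05)
    expect_equal(sel2$trace$dropped[1], names(which.max(pv)))
  expect_true(all(sel2$retained$p < 0.05))
})

test_that("the elimination trace re-applied step-by-step reproduces the
           final model", {
  set.seed(13)
  n <- 120
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  x4 = rnorm(n))
  d$y <- 1.2 * d$x1 + 0.5 * d$x2 + rnorm(n)
  sel <- backward_eliminate(d, "y", c("x1", "x2", "x3", "x4"))
  current <- c("x1", "x2", "x3", "x4")
  for (i in seq_len(nrow(sel$trace))) {
    rhs <- paste(current, collapse = " + ")
    fit <- glm(as.formula(paste("y ~", rhs)), data = d,
               family = gaussian())
    pv <- drop1(fit, test = "F")[["Pr(>F)"]][-1]
    names(pv) <- attr(terms(fit), "term.labels")
    expect_equal(sel$trace$dropped[i], names(which.max(pv)))
    expect_equal(sel$trace$p_at_drop[i], unname(max(pv)))
    current <- setdiff(current, sel$trace$dropped[i])
  }
  expect_setequal(sel$retained$term, current)
})

test_that("rank deficiency is reported with the collinear term", {
  d <- data.frame(x1 = rnorm(30))
  d$x2 <- d$x1
  d$y <- d$x1 + rnorm(30)
  expect_error(backward_eliminate(d, "y", c("x1", "x2")), "collinear")
})

test_that("fit_trend recovers a noiseless linear trend exactly", {
  rows <- subject_prompts("A", days = 1:7)
  ds <- esm_dataset(blank_subject("A"), rows)
  panel <- compute_composites(ds)
  panel$positive <- 2 * panel$slot_index
  # "essentially perfect fit" warning is the point of this test
  tf <- suppressWarnings(
    fit_trend(panel, ds$subjects, "control", "positive", "hour_slot",
              method = "ols"))
  expect_equal(tf$linear$beta, 2, tolerance = 1e-8)
  expect_equal(tf$quadratic$beta[tf$quadratic$term == "time2"], 0,
               tolerance = 1e-8)
})

test_that("lmm trend fit on balanced data with zero random-intercept
           variance agrees with OLS", {
  set.seed(17)
  subs <- do.call(rbind, lapply(1:12, function(i)
    blank_subject(sprintf("s%02d", i))))
  rows <- do.call(rbind, lapply(subs$subject_id, subject_prompts))
  ds <- esm_dataset(subs, rows)
  panel <- compute_composites(ds)
  # no subject effect at all: pure fixed trend + iid noise
  panel$positive <- 30 + 0.8 * panel$weekday + rnorm(nrow(panel), sd = 2)
  lmm <- fit_trend(panel, ds$subjects, "control", "positive", "weekday",
                   method = "lmm")
  ols <- fit_trend(panel, ds$subjects, "control", "positive", "weekday",
                   method = "ols")
  expect_equal(lmm$linear$beta, ols$linear$beta, tolerance = 1e-6)
  expect_equal(lmm$quadratic$beta, ols$quadratic$beta, tolerance = 1e-6)
})

test_that("adjusted trend fits include age and sex without changing the
           time axis", {
  ds <- generate_dataset(small_config(n = 25), seed = 19)
  panel <- compute_composites(ds)
  tf <- fit_trend(panel, ds$subjects, "control", "negative", "hour_slot",
                  adjust = "age_sex", method = "ols")
  expect_true(tf$adjusted)
  expect_equal(tf$quadratic$term, c("time", "time2"))
  expect_true(all(is.finite(tf$quadratic$beta)))
})
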
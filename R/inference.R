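# Group comparisons, clinical correlations, backward elimination, and
# diurnal/weekly time-trend models.

#' Compare a subject-level quantity between groups
#'
#' For a numeric outcome: per-group Kolmogorov-Smirnov normality checks
#' (against a normal with the group's estimated mean and SD); one-way ANOVA
#' if every group passes at the 5% level, otherwise Kruskal-Wallis; when
#' the omnibus test is significant at `alpha`, Bonferroni-adjusted pairwise
#' post-hoc tests (pooled-SD t tests after ANOVA, Wilcoxon rank-sum after
#' Kruskal-Wallis), with p_adjusted = min(1, p_raw * number of pairs).
#' For a factor/character outcome: chi-square test of the contingency
#' table, no post-hoc.
#'
#' @param values vector of subject-level values (numeric, or
#'   factor/character for a chi-square comparison)
#' @param groups vector of group labels, same length as `values`
#' @param outcome optional name carried into the result
#' @param alpha omnibus significance level gating the post-hoc tests
#' @return object of class `group_comparison`: list with `outcome`, `test`,
#'   `statistic`, `p_value`, `normality_p` (named, numeric outcomes only),
#'   `posthoc` (data.frame `pair`, `p_raw`, `p_adjusted`; zero rows when
#'   not performed)
#' @export
compare_groups <- function(values, groups, outcome = "outcome",
                           alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs n >= 2", call. = FALSE)
  empty_ph <- data.frame(pair = character(), p_raw = numeric(),
                         p_adjusted = numeric(), stringsAsFactors = FALSE)

  if (!is.numeric(values)) {
    tab <- table(values, groups)
    ct <- suppressWarnings(chisq.test(tab))
    return(structure(list(outcome = outcome, test = "chi_square",
                          statistic = unname(ct$statistic),
                          p_value = ct$p.value, normality_p = NULL,
                          posthoc = empty_ph),
                     class = "group_comparison"))
  }

  norm_p <- vapply(levels(groups), function(g) {
    x <- values[groups == g]
    if (sd(x) == 0) return(0)   # degenerate: clearly non-normal sample
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }, 0)

  pairs <- combn(levels(groups), 2)
  npairs <- ncol(pairs)
  if (all(norm_p > 0.05)) {
    fit <- aov(values ~ groups)
    s <- summary(fit)[[1]]
    test <- "anova"
    statistic <- s[["F value"]][1]
    p_value <- s[["Pr(>F)"]][1]
    raw_fun <- function() suppressWarnings(
      pairwise.t.test(values, groups, p.adjust.method = "none",
                      pool.sd = TRUE)$p.value)
  } else {
    kw <- kruskal.test(values, groups)
    test <- "kruskal_wallis"
    statistic <- unname(kw$statistic)
    p_value <- kw$p.value
    raw_fun <- function() suppressWarnings(
      pairwise.wilcox.test(values, groups, p.adjust.method = "none",
                           exact = FALSE)$p.value)
  }

  posthoc <- empty_ph
  if (!is.na(p_value) && p_value < alpha) {
    pm <- raw_fun()
    rows <- lapply(seq_len(npairs), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      p_raw <- if (b %in% rownames(pm) && a %in% colnames(pm) &&
                     !is.na(pm[b, a])) pm[b, a] else pm[a, b]
      data.frame(pair = paste(a, b, sep = " vs "), p_raw = p_raw,
                 p_adjusted = min(1, p_raw * npairs),
                 stringsAsFactors = FALSE)
    })
    posthoc <- do.call(rbind, rows)
  }
  structure(list(outcome = outcome, test = test, statistic = statistic,
                 p_value = p_value, normality_p = norm_p,
                 posthoc = posthoc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s statistic=%.3f p=%.4g\n",
              x$outcome, x$test, x$statistic, x$p_value))
  if (nrow(x$posthoc) > 0) {
    cat("post-hoc (Bonferroni):\n")
    print.data.frame(x$posthoc)
  }
  invisible(x)
}

# Subject-level dynamics measures correlated with clinical totals.
CORRELATION_MEASURES <- c("intraday_var_positive", "intraday_var_negative",
                          "intraweek_var_positive", "intraweek_var_negative",
                          "instability_positive", "instability_negative")
CLINICAL_TOTALS <- c("bprs_total", "bnss_total", "slof_total")

#' Clinical correlation matrix (Spearman)
#'
#' Spearman rank correlations between per-subject dynamics measures
#' (intraday/intraweek variability and instability, both polarities) and
#' clinical totals (BPRS, BNSS, SLOF), computed on pairwise-complete
#' subjects and emitted for the pooled patient sample and each patient
#' subgroup. Cells with fewer than 3 complete pairs are flagged missing
#' (`NA` rho/p, `insufficient = TRUE`).
#'
#' @param subj_dyn per-subject dynamics from [subject_dynamics()]
#' @param subjects the subject covariate table of the dataset
#' @param measures dynamics columns to correlate (default: the six
#'   variability/instability measures)
#' @param clinical clinical columns (default BPRS/BNSS/SLOF totals)
#' @return data.frame of class `clinical_correlations` with columns
#'   `subset`, `measure`, `clinical`, `rho`, `p`, `n`, `insufficient`
#' @export
clinical_correlations <- function(subj_dyn, subjects,
                                  measures = CORRELATION_MEASURES,
                                  clinical = CLINICAL_TOTALS) {
  df <- merge(subj_dyn, subjects, by = "subject_id",
              suffixes = c("", ".subj"))
  subsets <- list(patients = c("residential", "outpatient"),
                  residential = "residential",
                  outpatient = "outpatient")
  rows <- list()
  for (sn in names(subsets)) {
    sub <- df[df$group %in% subsets[[sn]], , drop = FALSE]
    for (m in measures) for (cl in clinical) {
      ok <- complete.cases(sub[, c(m, cl)])
      n <- sum(ok)
      if (n < 3) {
        rows[[length(rows) + 1L]] <- data.frame(
          subset = sn, measure = m, clinical = cl, rho = NA_real_,
          p = NA_real_, n = n, insufficient = TRUE,
          stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(cor.test(sub[[m]][ok], sub[[cl]][ok],
                                        method = "spearman", exact = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          subset = sn, measure = m, clinical = cl,
          rho = unname(ct$estimate), p = ct$p.value, n = n,
          insufficient = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("clinical_correlations", "data.frame")
  out
}

#' Backward elimination over a Gaussian linear model
#'
#' Fits the full model `outcome ~ candidates` (Gaussian family, identity
#' link, maximum likelihood), then iteratively removes the term with the
#' largest p-value that is >= `alpha_stay` (term p-values from single-term
#' deletion F tests, so multi-level factors are handled as whole terms)
#' until every retained term is significant. Deterministic given the data.
#'
#' @param data data.frame holding outcome and candidate columns
#' @param outcome name of the outcome column (a per-subject dynamics
#'   measure)
#' @param candidates character vector of candidate predictor columns
#' @param alpha_stay stay-in significance level (default 0.05)
#' @return object of class `selected_model`: list with `outcome`,
#'   `formula`, `fit` (the final `glm`), `retained` (data.frame `term`,
#'   `beta`, `ci_low`, `ci_high`, `p` for each non-intercept coefficient),
#'   `trace` (data.frame `step`, `dropped`, `p_at_drop`), `alpha_stay`
#' @export
backward_eliminate <- function(data, outcome, candidates,
                               alpha_stay = 0.05) {
  stopifnot(length(candidates) >= 1)
  data <- data[complete.cases(data[, c(outcome, candidates)]), , drop = FALSE]
  if (nrow(data) <= length(candidates) + 2)
    stop("need more subjects than candidates + 2", call. = FALSE)
  current <- candidates
  trace <- data.frame(step = integer(), dropped = character(),
                      p_at_drop = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    rhs <- if (length(current) == 0) "1" else paste(current, collapse = " + ")
    fml <- as.formula(paste(outcome, "~", rhs))
    fit <- glm(fml, data = data, family = gaussian())
    alias <- is.na(coef(fit))
    if (any(alias))
      stop("rank-deficient model; collinear term(s): ",
           paste(names(coef(fit))[alias], collapse = ", "), call. = FALSE)
    if (length(current) == 0) break
    d1 <- drop1(fit, test = "F")
    pv <- d1[["Pr(>F)"]][-1]          # first row is <none>
    names(pv) <- rownames(d1)[-1]
    worst <- which.max(pv)
    if (pv[worst] < alpha_stay) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     dropped = names(pv)[worst],
                                     p_at_drop = unname(pv[worst]),
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, names(pv)[worst])
  }
  sm <- summary(fit)$coefficients
  keep <- setdiff(rownames(sm), "(Intercept)")
  z <- qnorm(0.975)
  retained <- data.frame(term = keep,
                         beta = sm[keep, "Estimate"],
                         ci_low = sm[keep, "Estimate"] -
                           z * sm[keep, "Std. Error"],
                         ci_high = sm[keep, "Estimate"] +
                           z * sm[keep, "Std. Error"],
                         p = sm[keep, 4],
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(outcome = outcome, formula = fml, fit = fit,
                 retained = retained, trace = trace,
                 alpha_stay = alpha_stay),
            class = "selected_model")
}

#' @export
print.selected_model <- function(x, ...) {
  cat("<selected_model> ", x$outcome, " ~ ",
      if (nrow(x$retained) == 0) "1 (nothing retained)"
      else paste(unique(x$retained$term), collapse = " + "), "\n", sep = "")
  if (nrow(x$retained) > 0) print.data.frame(x$retained, digits = 3)
  if (nrow(x$trace) > 0) {
    cat("dropped, in order:\n")
    print.data.frame(x$trace, digits = 3)
  }
  invisible(x)
}

#' Diurnal or weekly time-trend models for momentary ratings
#'
#' Fits, on all answered prompts of one group, a linear and a quadratic
#' trend of the composite rating over continuous time -- time of day coded
#' by the two-hour slot index (1 = 08-10 ... 8 = 22-24, i.e. one unit per
#' two hours) or weekday (1 = Monday ... 7) -- optionally adjusted for age
#' and sex. Each model carries a subject-level random
#' intercept and is estimated by maximum likelihood, so missing prompts are
#' simply absent from the fit; `method = "ols"` falls back to pooled
#' ordinary least squares. Time is centered at the axis midpoint before
#' squaring to reduce collinearity; coefficients are reported back on the
#' uncentered scale. CIs and p-values are Wald (normal) intervals.
#'
#' @param panel an `esm_panel`
#' @param subjects subject covariate table (needed when
#'   `adjust = "age_sex"`)
#' @param group group to fit (`"residential"`, `"outpatient"`,
#'   `"control"`)
#' @param polarity `"positive"` or `"negative"`
#' @param axis `"hour_slot"` (time of day) or `"weekday"` (day of week)
#' @param adjust `"none"` or `"age_sex"`
#' @param method `"lmm"` (random intercept, default) or `"ols"`
#' @return object of class `trend_fit`: list with `group`, `polarity`,
#'   `axis`, `adjusted`, `method`, `n_subjects`, `n_obs`, and two
#'   coefficient tables: `linear` (the linear model's time slope) and
#'   `quadratic` (the quadratic model's time and time^2 coefficients), each
#'   a data.frame with `term`, `beta`, `ci_low`, `ci_high`, `p`
#' @export
fit_trend <- function(panel, subjects = NULL,
                      group = ESM_GROUPS,
                      polarity = c("positive", "negative"),
                      axis = c("hour_slot", "weekday"),
                      adjust = c("none", "age_sex"),
                      method = c("lmm", "ols")) {
  group <- match.arg(group)
  polarity <- match.arg(polarity)
  axis <- match.arg(axis)
  adjust <- match.arg(adjust)
  method <- match.arg(method)
  d <- panel[panel$group == group, , drop = FALSE]
  if (nrow(d) == 0) stop("no prompts for group ", group, call. = FALSE)
  d$y <- d[[polarity]]
  d$time <- if (axis == "hour_slot") as.numeric(d$slot_index)
  else as.numeric(d$weekday)
  center <- if (axis == "hour_slot") 4.5 else 4
  d$tc <- d$time - center
  d$tc2 <- d$tc^2
  covs <- character()
  if (adjust == "age_sex") {
    if (is.null(subjects))
      stop("subjects table required for age/sex adjustment", call. = FALSE)
    d <- merge(d, subjects[, c("subject_id", "age", "sex")],
               by = "subject_id")
    covs <- c("age", "sex")
  }

  fit_one <- function(terms) {
    rhs <- paste(c(terms, covs), collapse = " + ")
    if (method == "lmm") {
      fml <- as.formula(paste("y ~", rhs, "+ (1 | subject_id)"))
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = d, REML = FALSE)))
      conv <- fit@optinfo$conv$opt
      if (!is.null(conv) && conv != 0)
        stop("trend model did not converge (optimizer code ", conv, "): ",
             paste(unlist(fit@optinfo$conv$lme4$messages),
                   collapse = "; "), call. = FALSE)
      est <- lme4::fixef(fit)
      V <- as.matrix(vcov(fit))
    } else {
      fml <- as.formula(paste("y ~", rhs))
      fit <- lm(fml, data = d)
      est <- coef(fit)
      V <- vcov(fit)
    }
    list(est = est, V = V)
  }

  wald_row <- function(term, beta, se) {
    z <- qnorm(0.975)
    data.frame(term = term, beta = beta, ci_low = beta - z * se,
               ci_high = beta + z * se,
               p = 2 * pnorm(-abs(beta / se)),
               stringsAsFactors = FALSE, row.names = NULL)
  }

  # linear model: slope invariant under centering
  lin <- fit_one("tc")
  linear <- wald_row("time", unname(lin$est["tc"]),
                     sqrt(lin$V["tc", "tc"]))

  # quadratic model: map centered coefficients back to the raw time scale:
  # y = b0 + b1*(t-c) + b2*(t-c)^2  =>  beta2 = b2, beta1 = b1 - 2*c*b2
  qd <- fit_one(c("tc", "tc2"))
  b1 <- unname(qd$est["tc"]); b2 <- unname(qd$est["tc2"])
  v11 <- qd$V["tc", "tc"]; v22 <- qd$V["tc2", "tc2"]
  v12 <- qd$V["tc", "tc2"]
  beta1 <- b1 - 2 * center * b2
  se1 <- sqrt(v11 + 4 * center^2 * v22 - 4 * center * v12)
  quadratic <- rbind(wald_row("time", beta1, se1),
                     wald_row("time2", b2, sqrt(v22)))

  structure(list(group = group, polarity = polarity, axis = axis,
                 adjusted = (adjust == "age_sex"), method = method,
                 n_subjects = length(unique(d$subject_id)),
                 n_obs = nrow(d), linear = linear, quadratic = quadratic),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s %s over %s (%s, %s): n=%d obs=%d\n",
              x$group, x$polarity, x$axis,
              if (x$adjusted) "adjusted" else "unadjusted", x$method,
              x$n_subjects, x$n_obs))
  cat("linear model:\n"); print.data.frame(x$linear, digits = 3)
  cat("quadratic model:\n"); print.data.frame(x$quadratic, digits = 3)
  invisible(x)
}
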
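# Synthetic three-group ESM study generator.
#
# The generator states a world matching the published design: residential
# (n=57), outpatient (n=46) and control (n=112) groups monitored 8
# prompts/day for 7 days; group intensity means and between-person SDs from
# the published descriptive table; within-person residual SDs chosen so the
# mean absolute successive difference matches the published instability
# (sigma = MASD * sqrt(pi) / 2 for Gaussian residuals); linear+quadratic
# weekly and diurnal trends for controls only; ~63.6% response rate.

#' Build a synthetic-study configuration
#'
#' Assembles and validates the full parameter set of the generator. Use
#' [default_paper_config()] for the published-design defaults; this
#' constructor is for bespoke worlds (small test fixtures, altered effect
#' sizes).
#'
#' @param groups named list (names are group labels among residential /
#'   outpatient / control); each element a list with `n`, `mu` (named
#'   c(positive=, negative=)), `tau` (between-person SDs, same shape),
#'   `sigma` (within-person residual SDs, same shape), and optionally
#'   `trend`: a list per polarity of lists `weekday = c(linear, quadratic)`
#'   and `diurnal = c(linear, quadratic)` on the slot axis 1..8 (missing
#'   entries mean zero trend)
#' @param rho latent positive-negative anti-correlation in \[-1, 0\],
#'   applied to both the person-level means and the momentary residuals
#' @param p_resp per-prompt response probability in (0, 1]
#' @param days monitoring days (default 7)
#' @param slots_per_day prompts per day (default 8)
#' @param item_sd SD of the clamped item-level perturbation around the
#'   latent composite (default 2; composites recover the latent value
#'   within +/- 2). Set 0 for items identical to the latent composite.
#' @param clinical_coupling slope tying patients' latent clinical severity
#'   to their negative-emotion residual SD multiplier (0 = off, default)
#' @param seed default RNG seed used by [generate_dataset()]
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(groups, rho = -0.6, p_resp = 0.636,
                             days = ESM_DAYS,
                             slots_per_day = ESM_SLOTS_PER_DAY,
                             item_sd = 2, clinical_coupling = 0,
                             seed = NULL) {
  cfg <- structure(list(groups = groups, rho = rho, p_resp = p_resp,
                        days = as.integer(days),
                        slots_per_day = as.integer(slots_per_day),
                        item_sd = item_sd,
                        clinical_coupling = clinical_coupling,
                        seed = seed),
                   class = "synthetic_config")
  .check_config(cfg)
  cfg
}

.check_config <- function(cfg) {
  stopifnot(is.list(cfg$groups), length(cfg$groups) >= 1)
  if (!all(names(cfg$groups) %in% ESM_GROUPS))
    stop("unknown group label(s): ",
         paste(setdiff(names(cfg$groups), ESM_GROUPS), collapse = ", "),
         call. = FALSE)
  for (g in names(cfg$groups)) {
    gc <- cfg$groups[[g]]
    if (is.null(gc$n) || gc$n < 0)
      stop("group ", g, ": n must be >= 0", call. = FALSE)
    for (f in c("mu", "tau", "sigma")) {
      v <- gc[[f]]
      if (is.null(v) || !all(c("positive", "negative") %in% names(v)))
        stop("group ", g, ": ", f,
             " must be named c(positive=, negative=)", call. = FALSE)
      if (f != "mu" && any(v < 0))
        stop("group ", g, ": ", f, " must be >= 0", call. = FALSE)
    }
  }
  if (cfg$rho < -1 || cfg$rho > 0)
    stop("rho must be in [-1, 0]", call. = FALSE)
  if (cfg$p_resp <= 0 || cfg$p_resp > 1)
    stop("p_resp must be in (0, 1]", call. = FALSE)
  if (cfg$item_sd < 0) stop("item_sd must be >= 0", call. = FALSE)
  if (cfg$days < 1 || cfg$slots_per_day < 2)
    stop("need >= 1 day and >= 2 slots/day", call. = FALSE)
  invisible(cfg)
}

# Published descriptive values used as generator defaults.
PAPER_GROUP_SIZES <- c(residential = 57L, outpatient = 46L, control = 112L)
PAPER_MU <- list(residential = c(positive = 62.3, negative = 30.3),
                 outpatient = c(positive = 60.0, negative = 25.4),
                 control = c(positive = 60.1, negative = 23.2))
PAPER_TAU <- list(residential = c(positive = 20.2, negative = 15.9),
                  outpatient = c(positive = 17.1, negative = 14.1),
                  control = c(positive = 11.9, negative = 10.4))
# Published instability (mean absolute successive difference); residual SDs
# follow as sigma = MASD * sqrt(pi) / 2 (E|X-Y| = 2*sigma/sqrt(pi) for
# X, Y iid Gaussian).
PAPER_INSTABILITY <- list(residential = c(positive = 9.17, negative = 10.53),
                          outpatient = c(positive = 9.24, negative = 9.06),
                          control = c(positive = 9.82, negative = 9.05))
# Published control-group trend coefficients on the analysis time scales
# (weekday 1..7, time of day as slot index 1..8): positive emotions rise
# over the week, negative emotions rise over the day and fall over the
# week. Patient groups carry no trend. (On the slot axis the implied
# diurnal swing is ~14 rating points, the same order as the weekly swing;
# coding time of day in clock hours would blow the quadratic term up to a
# ~63-point swing, which a 0-100 rating scale cannot carry.)
PAPER_CONTROL_TREND <- list(
  positive = list(weekday = c(linear = 1.03, quadratic = 0.13),
                  diurnal = c(linear = 0, quadratic = 0)),
  negative = list(weekday = c(linear = -0.75, quadratic = -0.10),
                  diurnal = c(linear = 0.97, quadratic = 0.11)))
# Clinical covariate means/SDs (patients only), truncated to instrument
# ranges at generation time.
PAPER_CLINICAL <- list(
  residential = list(bprs = c(48.4, 13.2), bnss = c(24.1, 15.0),
                     slof = c(175.1, 21.3), illness = c(19.8, 10.5),
                     ap = c(1.7, 0.8), noap = c(1.8, 1.3)),
  outpatient = list(bprs = c(40.8, 9.6), bnss = c(17.0, 13.2),
                    slof = c(188.5, 32.2), illness = c(15.3, 9.0),
                    ap = c(1.5, 0.8), noap = c(0.9, 0.8)))
PAPER_MALE_FRACTION <- c(residential = 0.702, outpatient = 0.587,
                         control = 0.607)

#' Published-design generator configuration
#'
#' Returns the [synthetic_config()] whose parameters are the published
#' study's descriptive values: group sizes 57/46/112; positive/negative
#' intensity means and SDs per group as the person-level means mu and
#' between-person SDs tau; within-person residual SDs derived from the
#' published instability values; weekly and diurnal linear+quadratic
#' trends for controls only; response probability 0.636; latent
#' anti-correlation -0.6.
#'
#' @param seed optional default seed carried in the config
#' @return a `synthetic_config`
#' @export
default_paper_config <- function(seed = NULL) {
  groups <- lapply(names(PAPER_GROUP_SIZES), function(g) {
    list(n = PAPER_GROUP_SIZES[[g]],
         mu = PAPER_MU[[g]],
         tau = PAPER_TAU[[g]],
         sigma = PAPER_INSTABILITY[[g]] * sqrt(pi) / 2,
         trend = if (g == "control") PAPER_CONTROL_TREND else NULL)
  })
  names(groups) <- names(PAPER_GROUP_SIZES)
  synthetic_config(groups = groups, rho = -0.6, p_resp = 0.636,
                   seed = seed)
}

# Trend surface over the (weekday, slot) grid for one polarity, mean-
# centered over the full grid so injecting it leaves the group mean at mu.
# Subtracting a constant changes neither the linear nor the quadratic
# coefficient a trend model recovers.
.trend_surface <- function(trend, polarity, weekday, slot, days, slots) {
  tp <- trend[[polarity]]
  if (is.null(tp)) return(0)
  wd <- if (!is.null(tp$weekday))
    tp$weekday[1] * weekday + tp$weekday[2] * weekday^2 else 0
  di <- if (!is.null(tp$diurnal))
    tp$diurnal[1] * slot + tp$diurnal[2] * slot^2 else 0
  grid_wd <- 1:7
  grid_sl <- seq_len(slots)
  const <- 0
  if (!is.null(tp$weekday))
    const <- const + mean(tp$weekday[1] * grid_wd +
                            tp$weekday[2] * grid_wd^2)
  if (!is.null(tp$diurnal))
    const <- const + mean(tp$diurnal[1] * grid_sl +
                            tp$diurnal[2] * grid_sl^2)
  wd + di - const
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, rnorm(n, mean, sd)))
}

#' Generate a synthetic study dataset
#'
#' Draws, for each subject, person-level positive/negative mean ratings
#' from a bivariate Gaussian (means `mu`, SDs `tau`, correlation `rho`),
#' then for each of the `days * slots_per_day` scheduled prompts adds the
#' group's (mean-centered) diurnal+weekly trend surface and bivariate
#' Gaussian residual noise (SDs `sigma`, correlation `rho`), truncating the
#' latent composites into \[0, 100\]. Item-level ratings are the latent
#' composite plus a Gaussian perturbation clamped to +/- 1.5 rating points
#' (then rounded and clipped to the 0-100 scale), so [compute_composites()] recovers the latent composite within +/- 2.
#' Each prompt is answered independently with probability `p_resp`. Each
#' subject's monitoring week starts on a uniformly drawn weekday.
#' Deterministic given `seed`.
#'
#' Patient subjects also receive clinical covariates drawn from truncated
#' Gaussians at the published group means/SDs (optionally tied to the
#' subject's negative-affect noise via `clinical_coupling`); controls have
#' all clinical fields missing.
#'
#' @param config a [synthetic_config()]
#' @param seed integer RNG seed; defaults to `config$seed`
#' @return an [esm_dataset()]
#' @export
generate_dataset <- function(config, seed = config$seed) {
  .check_config(config)
  if (is.null(seed)) stop("seed is required (argument or config$seed)",
                          call. = FALSE)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old), add = TRUE)

  days <- config$days
  slots <- config$slots_per_day
  rho <- config$rho
  subj_rows <- list()
  prompt_rows <- list()

  for (g in names(config$groups)) {
    gc <- config$groups[[g]]
    n <- gc$n
    if (n == 0) next
    ids <- sprintf("%s_%03d", substr(g, 1, 3), seq_len(n))

    # person-level means, anti-correlated across polarity
    z1 <- rnorm(n); z2 <- rnorm(n)
    pm_pos <- pmin(100, pmax(0, gc$mu[["positive"]] +
                               gc$tau[["positive"]] * z1))
    pm_neg <- pmin(100, pmax(0, gc$mu[["negative"]] +
                               gc$tau[["negative"]] *
                               (rho * z1 + sqrt(1 - rho^2) * z2)))

    sex <- ifelse(runif(n) < PAPER_MALE_FRACTION[[g]], "male", "female")
    age <- sample(20:55, n, replace = TRUE)
    sev <- rnorm(n)   # latent severity shared by clinical scores
    if (g %in% names(PAPER_CLINICAL)) {
      pc <- PAPER_CLINICAL[[g]]
      bprs <- round(.rtrunc_norm(n, pc$bprs[1] + pc$bprs[2] * 0.5 * sev,
                                 pc$bprs[2] * sqrt(0.75), 24, 168))
      bnss <- round(.rtrunc_norm(n, pc$bnss[1] + pc$bnss[2] * 0.5 * sev,
                                 pc$bnss[2] * sqrt(0.75), 0, 78))
      slof <- round(.rtrunc_norm(n, pc$slof[1] - pc$slof[2] * 0.5 * sev,
                                 pc$slof[2] * sqrt(0.75), 43, 215))
      illness <- round(.rtrunc_norm(n, pc$illness[1], pc$illness[2], 1, 40))
      ap <- pmin(4, pmax(0, round(rnorm(n, pc$ap[1], pc$ap[2]))))
      noap <- pmin(5, pmax(0, round(rnorm(n, pc$noap[1], pc$noap[2]))))
      mood <- pmin(noap, rbinom(n, 2, 0.3))
    } else {
      bprs <- bnss <- slof <- illness <- ap <- noap <- mood <-
        rep(NA_real_, n)
    }
    subj_rows[[g]] <- data.frame(
      subject_id = ids, group = g, sex = sex, age = age,
      illness_duration = illness, n_antipsychotics = ap,
      n_non_antipsychotics = noap, n_mood_stabilizers = mood,
      bprs_total = bprs, bnss_total = bnss, slof_total = slof,
      stringsAsFactors = FALSE)

    # residual SD, optionally inflated with latent severity (patients)
    sig_mult <- if (config$clinical_coupling != 0 &&
                      g %in% names(PAPER_CLINICAL))
      pmax(0.2, 1 + config$clinical_coupling * sev) else rep(1, n)

    start_wd <- sample.int(7, n, replace = TRUE)
    np <- days * slots
    grid <- expand.grid(slot_index = seq_len(slots),
                        day_index = seq_len(days))
    for (i in seq_len(n)) {
      weekday <- ((start_wd[i] - 1 + grid$day_index - 1) %% 7) + 1
      tr_pos <- if (!is.null(gc$trend))
        .trend_surface(gc$trend, "positive", weekday, grid$slot_index,
                       days, slots)
      else 0
      tr_neg <- if (!is.null(gc$trend))
        .trend_surface(gc$trend, "negative", weekday, grid$slot_index,
                       days, slots)
      else 0
      e1 <- rnorm(np); e2 <- rnorm(np)
      lat_pos <- pmin(100, pmax(0, pm_pos[i] + tr_pos +
                                  gc$sigma[["positive"]] * sig_mult[i] * e1))
      lat_neg <- pmin(100, pmax(0, pm_neg[i] + tr_neg +
                                  gc$sigma[["negative"]] * sig_mult[i] *
                                  (rho * e1 + sqrt(1 - rho^2) * e2)))
      answered <- runif(np) < config$p_resp
      p <- data.frame(subject_id = ids[i],
                      day_index = grid$day_index,
                      weekday = as.integer(weekday),
                      slot_index = grid$slot_index,
                      answered = answered,
                      stringsAsFactors = FALSE)
      for (item in ESM_ITEMS) {
        lat <- if (item %in% POSITIVE_ITEMS) lat_pos else lat_neg
        val <- .item_from_latent(lat, config$item_sd)
        p[[item]] <- ifelse(answered, val, NA_real_)
      }
      prompt_rows[[length(prompt_rows) + 1L]] <- p
    }
  }
  esm_dataset(do.call(rbind, subj_rows), do.call(rbind, prompt_rows))
}

# Item rating from latent composite: Gaussian perturbation clamped to
# +/- 1.5 so that after rounding each item (hence the composite) stays
# within +/- 2 of the latent value; item_sd = 0 gives rounded latent.
.item_from_latent <- function(lat, item_sd) {
  if (item_sd == 0) return(pmin(100, pmax(0, round(lat))))
  e <- pmax(-1.5, pmin(1.5, rnorm(length(lat), 0, item_sd)))
  pmin(100, pmax(0, round(lat + e)))
}

#' Study-flow percentages from screening counts
#'
#' Recomputes the recruitment-flow percentages (share of screened patients
#' excluded for cognitive impairment, share dropping out, share entering
#' the monitored sample) from raw counts, rounded to one decimal as
#' printed in flow diagrams.
#'
#' @param n_screened patients screened
#' @param n_mmse_excluded excluded for MMSE below cutoff
#' @param n_dropout dropouts
#' @param n_esm entering the ESM study (optional)
#' @return named numeric vector of percentages (`mmse_excluded_pct`,
#'   `dropout_pct`, and `esm_pct` if `n_esm` given)
#' @export
study_flow <- function(n_screened, n_mmse_excluded, n_dropout,
                       n_esm = NULL) {
  stopifnot(n_screened > 0)
  out <- c(mmse_excluded_pct = round(100 * n_mmse_excluded / n_screened, 1),
           dropout_pct = round(100 * n_dropout / n_screened, 1))
  if (!is.null(n_esm))
    out <- c(out, esm_pct = round(100 * n_esm / n_screened, 1))
  out
}

#' Response-rate accounting
#'
#' Percentage of answered prompts given a scheduled total, rounded to one
#' decimal (e.g. 8578 answered of 13,496 scheduled -> 63.6).
#'
#' @param n_answered answered prompts
#' @param n_scheduled scheduled prompts
#' @return percentage (one decimal)
#' @export
response_rate <- function(n_answered, n_scheduled) {
  stopifnot(n_scheduled > 0, n_answered >= 0, n_answered <= n_scheduled)
  round(100 * n_answered / n_scheduled, 1)
}
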
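# Pipeline orchestration: simulate/ingest -> validate -> compliance filter
# -> composites -> descriptive, dynamics, correlation, selection and trend
# tables, plus a reproducibility manifest.

#' Build a pipeline run configuration
#'
#' Exactly one input source must be given: either the two CSV paths
#' (`prompts_path` + `subjects_path`) or a simulation config
#' (`sim_config`).
#'
#' @param prompts_path,subjects_path input CSVs (observed-data mode)
#' @param sim_config a [synthetic_config()] (simulation mode)
#' @param threshold compliance threshold (default 0.30)
#' @param B bootstrap resamples for the dynamics table (default 2000)
#' @param seed integer master seed (required)
#' @param alpha significance level for omnibus/post-hoc decisions and
#'   backward elimination (default 0.05)
#' @param out_dir output directory (created if needed)
#' @param trend_method `"lmm"` or `"ols"` for [fit_trend()]
#' @return object of class `run_config`
#' @export
run_config <- function(prompts_path = NULL, subjects_path = NULL,
                       sim_config = NULL, threshold = 0.30, B = 2000,
                       seed, alpha = 0.05, out_dir = "esmaff-out",
                       trend_method = "lmm") {
  have_files <- !is.null(prompts_path) || !is.null(subjects_path)
  have_sim <- !is.null(sim_config)
  if (have_files == have_sim)
    stop("exactly one of {input paths, simulation config} must be set",
         call. = FALSE)
  if (have_files && (is.null(prompts_path) || is.null(subjects_path)))
    stop("both prompts_path and subjects_path are required", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  structure(list(prompts_path = prompts_path,
                 subjects_path = subjects_path, sim_config = sim_config,
                 threshold = threshold, B = B, seed = as.integer(seed),
                 alpha = alpha, out_dir = out_dir,
                 trend_method = trend_method),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured input and writes tidy CSV result
#' tables to `config$out_dir`: `table1_intensity.csv` (group descriptive
#' summary of subject mean ratings), `table2_dynamics.csv` (dynamics
#' metrics with bootstrap CIs), `table3_correlations.csv` (Spearman
#' clinical correlations), `table4_models.csv` (backward-elimination
#' models for the six dynamics outcomes), `table5_trends.csv`
#' (linear/quadratic diurnal and weekly trends per group, unadjusted and
#' age/sex-adjusted), `compliance_report.csv`, and `manifest.json`
#' (package version, seeds, per-stage subject/prompt counts). Rerunning
#' with the same config reproduces identical outputs.
#'
#' @param config a [run_config()]
#' @param quiet suppress per-stage progress messages
#' @return invisibly, the manifest (a list)
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[esmaff] ", ...)
  stage <- "input"
  abort <- function(e) stop("pipeline stage '", stage, "' failed: ",
                            conditionMessage(e), call. = FALSE)
  tryCatch({
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

    if (!is.null(config$sim_config)) {
      ds <- generate_dataset(config$sim_config, seed = config$seed)
      input_desc <- "simulated"
    } else {
      ds <- read_long_table(config$prompts_path, config$subjects_path)
      input_desc <- paste(config$prompts_path, config$subjects_path,
                          sep = " + ")
    }
    n0 <- nrow(ds$subjects)
    say("input (", input_desc, "): ", n0, " subjects, ",
        nrow(ds$prompts), " prompts, ", sum(ds$prompts$answered),
        " answered")

    stage <- "validate"
    rep <- validate_dataset(ds)
    if (nrow(rep) > 0)
      stop(nrow(rep), " validation violation(s); first: ", rep$message[1])

    stage <- "compliance_filter"
    cf <- compliance_filter(ds, config$threshold)
    n1 <- nrow(cf$dataset$subjects)
    if (n1 == 0) stop("no subjects retained")
    say("compliance filter (>= ", config$threshold * 100, "%): ", n1,
        " of ", n0, " subjects retained")
    write.csv(cf$report, file.path(config$out_dir,
                                   "compliance_report.csv"),
              row.names = FALSE)

    stage <- "composites"
    panel <- compute_composites(cf$dataset)
    say("composites: ", nrow(panel), " answered prompts scored")

    stage <- "intensity_summary"
    t1 <- do.call(rbind, lapply(intersect(ESM_GROUPS, unique(panel$group)),
                                function(g) {
      sub <- panel[panel$group == g, ]
      do.call(rbind, lapply(c("positive", "negative"), function(pol) {
        m <- subject_means(sub, pol)
        data.frame(group = g, polarity = pol, n_subjects = length(m),
                   mean = mean(m), sd = sd(m), median = median(m),
                   iqr = IQR(m), stringsAsFactors = FALSE)
      }))
    }))
    write.csv(t1, file.path(config$out_dir, "table1_intensity.csv"),
              row.names = FALSE)

    stage <- "dynamics"
    t2 <- dynamics_table(panel, B = config$B, seed = config$seed)
    write.csv(t2, file.path(config$out_dir, "table2_dynamics.csv"),
              row.names = FALSE)
    say("dynamics: ", nrow(t2), " metric cells (B = ", config$B, ")")

    stage <- "subject_dynamics"
    sdyn <- subject_dynamics(panel)

    stage <- "correlations"
    t3 <- clinical_correlations(sdyn, cf$dataset$subjects)
    write.csv(t3, file.path(config$out_dir, "table3_correlations.csv"),
              row.names = FALSE)

    stage <- "selection"
    mdat <- merge(sdyn, cf$dataset$subjects, by = "subject_id",
                  suffixes = c("", ".s"))
    mdat <- mdat[mdat$group %in% c("residential", "outpatient"), ]
    cands <- c("illness_duration", "age", "sex", "n_antipsychotics",
               "n_non_antipsychotics", "n_mood_stabilizers", "bprs_total",
               "bnss_total", "slof_total", "mean_positive",
               "mean_negative")
    t4 <- list()
    for (oc in CORRELATION_MEASURES) {
      sel <- tryCatch(
        backward_eliminate(mdat, oc, cands, alpha_stay = config$alpha),
        error = function(e) NULL)
      if (is.null(sel)) next
      if (nrow(sel$retained) > 0)
        t4[[oc]] <- cbind(outcome = oc, sel$retained)
    }
    t4 <- if (length(t4) > 0) do.call(rbind, t4)
    else data.frame(outcome = character(), term = character(),
                    beta = numeric(), ci_low = numeric(),
                    ci_high = numeric(), p = numeric())
    write.csv(t4, file.path(config$out_dir, "table4_models.csv"),
              row.names = FALSE)

    stage <- "trends"
    t5 <- list()
    for (g in intersect(ESM_GROUPS, unique(panel$group)))
      for (pol in c("positive", "negative"))
        for (ax in c("hour_slot", "weekday"))
          for (adj in c("none", "age_sex")) {
            tf <- fit_trend(panel, cf$dataset$subjects, g, pol, ax, adj,
                            method = config$trend_method)
            t5[[length(t5) + 1L]] <- data.frame(
              group = g, polarity = pol, axis = ax,
              adjusted = tf$adjusted,
              model = c("linear", "quadratic", "quadratic"),
              term = c("time", tf$quadratic$term),
              beta = c(tf$linear$beta, tf$quadratic$beta),
              ci_low = c(tf$linear$ci_low, tf$quadratic$ci_low),
              ci_high = c(tf$linear$ci_high, tf$quadratic$ci_high),
              p = c(tf$linear$p, tf$quadratic$p),
              stringsAsFactors = FALSE)
          }
    t5 <- do.call(rbind, t5)
    write.csv(t5, file.path(config$out_dir, "table5_trends.csv"),
              row.names = FALSE)
    say("trends: ", nrow(t5), " coefficient rows")

    stage <- "manifest"
    manifest <- list(
      package = "esmaff",
      version = as.character(packageVersion("esmaff")),
      seed = config$seed,
      threshold = config$threshold,
      bootstrap_B = config$B,
      alpha = config$alpha,
      trend_method = config$trend_method,
      input = input_desc,
      counts = list(subjects_input = n0,
                    subjects_retained = n1,
                    prompts_scheduled = nrow(ds$prompts),
                    prompts_answered = sum(ds$prompts$answered),
                    prompts_analyzed = nrow(panel)),
      outputs = c("compliance_report.csv", "table1_intensity.csv",
                  "table2_dynamics.csv", "table3_correlations.csv",
                  "table4_models.csv", "table5_trends.csv"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("done: outputs in ", config$out_dir)
    invisible(manifest)
  }, error = abort)
}

# ---- command-line interface ----------------------------------------------

#' Command-line entry point
#'
#' Dispatches the `esmaff` subcommands (`validate`, `qc`, `composites`,
#' `simulate`, `dynamics`, `run`) used by the `inst/cli/esmaff` script:
#' \preformatted{
#'   esmaff validate <prompts.csv> <subjects.csv>
#'   esmaff qc --threshold 0.30 <prompts.csv> <subjects.csv> --out report.csv
#'   esmaff composites <prompts.csv> <subjects.csv> --out panel.csv
#'   esmaff simulate [--config cfg.yaml | --paper-defaults] --seed 7
#'          --out-prompts p.csv --out-subjects s.csv
#'   esmaff dynamics <prompts.csv> <subjects.csv> --B 2000 --seed 7
#'          --out table2.csv [--per-subject-first]
#'   esmaff run --config run.yaml
#' }
#' Exit codes: 0 success, 2 validation failure, 3 stage/usage error.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments)
#' @return integer exit code, invisibly (the wrapper script calls `quit`
#'   with it)
#' @export
esmaff_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(args) == 0)
      stop("usage: esmaff <validate|qc|composites|simulate|dynamics|run> ...",
           call. = FALSE)
    cmd <- args[1]
    rest <- args[-1]
    opts <- .parse_cli(rest)
    switch(cmd,
      validate = .cli_validate(opts),
      qc = .cli_qc(opts),
      composites = .cli_composites(opts),
      simulate = .cli_simulate(opts),
      dynamics = .cli_dynamics(opts),
      run = .cli_run(opts),
      stop("unknown subcommand: ", cmd, call. = FALSE))
  }, error = function(e) {
    message("esmaff error: ", conditionMessage(e))
    3L
  })
  invisible(as.integer(code))
}

# --key value / --flag parser; bare arguments collect into $positional
.parse_cli <- function(args) {
  opts <- list(positional = character())
  i <- 1L
  flags <- c("--paper-defaults", "--per-subject-first", "--quiet")
  while (i <= length(args)) {
    a <- args[i]
    key <- gsub("-", "_", sub("^--", "", a))
    if (a %in% flags) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else if (startsWith(a, "--")) {
      if (i == length(args)) stop("missing value for ", a, call. = FALSE)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

.need_pos <- function(opts, n, what) {
  if (length(opts$positional) < n)
    stop("expected ", n, " positional argument(s): ", what, call. = FALSE)
  opts$positional
}

.cli_validate <- function(opts) {
  p <- .need_pos(opts, 2, "<prompts.csv> <subjects.csv>")
  ok <- tryCatch({
    read_long_table(p[1], p[2])
    TRUE
  }, error = function(e) {
    message(conditionMessage(e))
    FALSE
  })
  if (ok) {
    message("valid")
    0L
  } else 2L
}

.cli_qc <- function(opts) {
  p <- .need_pos(opts, 2, "<prompts.csv> <subjects.csv>")
  ds <- read_long_table(p[1], p[2])
  thr <- as.numeric(opts$threshold %||% 0.30)
  res <- compliance_filter(ds, thr)
  out <- opts$out %||% "compliance_report.csv"
  write.csv(res$report, out, row.names = FALSE)
  message("retained ", sum(res$report$retained), " of ",
          nrow(res$report), " subjects; report: ", out)
  0L
}

.cli_composites <- function(opts) {
  p <- .need_pos(opts, 2, "<prompts.csv> <subjects.csv>")
  ds <- read_long_table(p[1], p[2])
  panel <- compute_composites(ds)
  out <- opts$out %||% "panel.csv"
  write.csv(panel, out, row.names = FALSE)
  message(nrow(panel), " composite rows: ", out)
  0L
}

.cli_simulate <- function(opts) {
  if (is.null(opts$seed)) stop("--seed is required", call. = FALSE)
  cfg <- if (isTRUE(opts$paper_defaults)) default_paper_config()
  else if (!is.null(opts$config)) .config_from_yaml(opts$config)
  else stop("need --config cfg.yaml or --paper-defaults", call. = FALSE)
  ds <- generate_dataset(cfg, seed = as.integer(opts$seed))
  write_long_table(ds, opts$out_prompts %||% "prompts.csv",
                   opts$out_subjects %||% "subjects.csv")
  message(nrow(ds$subjects), " subjects, ", nrow(ds$prompts),
          " prompts written")
  0L
}

.cli_dynamics <- function(opts) {
  p <- .need_pos(opts, 2, "<panel-or-prompts.csv> <subjects.csv>")
  if (is.null(opts$seed)) stop("--seed is required", call. = FALSE)
  ds <- read_long_table(p[1], p[2])
  panel <- compute_composites(ds)
  t2 <- dynamics_table(panel, B = as.integer(opts$B %||% 2000),
                       seed = as.integer(opts$seed),
                       per_subject_first = isTRUE(opts$per_subject_first))
  out <- opts$out %||% "table2.csv"
  write.csv(t2, out, row.names = FALSE)
  message(nrow(t2), " dynamics rows: ", out)
  0L
}

.cli_run <- function(opts) {
  if (is.null(opts$config)) stop("--config run.yaml is required",
                                 call. = FALSE)
  y <- yaml::read_yaml(opts$config)
  sim <- if (!is.null(y$simulate))
    if (isTRUE(y$simulate$paper_defaults)) default_paper_config()
    else .config_from_list(y$simulate)
  cfg <- run_config(prompts_path = y$prompts, subjects_path = y$subjects,
                    sim_config = sim,
                    threshold = y$threshold %||% 0.30,
                    B = y$B %||% 2000,
                    seed = y$seed %||% stop("run.yaml must set seed",
                                            call. = FALSE),
                    alpha = y$alpha %||% 0.05,
                    out_dir = y$out_dir %||% "esmaff-out",
                    trend_method = y$trend_method %||% "lmm")
  run_pipeline(cfg, quiet = isTRUE(opts$quiet))
  0L
}

.config_from_yaml <- function(path) .config_from_list(yaml::read_yaml(path))

# YAML lists arrive as plain lists; rebuild the named numeric vectors the
# config constructor expects.
.config_from_list <- function(y) {
  groups <- lapply(y$groups, function(g) {
    out <- list(n = g$n,
                mu = unlist(g$mu), tau = unlist(g$tau),
                sigma = unlist(g$sigma))
    if (!is.null(g$trend))
      out$trend <- lapply(g$trend, function(tp) lapply(tp, unlist))
    out
  })
  synthetic_config(groups = groups,
                   rho = y$rho %||% -0.6,
                   p_resp = y$p_resp %||% 0.636,
                   days = y$days %||% ESM_DAYS,
                   slots_per_day = y$slots_per_day %||% ESM_SLOTS_PER_DAY,
                   item_sd = y$item_sd %||% 2,
                   clinical_coupling = y$clinical_coupling %||% 0,
                   seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
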
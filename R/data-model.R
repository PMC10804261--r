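#' Construct a study dataset
#'
#' Bundles a subject covariate table and a long prompt-level table into a
#' validated `esm_dataset`. The prompt table has one row per scheduled
#' notification; unanswered prompts are kept as rows with `answered = FALSE`
#' and missing ratings (no imputation anywhere downstream).
#'
#' @param subjects data.frame with columns `subject_id`, `group`
#'   (residential/outpatient/control), `sex` (male/female), `age`, and the
#'   clinical fields `illness_duration`, `n_antipsychotics`,
#'   `n_non_antipsychotics`, `n_mood_stabilizers`, `bprs_total`,
#'   `bnss_total`, `slof_total` (all `NA` for controls).
#' @param prompts data.frame with columns `subject_id`, `day_index` (1-7,
#'   1 = first monitoring day), `weekday` (1 = Monday ... 7 = Sunday),
#'   `slot_index` (1-8 over the two-hour windows 08-10 ... 22-24),
#'   `answered` (logical), and the seven emotion items
#'   `happy, sad, tired, relaxed, nervous, calm, full_of_energy` in
#'   \[0, 100\] (`NA` iff unanswered).
#' @param check if `TRUE` (default) run [validate_dataset()] and stop on any
#'   violation.
#' @return an object of class `esm_dataset`: a list with elements
#'   `subjects` and `prompts`.
#' @seealso [read_long_table()], [validate_dataset()]
#' @export
esm_dataset <- function(subjects, prompts, check = TRUE) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  prompts <- as.data.frame(prompts, stringsAsFactors = FALSE)
  need_subj <- c("subject_id", "group", "sex", "age", "illness_duration",
                 "n_antipsychotics", "n_non_antipsychotics",
                 "n_mood_stabilizers", "bprs_total", "bnss_total",
                 "slof_total")
  need_prompt <- c("subject_id", "day_index", "weekday", "slot_index",
                   "answered", ESM_ITEMS)
  miss <- setdiff(need_subj, names(subjects))
  if (length(miss) > 0)
    stop("subject table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(need_prompt, names(prompts))
  if (length(miss) > 0)
    stop("prompt table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  subjects$subject_id <- as.character(subjects$subject_id)
  prompts$subject_id <- as.character(prompts$subject_id)
  prompts$answered <- as.logical(prompts$answered)
  # normalise storage so an all-missing column read back from CSV (logical
  # NA) compares equal to the numeric column it was written from
  for (cc in c("age", "illness_duration", "n_antipsychotics",
               "n_non_antipsychotics", "n_mood_stabilizers", "bprs_total",
               "bnss_total", "slof_total"))
    subjects[[cc]] <- as.numeric(subjects[[cc]])
  for (cc in c("day_index", "weekday", "slot_index"))
    prompts[[cc]] <- as.integer(prompts[[cc]])
  for (cc in ESM_ITEMS) prompts[[cc]] <- as.numeric(prompts[[cc]])
  subjects$group <- as.character(subjects$group)
  subjects$sex <- as.character(subjects$sex)
  subjects <- subjects[, need_subj]
  prompts <- prompts[, need_prompt]
  rownames(subjects) <- NULL
  rownames(prompts) <- NULL
  x <- structure(list(subjects = subjects, prompts = prompts),
                 class = "esm_dataset")
  if (check) {
    rep <- validate_dataset(x)
    if (nrow(rep) > 0)
      stop("invalid dataset: ", nrow(rep), " violation(s); first: ",
           rep$message[1], call. = FALSE)
  }
  x
}

#' @export
print.esm_dataset <- function(x, ...) {
  n_ans <- sum(x$prompts$answered)
  cat("<esm_dataset> ", nrow(x$subjects), " subjects (",
      paste(sprintf("%s=%d", ESM_GROUPS,
                    vapply(ESM_GROUPS, function(g)
                      sum(x$subjects$group == g), 0L)), collapse = ", "),
      "), ", nrow(x$prompts), " scheduled prompts, ", n_ans,
      " answered (", sprintf("%.1f%%", 100 * n_ans /
                               max(1L, nrow(x$prompts))), ")\n", sep = "")
  invisible(x)
}

# Instrument ranges for clinical totals (used by validation and the
# generator's truncation): BPRS 24 items scored 1-7, BNSS 13 items 0-6,
# SLOF 43 items 1-5.
CLINICAL_RANGES <- list(bprs_total = c(24, 168),
                        bnss_total = c(0, 78),
                        slof_total = c(43, 215))

#' Validate a study dataset
#'
#' Checks every structural invariant of the data model and returns a report
#' of all violations found (zero rows means the dataset is valid). Nothing
#' is raised and the input is never modified, so the function can be used
#' to audit untrusted files.
#'
#' Checked invariants: enum fields within their domains; ratings in
#' \[0, 100\] and present iff the prompt was answered; `day_index`,
#' `weekday`, `slot_index` within range; at most one row per
#' (subject, day, slot); at most 56 prompts per subject; every prompt's
#' subject known ("orphan prompt"); controls carry no clinical or
#' medication values; clinical totals inside instrument ranges.
#'
#' @param dataset an [esm_dataset()] (or a bare list with `subjects` and
#'   `prompts` data.frames)
#' @return data.frame of class `esm_validation` with columns `rule`,
#'   `where`, `message`
#' @export
validate_dataset <- function(dataset) {
  subjects <- dataset$subjects
  prompts <- dataset$prompts
  out <- list()
  bad <- function(rule, where, message) {
    out[[length(out) + 1L]] <<- data.frame(rule = rule, where = where,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }

  if (anyDuplicated(subjects$subject_id))
    bad("duplicate_subject", "subjects",
        paste("duplicate subject_id:",
              paste(unique(subjects$subject_id[
                duplicated(subjects$subject_id)]), collapse = ", ")))
  bad_grp <- !subjects$group %in% ESM_GROUPS
  for (i in which(bad_grp))
    bad("bad_group", subjects$subject_id[i],
        paste0("unknown group '", subjects$group[i], "'"))
  bad_sex <- !subjects$sex %in% c("male", "female")
  for (i in which(bad_sex))
    bad("bad_sex", subjects$subject_id[i],
        paste0("unknown sex '", subjects$sex[i], "'"))

  clin_cols <- c("illness_duration", "n_antipsychotics",
                 "n_non_antipsychotics", "n_mood_stabilizers",
                 names(CLINICAL_RANGES))
  is_ctrl <- subjects$group == "control"
  for (cc in clin_cols) {
    filled <- which(is_ctrl & !is.na(subjects[[cc]]))
    for (i in filled)
      bad("clinical_score_on_control", subjects$subject_id[i],
          paste0("clinical score on control: ", cc, " = ",
                 subjects[[cc]][i]))
  }
  for (cc in names(CLINICAL_RANGES)) {
    rng <- CLINICAL_RANGES[[cc]]
    off <- which(!is.na(subjects[[cc]]) &
                   (subjects[[cc]] < rng[1] | subjects[[cc]] > rng[2]))
    for (i in off)
      bad("clinical_out_of_range", subjects$subject_id[i],
          paste0(cc, " = ", subjects[[cc]][i], " outside [", rng[1],
                 ", ", rng[2], "]"))
  }

  orphan <- which(!prompts$subject_id %in% subjects$subject_id)
  for (i in orphan)
    bad("orphan_prompt", paste0("prompts row ", i),
        paste0("orphan prompt: unknown subject '", prompts$subject_id[i],
               "'"))

  idx_bad <- which(!(prompts$day_index %in% 1:ESM_DAYS) |
                     !(prompts$weekday %in% 1:7) |
                     !(prompts$slot_index %in% 1:ESM_SLOTS_PER_DAY))
  for (i in idx_bad)
    bad("bad_index", paste0("prompts row ", i),
        paste0("day_index/weekday/slot_index out of range (",
               prompts$day_index[i], ", ", prompts$weekday[i], ", ",
               prompts$slot_index[i], ")"))

  key <- paste(prompts$subject_id, prompts$day_index, prompts$slot_index)
  dup <- which(duplicated(key))
  for (i in dup)
    bad("duplicate_prompt", paste0("prompts row ", i),
        paste0("duplicate (subject, day, slot): ", key[i]))

  cnt <- table(prompts$subject_id)
  over <- names(cnt)[cnt > ESM_DAYS * ESM_SLOTS_PER_DAY]
  for (s in over)
    bad("too_many_prompts", s,
        paste0("subject has ", cnt[[s]], " prompts (> ",
               ESM_DAYS * ESM_SLOTS_PER_DAY, ")"))

  for (item in ESM_ITEMS) {
    v <- prompts[[item]]
    off <- which(!is.na(v) & (v < 0 | v > 100))
    for (i in off)
      bad("rating_out_of_range", paste0("prompts row ", i),
          paste0(item, " = ", v[i], " outside [0, 100]"))
  }
  rat <- as.matrix(prompts[, ESM_ITEMS])
  n_na <- rowSums(is.na(rat))
  ghost <- which(!prompts$answered & n_na < length(ESM_ITEMS))
  for (i in ghost)
    bad("ratings_on_unanswered", paste0("prompts row ", i),
        "ratings present on unanswered prompt")
  holey <- which(prompts$answered & n_na > 0)
  for (i in holey)
    bad("missing_rating_on_answered", paste0("prompts row ", i),
        "answered prompt with missing rating(s)")

  rep <- if (length(out) == 0)
    data.frame(rule = character(), where = character(),
               message = character(), stringsAsFactors = FALSE)
  else do.call(rbind, out)
  class(rep) <- c("esm_validation", "data.frame")
  rep
}

#' @export
print.esm_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<esm_validation> valid: no violations\n")
  } else {
    cat("<esm_validation> ", nrow(x), " violation(s)\n", sep = "")
    print.data.frame(x, ...)
  }
  invisible(x)
}

#' Read a long-format ESM study from two CSV files
#'
#' Reads the prompt-level long table and the subject covariate table
#' (UTF-8, comma-delimited, header row mandatory, missing values as empty
#' fields), validates both, and returns an [esm_dataset()]. Unanswered
#' prompts must be present as rows with empty rating fields; nothing is
#' imputed.
#'
#' @param path path to the prompts CSV
#' @param covariate_path path to the subjects CSV
#' @return an `esm_dataset`
#' @examples
#' p <- system.file("extdata", "example_prompts.csv", package = "esmaff")
#' s <- system.file("extdata", "example_subjects.csv", package = "esmaff")
#' read_long_table(p, s)
#' @export
read_long_table <- function(path, covariate_path) {
  for (f in c(path, covariate_path))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  prompts <- read.csv(path, stringsAsFactors = FALSE,
                      na.strings = "", colClasses = NA)
  subjects <- read.csv(covariate_path, stringsAsFactors = FALSE,
                       na.strings = "")
  if (!"answered" %in% names(prompts))
    stop("prompt table is missing required column(s): answered",
         call. = FALSE)
  # accept TRUE/FALSE, true/false, 0/1
  prompts$answered <- as.logical(
    ifelse(prompts$answered %in% c("0", "1"),
           prompts$answered == "1", prompts$answered))
  ds <- esm_dataset(subjects, prompts, check = FALSE)
  rep <- validate_dataset(ds)
  if (nrow(rep) > 0)
    stop("validation failed (", nrow(rep), " violation(s)); first: ",
         rep$message[1], " [", rep$where[1], "]", call. = FALSE)
  ds
}

#' Write a study dataset to two CSV files
#'
#' Inverse of [read_long_table()]: `read_long_table()` applied to the files
#' written here reproduces the dataset field-for-field. Missing values are
#' written as empty fields, so unanswered prompts appear as rows with empty
#' rating columns.
#'
#' @param dataset an `esm_dataset`
#' @param path output path for the prompts CSV
#' @param covariate_path output path for the subjects CSV
#' @return invisibly, the two paths
#' @export
write_long_table <- function(dataset, path, covariate_path) {
  stopifnot(inherits(dataset, "esm_dataset"))
  write.csv(dataset$prompts, path, row.names = FALSE, na = "")
  write.csv(dataset$subjects, covariate_path, row.names = FALSE, na = "")
  invisible(c(path, covariate_path))
}
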
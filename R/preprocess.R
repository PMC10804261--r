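#' Compliance filter
#'
#' Retains subjects who answered at least `threshold` of their scheduled
#' prompts (the retention rule is a non-strict inequality: subjects are
#' excluded when answered/scheduled falls strictly below the threshold, so
#' 17 of 56 answered prompts is retained at the default 30%). The
#' denominator is each subject's actual number of scheduled prompt rows,
#' which reduces to 56 for a full week but also handles partial schedules.
#'
#' @param dataset an [esm_dataset()]
#' @param threshold retention fraction in (0, 1]; default 0.30
#' @return list with `dataset` (the filtered `esm_dataset`, subjects and all
#'   their prompts) and `report` (data.frame of class `compliance_report`:
#'   one row per input subject with `scheduled`, `answered`, `fraction`,
#'   `retained`, `note`, plus the threshold as attribute `threshold`)
#' @export
compliance_filter <- function(dataset, threshold = 0.30) {
  stopifnot(inherits(dataset, "esm_dataset"),
            is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold <= 1)
  subjects <- dataset$subjects
  prompts <- dataset$prompts
  sched <- table(factor(prompts$subject_id, levels = subjects$subject_id))
  ans <- tapply(prompts$answered,
                factor(prompts$subject_id, levels = subjects$subject_id),
                sum)
  ans[is.na(ans)] <- 0L
  scheduled <- as.integer(sched)
  answered <- as.integer(ans)
  fraction <- ifelse(scheduled > 0, answered / scheduled, NA_real_)
  retained <- !is.na(fraction) & fraction >= threshold
  note <- ifelse(scheduled == 0, "no schedule", "")
  report <- data.frame(subject_id = subjects$subject_id,
                       group = subjects$group,
                       scheduled = scheduled, answered = answered,
                       fraction = fraction, retained = retained,
                       note = note, stringsAsFactors = FALSE)
  attr(report, "threshold") <- threshold
  class(report) <- c("compliance_report", "data.frame")
  keep <- subjects$subject_id[retained]
  out <- esm_dataset(subjects[subjects$subject_id %in% keep, , drop = FALSE],
                     prompts[prompts$subject_id %in% keep, , drop = FALSE],
                     check = FALSE)
  list(dataset = out, report = report)
}

#' Positive/negative composite scores per answered prompt
#'
#' Computes, for every answered prompt of every subject in the dataset, the
#' positive composite (mean of happy, relaxed, calm, full of energy) and
#' the negative composite (mean of sad, tired, nervous). Unanswered prompts
#' produce no row; nothing is imputed.
#'
#' @param dataset an [esm_dataset()] (typically after [compliance_filter()])
#' @return data.frame of class `esm_panel` with columns `subject_id`,
#'   `group`, `day_index`, `weekday`, `slot_index`, `positive`, `negative`
#' @export
compute_composites <- function(dataset) {
  stopifnot(inherits(dataset, "esm_dataset"))
  pr <- dataset$prompts[dataset$prompts$answered, , drop = FALSE]
  grp <- setNames(dataset$subjects$group, dataset$subjects$subject_id)
  panel <- data.frame(
    subject_id = pr$subject_id,
    group = unname(grp[pr$subject_id]),
    day_index = pr$day_index,
    weekday = pr$weekday,
    slot_index = pr$slot_index,
    positive = rowMeans(pr[, POSITIVE_ITEMS, drop = FALSE]),
    negative = rowMeans(pr[, NEGATIVE_ITEMS, drop = FALSE]),
    stringsAsFactors = FALSE)
  rownames(panel) <- NULL
  class(panel) <- c("esm_panel", "data.frame")
  panel
}

#' Smallest retained answered count under the compliance rule
#'
#' Runs [compliance_filter()] over every possible answered count for a given
#' schedule length and returns the smallest count that is retained. With 56
#' scheduled prompts and the 30% threshold this is 17.
#'
#' @param scheduled number of scheduled prompts per subject (default 56)
#' @param threshold retention fraction (default 0.30)
#' @return integer: the minimum answered count that survives the filter
#' @export
min_retained_answered <- function(scheduled = ESM_DAYS * ESM_SLOTS_PER_DAY,
                                  threshold = 0.30) {
  ds <- .schedule_grid_dataset(scheduled)
  res <- compliance_filter(ds, threshold)
  kept <- res$report$answered[res$report$retained]
  if (length(kept) == 0) stop("no answered count is retained", call. = FALSE)
  min(kept)
}

# One subject per possible answered count k = 0..scheduled, each with a full
# row set; subject k answers its first k prompts (rating 50 everywhere).
.schedule_grid_dataset <- function(scheduled) {
  stopifnot(scheduled >= 1, scheduled <= ESM_DAYS * ESM_SLOTS_PER_DAY)
  ids <- sprintf("k%02d", 0:scheduled)
  subjects <- data.frame(subject_id = ids, group = "control",
                         sex = "female", age = 30,
                         illness_duration = NA, n_antipsychotics = NA,
                         n_non_antipsychotics = NA, n_mood_stabilizers = NA,
                         bprs_total = NA, bnss_total = NA, slof_total = NA,
                         stringsAsFactors = FALSE)
  grid <- expand.grid(slot_index = 1:ESM_SLOTS_PER_DAY,
                      day_index = 1:ESM_DAYS)[seq_len(scheduled), ]
  prompts <- do.call(rbind, lapply(0:scheduled, function(k) {
    p <- data.frame(subject_id = ids[k + 1],
                    day_index = grid$day_index,
                    weekday = grid$day_index,
                    slot_index = grid$slot_index,
                    answered = seq_len(scheduled) <= k,
                    stringsAsFactors = FALSE)
    for (item in ESM_ITEMS) p[[item]] <- ifelse(p$answered, 50, NA_real_)
    p
  }))
  esm_dataset(subjects, prompts)
}
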
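# In-code fixtures: small hand-built datasets and panels.

blank_subject <- function(subject_id, group = "control", sex = "female",
                          age = 30, ...) {
  out <- data.frame(subject_id = subject_id, group = group, sex = sex,
                    age = age, illness_duration = NA_real_,
                    n_antipsychotics = NA_real_,
                    n_non_antipsychotics = NA_real_,
                    n_mood_stabilizers = NA_real_, bprs_total = NA_real_,
                    bnss_total = NA_real_, slof_total = NA_real_,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# Full-week prompt rows for one subject; `answered` recycled over the 56
# slots; answered ratings deterministic unless `ratings` given.
subject_prompts <- function(subject_id, answered = TRUE, days = 1:7,
                            start_weekday = 1, ratings = NULL) {
  grid <- expand.grid(slot_index = 1:8, day_index = days)
  n <- nrow(grid)
  ans <- rep_len(answered, n)
  p <- data.frame(subject_id = subject_id,
                  day_index = grid$day_index,
                  weekday = ((start_weekday - 1 + grid$day_index - 1) %% 7) + 1,
                  slot_index = grid$slot_index,
                  answered = ans, stringsAsFactors = FALSE)
  for (item in c("happy", "sad", "tired", "relaxed", "nervous", "calm",
                 "full_of_energy")) {
    v <- if (is.null(ratings))
      (grid$slot_index * 7 + grid$day_index * 3 + nchar(item)) %% 101
    else rep_len(ratings, n)
    p[[item]] <- ifelse(ans, as.numeric(v), NA_real_)
  }
  p
}

# Two-subject dataset: A fully answered 7 days, B days 1-3 with some
# unanswered prompts.
two_subject_dataset <- function() {
  subjects <- rbind(
    blank_subject("A", group = "residential", sex = "male", age = 41,
                  illness_duration = 12, n_antipsychotics = 2,
                  n_non_antipsychotics = 1, n_mood_stabilizers = 1,
                  bprs_total = 48, bnss_total = 20, slof_total = 170),
    blank_subject("B"))
  prompts <- rbind(
    subject_prompts("A"),
    subject_prompts("B", answered = c(TRUE, TRUE, FALSE), days = 1:3,
                    start_weekday = 4))
  esm_dataset(subjects, prompts)
}

# Panel built directly from per-prompt composite values:
# ratings = list(subject_id = list(day = c(values by slot order))).
panel_from_values <- function(values, group = "control") {
  rows <- list()
  for (sid in names(values)) {
    for (d in names(values[[sid]])) {
      v <- values[[sid]][[d]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = group, day_index = as.integer(d),
        weekday = as.integer(d), slot_index = seq_along(v),
        positive = v, negative = rev(v) / 2,
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  class(panel) <- c("esm_panel", "data.frame")
  panel
}

# Small single-group generator config for fast simulation tests.
small_config <- function(n = 20, mu_pos = 55, mu_neg = 30, tau = 10,
                         sigma = 8, rho = -0.6, p_resp = 0.7,
                         trend = NULL, item_sd = 2) {
  synthetic_config(
    groups = list(control = list(
      n = n, mu = c(positive = mu_pos, negative = mu_neg),
      tau = c(positive = tau, negative = tau),
      sigma = c(positive = sigma, negative = sigma),
      trend = trend)),
    rho = rho, p_resp = p_resp, item_sd = item_sd)
}
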
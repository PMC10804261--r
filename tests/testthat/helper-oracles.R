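# Brute-force oracles for the dynamics metrics. Deliberately naive: every
# mean and pair is materialized with explicit loops, independently of the
# package's aggregation code paths.

oracle_between <- function(means) {
  n <- length(means)
  g <- sum(means) / n
  acc <- 0
  for (m in means) acc <- acc + (m - g)^2
  acc / n
}

oracle_within <- function(panel, polarity, unit) {
  ucol <- if (unit == "slot") "slot_index" else "weekday"
  total_ss <- 0
  total_cells <- 0
  for (sid in unique(panel$subject_id)) {
    sub <- panel[panel$subject_id == sid, ]
    units <- unique(sub[[ucol]])
    if (length(units) < 2) next
    unit_means <- numeric(0)
    for (u in units) {
      vals <- sub[[polarity]][sub[[ucol]] == u]
      unit_means <- c(unit_means, sum(vals) / length(vals))
    }
    grand <- sum(unit_means) / length(unit_means)
    for (um in unit_means) total_ss <- total_ss + (um - grand)^2
    total_cells <- total_cells + length(unit_means)
  }
  if (total_cells == 0) return(NA_real_)
  total_ss / total_cells
}

oracle_instability <- function(panel, polarity) {
  total <- 0
  npairs <- 0
  for (sid in unique(panel$subject_id)) {
    sub <- panel[panel$subject_id == sid, ]
    for (d in unique(sub$day_index)) {
      day <- sub[sub$day_index == d, ]
      day <- day[order(day$slot_index), ]
      vals <- day[[polarity]]
      if (length(vals) < 2) next
      for (j in 2:length(vals)) {
        total <- total + sqrt((vals[j] - vals[j - 1])^2)
        npairs <- npairs + 1
      }
    }
  }
  if (npairs == 0) return(NA_real_)
  total / npairs
}

oracle_subject_means <- function(panel, polarity) {
  out <- numeric(0)
  for (sid in sort(unique(panel$subject_id))) {
    v <- panel[[polarity]][panel$subject_id == sid]
    out[sid] <- sum(v) / length(v)
  }
  out
}

# Random micro-panel: <= 5 subjects, <= 20 answered prompts total, random
# (day, slot) schedules without duplicates.
random_micro_panel <- function(seed) {
  set.seed(seed)
  n_subj <- sample(1:5, 1)
  rows <- list()
  total <- 0
  for (i in seq_len(n_subj)) {
    cap <- min(20 - total, sample(1:8, 1))
    if (cap < 1) break
    k <- sample(seq_len(cap), 1)
    grid <- expand.grid(day_index = 1:7, slot_index = 1:8)
    pick <- grid[sample(nrow(grid), k), ]
    rows[[i]] <- data.frame(
      subject_id = sprintf("s%02d", i),
      group = "control",
      day_index = pick$day_index,
      weekday = pick$day_index,
      slot_index = pick$slot_index,
      positive = round(runif(k, 0, 100), 1),
      negative = round(runif(k, 0, 100), 1),
      stringsAsFactors = FALSE)
    total <- total + k
  }
  panel <- do.call(rbind, rows)
  class(panel) <- c("esm_panel", "data.frame")
  panel
}
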
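#!/usr/bin/env Rscript
# Per-player time-motion summaries: total distance and distance per
# movement-intensity category, per match. Writes results/time_motion.csv
# and prints level means.

suppressPackageStartupMessages({
  library(teamsync)
  library(dplyr)
})

meta <- read_match_meta("results/raw/match_meta.csv")

tm <- bind_rows(lapply(meta$match_id, function(id) {
  traj <- utils::read.csv(sprintf("results/trajectories/trajectories_%s.csv", id))
  match_time_motion(tibble::as_tibble(traj))
})) |>
  left_join(meta, by = "match_id")

utils::write.csv(tm, "results/time_motion.csv", row.names = FALSE)

cat("Per-level means (m, per player per half):\n")
tm |>
  group_by(opposition_level) |>
  summarise(across(c(total_m, low_m, moderate_m, high_m, very_high_m),
                   ~ round(mean(.x), 1)), .groups = "drop") |>
  as.data.frame() |>
  print(row.names = FALSE)
cat("\nWrote results/time_motion.csv (", nrow(tm), "player-match rows )\n")
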
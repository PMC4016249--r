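#!/usr/bin/env Rscript
# Group dyads into three synchronization-level clusters per axis by
# k-means on each dyad's mean overall synchronization percentage.
# Writes results/clusters.csv and prints group sizes and centroids.

suppressPackageStartupMessages({
  library(teamsync)
  library(dplyr)
})

sync <- tibble::as_tibble(utils::read.csv("results/sync.csv"))
clusters <- cluster_study_dyads(sync, k = 3, seed = 1L)
utils::write.csv(clusters, "results/clusters.csv", row.names = FALSE)

for (ax in unique(clusters$axis)) {
  cat(sprintf("\nAxis %s (%s):\n", ax,
              if (ax == "x") "longitudinal" else "lateral"))
  clusters |>
    filter(axis == ax) |>
    group_by(group) |>
    summarise(n_dyads = dplyr::n(),
              centroid_pct = round(mean(feature), 1),
              sd_pct = round(sd(feature), 1), .groups = "drop") |>
    as.data.frame() |>
    print(row.names = FALSE)
}
cat("\nWrote results/clusters.csv\n")
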
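#' Run the full synthetic-study pipeline
#'
#' End-to-end driver: simulate matches against three opposition levels,
#' preprocess every raw log (interpolate, project, rotate, smooth), compute
#' per-player time-motion summaries and per-dyad synchronization records,
#' cluster dyads into synchronization-level groups per axis, and compare
#' outcomes across opposition levels (ANOVA + partial eta^2, LSD pairwise
#' tests, Cohen's d with 95% CI).
#'
#' Units of analysis mirror the study design the pipeline targets:
#' player x match for time-motion outcomes and dyad x match for
#' synchronization outcomes, so with 10 players, 3 levels and 2 matches per
#' level the error degrees of freedom are 57 and 267 respectively. Dyads
#' recur across matches but are treated as independent observations; see
#' the methods vignette for the caveat.
#'
#' @param config base [sim_config()].
#' @param seed study seed driving all randomness (match sub-seeds and
#'   k-means restarts).
#' @param n_per_level matches per opposition level.
#' @param band in-phase band half-width, degrees.
#' @param cutoff_hz low-pass cutoff, Hz.
#' @param k number of dyad clusters.
#' @param out_dir optional directory; when given, all result tables are
#'   written there as CSV.
#' @return list with tibbles `meta`, `time_motion`, `sync`, `clusters`,
#'   `tm_anova`, `tm_pairwise`, `sync_anova`, `sync_pairwise`,
#'   `cluster_anova`, plus `theta_deg` (fitted pitch orientation per match)
#'   and `truth` (per-match ground truth lists).
#' @export
run_study <- function(config = sim_config(), seed = 1L, n_per_level = 2,
                      band = 30, cutoff_hz = 3, k = 3, out_dir = NULL) {
  sim <- simulate_study(config, seed = seed, n_per_level = n_per_level)
  vertices <- generate_field_vertices(config)

  tm_list <- list(); sync_list <- list(); theta <- numeric(0)
  for (m in seq_along(sim$matches)) {
    mt <- sim$matches[[m]]
    traj <- suppressWarnings(
      preprocess_match(mt$log, vertices,
                       rate_hz = config$sample_rate_hz, cutoff_hz = cutoff_hz)
    )
    theta[mt$truth$match_id] <- attr(traj, "theta_deg")
    tm_list[[m]] <- match_time_motion(traj, rate_hz = config$sample_rate_hz)
    sync_list[[m]] <- compute_dyad_sync(traj, rate_hz = config$sample_rate_hz,
                                        band = band)
  }
  time_motion <- dplyr::left_join(dplyr::bind_rows(tm_list), sim$meta, by = "match_id")
  sync <- dplyr::left_join(dplyr::bind_rows(sync_list), sim$meta, by = "match_id")

  clusters <- cluster_study_dyads(sync, k = k, seed = seed)

  # degenerate outcomes (zero variance on a short synthetic half) are
  # skipped rather than crashing the driver
  safe_compare <- function(v, g, name) {
    if (sum(is.finite(v)) < 6 || stats::var(v, na.rm = TRUE) < 1e-12) return(NULL)
    compare_opposition(v[is.finite(v)], g[is.finite(v)], name)
  }

  tm_outcomes <- c("total_m", paste0(speed_categories()$category, "_m"))
  tm_res <- Filter(Negate(is.null), lapply(tm_outcomes, function(oc) {
    safe_compare(time_motion[[oc]], time_motion$opposition_level, oc)
  }))

  sync_keys <- unique(sync[c("axis", "category")])
  sync_res <- Filter(Negate(is.null), lapply(seq_len(nrow(sync_keys)), function(i) {
    d <- sync[sync$axis == sync_keys$axis[i] &
                sync$category == sync_keys$category[i], ]
    safe_compare(d$pct_in_phase, d$opposition_level,
                 paste(sync_keys$axis[i], sync_keys$category[i], sep = "_"))
  }))

  cl_key <- unique(clusters[c("axis", "group")])
  cluster_res <- lapply(seq_len(nrow(cl_key)), function(i) {
    cl <- clusters[clusters$axis == cl_key$axis[i] &
                     clusters$group == cl_key$group[i], ]
    d <- dplyr::semi_join(
      sync[sync$axis == cl_key$axis[i] & sync$category == "overall", ],
      cl, by = c("axis", "player_a", "player_b")
    )
    tryCatch(
      one_way_anova(d$pct_in_phase, d$opposition_level,
                    paste(cl_key$axis[i], cl_key$group[i], sep = "_")),
      error = function(e) NULL
    )
  })
  cluster_res <- Filter(Negate(is.null), cluster_res)

  out <- list(
    meta = sim$meta,
    time_motion = time_motion,
    sync = sync,
    clusters = clusters,
    tm_anova = dplyr::bind_rows(lapply(tm_res, `[[`, "anova")),
    tm_pairwise = dplyr::bind_rows(lapply(tm_res, `[[`, "pairwise")),
    sync_anova = dplyr::bind_rows(lapply(sync_res, `[[`, "anova")),
    sync_pairwise = dplyr::bind_rows(lapply(sync_res, `[[`, "pairwise")),
    cluster_anova = dplyr::bind_rows(cluster_res),
    theta_deg = theta,
    truth = lapply(sim$matches, `[[`, "truth")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("meta", "time_motion", "sync", "clusters", "tm_anova",
                 "tm_pairwise", "sync_anova", "sync_pairwise", "cluster_anova")) {
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}
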
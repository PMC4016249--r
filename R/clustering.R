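#' Cluster dyads into synchronization-level groups
#'
#' k-means (multiple random restarts) on a single feature per dyad — its
#' synchronization percentage, typically averaged over matches — run
#' independently per axis by the caller. Cluster labels are mapped to
#' `higher` / `intermediate` / `lower` by descending centroid, so group
#' names are comparable across runs and axes.
#'
#' @param features named numeric vector: one synchronization percentage per
#'   dyad (names identify the dyads).
#' @param k number of groups.
#' @param seed integer seed making the restarts deterministic.
#' @param nstart number of random restarts.
#' @return tibble `dyad, feature, group, group_centroid, group_sd`, with
#'   `group` an ordered factor `higher > intermediate > lower` (for k = 3;
#'   `group1..groupk` otherwise).
#' @export
cluster_dyads <- function(features, k = 3, seed = 1L, nstart = 50) {
  stopifnot(is.numeric(features), k >= 2)
  if (is.null(names(features))) names(features) <- seq_along(features)
  if (any(!is.finite(features))) stop("features must be finite")
  if (length(unique(features)) < k) {
    stop(sprintf("fewer distinct feature values (%d) than clusters (%d)",
                 length(unique(features)), k))
  }
  km <- withr::with_seed(seed, stats::kmeans(features, centers = k, nstart = nstart))
  if (any(km$size == 0)) stop("k-means produced an empty cluster")
  ord <- order(km$centers[, 1], decreasing = TRUE)
  rank_of <- match(seq_len(k), ord)
  labels <- if (k == 3) c("higher", "intermediate", "lower") else paste0("group", seq_len(k))
  grp <- labels[rank_of[km$cluster]]
  sds <- vapply(seq_len(k), function(j) {
    v <- features[km$cluster == j]
    if (length(v) > 1) stats::sd(v) else 0
  }, numeric(1))
  tibble::tibble(
    dyad = names(features),
    feature = unname(features),
    group = factor(grp, levels = labels, ordered = TRUE),
    group_centroid = unname(km$centers[km$cluster, 1]),
    group_sd = sds[km$cluster]
  )
}

#' Cluster all dyads of a study, per axis
#'
#' The clustering feature is each dyad's mean overall synchronization
#' percentage across matches; axes are clustered independently.
#'
#' @param sync_tbl dyadic sync records ([compute_dyad_sync()] output bound
#'   over matches).
#' @param k number of groups.
#' @param seed integer seed.
#' @return tibble `axis, player_a, player_b, feature, group,
#'   group_centroid, group_sd`.
#' @export
cluster_study_dyads <- function(sync_tbl, k = 3, seed = 1L) {
  overall <- sync_tbl[sync_tbl$category == "overall", ]
  out <- lapply(unique(overall$axis), function(ax) {
    d <- overall[overall$axis == ax, ]
    agg <- stats::aggregate(pct_in_phase ~ player_a + player_b, data = d, FUN = mean)
    feats <- agg$pct_in_phase
    names(feats) <- paste(agg$player_a, agg$player_b, sep = "-")
    cl <- cluster_dyads(feats, k = k, seed = seed)
    tibble::tibble(
      axis = ax, player_a = agg$player_a, player_b = agg$player_b,
      feature = cl$feature, group = cl$group,
      group_centroid = cl$group_centroid, group_sd = cl$group_sd
    )
  })
  dplyr::bind_rows(out)
}
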
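#' Movement speed category scheme
#'
#' Ordered intensity bins in km/h: low `[0, 3.6)`, moderate `[3.6, 14.4)`,
#' high `[14.4, 19.8)`, very_high `[19.8, Inf)`. Bins are contiguous,
#' left-closed and exhaustive over the non-negative speeds; printed schemes
#' that leave 0.1 km/h gaps between bins are a rounding artifact for a
#' continuous quantity, so the lower edges are taken as the boundaries.
#'
#' @return tibble with columns `category`, `lower_kmh`, `upper_kmh`.
#' @export
speed_categories <- function() {
  tibble::tibble(
    category = c("low", "moderate", "high", "very_high"),
    lower_kmh = c(0, 3.6, 14.4, 19.8),
    upper_kmh = c(3.6, 14.4, 19.8, Inf)
  )
}

#' Per-sample speed of a trajectory
#'
#' Planar displacement between consecutive samples times the sampling rate,
#' converted to km/h. The first sample replicates the second's speed so the
#' series has the same length as the trajectory.
#'
#' @param x_m,y_m pitch-frame coordinates, metres.
#' @param rate_hz sampling rate, Hz.
#' @return numeric vector of speeds in km/h, same length as `x_m`.
#' @export
compute_speed <- function(x_m, y_m, rate_hz) {
  stopifnot(length(x_m) == length(y_m), rate_hz > 0)
  if (length(x_m) < 2) stop("need at least 2 samples to compute speed")
  v <- sqrt(diff(x_m)^2 + diff(y_m)^2) * rate_hz * 3.6
  c(v[1], v)
}

#' Classify speeds into intensity categories
#'
#' @param speed_kmh non-negative finite speeds, km/h.
#' @param scheme a [speed_categories()] tibble.
#' @return factor with the scheme's category levels.
#' @export
classify_speed <- function(speed_kmh, scheme = speed_categories()) {
  if (any(!is.finite(speed_kmh)) || any(speed_kmh < 0)) {
    stop("speeds must be finite and non-negative")
  }
  idx <- findInterval(speed_kmh, scheme$lower_kmh)
  factor(scheme$category[idx], levels = scheme$category)
}

#' Time-motion summary of one trajectory
#'
#' Accumulates each inter-sample displacement into the category of that
#' sample's instantaneous speed. Distances per category partition the total
#' exactly; times per category partition the trajectory duration.
#'
#' @param traj tibble with columns `x_m`, `y_m` (one player, one match).
#' @param rate_hz sampling rate, Hz.
#' @param scheme a [speed_categories()] tibble.
#' @return one-row tibble: `total_m`, `<category>_m` distance and
#'   `<category>_s` time per category.
#' @export
summarize_time_motion <- function(traj, rate_hz, scheme = speed_categories()) {
  sp <- compute_speed(traj$x_m, traj$y_m, rate_hz)
  cat_f <- classify_speed(sp, scheme)
  disp <- c(0, sqrt(diff(traj$x_m)^2 + diff(traj$y_m)^2))
  dist_by <- tapply(disp, cat_f, sum, default = 0)
  time_by <- tapply(rep(1 / rate_hz, length(sp)), cat_f, sum, default = 0)
  out <- tibble::tibble(total_m = sum(disp))
  for (cc in scheme$category) {
    out[[paste0(cc, "_m")]] <- unname(dist_by[cc])
    out[[paste0(cc, "_s")]] <- unname(time_by[cc])
  }
  out
}

#' Time-motion summaries for all players of a preprocessed match
#'
#' @param traj_tbl output of [preprocess_match()] (or any tibble with
#'   `match_id, player_id, t_s, x_m, y_m`).
#' @param rate_hz sampling rate, Hz.
#' @param scheme a [speed_categories()] tibble.
#' @return tibble with one row per player.
#' @export
match_time_motion <- function(traj_tbl, rate_hz = 5, scheme = speed_categories()) {
  traj_tbl |>
    dplyr::group_by(.data$match_id, .data$player_id) |>
    dplyr::group_modify(function(d, g) {
      summarize_time_motion(d[order(d$t_s), ], rate_hz, scheme)
    }) |>
    dplyr::ungroup()
}
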
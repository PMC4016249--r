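#' Synchronize players onto a common time base and fill gaps
#'
#' All players of a match are resampled onto one uniform grid at `rate_hz`
#' covering the intersection of their time coverage (never the union:
#' dyadic statistics need simultaneous samples, and extrapolation is never
#' performed). Interior gaps are filled by linear interpolation of each
#' coordinate; the `interpolated` flag marks grid samples with no raw
#' observation within half a sampling interval.
#'
#' @param log raw position log tibble (`match_id, player_id, unix_time_s,
#'   lat_deg, lon_deg`), one match.
#' @param rate_hz nominal sampling rate of the grid.
#' @return tibble `match_id, player_id, t_s, lat_deg, lon_deg, interpolated`
#'   with identical `t_s` for every player.
#' @export
synchronize_and_interpolate <- function(log, rate_hz = 5) {
  stopifnot(length(unique(log$match_id)) == 1)
  players <- split(log, log$player_id)
  counts <- vapply(players, nrow, integer(1))
  if (any(counts < 2)) {
    stop("players with fewer than 2 samples: ",
         paste(names(players)[counts < 2], collapse = ", "))
  }
  t_start <- max(vapply(players, function(p) min(p$unix_time_s), numeric(1)))
  t_end <- min(vapply(players, function(p) max(p$unix_time_s), numeric(1)))
  if (t_end <= t_start) stop("players have no common time coverage")
  dt <- 1 / rate_hz
  # integer grid indices, tolerant of float rounding in the timestamps
  k0 <- ceiling(t_start * rate_hz - 1e-6)
  k1 <- floor(t_end * rate_hz + 1e-6)
  grid <- (k0:k1) / rate_hz
  out <- lapply(players, function(p) {
    p <- p[order(p$unix_time_s), ]
    if (any(diff(p$unix_time_s) <= 0)) stop("timestamps must be strictly increasing")
    # observed = a raw sample within half a sampling interval of the grid time
    idx <- findInterval(grid, p$unix_time_s - dt / 2 + 1e-9)
    observed <- idx >= 1 & idx <= nrow(p) &
      abs(grid - p$unix_time_s[pmin(pmax(idx, 1), nrow(p))]) < dt / 2
    tibble::tibble(
      match_id = p$match_id[1],
      player_id = p$player_id[1],
      t_s = grid,
      lat_deg = stats::approx(p$unix_time_s, p$lat_deg, xout = grid, rule = 1)$y,
      lon_deg = stats::approx(p$unix_time_s, p$lon_deg, xout = grid, rule = 1)$y,
      interpolated = !observed
    )
  })
  dplyr::bind_rows(out)
}

#' Fit the pitch orientation from projected field vertices
#'
#' The four vertices (in perimeter order, metric coordinates) define two
#' pairs of opposite sides; theta is the direction of the longer pair,
#' averaged over the two long sides on the doubled-angle circle and reduced
#' modulo 180 degrees, so the attacking direction is deliberately not
#' encoded.
#'
#' @param vertices 4x2 matrix or data frame of projected vertices
#'   (`easting`, `northing`), perimeter order.
#' @return theta in degrees, `[0, 180)`.
#' @export
fit_rotation <- function(vertices) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  stopifnot(nrow(v) == 4, all(is.finite(v)))
  d <- v[c(2, 3, 4, 1), ] - v
  len <- sqrt(rowSums(d^2))
  area2 <- abs(sum(v[, 1] * v[c(2, 3, 4, 1), 2] - v[c(2, 3, 4, 1), 1] * v[, 2]))
  if (area2 < 1e-9 * max(len)^2) stop("degenerate (collinear) field vertices")
  pair1 <- c(1, 3); pair2 <- c(2, 4)
  long <- if (mean(len[pair1]) >= mean(len[pair2])) pair1 else pair2
  if (abs(diff(len[long])) > 0.05 * mean(len[long])) {
    warning("opposite field sides disagree by more than 5%; vertices are not a rectangle")
  }
  phi <- atan2(d[long, 2], d[long, 1])
  theta <- atan2(sum(sin(2 * phi)), sum(cos(2 * phi))) / 2 * 180 / pi
  theta <- theta %% 180
  if (theta > 180 - 1e-9) theta <- 0
  theta
}

#' Rotate metric positions into the pitch-aligned frame
#'
#' Rotation by `-theta` about `center`, so that after the transform the
#' pitch long axis lies along x (longitudinal) and the width along y
#' (lateral). A rotation is an isometry: all pairwise distances are
#' preserved.
#'
#' @param easting,northing metric coordinates.
#' @param theta_deg pitch orientation from [fit_rotation()].
#' @param center length-2 numeric, rotation centre (typically the centroid
#'   of the field vertices).
#' @return tibble with columns `x`, `y`.
#' @export
apply_rotation <- function(easting, northing, theta_deg, center = c(0, 0)) {
  stopifnot(all(is.finite(easting)), all(is.finite(northing)))
  th <- -theta_deg * pi / 180
  e <- easting - center[1]
  n <- northing - center[2]
  tibble::tibble(
    x = e * cos(th) - n * sin(th),
    y = e * sin(th) + n * cos(th)
  )
}

# Steady-state initial filter state for a step of unit height (direct form
# II transposed), so a constant input produces a constant output from the
# first sample.
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  comp <- rbind(-a[-1], cbind(diag(n - 2), 0))  # companion matrix of a
  solve(diag(n - 1) - t(comp), b[-1] - a[-1] * b[1])
}

# Linear filter with explicit initial state (direct form II transposed).
.lfilter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  z <- zi
  nz <- n - 1
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    ym <- b[1] * x[m] + z[1]
    if (nz > 1) z[1:(nz - 1)] <- b[2:nz] * x[m] + z[2:nz] - a[2:nz] * ym
    z[nz] <- b[n] * x[m] - a[n] * ym
    y[m] <- ym
  }
  y
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth applied forward and backward
#' (effective fourth order, zero phase lag) — the de facto smoothing
#' standard in movement science. Edge handling follows the usual
#' forward-backward convention: the series is extended by odd reflection
#' and each pass starts from the steady-state filter conditions, so a
#' constant series passes through unchanged. A cutoff at or above the
#' Nyquist frequency is not realizable; it is clamped to 0.99 x Nyquist
#' with a warning rather than rejected, because tracking practice often
#' quotes cutoffs tied to the hardware rather than the sampling theorem.
#'
#' @param x uniformly sampled numeric series.
#' @param cutoff_hz cutoff frequency, Hz; `> 0`.
#' @param rate_hz sampling rate, Hz.
#' @param order filter order of each pass.
#' @return filtered series, same length.
#' @export
lowpass_smooth <- function(x, cutoff_hz, rate_hz, order = 2) {
  stopifnot(is.numeric(x), cutoff_hz > 0, rate_hz > 0)
  nyq <- rate_hz / 2
  if (cutoff_hz >= nyq) {
    warning(sprintf("cutoff %.3g Hz >= Nyquist %.3g Hz; clamped to %.4g Hz",
                    cutoff_hz, nyq, 0.99 * nyq))
    cutoff_hz <- 0.99 * nyq
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  b <- bf$b; a <- bf$a
  min_pad <- 3 * (max(length(b), length(a)) - 1)
  n <- length(x)
  if (n <= min_pad) {
    stop(sprintf("series of length %d shorter than filter warm-up (%d)",
                 n, min_pad + 1))
  }
  # pad until the slowest pole has decayed below 1e-9, so edge transients
  # die inside the reflection padding even for near-Nyquist cutoffs
  rmax <- max(Mod(polyroot(rev(a))))
  padlen <- if (rmax < 1) ceiling(log(1e-9) / log(rmax)) else n - 1
  padlen <- min(n - 1, max(min_pad, padlen))
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- .lfilter_zi(b, a)
  y <- .lfilter(b, a, ext, zi * ext[1])
  y <- rev(.lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Full preprocessing pipeline for one match
#'
#' Raw lat/lon log -> common 5 Hz time base with interior gaps filled ->
#' UTM metric coordinates -> rotation into the pitch frame fitted from the
#' field vertices -> zero-phase Butterworth smoothing of each axis.
#'
#' @param log raw position log tibble for one match.
#' @param field_vertices tibble of 4 geographic vertices
#'   (`lat_deg, lon_deg`, perimeter order).
#' @param rate_hz grid rate, Hz.
#' @param cutoff_hz low-pass cutoff, Hz (clamped below Nyquist, see
#'   [lowpass_smooth()]).
#' @return tibble `match_id, player_id, t_s, x_m, y_m, interpolated`, with
#'   attributes `theta_deg` (fitted pitch orientation), `rate_hz`, and
#'   `field_center` (UTM centroid of the vertices).
#' @export
preprocess_match <- function(log, field_vertices, rate_hz = 5, cutoff_hz = 3) {
  synced <- synchronize_and_interpolate(log, rate_hz)
  zone <- unique(utm_zone(c(field_vertices$lon_deg, synced$lon_deg)))
  if (length(zone) > 1) {
    stop(sprintf("match data straddles UTM zones %s",
                 paste(sort(zone), collapse = " and ")))
  }
  vert_utm <- latlon_to_utm(field_vertices$lat_deg, field_vertices$lon_deg, zone = zone)
  theta <- fit_rotation(vert_utm)
  center <- c(mean(vert_utm$easting), mean(vert_utm$northing))
  pos_utm <- latlon_to_utm(synced$lat_deg, synced$lon_deg, zone = zone)
  aligned <- apply_rotation(pos_utm$easting, pos_utm$northing, theta, center)
  synced$x_m <- aligned$x
  synced$y_m <- aligned$y
  parts <- split(seq_len(nrow(synced)), synced$player_id)
  for (idx in parts) {
    synced$x_m[idx] <- lowpass_smooth(synced$x_m[idx], cutoff_hz, rate_hz)
    synced$y_m[idx] <- lowpass_smooth(synced$y_m[idx], cutoff_hz, rate_hz)
  }
  span_x <- diff(range(synced$x_m))
  span_y <- diff(range(synced$y_m))
  field_len <- max(dist(as.matrix(vert_utm)))
  if (span_x > 1.2 * field_len || span_y > 1.2 * field_len) {
    warning("player positions extend far beyond the field extent")
  }
  out <- synced[c("match_id", "player_id", "t_s", "x_m", "y_m", "interpolated")]
  attr(out, "theta_deg") <- theta
  attr(out, "rate_hz") <- rate_hz
  attr(out, "field_center") <- center
  out
}
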
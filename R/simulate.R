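#' Role anchor positions for the simulated formation
#'
#' Nominal 4-4-2 anchors (4 defenders, 4 midfielders, 2 forwards) in the
#' pitch frame (x along field length, origin at pitch centre). Anchors set
#' where each player oscillates about; they carry no phase information.
#'
#' @param n_players currently 2..10; the first `n_players` anchors are used.
#' @return tibble with columns `player_id`, `role`, `anchor_x`, `anchor_y`.
#' @export
role_anchors <- function(n_players = 10) {
  stopifnot(n_players >= 2, n_players <= 10)
  full <- tibble::tibble(
    player_id = sprintf("P%02d", 1:10),
    role = c(rep("D", 4), rep("M", 4), rep("F", 2)),
    anchor_x = c(-30, -30, -30, -30, 0, 0, 0, 0, 25, 25),
    anchor_y = c(-22, -8, 8, 22, -22, -8, 8, 22, -10, 10)
  )
  full[seq_len(n_players), ]
}

# Bounded triangular drift wave: |d/dt| == speed everywhere except the
# reversal instants, so a match with zero oscillation amplitude is a
# constant-speed track.
.drift_wave <- function(t, speed, period) {
  if (speed == 0) return(rep(0, length(t)))
  amp <- speed * period / 4
  (2 * amp / pi) * asin(sin(2 * pi * t / period))
}

.ar1_noise <- function(n, sd, corr_time, dt) {
  if (sd == 0) return(rep(0, n))
  phi <- exp(-dt / corr_time)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
  for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
  x
}

# Pitch-frame -> geographic: rotate by +theta, translate to the pitch
# centre's UTM coordinates, invert the projection. The preprocessing stage
# applies the exact inverse chain, which is what makes ground-truth
# round-trip tests meaningful.
.field_to_latlon <- function(x, y, cfg) {
  th <- cfg$field_rotation_deg * pi / 180
  e <- x * cos(th) - y * sin(th)
  n <- x * sin(th) + y * cos(th)
  origin <- latlon_to_utm(cfg$field_origin_lat, cfg$field_origin_lon)
  utm_to_latlon(origin$easting + e, origin$northing + n,
                zone = attr(origin, "zone"),
                hemisphere = attr(origin, "hemisphere"))
}

#' Generate a synthetic match with known ground truth
#'
#' Simulates `n_players` outfield players as phase-coupled oscillators and
#' emits the raw GPS-style position log the preprocessing stage consumes,
#' together with the imposed ground truth (per-player phase offsets and all
#' wrapped dyadic phase differences) against which downstream estimates can
#' be validated.
#'
#' @param config a [sim_config()].
#' @param opposition_level optional, one of [opposition_levels()]; when
#'   supplied and `apply_preset = TRUE`, the coupling concentrations are
#'   taken from [kappa_preset()].
#' @param match_id identifier stamped on every emitted sample.
#' @param apply_preset set to `FALSE` to keep the config's own `kappa`
#'   values while still recording the opposition level.
#' @return list with elements
#'   \describe{
#'     \item{log}{tibble `match_id, player_id, unix_time_s, lat_deg, lon_deg`,
#'       with `gap_fraction` of each player's interior samples deleted.}
#'     \item{truth}{list: per-player offsets (degrees), per-dyad wrapped
#'       phase differences (degrees), the kappas used, the field rotation,
#'       anchors, and the common time base before gap deletion.}
#'   }
#' @export
generate_match <- function(config, opposition_level = NULL,
                           match_id = "M01", apply_preset = TRUE) {
  validate_sim_config(config)
  if (!is.null(opposition_level)) {
    opposition_level <- match.arg(opposition_level, opposition_levels())
    if (apply_preset) {
      preset <- kappa_preset(opposition_level)
      config$kappa_x <- preset$kappa_x
      config$kappa_y <- preset$kappa_y
    }
  }
  cfg <- config
  n <- as.integer(round(cfg$duration_s * cfg$sample_rate_hz))
  dt <- 1 / cfg$sample_rate_hz
  t <- (seq_len(n) - 1) * dt
  t0 <- 1.7e9  # arbitrary fixed epoch for unix timestamps
  anchors <- role_anchors(cfg$n_players)

  withr::with_seed(cfg$seed, {
    off_x <- rvonmises(cfg$n_players, 0, cfg$kappa_x)
    off_y <- rvonmises(cfg$n_players, 0, cfg$kappa_y)
    drift <- .drift_wave(t, cfg$drift_speed_mps, cfg$drift_period_s)
    # positions for all players are drawn before any gap deletion, so two
    # configs differing only in gap_fraction share identical paths
    paths <- vector("list", cfg$n_players)
    for (i in seq_len(cfg$n_players)) {
      x <- anchors$anchor_x[i] + drift +
        cfg$amp_x_m * sin(2 * pi * t / cfg$base_period_x_s + off_x[i]) +
        .ar1_noise(n, cfg$noise_sd_m, cfg$noise_corr_time_s, dt)
      y <- anchors$anchor_y[i] +
        cfg$amp_y_m * sin(2 * pi * t / cfg$base_period_y_s + off_y[i]) +
        .ar1_noise(n, cfg$noise_sd_m, cfg$noise_corr_time_s, dt)
      paths[[i]] <- .field_to_latlon(x, y, cfg)
    }
    logs <- vector("list", cfg$n_players)
    n_del <- as.integer(round(cfg$gap_fraction * n))
    for (i in seq_len(cfg$n_players)) {
      keep <- rep(TRUE, n)
      if (n_del > 0) {
        keep[sample(2:(n - 1), n_del)] <- FALSE
      }
      logs[[i]] <- tibble::tibble(
        match_id = match_id,
        player_id = anchors$player_id[i],
        unix_time_s = t0 + t[keep],
        lat_deg = paths[[i]]$lat_deg[keep],
        lon_deg = paths[[i]]$lon_deg[keep]
      )
    }
  })

  offsets_x_deg <- wrap_deg(off_x * 180 / pi)
  offsets_y_deg <- wrap_deg(off_y * 180 / pi)
  names(offsets_x_deg) <- names(offsets_y_deg) <- anchors$player_id
  dyads <- dyad_pairs(anchors$player_id)
  dyads$dphi_x_deg <- wrap_deg(offsets_x_deg[dyads$player_a] - offsets_x_deg[dyads$player_b])
  dyads$dphi_y_deg <- wrap_deg(offsets_y_deg[dyads$player_a] - offsets_y_deg[dyads$player_b])

  list(
    log = dplyr::bind_rows(logs),
    truth = list(
      match_id = match_id,
      opposition_level = opposition_level,
      offsets_x_deg = offsets_x_deg,
      offsets_y_deg = offsets_y_deg,
      dyads = dyads,
      kappa_x = cfg$kappa_x,
      kappa_y = cfg$kappa_y,
      field_rotation_deg = cfg$field_rotation_deg,
      anchors = anchors,
      t = t + t0
    )
  )
}

#' Geographic vertices of the simulated pitch
#'
#' Four corners of the `field_length_m` x `field_width_m` rectangle rotated
#' by `field_rotation_deg` about the pitch centre, in perimeter order
#' starting at the corner with negative x and y in the pitch frame, in the
#' same geographic frame as the player positions.
#'
#' @param config a [sim_config()].
#' @return tibble with 4 rows, columns `lat_deg`, `lon_deg`.
#' @export
generate_field_vertices <- function(config) {
  validate_sim_config(config)
  hl <- config$field_length_m / 2
  hw <- config$field_width_m / 2
  x <- c(-hl, hl, hl, -hl)
  y <- c(-hw, -hw, hw, hw)
  .field_to_latlon(x, y, config)
}

#' Simulate a full study: matches against three opposition levels
#'
#' Generates `n_per_level` matches against each opposition level (defaults
#' reproduce a 6-match design: 2 x first_league, 2 x second_league,
#' 2 x amateur), with coupling strength set by [kappa_preset()] and an
#' independent sub-seed per match.
#'
#' @param config base [sim_config()]; its `seed` is ignored in favour of
#'   per-match sub-seeds derived from `seed`.
#' @param seed study-level integer seed.
#' @param n_per_level matches per opposition level.
#' @return list with `matches` (list of [generate_match()] results),
#'   `meta` (tibble `match_id`, `opposition_level`) and `config`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L, n_per_level = 2) {
  levels <- rep(opposition_levels(), each = n_per_level)
  n_matches <- length(levels)
  match_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_matches))
  matches <- vector("list", n_matches)
  meta <- tibble::tibble(
    match_id = sprintf("M%02d", seq_len(n_matches)),
    opposition_level = levels
  )
  for (m in seq_len(n_matches)) {
    cfg <- config
    cfg$seed <- match_seeds[m]
    matches[[m]] <- generate_match(cfg, opposition_level = levels[m],
                                   match_id = meta$match_id[m])
  }
  list(matches = matches, meta = meta, config = config)
}
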
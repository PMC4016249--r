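#' Opposition levels recognised by the pipeline
#' @export
opposition_levels <- function() c("first_league", "second_league", "amateur")

#' Phase-coupling presets per opposition level
#'
#' The generator encodes the design assumption that a team is driven into
#' tighter synchronization by stronger opponents: the von Mises
#' concentration of player phase offsets increases with opposition level
#' (amateur < second_league < first_league). Values are overridable via
#' [sim_config()].
#'
#' @param level one of [opposition_levels()].
#' @return named list with elements `kappa_x` and `kappa_y`.
#' @export
kappa_preset <- function(level) {
  level <- match.arg(level, opposition_levels())
  k <- switch(level, amateur = 2, second_league = 6, first_league = 16)
  list(kappa_x = k, kappa_y = k)
}

#' Simulation configuration for a synthetic match
#'
#' Players are modelled as phase-coupled oscillators: each player's planar
#' path is a role anchor plus a slow team drift plus one sinusoid per pitch
#' axis, with a per-player phase offset drawn from a von Mises distribution
#' centred at zero. The concentration `kappa` per axis is the coupling dial:
#' `kappa = 0` gives independent (uniform) phases, large `kappa` a team
#' moving in lockstep. Positional jitter is AR(1)-correlated to mimic the
#' slow wander of GPS error rather than white noise.
#'
#' @param n_players number of outfield players (default 10, i.e. 45 dyads).
#' @param duration_s length of the simulated half, seconds.
#' @param sample_rate_hz sampling rate of the virtual GPS units.
#' @param field_length_m,field_width_m pitch dimensions, metres.
#' @param field_rotation_deg orientation of the pitch long axis relative to
#'   UTM grid east, degrees.
#' @param field_origin_lat,field_origin_lon geographic position of the pitch
#'   centre, decimal degrees.
#' @param kappa_x,kappa_y von Mises concentration of player phase offsets
#'   per axis; `>= 0`.
#' @param base_period_x_s,base_period_y_s period of the team's shared
#'   oscillation per axis, seconds.
#' @param amp_x_m,amp_y_m oscillation amplitudes, metres. Defaults (15, 8)
#'   are chosen so instantaneous speeds span all four intensity categories.
#' @param drift_speed_mps magnitude of the slow up-and-down-the-pitch team
#'   drift (triangular wave along x), metres per second.
#' @param drift_period_s period of the drift wave, seconds.
#' @param noise_sd_m stationary standard deviation of the AR(1) positional
#'   jitter, metres.
#' @param noise_corr_time_s correlation time of the jitter, seconds.
#' @param gap_fraction fraction of interior samples deleted per player to
#'   emulate GPS dropouts; in `[0, 0.5)`. Endpoints are never deleted so
#'   interpolation never extrapolates.
#' @param seed integer seed; identical seeds give byte-identical matches.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_players = 10,
                       duration_s = 2700,
                       sample_rate_hz = 5,
                       field_length_m = 105,
                       field_width_m = 68,
                       field_rotation_deg = 17,
                       field_origin_lat = 38.57,
                       field_origin_lon = -7.91,
                       kappa_x = 8,
                       kappa_y = 8,
                       base_period_x_s = 20,
                       base_period_y_s = 12,
                       amp_x_m = 15,
                       amp_y_m = 8,
                       drift_speed_mps = 0.4,
                       drift_period_s = 300,
                       noise_sd_m = 0.1,
                       noise_corr_time_s = 1,
                       gap_fraction = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_players = as.integer(n_players), duration_s = duration_s,
    sample_rate_hz = sample_rate_hz, field_length_m = field_length_m,
    field_width_m = field_width_m, field_rotation_deg = field_rotation_deg,
    field_origin_lat = field_origin_lat, field_origin_lon = field_origin_lon,
    kappa_x = kappa_x, kappa_y = kappa_y,
    base_period_x_s = base_period_x_s, base_period_y_s = base_period_y_s,
    amp_x_m = amp_x_m, amp_y_m = amp_y_m,
    drift_speed_mps = drift_speed_mps, drift_period_s = drift_period_s,
    noise_sd_m = noise_sd_m, noise_corr_time_s = noise_corr_time_s,
    gap_fraction = gap_fraction, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (!all(is.finite(num))) stop("sim_config contains non-finite values")
  if (cfg$n_players < 2) stop("n_players must be at least 2")
  if (cfg$kappa_x < 0 || cfg$kappa_y < 0) stop("kappa must be >= 0")
  if (cfg$gap_fraction < 0 || cfg$gap_fraction >= 0.5) {
    stop("gap_fraction must be in [0, 0.5)")
  }
  n_samples <- cfg$duration_s * cfg$sample_rate_hz
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("duration_s * sample_rate_hz must be an integer sample count")
  }
  invisible(cfg)
}
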
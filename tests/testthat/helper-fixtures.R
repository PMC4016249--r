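# Shared fixture builders: small, fast configs and hand-made trajectories.

quick_config <- function(...) {
  args <- list(...)
  defaults <- list(duration_s = 120, gap_fraction = 0, noise_sd_m = 0, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# A one-player trajectory tibble in the pitch frame.
traj_tbl <- function(x, y, rate_hz = 5, player_id = "P01", match_id = "T01") {
  n <- length(x)
  tibble::tibble(
    match_id = match_id, player_id = player_id,
    t_s = (seq_len(n) - 1) / rate_hz, x_m = x, y_m = y
  )
}

# Deterministic smooth random trajectory (sum of low-frequency sinusoids).
random_traj <- function(n, seed, rate_hz = 5) {
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) / rate_hz
    mk <- function() {
      f <- stats::runif(3, 0.01, 0.2)
      a <- stats::runif(3, 1, 10)
      ph <- stats::runif(3, 0, 2 * pi)
      rowSums(sapply(1:3, function(i) a[i] * sin(2 * pi * f[i] * t + ph[i])))
    }
    traj_tbl(mk(), mk(), rate_hz)
  })
}
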
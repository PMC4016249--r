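#' Instantaneous phase via the analytic signal
#'
#' The series is centred (its mean removed) and extended to a complex
#' analytic signal by the discrete Hilbert transform (FFT construction:
#' negative frequencies zeroed, positive doubled); the instantaneous phase
#' is the argument of the analytic signal. For a pure sinusoid the phase
#' advances linearly at the signal frequency, which is the property the
#' dyadic relative-phase measure relies on.
#'
#' @param x uniformly sampled oscillatory series (e.g. one pitch axis of a
#'   player trajectory), at least 64 samples.
#' @param detrend_window optional odd window length (samples) of a moving
#'   average removed before the transform, for data with slow drift;
#'   `NULL` (default) subtracts only the series mean.
#' @return numeric vector of phases in degrees, wrapped to (-180, 180].
#' @export
instantaneous_phase <- function(x, detrend_window = NULL) {
  stopifnot(is.numeric(x))
  if (length(x) < 64) stop("need at least 64 samples for a stable analytic signal")
  if (!is.null(detrend_window)) {
    w <- as.integer(detrend_window)
    stopifnot(w %% 2 == 1, w >= 3)
    trend <- stats::filter(x, rep(1 / w, w), sides = 2)
    trend[is.na(trend)] <- mean(x)
    x <- x - as.numeric(trend)
  } else {
    x <- x - mean(x)
  }
  if (stats::sd(x) < 1e-12) stop("constant (zero-variance) series has no phase")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  wrap_deg(atan2(Im(z), Re(z)) * 180 / pi)
}

#' Relative phase of a dyad
#'
#' Per-sample wrapped difference `phi_a - phi_b` in degrees. The canonical
#' sign convention takes `a` as the lexicographically smaller player id;
#' swapping the order negates every sample.
#'
#' @param phi_a,phi_b phase series in degrees, equal length.
#' @return wrapped relative phase in (-180, 180].
#' @export
relative_phase <- function(phi_a, phi_b) {
  if (length(phi_a) != length(phi_b)) stop("phase series lengths differ")
  wrap_deg(phi_a - phi_b)
}

#' Percentage of samples with relative phase inside a band
#'
#' @param rel_phi wrapped relative phase, degrees.
#' @param lo,hi closed band limits, degrees (`lo < hi`); the default
#'   `[-30, 30]` is the near-in-phase synchronization band.
#' @param mask optional logical subset of samples (e.g. one speed
#'   category); an empty mask yields `NA` (undefined percentage).
#' @return list with `pct` (percentage in `[0, 100]`, or `NA`) and `n`
#'   (number of samples considered).
#' @export
percent_in_band <- function(rel_phi, lo = -30, hi = 30, mask = NULL) {
  stopifnot(lo < hi)
  if (is.null(mask)) mask <- rep(TRUE, length(rel_phi))
  stopifnot(length(mask) == length(rel_phi))
  n <- sum(mask)
  if (n == 0) return(list(pct = NA_real_, n = 0L))
  list(pct = 100 * sum(rel_phi[mask] >= lo & rel_phi[mask] <= hi) / n,
       n = as.integer(n))
}

#' Per-sample speed category of a dyad
#'
#' The dyad's speed at each sample is the arithmetic mean of the two
#' players' instantaneous speeds, classified with the usual intensity
#' scheme. Sample-level stratification (rather than one category per dyad
#' per match) lets a single half populate every category.
#'
#' @param speed_a,speed_b speeds in km/h, equal length.
#' @param scheme a [speed_categories()] tibble.
#' @return factor of categories, one per sample.
#' @export
dyad_speed_category <- function(speed_a, speed_b, scheme = speed_categories()) {
  if (length(speed_a) != length(speed_b)) stop("speed series lengths differ")
  classify_speed((speed_a + speed_b) / 2, scheme)
}

#' Dyadic synchronization records for one match
#'
#' For every unordered pair of players and each pitch axis, computes the
#' percentage of time spent in the near-in-phase band of relative phase
#' (closed `[-band, band]` degrees), overall and stratified by the dyad's
#' per-sample speed category.
#'
#' @param traj_tbl preprocessed trajectories (one match): columns
#'   `match_id, player_id, t_s, x_m, y_m`.
#' @param rate_hz sampling rate, Hz.
#' @param band half-width of the in-phase band, degrees.
#' @param scheme a [speed_categories()] tibble.
#' @param detrend_window passed to [instantaneous_phase()].
#' @return tibble `match_id, player_a, player_b, axis, category,
#'   pct_in_phase, n_samples` with `category` in
#'   `overall, low, moderate, high, very_high`.
#' @export
compute_dyad_sync <- function(traj_tbl, rate_hz = 5, band = 30,
                              scheme = speed_categories(),
                              detrend_window = NULL) {
  stopifnot(length(unique(traj_tbl$match_id)) == 1)
  match_id <- traj_tbl$match_id[1]
  players <- split(traj_tbl, traj_tbl$player_id)
  if (length(players) < 2) stop("need at least 2 players")
  players <- lapply(players, function(p) p[order(p$t_s), ])
  ns <- vapply(players, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("players are not on a common time base")

  phase <- lapply(players, function(p) {
    list(x = instantaneous_phase(p$x_m, detrend_window),
         y = instantaneous_phase(p$y_m, detrend_window))
  })
  speed <- lapply(players, function(p) compute_speed(p$x_m, p$y_m, rate_hz))

  dyads <- dyad_pairs(names(players))
  cats <- c("overall", scheme$category)
  rows <- vector("list", nrow(dyads) * 2)
  k <- 0
  for (i in seq_len(nrow(dyads))) {
    a <- dyads$player_a[i]; b <- dyads$player_b[i]
    cat_f <- dyad_speed_category(speed[[a]], speed[[b]], scheme)
    for (axis in c("x", "y")) {
      rel <- relative_phase(phase[[a]][[axis]], phase[[b]][[axis]])
      pct <- numeric(length(cats)); nn <- integer(length(cats))
      for (j in seq_along(cats)) {
        msk <- if (cats[j] == "overall") NULL else cat_f == cats[j]
        pb <- percent_in_band(rel, -band, band, msk)
        pct[j] <- pb$pct; nn[j] <- pb$n
      }
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        match_id = match_id, player_a = a, player_b = b,
        axis = axis, category = cats, pct_in_phase = pct, n_samples = nn
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$category <- factor(out$category, levels = cats)
  out
}
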
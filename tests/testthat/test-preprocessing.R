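# --- UTM projection -------------------------------------------------------

test_that("UTM round trip is identity to below 1e-9 degrees", {
  withr::with_seed(11, {
    lat <- runif(1000, 37, 42)
    lon <- runif(1000, -8.99, -3.01)  # zone 29 or 30 individually
  })
  zone <- utm_zone(lon)
  for (z in unique(zone)) {
    sel <- zone == z
    p <- latlon_to_utm(lat[sel], lon[sel])
    inv <- utm_to_latlon(p$easting, p$northing, attr(p, "zone"), attr(p, "hemisphere"))
    expect_lt(max(abs(inv$lat_deg - lat[sel])), 1e-9)
    expect_lt(max(abs(inv$lon_deg - lon[sel])), 1e-9)
  }
})

test_that("projected distances match geodesic distances", {
  skip_if_not_installed("geosphere")
  # two points ~100 m apart on a meridian
  lat0 <- 38.5; lon0 <- -7.91
  dlat <- 0.0009
  geo <- geosphere::distGeo(c(lon0, lat0), c(lon0, lat0 + dlat))
  p <- latlon_to_utm(c(lat0, lat0 + dlat), c(lon0, lon0))
  proj <- sqrt(diff(p$easting)^2 + diff(p$northing)^2)
  expect_lt(abs(proj - geo) / geo, 0.001)
})

test_that("northing on the central meridian equals scaled geodesic meridian arc", {
  skip_if_not_installed("geosphere")
  # independent geodesy cross-check: on the central meridian the transverse
  # Mercator northing is k0 times the meridian arc from the equator
  cm <- -9  # zone 29
  for (lat in c(10, 38.57, 60)) {
    p <- latlon_to_utm(lat, cm)
    arc <- geosphere::distGeo(c(cm, 0), c(cm, lat))
    expect_lt(abs(p$northing - 0.9996 * arc), 0.01)
    expect_equal(p$easting, 5e5, tolerance = 1e-9)
  }
})

test_that("points straddling a zone boundary raise an error naming both zones", {
  expect_error(latlon_to_utm(c(38.5, 38.5), c(-6.01, -5.99)), "29 and 30")
})

test_that("southern-hemisphere projection uses the false northing and inverts", {
  p <- latlon_to_utm(-33.9, 18.4)
  expect_equal(attr(p, "hemisphere"), "S")
  expect_gt(p$northing, 6e6)
  inv <- utm_to_latlon(p$easting, p$northing, attr(p, "zone"), "S")
  expect_equal(inv$lat_deg, -33.9, tolerance = 1e-9)
})

# --- rotation fitting and application -------------------------------------

rect_vertices <- function(theta_deg, center = c(0, 0), L = 105, W = 68) {
  x <- c(-L / 2, L / 2, L / 2, -L / 2)
  y <- c(-W / 2, -W / 2, W / 2, W / 2)
  th <- theta_deg * pi / 180
  cbind(easting = center[1] + x * cos(th) - y * sin(th),
        northing = center[2] + x * sin(th) + y * cos(th))
}

test_that("pitch orientation is recovered from vertices", {
  expect_equal(fit_rotation(rect_vertices(0)), 0)
  expect_equal(fit_rotation(rect_vertices(30)), 30, tolerance = 1e-9)
  withr::with_seed(3, {
    thetas <- runif(500, 0, 180)
    centers <- matrix(runif(1000, -1e5, 1e5), ncol = 2)
  })
  rec <- vapply(seq_along(thetas), function(i) {
    fit_rotation(rect_vertices(thetas[i], centers[i, ]))
  }, numeric(1))
  err <- abs(wrap_deg(2 * (rec - thetas))) / 2  # distance mod 180
  expect_lt(max(err), 1e-6)
})

test_that("degenerate or skewed vertices are flagged", {
  coll <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_error(fit_rotation(coll), "degenerate")
  skew <- rect_vertices(10)
  skew[2, ] <- skew[2, ] + c(8, 0)  # one long side stretched > 5%
  expect_warning(fit_rotation(skew), "disagree")
})

test_that("rotation into the pitch frame is an isometry with the right sign", {
  expect_equal(as.numeric(apply_rotation(1, 0, 90)), c(0, -1), tolerance = 1e-12)
  expect_equal(as.numeric(apply_rotation(3, -2, 0)), c(3, -2))
  withr::with_seed(4, {
    pts <- matrix(runif(40, -50, 50), ncol = 2)
  })
  rot <- apply_rotation(pts[, 1], pts[, 2], 137.3, center = c(10, -5))
  d0 <- dist(pts)
  d1 <- dist(cbind(rot$x, rot$y))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

# --- synchronization and interpolation ------------------------------------

test_that("gap-free uniform input passes through unchanged", {
  m <- generate_match(quick_config(duration_s = 20))
  synced <- synchronize_and_interpolate(m$log, 5)
  expect_false(any(synced$interpolated))
  one <- synced[synced$player_id == "P03", ]
  raw <- m$log[m$log$player_id == "P03", ]
  expect_equal(nrow(one), nrow(raw))
  expect_equal(one$lat_deg, raw$lat_deg, tolerance = 1e-12)
})

test_that("a single interior gap is filled at the linear midpoint", {
  log <- tibble::tibble(
    match_id = "T", player_id = "P01",
    unix_time_s = c(0, 0.2, 0.6, 0.8),  # sample at 0.4 s missing
    lat_deg = c(1.0e-4, 1.0e-4, 1.2e-4, 1.2e-4),
    lon_deg = c(0, 0, 0, 0)
  )
  log2 <- log; log2$player_id <- "P02"  # second player, full coverage
  log2$unix_time_s <- c(0, 0.2, 0.4, 0.8)
  synced <- synchronize_and_interpolate(rbind(log, log2), 5)
  p1 <- synced[synced$player_id == "P01", ]
  expect_equal(p1$lat_deg[p1$t_s == 0.4], 1.1e-4)
  expect_true(p1$interpolated[p1$t_s == 0.4])
  expect_false(p1$interpolated[p1$t_s == 0.2])
})

test_that("players are cut to the intersection of their coverage", {
  m <- generate_match(quick_config(duration_s = 20))
  log <- m$log
  # truncate one player's head and another's tail
  log <- log[!(log$player_id == "P01" & log$unix_time_s < min(log$unix_time_s) + 2), ]
  log <- log[!(log$player_id == "P02" & log$unix_time_s > max(log$unix_time_s) - 3), ]
  synced <- synchronize_and_interpolate(log, 5)
  expect_equal(length(unique(table(synced$player_id))), 1L)
  expect_equal(min(synced$t_s), min(log$unix_time_s[log$player_id == "P01"]))
  expect_equal(max(synced$t_s), max(log$unix_time_s[log$player_id == "P02"]))
})

test_that("interpolation error on deleted samples respects the curvature bound", {
  cfg_gap <- quick_config(duration_s = 300, gap_fraction = 0.1, drift_speed_mps = 0)
  cfg_full <- quick_config(duration_s = 300, gap_fraction = 0, drift_speed_mps = 0)
  gap <- generate_match(cfg_gap)
  full <- generate_match(cfg_full)
  synced <- synchronize_and_interpolate(gap$log, 5)
  for (p in c("P01", "P07")) {
    got <- synced[synced$player_id == p, ]
    truth <- full$log[full$log$player_id == p, ]
    expect_equal(nrow(got), nrow(truth))
    zone <- utm_zone(truth$lon_deg[1])
    g <- latlon_to_utm(got$lat_deg, got$lon_deg, zone)
    tr <- latlon_to_utm(truth$lat_deg, truth$lon_deg, zone)
    err <- sqrt((g$easting - tr$easting)^2 + (g$northing - tr$northing)^2)
    # linear interpolation over a gap of run length r spans (r+1) samples;
    # |error| <= max|f''| ((r+1) dt)^2 / 8 per axis
    runs <- rle(got$interpolated)
    rmax <- max(c(0, runs$lengths[runs$values]))
    f2 <- max(15 * (2 * pi / 20)^2, 8 * (2 * pi / 12)^2)
    bound <- sqrt(2) * f2 * ((rmax + 1) * 0.2)^2 / 8
    expect_lt(max(err[got$interpolated]), bound + 1e-9)
    expect_lt(max(err[!got$interpolated]), 1e-9)
  }
})

test_that("degenerate logs are rejected", {
  m <- generate_match(quick_config(duration_s = 10))
  log <- m$log
  one_sample <- log[log$player_id != "P01" | log$unix_time_s == min(log$unix_time_s), ]
  expect_error(synchronize_and_interpolate(one_sample, 5), "fewer than 2")
  # disjoint coverage
  half1 <- log[log$player_id == "P01" & log$unix_time_s < stats::median(log$unix_time_s), ]
  half2 <- log[log$player_id == "P02" & log$unix_time_s > stats::median(log$unix_time_s), ]
  expect_error(synchronize_and_interpolate(rbind(half1, half2), 5), "common time coverage")
})

# --- low-pass filtering ----------------------------------------------------

test_that("filter has unit DC gain and clamps cutoffs at Nyquist", {
  x <- rep(7.3, 500)
  expect_warning(y <- lowpass_smooth(x, 3, 5), "clamped")
  expect_lt(max(abs(y - 7.3)), 1e-9)
  expect_silent(lowpass_smooth(x, 2, 5))
  expect_error(suppressWarnings(lowpass_smooth(x[1:5], 3, 5)), "warm-up")
})

test_that("passband and stopband gains match the dual-pass transfer function", {
  rate <- 5
  t <- (0:4999) / rate
  # passband: 0.1 Hz sinusoid survives a clamped 2.475 Hz cutoff within 1%
  x <- sin(2 * pi * 0.1 * t)
  y <- suppressWarnings(lowpass_smooth(x, 3, rate))
  expect_equal(fitted_amplitude(y, 0.1, rate), 1, tolerance = 0.01)
  # stopband edge: 2.4 Hz attenuation equals |H|^2 from the filter
  # coefficients, evaluated independently of filtfilt
  x2 <- sin(2 * pi * 2.4 * t)
  y2 <- suppressWarnings(lowpass_smooth(x2, 3, rate))
  bf2 <- signal::butter(2, 2.475 / 2.5, type = "low")
  expected <- digital_gain(bf2$b, bf2$a, 2.4, rate)^2
  got <- fitted_amplitude(y2, 2.4, rate)
  expect_equal(got, expected, tolerance = 0.05 * expected)
})

# --- assembled pipeline -----------------------------------------------------

test_that("preprocessing recovers the generator's pitch frame", {
  cfg <- quick_config(duration_s = 60, field_rotation_deg = 73.2)
  m <- generate_match(cfg)
  v <- generate_field_vertices(cfg)
  traj <- suppressWarnings(preprocess_match(m$log, v))
  expect_equal(attr(traj, "theta_deg"), 73.2, tolerance = 1e-6)
  expect_equal(sort(unique(traj$player_id)), sprintf("P%02d", 1:10))
  expect_false(any(is.na(traj$x_m)))
  # x spans roughly the anchor spread + oscillation, well within the field
  expect_lt(diff(range(traj$x_m)), 105)
})

test_that("projection and rotation round-trip reproduces generator coordinates", {
  cfg <- quick_config(duration_s = 60, field_rotation_deg = 41)
  m <- generate_match(cfg)
  v <- generate_field_vertices(cfg)
  synced <- synchronize_and_interpolate(m$log, 5)
  zone <- utm_zone(v$lon_deg[1])
  vm <- latlon_to_utm(v$lat_deg, v$lon_deg, zone)
  theta <- fit_rotation(vm)
  pos <- latlon_to_utm(synced$lat_deg, synced$lon_deg, zone)
  aligned <- apply_rotation(pos$easting, pos$northing, theta,
                            c(mean(vm$easting), mean(vm$northing)))
  # reconstruct the generator's pitch-frame path from ground truth
  tr <- m$truth
  t <- tr$t - tr$t[1]
  p <- "P05"
  sel <- synced$player_id == p
  i <- which(tr$anchors$player_id == p)
  x_true <- tr$anchors$anchor_x[i] +
    teamsync:::.drift_wave(t, cfg$drift_speed_mps, cfg$drift_period_s) +
    cfg$amp_x_m * sin(2 * pi * t / cfg$base_period_x_s + tr$offsets_x_deg[p] * pi / 180)
  expect_lt(max(abs(aligned$x[sel] - x_true)), 1e-6)
})

test_that("the pipeline preserves the length of a straight constant-velocity track", {
  skip_if_not_installed("geosphere")
  # straight 2 m/s track crossing the pitch, plus one stationary teammate
  cfg <- quick_config(duration_s = 40)
  n <- 200
  t <- (0:(n - 1)) / 5
  origin <- latlon_to_utm(cfg$field_origin_lat, cfg$field_origin_lon)
  track <- utm_to_latlon(origin$easting - 40 + 2 * t * cos(0.3),
                         origin$northing + 2 * t * sin(0.3),
                         attr(origin, "zone"))
  log <- rbind(
    tibble::tibble(match_id = "S", player_id = "P01", unix_time_s = t,
                   lat_deg = track$lat_deg, lon_deg = track$lon_deg),
    tibble::tibble(match_id = "S", player_id = "P02", unix_time_s = t,
                   lat_deg = track$lat_deg[1], lon_deg = track$lon_deg[1] + 1e-4)
  )
  v <- generate_field_vertices(cfg)
  traj <- suppressWarnings(preprocess_match(log, v))
  p1 <- traj[traj$player_id == "P01", ]
  plen <- sum(sqrt(diff(p1$x_m)^2 + diff(p1$y_m)^2))
  geo <- sum(geosphere::distGeo(cbind(track$lon_deg, track$lat_deg)[-n, ],
                                cbind(track$lon_deg, track$lat_deg)[-1, ]))
  expect_lt(abs(plen - geo) / geo, 0.005)
})

test_that("preprocessing is deterministic", {
  cfg <- quick_config(duration_s = 30, gap_fraction = 0.1, noise_sd_m = 0.1)
  m <- generate_match(cfg)
  v <- generate_field_vertices(cfg)
  t1 <- suppressWarnings(preprocess_match(m$log, v))
  t2 <- suppressWarnings(preprocess_match(m$log, v))
  expect_identical(t1, t2)
})
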
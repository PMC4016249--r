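# Transverse Mercator (UTM) on the WGS84 ellipsoid, using the
# Karney-Krueger series in the third flattening n (terms through n^6;
# accuracy well below 1 mm anywhere inside a zone). Implemented here
# because this R stack carries no PROJ-backed geodesy package; tests
# cross-check distances against geodesic computations.

.wgs84 <- list(a = 6378137.0, f = 1 / 298.257223563)
.utm_k0 <- 0.9996
.utm_false_easting <- 500000
.utm_false_northing_south <- 10000000

.tm_constants <- local({
  f <- .wgs84$f
  n <- f / (2 - f)
  n2 <- n^2; n3 <- n^3; n4 <- n^4; n5 <- n^5; n6 <- n^6
  list(
    n = n,
    A = .wgs84$a / (1 + n) * (1 + n2 / 4 + n4 / 64 + n6 / 256),
    alpha = c(
      n / 2 - 2 * n2 / 3 + 5 * n3 / 16 + 41 * n4 / 180 - 127 * n5 / 288 + 7891 * n6 / 37800,
      13 * n2 / 48 - 3 * n3 / 5 + 557 * n4 / 1440 + 281 * n5 / 630 - 1983433 * n6 / 1935360,
      61 * n3 / 240 - 103 * n4 / 140 + 15061 * n5 / 26880 + 167603 * n6 / 181440,
      49561 * n4 / 161280 - 179 * n5 / 168 + 6601661 * n6 / 7257600,
      34729 * n5 / 80640 - 3418889 * n6 / 1995840,
      212378941 * n6 / 319334400
    ),
    beta = c(
      n / 2 - 2 * n2 / 3 + 37 * n3 / 96 - n4 / 360 - 81 * n5 / 512 + 96199 * n6 / 604800,
      n2 / 48 + n3 / 15 - 437 * n4 / 1440 + 46 * n5 / 105 - 1118711 * n6 / 3870720,
      17 * n3 / 480 - 37 * n4 / 840 - 209 * n5 / 4480 + 5569 * n6 / 90720,
      4397 * n4 / 161280 - 11 * n5 / 504 - 830251 * n6 / 7257600,
      4583 * n5 / 161280 - 108847 * n6 / 3991680,
      20648693 * n6 / 638668800
    ),
    delta = c(
      2 * n - 2 * n2 / 3 - 2 * n3 + 116 * n4 / 45 + 26 * n5 / 45 - 2854 * n6 / 675,
      7 * n2 / 3 - 8 * n3 / 5 - 227 * n4 / 45 + 2704 * n5 / 315 + 2323 * n6 / 945,
      56 * n3 / 15 - 136 * n4 / 35 - 1262 * n5 / 105 + 73814 * n6 / 2835,
      4279 * n4 / 630 - 332 * n5 / 35 - 399572 * n6 / 14175,
      4174 * n5 / 315 - 144838 * n6 / 6237,
      601676 * n6 / 22275
    )
  )
})

#' UTM zone number of a longitude
#'
#' @param lon_deg longitude in decimal degrees, `[-180, 180)`.
#' @return integer zone number in 1..60.
#' @export
utm_zone <- function(lon_deg) {
  as.integer(floor((lon_deg + 180) / 6) %% 60) + 1L
}

.utm_central_meridian <- function(zone) -180 + 6 * (zone - 0.5)

#' Project geographic coordinates to UTM
#'
#' Forward transverse Mercator projection of WGS84 latitude/longitude to
#' metric easting/northing in one UTM zone. All points of a match must fall
#' in a single zone: planar distances across a zone seam are meaningless, so
#' a straddle is an error rather than a silent re-projection.
#'
#' @param lat_deg,lon_deg numeric vectors, decimal degrees.
#' @param zone optional zone number; by default derived from the longitudes,
#'   with an error naming both zones if the points straddle a boundary.
#' @return a tibble with columns `easting`, `northing` (metres), plus the
#'   `zone` and `hemisphere` attributes needed to invert the projection.
#' @seealso [utm_to_latlon()]
#' @export
latlon_to_utm <- function(lat_deg, lon_deg, zone = NULL) {
  stopifnot(length(lat_deg) == length(lon_deg),
            all(is.finite(lat_deg)), all(is.finite(lon_deg)),
            all(abs(lat_deg) <= 90), all(abs(lon_deg) <= 180))
  zones <- unique(utm_zone(lon_deg))
  if (is.null(zone)) {
    if (length(zones) > 1) {
      stop(sprintf("points straddle UTM zones %s", paste(sort(zones), collapse = " and ")))
    }
    zone <- zones
  }
  hemisphere <- if (mean(lat_deg) >= 0) "N" else "S"
  k <- .tm_constants
  phi <- lat_deg * pi / 180
  lam <- (lon_deg - .utm_central_meridian(zone)) * pi / 180
  e2n <- 2 * sqrt(k$n) / (1 + k$n)
  t <- sinh(atanh(sin(phi)) - e2n * atanh(e2n * sin(phi)))
  xi_p <- atan2(t, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(t^2 + cos(lam)^2))
  xi <- xi_p
  eta <- eta_p
  for (j in 1:6) {
    xi <- xi + k$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + k$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  northing <- .utm_k0 * k$A * xi +
    if (hemisphere == "S") .utm_false_northing_south else 0
  out <- tibble::tibble(
    easting = .utm_k0 * k$A * eta + .utm_false_easting,
    northing = northing
  )
  attr(out, "zone") <- as.integer(zone)
  attr(out, "hemisphere") <- hemisphere
  out
}

#' Invert the UTM projection
#'
#' @param easting,northing metric UTM coordinates.
#' @param zone UTM zone number used by the forward projection.
#' @param hemisphere `"N"` or `"S"`.
#' @return a tibble with columns `lat_deg`, `lon_deg`.
#' @seealso [latlon_to_utm()]
#' @export
utm_to_latlon <- function(easting, northing, zone, hemisphere = "N") {
  stopifnot(length(easting) == length(northing),
            all(is.finite(easting)), all(is.finite(northing)),
            hemisphere %in% c("N", "S"))
  k <- .tm_constants
  if (hemisphere == "S") northing <- northing - .utm_false_northing_south
  xi <- northing / (.utm_k0 * k$A)
  eta <- (easting - .utm_false_easting) / (.utm_k0 * k$A)
  xi_p <- xi
  eta_p <- eta
  for (j in 1:6) {
    xi_p <- xi_p - k$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - k$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  chi <- asin(pmin(pmax(sin(xi_p) / cosh(eta_p), -1), 1))
  phi <- chi
  for (j in 1:6) {
    phi <- phi + k$delta[j] * sin(2 * j * chi)
  }
  lam <- atan2(sinh(eta_p), cos(xi_p))
  tibble::tibble(
    lat_deg = phi * 180 / pi,
    lon_deg = .utm_central_meridian(zone) + lam * 180 / pi
  )
}
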
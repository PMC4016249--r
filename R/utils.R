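#' Wrap angles in degrees to (-180, 180]
#'
#' Relative-phase arithmetic works on the circle; this is the canonical
#' representative used throughout the package.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector with every element in (-180, 180].
#' @examples
#' wrap_deg(c(0, 180, -180, 270, 540))
#' @export
wrap_deg <- function(x) {
  -(((-x + 180) %% 360) - 180)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler (wrapped-Cauchy envelope). Used by the
#' match generator to impose player phase offsets with controllable
#' concentration; `kappa = 0` reduces to the uniform circular distribution.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration parameter, `>= 0`.
#' @return numeric vector of angles in radians, in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(is.finite(kappa), kappa >= 0, n >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
        break
      }
    }
  }
  wrap_deg(out * 180 / pi) * pi / 180 + mu
}

#' Mean resultant length of circular data
#'
#' @param theta angles in radians.
#' @return scalar in `[0, 1]`; 0 for perfectly dispersed, 1 for identical angles.
#' @export
circular_resultant <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

# All unordered pairs of ids, lexicographically ordered within each pair
# and across pairs, so dyad identity and the relative-phase sign convention
# are deterministic.
dyad_pairs <- function(ids) {
  ids <- sort(unique(as.character(ids)))
  if (length(ids) < 2) stop("need at least 2 players to form dyads")
  cmb <- utils::combn(ids, 2)
  tibble::tibble(player_a = cmb[1, ], player_b = cmb[2, ])
}
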
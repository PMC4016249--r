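# Delimited-text interchange formats shared by the generator and the
# preprocessing reader: comma-separated, header required, UTF-8.

#' Write / read a raw position log
#'
#' Columns: `match_id, player_id, unix_time_s, lat_deg, lon_deg`.
#'
#' @param log tibble of raw samples.
#' @param path file path.
#' @return `read_position_log` returns the tibble; writers return the path
#'   invisibly.
#' @export
write_position_log <- function(log, path) {
  stopifnot(all(c("match_id", "player_id", "unix_time_s",
                  "lat_deg", "lon_deg") %in% names(log)))
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_position_log
#' @export
read_position_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("match_id", "player_id", "unix_time_s", "lat_deg", "lon_deg")
  if (!all(need %in% names(df))) {
    stop("position log must have header columns: ", paste(need, collapse = ", "))
  }
  if (any(abs(df$lat_deg) > 90) || any(abs(df$lon_deg) > 180)) {
    stop("latitude/longitude out of range")
  }
  tibble::as_tibble(df[need])
}

#' Write / read field vertices
#'
#' Four geographic vertices of the pitch in perimeter order, columns
#' `lat_deg, lon_deg`.
#'
#' @param vertices tibble with 4 rows.
#' @param path file path.
#' @export
write_field_vertices <- function(vertices, path) {
  stopifnot(nrow(vertices) == 4,
            all(c("lat_deg", "lon_deg") %in% names(vertices)))
  utils::write.csv(vertices[c("lat_deg", "lon_deg")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_vertices
#' @export
read_field_vertices <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) != 4 || !all(c("lat_deg", "lon_deg") %in% names(df))) {
    stop("field file must contain exactly 4 rows of lat_deg, lon_deg")
  }
  tibble::as_tibble(df[c("lat_deg", "lon_deg")])
}

#' Write / read the match metadata table
#'
#' Columns: `match_id, opposition_level`.
#'
#' @param meta tibble.
#' @param path file path.
#' @export
write_match_meta <- function(meta, path) {
  stopifnot(all(c("match_id", "opposition_level") %in% names(meta)))
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_match_meta
#' @export
read_match_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(df$opposition_level %in% opposition_levels())) {
    stop("unknown opposition_level in metadata; expected one of: ",
         paste(opposition_levels(), collapse = ", "))
  }
  tibble::as_tibble(df)
}
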
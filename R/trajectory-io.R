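# Ingest of raw GPS fix streams. A trajectory is a tibble of fixes
# (t, lat, lon, speed, heading, altitude) with `subject_id` and `tz`
# attributes; timestamps are stored UTC and the local calendar day is always
# derived through the trajectory's IANA timezone.

#' Construct a validated trajectory
#'
#' Builds the canonical trajectory tibble from per-fix vectors, enforcing the
#' coordinate/speed invariants, dropping duplicate timestamps (first
#' occurrence kept) and sorting by time.
#'
#' @param t POSIXct timestamps (converted to UTC).
#' @param lat,lon WGS84 decimal degrees.
#' @param speed Optional recorded speed, mph, non-negative.
#' @param heading Optional heading, degrees `[0, 360)`.
#' @param altitude Optional altitude, metres.
#' @param subject_id Opaque subject identifier.
#' @param tz IANA timezone used for local-day assignment downstream.
#' @return A tibble of fixes, sorted by `t`, with attributes `subject_id`,
#'   `tz` and `parse_log` (rows rejected / duplicates dropped).
#' @export
trajectory <- function(t, lat, lon, speed = NULL, heading = NULL,
                       altitude = NULL, subject_id = "S1", tz = "UTC") {
  n <- length(t)
  fx <- tibble(
    t = lubridate::with_tz(t, "UTC"),
    lat = as.numeric(lat),
    lon = as.numeric(lon),
    speed = if (is.null(speed)) NA_real_ else as.numeric(speed),
    heading = if (is.null(heading)) NA_real_ else as.numeric(heading),
    altitude = if (is.null(altitude)) NA_real_ else as.numeric(altitude)
  )
  ok <- !is.na(fx$t) & !is.na(fx$lat) & !is.na(fx$lon) &
    fx$lat >= -90 & fx$lat <= 90 & fx$lon >= -180 & fx$lon <= 180 &
    (is.na(fx$speed) | fx$speed >= 0)
  n_rejected <- sum(!ok)
  fx <- fx[ok, ]
  fx <- fx[order(fx$t), ]
  dup <- duplicated(fx$t)
  n_dup <- sum(dup)
  fx <- fx[!dup, ]
  if (nrow(fx) == 0) abort("empty trajectory: no valid fixes")
  attr(fx, "subject_id") <- subject_id
  attr(fx, "tz") <- tz
  attr(fx, "parse_log") <- list(
    n_input = n, n_rejected = n_rejected, n_duplicates = n_dup,
    n_fixes = nrow(fx)
  )
  fx
}

#' Timezone of a trajectory
#' @param traj A trajectory tibble.
#' @return The IANA timezone name attached to the trajectory (UTC fallback).
#' @export
trajectory_tz <- function(traj) {
  tz <- attr(traj, "tz", exact = TRUE)
  if (is.null(tz)) "UTC" else tz
}

#' Column-map dialect for device CSV exports
#'
#' Describes how to find the mandatory timestamp/latitude/longitude columns
#' (and the optional speed/heading/altitude ones) in a consumer tracker's CSV
#' export, how timestamps are formatted, and which timezone they are written
#' in. Defaults match the fix tables written by [simulate_study()].
#'
#' @param time,lat,lon Column names of the mandatory fields.
#' @param speed,heading,altitude Column names of optional fields, or `NULL`.
#' @param time_format A [strptime()] format, or `"unix"` for epoch seconds,
#'   or `"iso8601"`.
#' @param time_tz Timezone the file's timestamps are expressed in.
#' @param delim Field delimiter.
#' @return A named list used by [read_fix_table()].
#' @export
fix_dialect <- function(time = "time", lat = "latitude", lon = "longitude",
                        speed = "speed", heading = "heading",
                        altitude = "altitude",
                        time_format = "iso8601", time_tz = "UTC",
                        delim = ",") {
  list(
    time = time, lat = lat, lon = lon, speed = speed, heading = heading,
    altitude = altitude, time_format = time_format, time_tz = time_tz,
    delim = delim
  )
}

parse_fix_times <- function(x, format, tz) {
  if (identical(format, "unix")) {
    lubridate::as_datetime(as.numeric(x), tz = "UTC")
  } else if (identical(format, "iso8601")) {
    lubridate::as_datetime(x, tz = tz)
  } else {
    as.POSIXct(as.character(x), format = format, tz = tz)
  }
}

#' Read a GPS fix table (CSV)
#'
#' Ingests a device CSV export through a column-map dialect, returning a
#' validated trajectory. Rows with unparseable or out-of-range coordinates
#' are rejected and counted in the parse log, never silently dropped;
#' duplicate timestamps keep the first occurrence; rows are sorted by time.
#'
#' @param path Path to the CSV file.
#' @param dialect A [fix_dialect()].
#' @param subject_id Subject identifier to attach.
#' @param tz IANA timezone for local-day assignment.
#' @return A trajectory tibble (see [trajectory()]).
#' @export
read_fix_table <- function(path, dialect = fix_dialect(), subject_id = "S1",
                           tz = "UTC") {
  if (!file.exists(path)) abort(paste0("fix table not found: ", path))
  raw <- readr::read_delim(
    path,
    delim = dialect$delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  need <- c(dialect$time, dialect$lat, dialect$lon)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0(
      "fix table is missing mandatory column(s): ",
      paste(miss, collapse = ", ")
    ))
  }
  opt <- function(col) {
    if (!is.null(col) && col %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[col]]))
    } else {
      NULL
    }
  }
  trajectory(
    t = parse_fix_times(raw[[dialect$time]], dialect$time_format,
                        dialect$time_tz),
    lat = suppressWarnings(as.numeric(raw[[dialect$lat]])),
    lon = suppressWarnings(as.numeric(raw[[dialect$lon]])),
    speed = opt(dialect$speed), heading = opt(dialect$heading),
    altitude = opt(dialect$altitude),
    subject_id = subject_id, tz = tz
  )
}

#' Read a GPX 1.1 track
#'
#' Maps `trkpt` elements (and their optional `time`/`ele` children) to fixes.
#' Recorded speed has no standard GPX home, so it is left unset and the
#' implied (displacement/time) speed is used downstream.
#'
#' @inheritParams read_fix_table
#' @return A trajectory tibble.
#' @export
read_gpx <- function(path, subject_id = "S1", tz = "UTC") {
  if (!file.exists(path)) abort(paste0("GPX file not found: ", path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("malformed GPX: ", conditionMessage(e)))
  })
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) == 0) abort("empty trajectory: GPX track has no points")
  times <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  ele <- suppressWarnings(
    as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./ele")))
  )
  trajectory(
    t = lubridate::as_datetime(times, tz = "UTC"),
    lat = as.numeric(xml2::xml_attr(pts, "lat")),
    lon = as.numeric(xml2::xml_attr(pts, "lon")),
    altitude = ele,
    subject_id = subject_id, tz = tz
  )
}

#' Write a GPX 1.1 track
#'
#' Inverse of [read_gpx()] for the generator's output; timestamps written as
#' ISO-8601 UTC.
#'
#' @param traj A trajectory tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(traj, path) {
  pt <- sprintf(
    '    <trkpt lat="%.7f" lon="%.7f"><time>%s</time></trkpt>',
    traj$lat, traj$lon,
    format(traj$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gpx version="1.1" creator="geovalid" xmlns="http://www.topografix.com/GPX/1/1">',
    "  <trk><trkseg>", pt, "  </trkseg></trk>", "</gpx>"
  ), path)
  invisible(path)
}

#' Write the per-stop activity report
#'
#' One CSV row per stop: arrival/departure (ISO-8601 UTC), centroid
#' coordinates (standing in for an estimated street address), distance from
#' the previous stop's centroid, dwell duration, fix count and flags. The
#' report round-trips through [read_activity_report()].
#'
#' @param stops A stop tibble from [detect_stops()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_report <- function(stops, path) {
  out <- tibble(
    arrive = format(stops$arrive_t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    depart = format(stops$depart_t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    centroid_lat = round(stops$centroid_lat, 7),
    centroid_lon = round(stops$centroid_lon, 7),
    prev_distance_m = round(stops$prev_distance_m, 3),
    duration_s = stops$duration_s,
    n_fixes = stops$n_fixes,
    radius_m = round(stops$radius_m, 3),
    gap_inferred = stops$gap_inferred,
    anomalous = stops$anomalous
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read an activity report back into a stop tibble
#'
#' @param path Path written by [write_activity_report()].
#' @return A stop tibble with the same columns as [detect_stops()] output.
#' @export
read_activity_report <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = "")
  if (nrow(raw) == 0) {
    return(empty_stop_tibble())
  }
  tibble(
    arrive_t = lubridate::as_datetime(raw$arrive, tz = "UTC"),
    depart_t = lubridate::as_datetime(raw$depart, tz = "UTC"),
    duration_s = as.numeric(raw$duration_s),
    centroid_lat = as.numeric(raw$centroid_lat),
    centroid_lon = as.numeric(raw$centroid_lon),
    radius_m = as.numeric(raw$radius_m),
    n_fixes = as.integer(raw$n_fixes),
    gap_inferred = as.logical(raw$gap_inferred),
    prev_distance_m = as.numeric(raw$prev_distance_m),
    anomalous = as.logical(raw$anomalous)
  )
}

empty_stop_tibble <- function() {
  tibble(
    arrive_t = lubridate::as_datetime(numeric(0)),
    depart_t = lubridate::as_datetime(numeric(0)),
    duration_s = numeric(0), centroid_lat = numeric(0),
    centroid_lon = numeric(0), radius_m = numeric(0),
    n_fixes = integer(0), gap_inferred = logical(0),
    prev_distance_m = numeric(0), anomalous = logical(0)
  )
}
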
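# Stay-point detection: convert a 1 Hz trajectory into ordered dwell
# episodes (stops), after screening movement anomalies (impossible speeds in
# random directions). The device records only while moving, so a recording
# gap bounded by near-identical positions is itself evidence of dwell.

#' Stop-detection configuration
#'
#' @param min_dwell_s Minimum dwell, seconds, for a window to count as a stop
#'   (default 600 s = 10 min; a dwell exactly equal counts).
#' @param eps_m Stationarity radius, metres: every fix in a stop window must
#'   lie within `eps_m` of the window's running centroid (default 50 m,
#'   consumer-GPS scatter).
#' @param max_speed_mph Anomaly speed bound (default 75 mph).
#' @param turn_deg Anomaly heading-change bound, degrees in (0, 180]
#'   (default 90): fast fixes are only anomalous when they also head off in
#'   an apparently random direction.
#' @param gap_dwell_eps_m Maximum displacement across a recording gap still
#'   counted as continued dwell (default `eps_m`).
#' @param gap_s Elapsed time between consecutive fixes above which the
#'   interval is treated as a recording gap rather than ordinary 1 Hz
#'   sampling (default 10 s).
#' @return A named list of parameters.
#' @export
stop_config <- function(min_dwell_s = 600, eps_m = 50, max_speed_mph = 75,
                        turn_deg = 90, gap_dwell_eps_m = eps_m, gap_s = 10) {
  stopifnot(
    min_dwell_s > 0, eps_m > 0, max_speed_mph > 0,
    turn_deg > 0, turn_deg <= 180, gap_dwell_eps_m > 0, gap_s > 0
  )
  list(
    min_dwell_s = min_dwell_s, eps_m = eps_m, max_speed_mph = max_speed_mph,
    turn_deg = turn_deg, gap_dwell_eps_m = gap_dwell_eps_m, gap_s = gap_s
  )
}

#' Flag movement-anomalous fixes
#'
#' A fix is flagged when its speed exceeds `max_speed_mph` (recorded speed if
#' present, otherwise the speed implied by displacement from the previous
#' fix) *and* its heading departs from the previous fix's heading by more
#' than `turn_deg` (circular difference). High speed on a steady bearing —
#' highway driving — is not anomalous. The first fix is never flagged.
#'
#' @param traj A trajectory tibble.
#' @param cfg A [stop_config()].
#' @return A logical vector, one element per fix.
#' @export
flag_anomalous_fixes <- function(traj, cfg = stop_config()) {
  n <- nrow(traj)
  if (n == 0) abort("empty trajectory")
  if (n == 1) return(FALSE)
  tnum <- as.numeric(traj$t)
  dt <- diff(tnum)
  step_m <- haversine_m(
    traj$lat[-n], traj$lon[-n], traj$lat[-1], traj$lon[-1]
  )
  implied <- step_m / dt * MPH_PER_MPS
  speed <- traj$speed
  fast <- (!is.na(speed[-1]) & speed[-1] > cfg$max_speed_mph) |
    implied > cfg$max_speed_mph
  # heading of each fix: recorded if present, else bearing from previous fix
  brg <- bearing_deg(traj$lat[-n], traj$lon[-n], traj$lat[-1], traj$lon[-1])
  hd <- traj$heading
  eff <- c(NA_real_, brg)
  eff[!is.na(hd)] <- hd[!is.na(hd)]
  turn <- heading_diff_deg(eff[-1], eff[-n])
  random_dir <- !is.na(turn) & turn > cfg$turn_deg
  c(FALSE, fast & random_dir)
}

#' Detect stops (stay points) in a trajectory
#'
#' Sweeps the unflagged fixes in time order, growing a window while each new
#' fix lies within `eps_m` of the window's running centroid. A recording gap
#' (elapsed time > `gap_s`) extends the window only if the displacement
#' across the gap is at most `gap_dwell_eps_m`; such windows are marked
#' `gap_inferred`. Maximal windows with dwell >= `min_dwell_s` become stops.
#'
#' @param traj A trajectory tibble.
#' @param cfg A [stop_config()].
#' @param mask Optional logical anomaly mask from [flag_anomalous_fixes()];
#'   computed from `traj` when omitted. Flagged fixes are excluded from stop
#'   formation.
#' @return A tibble of stops, ordered and non-overlapping, with columns
#'   `arrive_t`, `depart_t`, `duration_s`, `centroid_lat`, `centroid_lon`,
#'   `radius_m`, `n_fixes`, `gap_inferred`, `prev_distance_m`, `anomalous`.
#'   A stop inherits `anomalous = TRUE` when the flagged fixes falling inside
#'   its time window outnumber its member fixes.
#' @export
detect_stops <- function(traj, cfg = stop_config(), mask = NULL) {
  if (nrow(traj) == 0) abort("empty trajectory")
  if (is.null(mask)) mask <- flag_anomalous_fixes(traj, cfg)
  stopifnot(length(mask) == nrow(traj))
  flagged_t <- as.numeric(traj$t[mask])
  keep <- which(!mask)
  tnum <- as.numeric(traj$t)[keep]
  lat <- traj$lat[keep]
  lon <- traj$lon[keep]
  n <- length(tnum)
  if (n == 0) {
    return(empty_stop_tibble())
  }

  latr <- lat * pi / 180
  lonr <- lon * pi / 180
  R2 <- 2 * EARTH_RADIUS_M
  dist_rad <- function(p1, l1, p2, l2) {
    a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin((l2 - l1) / 2)^2
    R2 * asin(sqrt(min(max(a, 0), 1)))
  }

  out <- list()
  i <- 1L
  while (i <= n) {
    cp <- latr[i]
    cl <- lonr[i]
    m <- 1L
    gap_seen <- FALSE
    j <- i + 1L
    while (j <= n) {
      if (dist_rad(latr[j], lonr[j], cp, cl) > cfg$eps_m) break
      dt <- tnum[j] - tnum[j - 1L]
      if (dt > cfg$gap_s) {
        if (dist_rad(latr[j], lonr[j], latr[j - 1L], lonr[j - 1L]) >
              cfg$gap_dwell_eps_m) {
          break
        }
        gap_seen <- TRUE
      }
      m <- m + 1L
      cp <- cp + (latr[j] - cp) / m
      cl <- cl + (lonr[j] - cl) / m
      j <- j + 1L
    }
    last <- i + m - 1L
    dwell <- tnum[last] - tnum[i]
    if (dwell >= cfg$min_dwell_s) {
      idx <- i:last
      clat <- mean(lat[idx])
      clon <- mean(lon[idx])
      rad <- max(haversine_m(lat[idx], lon[idx], clat, clon))
      n_flag_in <- sum(flagged_t >= tnum[i] & flagged_t <= tnum[last])
      out[[length(out) + 1L]] <- list(
        arrive = tnum[i], depart = tnum[last], clat = clat, clon = clon,
        radius = rad, n_fixes = m, gap = gap_seen,
        anomalous = n_flag_in > m
      )
      i <- j
    } else {
      i <- i + 1L
    }
  }

  if (length(out) == 0) {
    return(empty_stop_tibble())
  }
  st <- tibble(
    arrive_t = lubridate::as_datetime(
      purrr::map_dbl(out, "arrive"), tz = "UTC"
    ),
    depart_t = lubridate::as_datetime(
      purrr::map_dbl(out, "depart"), tz = "UTC"
    ),
    duration_s = purrr::map_dbl(out, ~ .x$depart - .x$arrive),
    centroid_lat = purrr::map_dbl(out, "clat"),
    centroid_lon = purrr::map_dbl(out, "clon"),
    radius_m = purrr::map_dbl(out, "radius"),
    n_fixes = purrr::map_int(out, "n_fixes"),
    gap_inferred = purrr::map_lgl(out, "gap"),
    anomalous = purrr::map_lgl(out, "anomalous")
  )
  recompute_prev_distance(st)
}

recompute_prev_distance <- function(stops) {
  k <- nrow(stops)
  pd <- rep(NA_real_, k)
  if (k >= 2) {
    pd[-1] <- haversine_m(
      stops$centroid_lat[-k], stops$centroid_lon[-k],
      stops$centroid_lat[-1], stops$centroid_lon[-1]
    )
  }
  stops$prev_distance_m <- pd
  dplyr::relocate(stops, "prev_distance_m", .before = "anomalous")
}

#' Drop stops caused by movement anomalies
#'
#' Removes stops carrying `anomalous = TRUE`, preserves ordering and
#' recomputes the distance between consecutive surviving stop centroids.
#'
#' @param stops A stop tibble.
#' @return The filtered stop tibble.
#' @export
remove_anomalous_stops <- function(stops) {
  recompute_prev_distance(stops[!stops$anomalous, ])
}
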
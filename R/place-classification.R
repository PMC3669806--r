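# Promotion of stops to counted place visits and aggregation to NPV.
# The original protocol's manual map inspection (same address / same
# building / obviously in transit) is replaced by distance and
# bearing-continuity proxies; every stop receives an audit label.

#' Place-classification configuration
#'
#' @param merge_identical_m Centroid distance, metres, at or below which two
#'   consecutive stops are treated as one visit to an identical location
#'   (default 30 m).
#' @param merge_building_m Centroid distance, metres, at or below which two
#'   consecutive stops are treated as one visit to the same building or
#'   parcel (default 75 m). Must be >= `merge_identical_m`.
#' @param transit_bearing_deg Bearing-continuity tolerance, degrees, for the
#'   in-transit rule (default 30).
#' @param transit_max_dwell_s Maximum dwell, seconds, for a stop to be
#'   droppable as in-transit (default 900 s).
#' @param transit_rule_enabled Whether the in-transit rule runs (default
#'   `TRUE`).
#' @return A named list of parameters.
#' @export
classify_config <- function(merge_identical_m = 30, merge_building_m = 75,
                            transit_bearing_deg = 30,
                            transit_max_dwell_s = 900,
                            transit_rule_enabled = TRUE) {
  stopifnot(merge_identical_m <= merge_building_m)
  list(
    merge_identical_m = merge_identical_m,
    merge_building_m = merge_building_m,
    transit_bearing_deg = transit_bearing_deg,
    transit_max_dwell_s = transit_max_dwell_s,
    transit_rule_enabled = transit_rule_enabled
  )
}

#' Classify stops into place visits
#'
#' Applies, in order: the anomaly label (stops still flagged anomalous are
#' never counted), the in-transit rule (a short stop whose inbound and
#' outbound travel bearings agree within `transit_bearing_deg` is a pause in
#' transit, not a place), and the consecutive-merge rules (centroids at most
#' `merge_identical_m` apart merge as an identical location; between that
#' and `merge_building_m`, as the same building). Non-consecutive revisits
#' to the same coordinates each count as separate visits: NPV counts visit
#' events, not unique places.
#'
#' @param stops A stop tibble (ordered; anomalies normally already removed).
#' @param cfg A [classify_config()].
#' @param tz IANA timezone for local-day assignment.
#' @return A tibble with one row per input stop: the stop columns plus
#'   `local_day` (Date of arrival in `tz`), `day_type`
#'   (`"weekday"`/`"weekend"`), `counted` and `rule_applied` (one of
#'   `counted`, `merged_same_location`, `merged_same_building`,
#'   `dropped_in_transit`, `dropped_anomaly`).
#' @export
classify_stops <- function(stops, cfg = classify_config(), tz = "UTC") {
  k <- nrow(stops)
  local_arrive <- lubridate::with_tz(stops$arrive_t, tz)
  local_day <- as.Date(local_arrive, tz = tz)
  wd <- lubridate::wday(local_arrive, week_start = 1) # 1 = Mon .. 7 = Sun
  day_type <- if_else(wd >= 6, "weekend", "weekday")
  rule <- rep("counted", k)

  rule[stops$anomalous] <- "dropped_anomaly"

  if (cfg$transit_rule_enabled && k >= 3) {
    for (i in 2:(k - 1)) {
      if (rule[i] != "counted") next
      inb <- bearing_deg(
        stops$centroid_lat[i - 1], stops$centroid_lon[i - 1],
        stops$centroid_lat[i], stops$centroid_lon[i]
      )
      outb <- bearing_deg(
        stops$centroid_lat[i], stops$centroid_lon[i],
        stops$centroid_lat[i + 1], stops$centroid_lon[i + 1]
      )
      if (heading_diff_deg(inb, outb) <= cfg$transit_bearing_deg &&
            stops$duration_s[i] <= cfg$transit_max_dwell_s) {
        rule[i] <- "dropped_in_transit"
      }
    }
  }

  # consecutive-merge sweep: compare each surviving stop to the centroid of
  # the previous *counted* visit, so chains of near-coincident stops collapse
  # to one visit (idempotent at the visit-count level)
  last_counted <- NA_integer_
  for (i in seq_len(k)) {
    if (rule[i] != "counted") next
    if (!is.na(last_counted)) {
      d <- haversine_m(
        stops$centroid_lat[last_counted], stops$centroid_lon[last_counted],
        stops$centroid_lat[i], stops$centroid_lon[i]
      )
      if (d <= cfg$merge_identical_m) {
        rule[i] <- "merged_same_location"
        next
      } else if (d <= cfg$merge_building_m) {
        rule[i] <- "merged_same_building"
        next
      }
    }
    last_counted <- i
  }

  stops %>%
    mutate(
      local_day = local_day,
      day_type = day_type,
      counted = rule == "counted",
      rule_applied = rule
    )
}

#' Count place visits per local calendar day
#'
#' Buckets counted visits by the local day of arrival (a visit spanning
#' midnight is credited to its arrival day).
#'
#' @param visits A classified visit tibble from [classify_stops()].
#' @return A tibble with `local_day`, `day_type` and `npv`; days with no
#'   counted visits are absent.
#' @export
count_daily_npv <- function(visits) {
  visits %>%
    filter(.data$counted) %>%
    count(.data$local_day, .data$day_type, name = "npv")
}

#' Validate a 2 + 2 study calendar
#'
#' @param calendar Four `Date`s: exactly two weekdays and two weekend days.
#' @return The calendar, sorted, invisibly usable.
#' @export
study_calendar <- function(calendar) {
  calendar <- sort(as.Date(calendar))
  if (length(calendar) != 4) {
    abort("study_calendar: exactly 4 dates are required")
  }
  if (anyDuplicated(calendar)) {
    abort("study_calendar: the 4 dates must be distinct")
  }
  wd <- lubridate::wday(calendar, week_start = 1)
  n_we <- sum(wd >= 6)
  if (n_we != 2) {
    abort(paste0(
      "study_calendar: need 2 weekday + 2 weekend dates, got ",
      4 - n_we, " + ", n_we
    ))
  }
  calendar
}

#' Aggregate daily visit counts to period NPV records
#'
#' Sums counted visits over the study calendar into weekday, weekend and
#' 4-day totals. Days outside the calendar (e.g. partial first/last days)
#' are excluded from every aggregate. The conservation identity
#' weekday + weekend = total4day holds by construction and is asserted.
#'
#' @param daily A daily count tibble from [count_daily_npv()].
#' @param calendar Four dates, two weekday + two weekend ([study_calendar()]).
#' @param subject_id Subject identifier for the output records.
#' @param method Measurement method label (default `"GPS"`).
#' @return A tibble with `subject_id`, `method`, `period`
#'   (`weekday`/`weekend`/`total4day`) and `npv`.
#' @export
aggregate_npv <- function(daily, calendar, subject_id = "S1",
                          method = "GPS") {
  calendar <- study_calendar(calendar)
  inside <- daily[daily$local_day %in% calendar, ]
  wk <- sum(inside$npv[inside$day_type == "weekday"])
  we <- sum(inside$npv[inside$day_type == "weekend"])
  out <- tibble(
    subject_id = subject_id,
    method = method,
    period = c("weekday", "weekend", "total4day"),
    npv = as.integer(c(wk, we, wk + we))
  )
  stopifnot(out$npv[3] == out$npv[1] + out$npv[2])
  out
}

#' GPS fixes to NPV records, end to end
#'
#' Convenience wrapper: anomaly screen, stop detection, anomalous-stop
#' removal, classification and calendar aggregation in one call.
#'
#' @param traj A trajectory tibble.
#' @param calendar Four dates ([study_calendar()]).
#' @param stop_cfg A [stop_config()].
#' @param classify_cfg A [classify_config()].
#' @return A list with `npv` (three NPV records), `visits` (the audit
#'   table) and `stops`.
#' @export
extract_npv <- function(traj, calendar, stop_cfg = stop_config(),
                        classify_cfg = classify_config()) {
  tz <- trajectory_tz(traj)
  stops <- detect_stops(traj, stop_cfg)
  stops <- remove_anomalous_stops(stops)
  visits <- classify_stops(stops, classify_cfg, tz = tz)
  daily <- count_daily_npv(visits)
  npv <- aggregate_npv(
    daily, calendar,
    subject_id = attr(traj, "subject_id") %||% "S1"
  )
  list(npv = npv, visits = visits, stops = stops)
}
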
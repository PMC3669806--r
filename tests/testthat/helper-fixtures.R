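# Fixture builders shared across the suite. Everything is generated in code;
# no stored data.

utc <- function(x) lubridate::as_datetime(x, tz = "UTC")

# fixes jittered around one point; dt seconds apart
dwell_fixes <- function(lat0, lon0, t0, n, dt = 5, jitter_m = 0) {
  t <- t0 + seq(0, by = dt, length.out = n)
  if (jitter_m > 0) {
    lat <- lat0 + rnorm(n, 0, jitter_m) / 111320
    lon <- lon0 + rnorm(n, 0, jitter_m) / (111320 * cos(lat0 * pi / 180))
  } else {
    lat <- rep(lat0, n)
    lon <- rep(lon0, n)
  }
  list(t = t, lat = lat, lon = lon)
}

# straight-line traverse at constant speed (m/s), 1 fix per `dt` seconds
traverse_fixes <- function(lat0, lon0, bearing, speed_mps, dur_s, t0, dt = 1) {
  t <- t0 + seq(0, dur_s, by = dt)
  d <- seq(0, dur_s, by = dt) * speed_mps
  p <- dest_point(lat0, lon0, bearing, d)
  list(t = t, lat = p$lat, lon = p$lon)
}

cat_fixes <- function(...) {
  parts <- list(...)
  list(
    t = do.call(c, lapply(parts, `[[`, "t")),
    lat = do.call(c, lapply(parts, `[[`, "lat")),
    lon = do.call(c, lapply(parts, `[[`, "lon"))
  )
}

as_traj <- function(fx, ...) trajectory(fx$t, fx$lat, fx$lon, ...)

# hand-built stop tibble from centroids + arrival times + durations
make_stops <- function(lat, lon, arrive, duration_s, anomalous = FALSE) {
  k <- length(lat)
  st <- tibble::tibble(
    arrive_t = utc(arrive),
    depart_t = utc(arrive) + duration_s,
    duration_s = duration_s,
    centroid_lat = lat, centroid_lon = lon,
    radius_m = 0, n_fixes = 10L, gap_inferred = FALSE,
    prev_distance_m = NA_real_,
    anomalous = rep_len(anomalous, k)
  )
  geovalid:::recompute_prev_distance(st)
}

# independent nested-refit oracle: sequential SS as residual-SS differences
# of cumulative lm() fits
lm_sequential_ss <- function(long, terms) {
  rhs <- character()
  prev_rss <- sum((long$npv - mean(long$npv))^2)
  ss <- numeric(length(terms))
  for (i in seq_along(terms)) {
    rhs <- c(rhs, terms[i])
    m <- stats::lm(
      stats::as.formula(paste("npv ~", paste(rhs, collapse = "+"))),
      data = long
    )
    rss <- sum(stats::residuals(m)^2)
    ss[i] <- prev_rss - rss
    prev_rss <- rss
  }
  ss
}

# small random unbalanced study long-table (true latents as covariates)
random_long_table <- function(n_subjects, drop = 2) {
  lat <- simulate_latents(n_subjects, -0.3)
  g <- tidyr::expand_grid(
    subject_id = lat$subject_id,
    period = c("weekday", "weekend"),
    method = c("Diary", "Google", "GPS")
  )
  g$npv <- as.integer(rpois(nrow(g), 12))
  if (drop > 0) g <- g[-sample(nrow(g), drop), ]
  build_long_table(
    g,
    dplyr::transmute(lat, subject_id, AL = AL_true, SL = SL_true)
  )
}
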
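# Synthetic study generator. Emulates everything the pipeline consumes —
# latent lifestyle factors, questionnaire indicators, per-period true visit
# counts, day-level itineraries rendered as 1 Hz GPS trajectories with
# noise/dropout/anomalies, recall-error self-reports and MCAR missingness —
# with the ground truth retained so recovery can be tested end to end.
#
# All randomness flows through R's RNG: set.seed() once (or call
# simulate_study(seed = )) and every generated byte is reproducible.

#' Simulation configuration
#'
#' Defaults are the study conditions the analysis models assume: 96
#' subjects; a 2-weekday + 2-weekend calendar; structural NPV model
#' intercept 11.87, AL slope 1.79, Time (weekend - weekday) effect -3.68
#' per two-day period, no SL effect; latent AL/SL correlation -0.30;
#' indicator loadings and moments from [indicator_metadata()].
#'
#' @param n_subjects Number of subjects.
#' @param calendar Four dates, two weekday + two weekend.
#' @param tz IANA timezone for local-day assignment.
#' @param intercept,b_AL,b_SL,b_Time Structural coefficients of the
#'   period-level NPV model (Time coded -1/2 weekday, +1/2 weekend).
#' @param subject_sd SD of the per-subject random intercept (places).
#' @param truth_sd SD of period-level behavioural noise (places).
#' @param count_model `"gaussian"` (rounded, floored at 0; matches the
#'   linear analysis) or `"poisson"`.
#' @param latent_corr Correlation of the latent AL and SL factors.
#' @param loadings Indicator metadata tibble ([indicator_metadata()]).
#' @param gps List: `fix_rate_hz`, `noise_sd_m`, `dropout_when_stationary`,
#'   `anomaly_rate` (per eligible travel fix), `travel_speed_mph`,
#'   `place_ring_m` (radius of the place ring around home), `n_places`
#'   (pool size), `dwell_s` (planned dwell), `dwell_jitter_s`,
#'   `max_visits_per_day`.
#' @param reports List of self-report error parameters per method:
#'   `p_recall_diary`, `p_recall_google` (binomial recall thinning),
#'   `false_rate_diary`, `false_rate_google` (Poisson false reports),
#'   `noise_sd_diary`, `noise_sd_google`, `noise_sd_gps` (additive
#'   rounded-Gaussian reporting error; the mean-preserving default, matching
#'   the absence of method mean differences the validity analysis assumes).
#' @param missing_rate MCAR deletion probability per subject x task cell.
#' @param render_gps If `TRUE`, [simulate_study()] renders trajectories and
#'   measures GPS NPV through the full detection pipeline; if `FALSE`
#'   (default), the GPS method observes the true counts plus
#'   `noise_sd_gps` error.
#' @param movement If `FALSE`, skip itinerary construction entirely (useful
#'   for model-level replicate studies that never touch trajectories);
#'   forced `TRUE` when `render_gps` is `TRUE`.
#' @return A nested configuration list.
#' @export
sim_config <- function(n_subjects = 96,
                       calendar = as.Date(c(
                         "2010-11-04", "2010-11-05",
                         "2010-11-06", "2010-11-07"
                       )),
                       tz = "America/Phoenix",
                       intercept = 11.87, b_AL = 1.79, b_SL = 0,
                       b_Time = -3.68,
                       subject_sd = 3, truth_sd = 2,
                       count_model = c("gaussian", "poisson"),
                       latent_corr = -0.30,
                       loadings = indicator_metadata(),
                       gps = list(),
                       reports = list(),
                       missing_rate = 0,
                       render_gps = FALSE,
                       movement = TRUE) {
  gps_def <- list(
    fix_rate_hz = 1, noise_sd_m = 0, dropout_when_stationary = TRUE,
    anomaly_rate = 0, travel_speed_mph = 25, place_ring_m = 1500,
    n_places = 40, dwell_s = 1200, dwell_jitter_s = 300,
    max_visits_per_day = 25,
    home_lat = 32.2319, home_lon = -110.9501
  )
  rep_def <- list(
    p_recall_diary = 1, p_recall_google = 1,
    false_rate_diary = 0, false_rate_google = 0,
    noise_sd_diary = 4, noise_sd_google = 4, noise_sd_gps = 0
  )
  gps <- utils::modifyList(gps_def, gps)
  reports <- utils::modifyList(rep_def, reports)
  stopifnot(
    abs(latent_corr) < 1, missing_rate >= 0, missing_rate < 1,
    reports$p_recall_diary >= 0, reports$p_recall_diary <= 1,
    reports$p_recall_google >= 0, reports$p_recall_google <= 1
  )
  list(
    n_subjects = n_subjects, calendar = study_calendar(calendar), tz = tz,
    intercept = intercept, b_AL = b_AL, b_SL = b_SL, b_Time = b_Time,
    subject_sd = subject_sd, truth_sd = truth_sd,
    count_model = match.arg(count_model),
    latent_corr = latent_corr, loadings = loadings,
    gps = gps, reports = reports, missing_rate = missing_rate,
    render_gps = render_gps, movement = movement || render_gps
  )
}

subject_ids <- function(n) sprintf("S%03d", seq_len(n))

#' Draw latent AL and SL factors
#'
#' Standard bivariate normal with the configured correlation.
#'
#' @param n Number of subjects.
#' @param corr Latent correlation, |corr| < 1.
#' @return A tibble `subject_id`, `AL_true`, `SL_true`.
#' @export
simulate_latents <- function(n, corr = -0.30) {
  stopifnot(abs(corr) < 1)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  tibble(
    subject_id = subject_ids(n),
    AL_true = z1,
    SL_true = corr * z1 + sqrt(1 - corr^2) * z2
  )
}

#' Simulate questionnaire indicators from the latents
#'
#' Each indicator's z-score is `loading * latent + sqrt(1 - loading^2) *
#' noise` (SWL loads negatively on SL before analysis-time reversal), then
#' rescaled to the declared population mean/SD and clipped to the possible
#' range.
#'
#' @param latents A tibble from [simulate_latents()].
#' @param loadings Indicator metadata ([indicator_metadata()]).
#' @return A tibble `subject_id` plus one column per indicator.
#' @export
simulate_indicators <- function(latents, loadings = indicator_metadata()) {
  n <- nrow(latents)
  out <- tibble(subject_id = latents$subject_id)
  for (i in seq_len(nrow(loadings))) {
    m <- loadings[i, ]
    latent <- if (m$factor == "AL") latents$AL_true else latents$SL_true
    lam <- m$loading
    z <- lam * latent + sqrt(1 - lam^2) * rnorm(n)
    x <- m$mean + m$sd * z
    out[[m$indicator]] <- pmin(pmax(x, m$min), m$max)
  }
  out
}

#' Simulate true per-period visit counts
#'
#' Period-level mean: intercept + b_AL * AL + b_SL * SL + b_Time * Time
#' (+/- 1/2) + subject effect; counts are the floored-at-zero rounded
#' Gaussian (or Poisson) realization.
#'
#' @param latents A tibble from [simulate_latents()].
#' @param cfg A [sim_config()].
#' @return A tibble `subject_id`, `period`, `Time`, `mu`, `npv_true` with
#'   two rows (weekday/weekend) per subject.
#' @export
simulate_true_npv <- function(latents, cfg = sim_config()) {
  n <- nrow(latents)
  subj_eff <- rnorm(n, 0, cfg$subject_sd)
  grid <- tidyr::expand_grid(
    idx = seq_len(n),
    period = c("weekday", "weekend")
  )
  grid$Time <- if_else(grid$period == "weekend", 0.5, -0.5)
  mu <- cfg$intercept + cfg$b_AL * latents$AL_true[grid$idx] +
    cfg$b_SL * latents$SL_true[grid$idx] + cfg$b_Time * grid$Time +
    subj_eff[grid$idx]
  npv <- if (cfg$count_model == "poisson") {
    rpois(nrow(grid), pmax(mu, 0))
  } else {
    pmax(0, round(mu + rnorm(nrow(grid), 0, cfg$truth_sd)))
  }
  tibble(
    subject_id = latents$subject_id[grid$idx],
    period = grid$period, Time = grid$Time, mu = mu,
    npv_true = as.integer(npv),
    subject_effect = subj_eff[grid$idx]
  )
}

#' Allocate period counts to the calendar days
#'
#' Each true visit in a period lands uniformly on one of the period's two
#' days, capped at the itinerary's feasible per-day maximum.
#'
#' @param truth A tibble from [simulate_true_npv()].
#' @param cfg A [sim_config()].
#' @return A tibble `subject_id`, `local_day`, `day_type`, `n_visits`; the
#'   realized (post-cap) day counts are the generator's ground truth.
#' @export
allocate_visit_days <- function(truth, cfg = sim_config()) {
  cal <- cfg$calendar
  wd <- lubridate::wday(cal, week_start = 1)
  days <- tibble(
    local_day = cal,
    day_type = if_else(wd >= 6, "weekend", "weekday")
  )
  purrr::pmap_dfr(truth, function(subject_id, period, npv_true, ...) {
    dd <- days$local_day[days$day_type == period]
    first <- rbinom(1, npv_true, 0.5)
    k <- pmin(c(first, npv_true - first), cfg$gps$max_visits_per_day)
    tibble(
      subject_id = subject_id, local_day = dd, day_type = period,
      n_visits = as.integer(k)
    )
  }) %>%
    arrange(.data$subject_id, .data$local_day)
}

local_time <- function(day, hms, tz) {
  lubridate::force_tz(lubridate::as_datetime(day) + hms, tz)
}

#' Build ground-truth itineraries
#'
#' Lays out a pool of places on a ring around each subject's home (spacing
#' well above the merge radius so true NPV is identifiable), then schedules
#' each day's visits: travel legs at constant speed, dwells of
#' `dwell_s` + jitter, overnight dwell at the day's last place. Consecutive
#' places are always distinct, so no true visit is lost to the
#' consecutive-merge rules.
#'
#' @param day_counts A tibble from [allocate_visit_days()].
#' @param cfg A [sim_config()].
#' @return A tibble of true visits: `subject_id`, `place_id`, `lat`, `lon`,
#'   `arrive_t`, `depart_t` (UTC), `local_day`. The first row per subject
#'   is the pre-study home dwell (its `local_day` precedes the calendar).
#' @export
simulate_itineraries <- function(day_counts, cfg = sim_config()) {
  g <- cfg$gps
  speed_mps <- g$travel_speed_mph / MPH_PER_MPS
  subs <- unique(day_counts$subject_id)
  purrr::map_dfr(subs, function(sid) {
    # home and place ring; >= 4x the stationarity radius between places
    home <- dest_point(
      g$home_lat, g$home_lon, runif(1, 0, 360), runif(1, 0, 20000)
    )
    ang <- (seq_len(g$n_places) - 1) * 360 / g$n_places
    ring <- dest_point(home$lat, home$lon, ang, g$place_ring_m)
    plat <- c(home$lat, ring$lat)
    plon <- c(home$lon, ring$lon)

    dc <- day_counts[day_counts$subject_id == sid, ]
    dc <- dc[order(dc$local_day), ]
    nv <- sum(dc$n_visits) + 1L
    v_place <- integer(nv)
    v_arr <- v_dep <- numeric(nv)
    r <- 0L
    cur_place <- 1L # home (index into plat/plon; place_id = index - 1)
    cur_arrive <- as.numeric(
      local_time(min(dc$local_day) - 1, lubridate::hms("22:00:00"), cfg$tz)
    )
    for (d in seq_len(nrow(dc))) {
      k <- dc$n_visits[d]
      if (k == 0) next
      t0 <- as.numeric(
        local_time(dc$local_day[d], lubridate::hms("08:30:00"), cfg$tz)
      ) + floor(runif(1, 0, 1800))
      dests <- 1L + sample(setdiff(seq_len(g$n_places), cur_place - 1L), k)
      depart <- t0
      for (j in seq_len(k)) {
        r <- r + 1L
        v_place[r] <- cur_place
        v_arr[r] <- cur_arrive
        v_dep[r] <- depart
        leg_m <- haversine_m(plat[cur_place], plon[cur_place],
                             plat[dests[j]], plon[dests[j]])
        cur_arrive <- depart + ceiling(leg_m / speed_mps)
        cur_place <- dests[j]
        depart <- cur_arrive + g$dwell_s + floor(runif(1, 0, g$dwell_jitter_s))
      }
    }
    end_t <- as.numeric(
      local_time(max(dc$local_day), lubridate::hms("23:00:00"), cfg$tz)
    )
    r <- r + 1L
    v_place[r] <- cur_place
    v_arr[r] <- cur_arrive
    v_dep[r] <- max(end_t, cur_arrive + g$dwell_s)
    arrive_t <- lubridate::as_datetime(v_arr, tz = "UTC")
    tibble(
      subject_id = sid, place_id = v_place - 1L,
      lat = plat[v_place], lon = plon[v_place],
      arrive_t = arrive_t,
      depart_t = lubridate::as_datetime(v_dep, tz = "UTC"),
      local_day = as.Date(lubridate::with_tz(arrive_t, cfg$tz), tz = cfg$tz)
    )
  })
}

#' Render an itinerary as a 1 Hz trajectory
#'
#' Travel legs get one fix per second interpolated between the endpoints
#' with the leg speed and bearing recorded; dwells get either boundary
#' fixes only (`dropout_when_stationary`, emulating motion-triggered
#' recording) or 1 Hz jittered fixes. Gaussian positional noise
#' (`noise_sd_m`) is added to every fix. Teleport anomalies are injected
#' afterwards via [inject_anomalies()] when `anomaly_rate > 0`.
#'
#' @param itinerary Visit rows for one subject ([simulate_itineraries()]).
#' @param cfg A [sim_config()].
#' @return A trajectory tibble.
#' @export
render_trajectory <- function(itinerary, cfg = sim_config()) {
  g <- cfg$gps
  it <- itinerary[order(itinerary$arrive_t), ]
  n <- nrow(it)
  if (n >= 2 && any(as.numeric(it$arrive_t[-1]) <
                      as.numeric(it$depart_t[-n]))) {
    abort("render_trajectory: overlapping itinerary entries")
  }
  step <- 1 / g$fix_rate_hz
  tt <- lat <- lon <- spd <- hdg <- list()
  add <- function(t, la, lo, sp, hd) {
    i <- length(tt) + 1L
    tt[[i]] <<- t
    lat[[i]] <<- la
    lon[[i]] <<- lo
    spd[[i]] <<- sp
    hdg[[i]] <<- hd
  }
  for (i in seq_len(n)) {
    a <- as.numeric(it$arrive_t[i])
    d <- as.numeric(it$depart_t[i])
    if (g$dropout_when_stationary) {
      add(c(a, d), rep(it$lat[i], 2), rep(it$lon[i], 2), c(0, 0),
          c(NA_real_, NA_real_))
    } else {
      ts <- seq(a, d, by = step)
      add(ts, rep(it$lat[i], length(ts)), rep(it$lon[i], length(ts)),
          rep(0, length(ts)), rep(NA_real_, length(ts)))
    }
    if (i < n) {
      a2 <- as.numeric(it$arrive_t[i + 1])
      if (a2 - d <= 2 * step) next
      ts <- seq(d + step, a2 - step, by = step)
      if (length(ts) > 0 && ts[1] < a2) {
        frac <- (ts - d) / (a2 - d)
        la <- it$lat[i] + frac * (it$lat[i + 1] - it$lat[i])
        lo <- it$lon[i] + frac * (it$lon[i + 1] - it$lon[i])
        leg_m <- haversine_m(it$lat[i], it$lon[i],
                             it$lat[i + 1], it$lon[i + 1])
        add(ts, la, lo,
            rep(leg_m / (a2 - d) * MPH_PER_MPS, length(ts)),
            rep(bearing_deg(it$lat[i], it$lon[i],
                            it$lat[i + 1], it$lon[i + 1]), length(ts)))
      }
    }
  }
  tt <- unlist(tt)
  lat <- unlist(lat)
  lon <- unlist(lon)
  if (g$noise_sd_m > 0) {
    lat <- lat + rnorm(length(lat), 0, g$noise_sd_m) / 111320
    lon <- lon + rnorm(length(lon), 0, g$noise_sd_m) /
      (111320 * cos(lat * pi / 180))
  }
  traj <- trajectory(
    t = lubridate::as_datetime(tt, tz = "UTC"),
    lat = lat, lon = lon, speed = unlist(spd), heading = unlist(hdg),
    subject_id = it$subject_id[1], tz = cfg$tz
  )
  if (g$anomaly_rate > 0) {
    traj <- inject_anomalies(traj, g$anomaly_rate)
  }
  traj
}

#' Inject teleport anomalies into a trajectory
#'
#' After each selected interior travel fix (both it and its successor
#' moving), inserts a single fix 10-20 km away on a bearing turned
#' 100-180 degrees off-course, with a high recorded speed — the
#' "impossible speed in a random direction" spike the anomaly screen is
#' built to catch. Selection is i.i.d. with probability `rate`.
#'
#' @param traj A trajectory tibble.
#' @param rate Per-eligible-fix insertion probability.
#' @return The trajectory with teleports inserted (attribute `n_injected`;
#'   attribute `injected_t` holds their timestamps).
#' @export
inject_anomalies <- function(traj, rate) {
  n <- nrow(traj)
  moving <- !is.na(traj$speed) & traj$speed > 1
  eligible <- which(moving & dplyr::lead(moving, default = FALSE) &
                      !is.na(traj$heading))
  sel <- eligible[runif(length(eligible)) < rate]
  if (length(sel) == 0) {
    attr(traj, "n_injected") <- 0L
    return(traj)
  }
  off <- sample(c(-1, 1), length(sel), replace = TRUE) *
    runif(length(sel), 100, 180)
  pos <- dest_point(
    traj$lat[sel], traj$lon[sel],
    (traj$heading[sel] + off) %% 360,
    runif(length(sel), 10000, 20000)
  )
  tele <- tibble(
    t = traj$t[sel] + 0.4,
    lat = pos$lat, lon = pos$lon,
    speed = runif(length(sel), 150, 500),
    heading = (traj$heading[sel] + off) %% 360,
    altitude = NA_real_
  )
  out <- dplyr::bind_rows(tibble::as_tibble(traj), tele) %>% arrange(.data$t)
  attr(out, "subject_id") <- attr(traj, "subject_id", exact = TRUE)
  attr(out, "tz") <- attr(traj, "tz", exact = TRUE)
  attr(out, "n_injected") <- length(sel)
  attr(out, "injected_t") <- tele$t
  out
}

#' Simulate self-reported NPV from true counts
#'
#' Recall model per period: each true visit is independently recalled with
#' probability `p_recall` (binomial thinning), Poisson false reports with
#' mean `false_rate` are added, plus a rounded mean-zero Gaussian reporting
#' error; the result is floored at zero.
#'
#' @param npv_true Integer vector of true per-period counts.
#' @param p_recall Recall probability in `[0, 1]`.
#' @param false_rate Poisson mean of false reports per period.
#' @param noise_sd SD of the additive reporting error.
#' @return An integer vector of reported counts.
#' @export
simulate_self_reports <- function(npv_true, p_recall = 1, false_rate = 0,
                                  noise_sd = 0) {
  n <- length(npv_true)
  rep_ <- rbinom(n, npv_true, p_recall)
  if (false_rate > 0) rep_ <- rep_ + rpois(n, false_rate)
  if (noise_sd > 0) rep_ <- rep_ + round(rnorm(n, 0, noise_sd))
  as.integer(pmax(0, rep_))
}

#' Apply MCAR missingness at the subject x task level
#'
#' Deletes each (subject, task) cell independently with probability `rate`,
#' where tasks are the three NPV methods and each questionnaire indicator.
#' Emits the 0/1 completion matrix for [missingness_screen()].
#'
#' @param reports Long NPV records (`subject_id`, `method`, `period`,
#'   `npv`).
#' @param indicators Indicator tibble (`subject_id` + indicator columns).
#' @param rate Deletion probability in `[0, 1)`.
#' @return A list `reports`, `indicators` (cells blanked to `NA`) and
#'   `completion` (subject x task 0/1 tibble).
#' @export
apply_mcar <- function(reports, indicators, rate) {
  stopifnot(rate >= 0, rate < 1)
  subs <- sort(unique(c(reports$subject_id, indicators$subject_id)))
  methods <- unique(reports$method)
  ind_cols <- setdiff(names(indicators), "subject_id")
  tasks <- c(methods, ind_cols)
  comp <- matrix(
    rbinom(length(subs) * length(tasks), 1, 1 - rate),
    nrow = length(subs), dimnames = list(subs, tasks)
  )
  for (m in methods) {
    gone <- subs[comp[, m] == 0]
    reports$npv[reports$method == m &
                  reports$subject_id %in% gone] <- NA_integer_
  }
  for (cl in ind_cols) {
    gone <- subs[comp[, cl] == 0]
    indicators[[cl]][indicators$subject_id %in% gone] <- NA_real_
  }
  completion <- tibble(subject_id = subs) %>%
    dplyr::bind_cols(tibble::as_tibble(comp))
  list(reports = reports, indicators = indicators, completion = completion)
}

period_records <- function(subject_id, period, npv) {
  tibble(subject_id = subject_id, period = period, npv = as.integer(npv))
}

add_total_records <- function(records) {
  totals <- records %>%
    filter(.data$period %in% c("weekday", "weekend")) %>%
    group_by(.data$subject_id, .data$method) %>%
    summarise(
      npv = if (any(is.na(.data$npv))) NA_integer_
      else as.integer(sum(.data$npv)),
      .groups = "drop"
    ) %>%
    mutate(period = "total4day")
  dplyr::bind_rows(records, totals)
}

#' Simulate a complete study
#'
#' End-to-end generation under one seed: latents, indicators, true
#' per-period counts, day allocation, itineraries (and, when
#' `cfg$render_gps`, rendered trajectories measured through the full stop
#' detection / classification pipeline), Diary and Google self-reports,
#' GPS records, MCAR missingness and the assembled long table.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A list: `config`, `latents`, `indicators`, `truth` (per-period
#'   counts), `day_counts`, `itineraries`, `trajectories` (list, only when
#'   rendered), `reports` (long NPV records incl. totals), `factors`
#'   (unit-weighted scores), `completion`, `long` (model-ready table).
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  latents <- simulate_latents(cfg$n_subjects, cfg$latent_corr)
  indicators <- simulate_indicators(latents, cfg$loadings)
  truth <- simulate_true_npv(latents, cfg)
  day_counts <- allocate_visit_days(truth, cfg)
  # realized (post-cap) ground truth at period level
  truth <- day_counts %>%
    group_by(.data$subject_id, period = .data$day_type) %>%
    summarise(npv_true = sum(.data$n_visits), .groups = "drop") %>%
    left_join(
      truth %>% select("subject_id", "period", "Time", "mu",
                       "subject_effect"),
      by = c("subject_id", "period")
    )
  itineraries <- if (cfg$movement) {
    simulate_itineraries(day_counts, cfg)
  } else {
    NULL
  }

  rp <- cfg$reports
  diary <- truth %>%
    mutate(
      method = "Diary",
      npv = simulate_self_reports(.data$npv_true, rp$p_recall_diary,
                                  rp$false_rate_diary, rp$noise_sd_diary)
    )
  google <- truth %>%
    mutate(
      method = "Google",
      npv = simulate_self_reports(.data$npv_true, rp$p_recall_google,
                                  rp$false_rate_google, rp$noise_sd_google)
    )

  trajectories <- NULL
  if (cfg$render_gps) {
    subs <- unique(itineraries$subject_id)
    trajectories <- purrr::map(
      stats::setNames(subs, subs),
      function(sid) {
        render_trajectory(itineraries[itineraries$subject_id == sid, ], cfg)
      }
    )
    gps <- purrr::map_dfr(trajectories, function(traj) {
      extract_npv(traj, cfg$calendar)$npv
    }) %>%
      filter(.data$period != "total4day") %>%
      mutate(method = "GPS")
  } else {
    gps <- truth %>%
      mutate(
        method = "GPS",
        npv = simulate_self_reports(.data$npv_true, 1, 0, rp$noise_sd_gps)
      )
  }

  keep <- c("subject_id", "method", "period", "npv")
  reports <- dplyr::bind_rows(diary[keep], google[keep], gps[keep])

  completion <- NULL
  if (cfg$missing_rate > 0) {
    mc <- apply_mcar(reports, indicators, cfg$missing_rate)
    reports <- mc$reports
    indicators <- mc$indicators
    completion <- mc$completion
  }
  reports <- add_total_records(reports)
  # composite scoring standardizes within the sample; meaningless below n = 3
  factors <- if (cfg$n_subjects >= 3) score_factors(indicators) else NULL
  long <- build_long_table(reports, factors)

  list(
    config = cfg, latents = latents, indicators = indicators,
    truth = truth, day_counts = day_counts, itineraries = itineraries,
    trajectories = trajectories, reports = reports, factors = factors,
    completion = completion, long = long
  )
}

#' Replicate the structural-model recovery experiment
#'
#' Repeatedly simulates a study at the configured conditions (latents, true
#' counts, method reports — movement is never rendered), fits the split-plot
#' model on the true latent covariates and the final two-predictor
#' regression, and records the estimates and key p-values. Used for
#' parameter-recovery and type-I-calibration checks.
#'
#' @param n_reps Number of replicate studies.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param fit_anova Whether to run the full split-plot fit each replicate
#'   (needed for the SL calibration; the regression alone is much cheaper).
#' @return A tibble with one row per replicate: `intercept`, `b_AL`,
#'   `b_Time` (final-regression estimates) and, when `fit_anova`, `p_AL`,
#'   `p_SL`, `p_Time` from the AL-first split-plot table.
#' @export
simulate_model_replicates <- function(n_reps, cfg = sim_config(), seed = 1,
                                      fit_anova = TRUE) {
  set.seed(seed)
  rp <- cfg$reports
  purrr::map_dfr(seq_len(n_reps), function(r) {
    lat <- simulate_latents(cfg$n_subjects, cfg$latent_corr)
    tr <- simulate_true_npv(lat, cfg)
    mk <- function(m, p, fr, ns) {
      tibble(
        subject_id = tr$subject_id, method = m, period = tr$period,
        npv = simulate_self_reports(tr$npv_true, p, fr, ns)
      )
    }
    reports <- dplyr::bind_rows(
      mk("Diary", rp$p_recall_diary, rp$false_rate_diary, rp$noise_sd_diary),
      mk("Google", rp$p_recall_google, rp$false_rate_google,
         rp$noise_sd_google),
      mk("GPS", 1, 0, rp$noise_sd_gps)
    )
    truth_cov <- tibble(
      subject_id = lat$subject_id, AL = lat$AL_true, SL = lat$SL_true
    )
    long <- build_long_table(reports, truth_cov)
    pf <- final_parameter_fit(long)
    out <- tibble(
      rep = r,
      intercept = pf$estimate[pf$term == "Intercept"],
      b_AL = pf$estimate[pf$term == "AL"],
      b_Time = pf$estimate[pf$term == "Time"]
    )
    if (fit_anova) {
      tab <- tidy(sequential_anova(long))
      out$p_AL <- tab$p[tab$term == "AL"]
      out$p_SL <- tab$p[tab$term == "SL"]
      out$p_Time <- tab$p[tab$term == "Time"]
    }
    out
  })
}
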
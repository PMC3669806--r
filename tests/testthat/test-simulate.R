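test_that("latents hit the configured correlation and are seed-stable", {
  set.seed(100)
  lat0 <- simulate_latents(10000, 0)
  expect_lt(abs(cor(lat0$AL_true, lat0$SL_true)), 0.03)
  set.seed(100)
  lat1 <- simulate_latents(10000, -0.30)
  r <- cor(lat1$AL_true, lat1$SL_true)
  expect_gt(r, -0.33)
  expect_lt(r, -0.27)
  set.seed(9)
  a <- simulate_latents(50, -0.3)
  set.seed(9)
  b <- simulate_latents(50, -0.3)
  expect_identical(a, b)
})

test_that("true counts follow the structural model", {
  # zero noise, AL = 0: weekday period count is round(11.87 + 1.84) = 14
  lat <- tibble::tibble(subject_id = "S001", AL_true = 0, SL_true = 0)
  cfg <- sim_config(subject_sd = 0, truth_sd = 0)
  tr <- simulate_true_npv(lat, cfg)
  expect_equal(tr$npv_true[tr$period == "weekday"], 14L)
  expect_equal(tr$npv_true[tr$period == "weekend"], 10L)

  set.seed(110)
  lat2 <- simulate_latents(5000, 0)
  tr2 <- simulate_true_npv(lat2, sim_config(b_AL = 0))
  wide <- tr2[tr2$period == "weekday", ]
  expect_lt(abs(cor(wide$npv_true, lat2$AL_true)), 0.05)
  # negative Time effect: weekends quieter
  expect_lt(
    mean(tr2$npv_true[tr2$period == "weekend"]),
    mean(tr2$npv_true[tr2$period == "weekday"])
  )
})

test_that("indicator moments match the censored-normal oracle", {
  # closed-form mean/sd of min(max(N(m, s), a), b) -- clipping at the scale
  # bounds shifts the moments of boundary-adjacent scales (e.g. BDI)
  censored_moments <- function(m, s, a, b) {
    al <- (a - m) / s
    be <- (b - m) / s
    p_mid <- pnorm(be) - pnorm(al)
    ex <- a * pnorm(al) + b * (1 - pnorm(be)) +
      m * p_mid + s * (dnorm(al) - dnorm(be))
    ex2 <- a^2 * pnorm(al) + b^2 * (1 - pnorm(be)) +
      (m^2 + s^2) * p_mid +
      s * ((m + a) * dnorm(al) - (m + b) * dnorm(be))
    c(mean = ex, sd = sqrt(ex2 - ex^2))
  }
  set.seed(120)
  lat <- simulate_latents(2000, -0.30)
  ind <- simulate_indicators(lat)
  meta <- indicator_metadata()
  for (i in seq_len(nrow(meta))) {
    x <- ind[[meta$indicator[i]]]
    om <- censored_moments(meta$mean[i], meta$sd[i], meta$min[i], meta$max[i])
    se_m <- om["sd"] / sqrt(2000)
    expect_lt(abs(mean(x) - om["mean"]), 4 * se_m)
    expect_lt(abs(sd(x) - om["sd"]) / om["sd"], 0.06)
    expect_true(all(x >= meta$min[i] & x <= meta$max[i]))
    # calibration stays close to the declared targets; clipping compresses
    # the spread of boundary-adjacent scales (BDI most of all) by up to
    # a sixth
    expect_lt(abs(mean(x) - meta$mean[i]), 1.0)
    expect_lt(abs(sd(x) - meta$sd[i]) / meta$sd[i], 0.2)
  }
})

test_that("self-report thinning is binomial in expectation and monotone", {
  set.seed(130)
  truth <- rep(10L, 5000)
  expect_identical(simulate_self_reports(truth, 1, 0, 0), truth)
  thin <- simulate_self_reports(truth, 0.8, 0, 0)
  expect_lt(abs(mean(thin) - 8), 3 * sqrt(10 * 0.8 * 0.2 / 5000) + 0.05)
  truth2 <- as.integer(rpois(5000, 12))
  cors <- purrr::map_dbl(c(1, 0.8, 0.6), function(p) {
    cor(truth2, simulate_self_reports(truth2, p, 0, 0))
  })
  expect_true(all(diff(cors) < 0))
})

test_that("rendered trajectories honour dropout, noise and gaps", {
  cfg <- sim_config(n_subjects = 1, render_gps = TRUE)
  st <- simulate_study(cfg, seed = 140)
  traj <- st$trajectories[[1]]
  dt <- diff(as.numeric(traj$t))
  expect_true(any(dt > 600))        # dropout during dwells
  expect_true(all(dt > 0))          # strictly increasing
  st1 <- detect_stops(traj)
  expect_true(any(st1$gap_inferred))

  # without dropout, dwells are densely sampled
  cfg2 <- sim_config(
    n_subjects = 1, render_gps = TRUE,
    gps = list(dropout_when_stationary = FALSE)
  )
  st2 <- simulate_study(cfg2, seed = 140)
  expect_gt(nrow(st2$trajectories[[1]]), nrow(traj))

  it <- st$itineraries
  it$arrive_t[2] <- it$arrive_t[1]
  expect_error(render_trajectory(it, cfg), "overlap")
})

test_that("every anomaly injection is caught by the flag rule", {
  cfg <- sim_config(n_subjects = 1, render_gps = TRUE)
  st <- simulate_study(cfg, seed = 150)
  set.seed(151)
  spiked <- inject_anomalies(st$trajectories[[1]], 0.05)
  ninj <- attr(spiked, "n_injected")
  expect_gt(ninj, 0)
  mask <- flag_anomalous_fixes(spiked)
  flagged_t <- as.numeric(spiked$t[mask])
  expect_true(all(as.numeric(attr(spiked, "injected_t")) %in% flagged_t))
})

test_that("a seed reproduces the whole study byte for byte", {
  cfg <- sim_config(n_subjects = 4, render_gps = TRUE, missing_rate = 0.1)
  a <- simulate_study(cfg, seed = 160)
  b <- simulate_study(cfg, seed = 160)
  expect_identical(a$reports, b$reports)
  expect_identical(a$indicators, b$indicators)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$completion, b$completion)
  c_ <- simulate_study(cfg, seed = 161)
  expect_false(identical(a$reports, c_$reports))
})

test_that("the long table reproduces the 2-period x 3-method design", {
  st <- simulate_study(sim_config(n_subjects = 8, movement = FALSE),
                       seed = 170)
  expect_equal(nrow(st$long), 48)
  shape <- dplyr::count(st$long, method, period)
  expect_equal(nrow(shape), 6)
  expect_true(all(shape$n == 8))
})
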
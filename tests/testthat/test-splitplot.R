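test_that("method contrasts are centered and orthogonal", {
  mc <- method_contrasts()
  expect_equal(sum(mc$C1), 0)
  expect_equal(sum(mc$C2), 0)
  expect_equal(sum(mc$C1 * mc$C2), 0)
  # C2 applied to method means is mean(self-report) - GPS
  m <- c(Diary = 10, Google = 14, GPS = 9)
  expect_equal(sum(mc$C2 * m[mc$method]), mean(m[c("Diary", "Google")]) - 9)
})

test_that("the long table has the design shape and drops missing rows", {
  set.seed(21)
  st <- simulate_study(sim_config(n_subjects = 96, movement = FALSE),
                       seed = 21)
  expect_equal(nrow(st$long), 96 * 6)
  expect_true(all(table(st$long$subject_id) == 6))
  expect_setequal(unique(st$long$Time), c(-0.5, 0.5))

  rec <- st$reports
  rec$npv[rec$subject_id == "S001" & rec$method == "GPS" &
            rec$period == "weekend"] <- NA
  long2 <- build_long_table(rec, st$factors)
  expect_equal(sum(long2$subject_id == "S001"), 5)
})

test_that("sequential SS match the nested-refit oracle on small instances", {
  set.seed(31)
  spec <- splitplot_terms("AL-first")
  for (rep in 1:25) {
    repeat {
      long <- random_long_table(sample(5:6, 1), drop = sample(0:2, 1))
      fit <- tryCatch(sequential_anova(long), error = function(e) e)
      if (!inherits(fit, "error")) break
    }
    oracle <- lm_sequential_ss(long, spec$terms)
    expect_equal(fit$terms$ss, oracle, tolerance = 1e-8)
    # conservation: terms + residual = corrected total
    expect_equal(sum(fit$terms$ss) + fit$ss_resid, fit$ss_total,
                 tolerance = 1e-10)
  }
})

test_that("balanced two-period design: F(Time) equals the paired t squared", {
  set.seed(41)
  d <- tibble::tibble(
    SID = factor(rep(sprintf("P%d", 1:8), each = 2)),
    period = rep(c("weekday", "weekend"), 8),
    Time = rep(c(-0.5, 0.5), 8),
    npv = rpois(16, 12)
  )
  fit <- sequential_anova(
    d,
    terms = c("SID", "Time"),
    strata = c(SID = "residual", Time = "residual")
  )
  wk <- d$npv[d$Time == -0.5]
  we <- d$npv[d$Time == 0.5]
  tt <- t.test(we, wk, paired = TRUE)
  f_time <- fit$terms$f[fit$terms$term == "Time"]
  expect_equal(f_time, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$terms$p[fit$terms$term == "Time"], tt$p.value,
               tolerance = 1e-10)
})

test_that("AL-first and SL-first orders agree on totals and joint SS", {
  set.seed(51)
  for (rep in 1:5) {
    long <- random_long_table(8, drop = 3)
    fits <- fit_both_orders(long)
    g1 <- glance(fits$al_first)
    g2 <- glance(fits$sl_first)
    expect_equal(g1$r_squared, g2$r_squared, tolerance = 1e-10)
    j1 <- sum(fits$al_first$terms$ss[1:3])
    j2 <- sum(fits$sl_first$terms$ss[1:3])
    expect_equal(j1, j2, tolerance = 1e-10)
  }
})

test_that("effect-size accounting: semi-partials sum to stratum totals", {
  set.seed(61)
  long <- random_long_table(10)
  fit <- sequential_anova(long)
  tab <- fit$terms
  # semi-partials and the error share partition the corrected total
  expect_equal(
    sum(tab$semi_partial_r2) + fit$ss_resid / fit$ss_total, 1,
    tolerance = 1e-10
  )
  bs <- tab$type == "BS"
  expect_equal(sum(tab$partial_r2[bs]), 1, tolerance = 1e-10)
  expect_equal(sum(tab$partial_r2[!bs]), 1, tolerance = 1e-10)
  expect_equal(
    attr(tab, "model_r2"),
    attr(tab, "bs_total") + attr(tab, "ws_total")
  )
})

test_that("degenerate error strata raise a named error", {
  d <- tibble::tibble(
    SID = factor(rep(c("a", "b"), each = 2)),
    Time = rep(c(-0.5, 0.5), 2),
    npv = c(1, 5, 2, 7)
  )
  # Time:SID exhausts the residual: no df left for SID's denominator
  expect_error(
    sequential_anova(
      d,
      terms = c("SID", "Time", "Time:SID"),
      strata = c(SID = "residual", Time = "Time:SID",
                 `Time:SID` = "residual")
    ),
    "stratum"
  )
})

test_that("the final regression recovers structural parameters", {
  # noiseless generator: exact recovery by construction
  cfg0 <- sim_config(
    subject_sd = 0, truth_sd = 0, movement = FALSE,
    reports = list(noise_sd_diary = 0, noise_sd_google = 0)
  )
  st0 <- simulate_study(cfg0, seed = 71)
  lat <- dplyr::transmute(st0$latents, subject_id, AL = AL_true,
                          SL = SL_true)
  long0 <- build_long_table(st0$reports, lat)
  pf0 <- final_parameter_fit(long0)
  # counts are integer-rounded, so recovery is exact up to rounding grain
  expect_equal(pf0$estimate[pf0$term == "Intercept"], 11.87,
               tolerance = 0.05)
  expect_equal(pf0$estimate[pf0$term == "AL"], 1.79, tolerance = 0.05)
  expect_equal(pf0$estimate[pf0$term == "Time"], -3.68, tolerance = 0.1)

  # a zero AL column yields a zero slope and the mean as intercept
  long0$AL <- 0
  long0$Time <- 0
  pf1 <- final_parameter_fit(long0)
  expect_equal(pf1$estimate[pf1$term == "AL"], 0)
  expect_equal(pf1$estimate[pf1$term == "Intercept"], mean(long0$npv))
})

test_that("tidy, glance and autoplot expose the fit", {
  set.seed(81)
  long <- random_long_table(8)
  fit <- sequential_anova(long)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 21)
  gl <- glance(fit)
  expect_true(gl$r_squared > 0 && gl$r_squared <= 1)
  expect_s3_class(autoplot(fit), "ggplot")
})
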
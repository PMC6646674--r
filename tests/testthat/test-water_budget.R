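test_that("whc sums plant-available water over horizons", {
  p <- soil_profile(data.frame(label = "LA", thickness_cm = 100,
                               theta_fc = 0.27, theta_wp = 0.12))
  expect_equal(whc(p), 150)
  expect_error(
    soil_profile(data.frame(label = "LA", thickness_cm = 0,
                            theta_fc = 0.27, theta_wp = 0.12)),
    class = "ct_validation_error"
  )
  expect_error(
    soil_profile(data.frame(label = "LA", thickness_cm = 50,
                            theta_fc = 0.10, theta_wp = 0.12)),
    class = "ct_validation_error"
  )
  shallow <- soil_profile(data.frame(label = "LA", thickness_cm = 30,
                                     theta_fc = 0.25, theta_wp = 0.15))
  expect_warning(whc(shallow), "outside the typical")
})

test_that("bucket steps conserve mass, clamp and drain", {
  # 10 days of 5 mm/day ET from a full 184 mm bucket
  s <- 184
  for (i in 1:10) s <- step_budget(s, 184, 0, 0, 5)$storage
  expect_equal(s, 134)

  over <- step_budget(180, 184, 30, 0, 0)
  expect_equal(over$storage, 184)
  expect_equal(over$drainage, 26)

  idle <- step_budget(120, 184, 0, 0, 0)
  expect_equal(idle$storage, 120)
  expect_equal(idle$drainage, 0)

  # ET demand beyond the stored water is limited, not overdrawn
  dry <- step_budget(2, 184, 0, 0, 10)
  expect_equal(dry$storage, 0)
  expect_equal(dry$et_actual, 2)

  expect_error(step_budget(100, 184, -1, 0, 0),
               class = "ct_validation_error")
})

test_that("seasonal ledger closes its daily mass balance exactly", {
  weather <- withr::with_seed(7, data.frame(
    date = as.Date("2017-02-23") + 0:119,
    rain_mm = rpois(120, 1) * rbinom(120, 1, 0.3),
    irrigation_mm = ifelse(seq_len(120) %% 20 == 0, 20, 0),
    et_mm = runif(120, 1, 6)
  ))
  led <- run_budget(weather, whc_mm = 184)
  storage_prev <- c(184, head(led$storage_mm, -1))
  lhs <- led$storage_mm - storage_prev
  rhs <- led$rain_mm + led$irrigation_mm - led$et_actual_mm - led$drainage_mm
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_true(all(led$storage_mm >= 0 & led$storage_mm <= 184))
  expect_true(all(led$deficit_mm == 184 - led$storage_mm))
})

test_that("stress factor is bounded, monotone, piecewise linear", {
  expect_equal(sinclair_stress_factor(1), 1)
  expect_equal(sinclair_stress_factor(0), 0)
  expect_equal(sinclair_stress_factor(0.2, breakpoint = 0.4), 0.5)
  expect_equal(sinclair_stress_factor(0.6, breakpoint = 0.4), 1)
  fr <- seq(0, 1, by = 0.05)
  sf <- sinclair_stress_factor(fr)
  expect_true(all(diff(sf) >= 0))
  expect_true(all(sf >= 0 & sf <= 1))
  expect_error(sinclair_stress_factor(1.2), class = "ct_domain_error")
})

test_that("irrigation triggers follow the stage-dependent thresholds", {
  z39 <- as.Date("2017-04-20")
  tens <- tension_series(data.frame(
    date = as.Date("2017-04-01") + c(0, 5, 10, 25, 30),
    depth_cm = 60,
    tension_cbar = c(50, 85, 70, 85, 105)
  ))
  trg <- irrigation_triggers(tens, z39)
  # pre-Z39 threshold 80: day 5 triggers; post-Z39 threshold 100: only 105
  expect_equal(trg$date, as.Date(c("2017-04-06", "2017-05-01")))
  expect_equal(trg$threshold, c(80, 100))

  # WW management keeps 80 cbar after Z39 as well
  trg_ww <- irrigation_triggers(tens, z39, irrinov_thresholds("WW"))
  expect_equal(nrow(trg_ww), 3)

  # constant 50 cbar never triggers
  quiet <- tension_series(data.frame(
    date = as.Date("2017-04-01") + 0:5, depth_cm = 30, tension_cbar = 50
  ))
  expect_equal(nrow(irrigation_triggers(quiet, z39)), 0)

  # censored cap: recorded at 200, trigger plus warning, stress flagged
  capped <- tension_series(data.frame(
    date = as.Date("2017-05-01"), depth_cm = 60, tension_cbar = 250
  ))
  expect_true(capped$censored)
  expect_equal(capped$tension_cbar, 200)
  expect_warning(trg_c <- irrigation_triggers(capped, z39), "censored")
  expect_true(trg_c$water_stress)
})

test_that("interception efficiency reproduces the pluviometer arithmetic", {
  eff <- interception_efficiency(15, c(161, 190))
  expect_equal(round(eff$efficiency_pct), 92)
  expect_equal(interception_efficiency(100, c(90, 100))$efficiency_pct, 0)
  expect_equal(interception_efficiency(0, 150)$efficiency_pct, 100)
  expect_lt(interception_efficiency(15, c(161, 190),
                                    reference = "mean")$efficiency_pct,
            eff$efficiency_pct)
  expect_error(interception_efficiency(10, 0), class = "ct_domain_error")
})

test_that("shelter side effects compare cumulative PAR and degree days", {
  out <- data.frame(date = as.Date("2017-02-23") + 0:99,
                    par = runif(100, 10, 40),
                    tmin = runif(100, 0, 8), tmax = runif(100, 8, 20))
  inside <- out
  inside$par <- 0.965 * out$par
  eff <- shelter_side_effects(inside, out)
  expect_equal(eff$delta_cum_par_pct, -3.5, tolerance = 1e-9)
  expect_equal(eff$delta_degree_days_pct, 0)

  expect_equal(degree_day(20, 10), 15)

  same <- shelter_side_effects(out, out)
  expect_equal(unlist(same), c(delta_cum_par_pct = 0,
                               delta_degree_days_pct = 0))
  shifted <- out; shifted$date <- shifted$date + 1
  expect_error(shelter_side_effects(shifted, out),
               class = "ct_validation_error")
})

test_that("TDR calibration recovers linear relations", {
  x <- c(10, 15, 20, 25, 30)
  cal <- calibrate_tdr(x, 0.9 * x + 2)
  expect_equal(cal$slope, 0.9)
  expect_equal(cal$intercept, 2)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$transform(20), 20)

  noisy <- withr::with_seed(5, {
    x2 <- runif(30, 5, 40)
    list(x = x2, y = 0.8 * x2 + 3 + rnorm(30, 0, 0.5))
  })
  cal2 <- calibrate_tdr(noisy$x, noisy$y)
  se <- summary(lm(noisy$y ~ noisy$x))$coefficients[2, 2]
  expect_lt(abs(cal2$slope - 0.8), 3 * se)

  expect_error(calibrate_tdr(c(1, 2), c(1, 2)),
               class = "ct_validation_error")
  expect_error(calibrate_tdr(rep(5, 4), 1:4),
               class = "ct_validation_error")
})
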
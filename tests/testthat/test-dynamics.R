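test_that("auc reproduces simple geometric areas", {
  tri <- toy_series(0:2, c(0, 1, 0))
  d0 <- as.numeric(tri$date[1])
  expect_equal(auc(tri, c(d0, d0 + 2)), 1.0)

  const <- toy_series(c(0, 10), c(2.5, 2.5))
  expect_equal(auc(const, c(d0, d0 + 10)), 25)

  # edge interpolation: half the triangle
  expect_equal(auc(tri, c(d0 + 0.5, d0 + 1.5)), 0.75)
  expect_error(auc(tri, c(d0 - 5, d0 + 1)), class = "ct_domain_error")
})

test_that("auc equals a fine-grid Riemann oracle and is additive/linear", {
  set.seed(99)
  days <- c(0, 3, 7, 12, 18, 25)
  vals <- runif(6, 0, 2)
  s <- toy_series(days, vals)
  d0 <- as.numeric(s$date[1])

  # brute-force oracle: trapezoid on a 1e-4-day grid of the interpolant
  f <- approxfun(days, vals)
  grid <- seq(0, 25, by = 1e-4)
  oracle <- sum(diff(grid) * (head(f(grid), -1) + tail(f(grid), -1)) / 2)
  expect_equal(auc(s, c(d0, d0 + 25)), oracle, tolerance = 1e-9)

  # additivity over subintervals, exact for the interpolant
  mid <- d0 + 11.3
  expect_equal(auc(s, c(d0, mid)) + auc(s, c(mid, d0 + 25)),
               auc(s, c(d0, d0 + 25)), tolerance = 1e-12)

  # linearity in the trait values
  s2 <- s; s2$value <- 3 * s$value
  expect_equal(auc(s2, c(d0, d0 + 25)), 3 * auc(s, c(d0, d0 + 25)),
               tolerance = 1e-12)
})

test_that("linear-interp fit reproduces observations exactly", {
  s <- toy_series(c(0, 5, 9, 14), c(0.2, 0.8, 0.5, 0.9))
  fit <- fit_curve(s, "linear-interp")
  expect_equal(fit$rmse, 0)
  expect_equal(predict_curve(fit, s$date), s$value)
})

test_that("logistic fits recover noiseless generator parameters", {
  days <- seq(0, 60, by = 4)
  truth <- list(asym = 0.9, mid = 30, rate = 0.25)
  vals <- truth$asym / (1 + exp(-truth$rate * (days - truth$mid)))
  fit <- fit_curve(toy_series(days, vals), "logistic", seed = 1)
  expect_equal(unname(fit$parameters["asym"]), truth$asym, tolerance = 0.01)
  expect_equal(unname(fit$parameters["mid"]), truth$mid, tolerance = 0.01)
  expect_equal(unname(fit$parameters["rate"]), truth$rate, tolerance = 0.01)

  expect_error(fit_curve(toy_series(c(0, 10), c(0, 1)), "logistic"),
               class = "ct_validation_error")
})

test_that("noisy logistic fits recover the midpoint in >= 90% of seeds", {
  days <- seq(0, 70, by = 5)  # 15 dates
  truth <- function(t) 0.9 / (1 + exp(-0.2 * (t - 35)))
  hits <- vapply(1:100, function(seed) {
    vals <- withr::with_seed(seed, truth(days) + rnorm(15, 0, 0.045))
    fit <- try(fit_curve(toy_series(days, vals), "logistic", seed = seed),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(FALSE)
    abs(fit$parameters[["mid"]] - 35) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("divergence onset finds sustained separations only", {
  days <- seq(0, 100, by = 2)
  base <- rep(0.8, length(days))
  a <- toy_series(days, base, plot = "a")
  expect_true(is.na(divergence_onset(a, a, delta = 0.05)))

  # step divergence at day 40
  stepped <- ifelse(days >= 40, 0.5, 0.8)
  b <- toy_series(days, stepped, plot = "b")
  onset <- divergence_onset(a, b, delta = 0.1, persistence = 5)
  expect_lte(abs(as.numeric(onset - a$date[1]) - 40), 1)
  # symmetric in (a, b)
  expect_equal(divergence_onset(b, a, delta = 0.1, persistence = 5), onset)

  # one-day spike does not count against a 5-day persistence rule
  spiked <- base; spiked[days == 40] <- 0.2
  c_ <- toy_series(days, spiked, plot = "c")
  expect_true(is.na(divergence_onset(a, c_, delta = 0.1, persistence = 5)))

  far <- toy_series(days + 500, base, plot = "d")
  expect_error(divergence_onset(a, far, delta = 0.1),
               class = "ct_domain_error")
})

test_that("grain nitrogen and relative-loss arithmetic", {
  expect_equal(nitrogen_grain_quantity(0, 12), 0)
  expect_equal(nitrogen_grain_quantity(8, 14.25), 200)
  expect_equal(nitrogen_grain_quantity(5.7, 10), 100)
  expect_equal(nitrogen_grain_quantity(5.7, 10, literal = TRUE), 10)
  expect_error(nitrogen_grain_quantity(-1, 10), class = "ct_domain_error")

  expect_equal(relative_loss(11.4, 8.0, digits = 0), 30)
  expect_equal(relative_loss(11.4, 9.7, digits = 0), 15)
  expect_equal(relative_loss(5, 5), 0)
  expect_error(relative_loss(0, 1), class = "ct_domain_error")
})

test_that("treatment summary separates distant groups, merges equal ones", {
  same <- withr::with_seed(1, data.frame(
    y = rnorm(24, 10, 1), g = rep(c("WW", "WD"), each = 12)
  ))
  tb <- treatment_summary(same, "y", "g")
  expect_equal(tb$letters[1], tb$letters[2])

  far <- same
  far$y[far$g == "WD"] <- far$y[far$g == "WD"] + 10
  tb2 <- treatment_summary(far, "y", "g")
  expect_false(tb2$letters[1] == tb2$letters[2])

  one <- data.frame(y = rnorm(5), g = "WW")
  expect_equal(treatment_summary(one, "y", "g")$letters, "a")

  single_rep <- data.frame(y = c(1, 2, 3), g = c("a", "a", "b"))
  expect_warning(treatment_summary(single_rep, "y", "g"),
                 "standard error undefined")
})
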
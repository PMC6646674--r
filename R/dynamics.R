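# Trait time-series analysis: AUC stress indicators over phenological
# windows, parametric curve fits, treatment-divergence onset, and the
# grain-nitrogen / yield-loss arithmetic used on trial endpoints.

# Extract (day, value) for one plot x trait from a trait series, with
# days as numeric offsets from the first date in the series (or from a
# supplied origin).
series_xy <- function(series, origin = NULL) {
  if (inherits(series, "trait_series") || is.data.frame(series)) {
    t <- as.numeric(as.Date(series$date))
    v <- series$value
  } else {
    ct_schema_error("expected a trait series or data frame")
  }
  if (!is.null(origin)) t <- t - as.numeric(as.Date(origin))
  ord <- order(t)
  list(t = t[ord], v = v[ord])
}

#' Area under a trait curve over a window
#'
#' Trapezoidal integral of the linearly interpolated (daily) series
#' between `window[1]` and `window[2]`, with boundary values
#' interpolated at the window edges. Exact for the piecewise-linear
#' interpolant, hence additive over subintervals. The canonical use is
#' the AUC of MTCI between flowering and maturity as a grain-filling
#' nitrogen indicator.
#'
#' @param series A [trait_series()] (or data frame with `date`,
#'   `value`) for a single plot and trait.
#' @param window Length-2 vector of dates (or numeric days) bounding the
#'   integral.
#' @return Area in trait-unit x days.
#' @export
auc <- function(series, window) {
  xy <- series_xy(series)
  win <- if (inherits(window, "Date") || is.character(window)) {
    as.numeric(as.Date(window))
  } else as.numeric(window)
  if (win[2] <= win[1]) ct_domain_error("window must have positive length")
  if (win[1] < min(xy$t) || win[2] > max(xy$t)) {
    ct_domain_error("window extends outside the series support")
  }
  if (sum(xy$t >= win[1] & xy$t <= win[2]) + 2 < 2) {
    ct_validation_error("need at least 2 observations overlapping the window")
  }
  inner <- xy$t[xy$t > win[1] & xy$t < win[2]]
  knots <- c(win[1], inner, win[2])
  vals <- approx(xy$t, xy$v, xout = knots)$y
  sum(diff(knots) * (head(vals, -1) + tail(vals, -1)) / 2)
}

#' Fit a temporal model to a trait series
#'
#' Models:
#' * `"linear-interp"` — the piecewise-linear interpolant (exact, rmse
#'   0); the package default for all daily evaluation.
#' * `"logistic"` — `asym / (1 + exp(-rate (t - mid)))`, least squares
#'   via Levenberg-Marquardt with seeded multi-start.
#' * `"double-logistic"` — `ymax (1/(1+exp(-r1 (t - t1))) -
#'   1/(1+exp(-r2 (t - t2))))`, a rise-then-senescence curve.
#'
#' @param series A [trait_series()] for one plot and trait.
#' @param model One of the model names above.
#' @param seed Seed for the multi-start jitter.
#' @param n_starts Number of jittered starts.
#' @return A `curve_fit`: `model`, `parameters`, `rmse`, `support` and a
#'   `predict(days)` function.
#' @export
fit_curve <- function(series, model = c("linear-interp", "logistic",
                                        "double-logistic"),
                      seed = 1L, n_starts = 5) {
  model <- match.arg(model)
  xy <- series_xy(series)
  t <- xy$t - min(xy$t)
  v <- xy$v
  n_par <- c("linear-interp" = 0, "logistic" = 3, "double-logistic" = 5)[model]
  if (length(t) <= n_par) {
    ct_validation_error(sprintf("%s fit is under-determined with %d points",
                                model, length(t)))
  }
  origin <- min(xy$t)
  if (model == "linear-interp") {
    f <- approxfun(t, v)
    return(new_curve_fit(model, numeric(0), 0, xy, origin, f))
  }
  fits <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      start <- curve_start(model, t, v, jitter = i > 1)
      try(minpack.lm::nlsLM(curve_formula(model),
                            data = data.frame(t = t, v = v),
                            start = start,
                            control = minpack.lm::nls.lm.control(maxiter = 200)),
          silent = TRUE)
    })
  })
  ok <- fits[!vapply(fits, inherits, logical(1), "try-error")]
  if (length(ok) == 0) ct_validation_error("curve fit did not converge")
  rss <- vapply(ok, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- ok[[which.min(rss)]]
  pars <- coef(best)
  f <- function(days) predict(best, newdata = data.frame(t = days))
  new_curve_fit(model, pars, sqrt(min(rss) / length(t)), xy, origin, f)
}

curve_formula <- function(model) {
  switch(model,
    logistic = v ~ asym / (1 + exp(-rate * (t - mid))),
    `double-logistic` =
      v ~ ymax * (1 / (1 + exp(-r1 * (t - t1))) - 1 / (1 + exp(-r2 * (t - t2))))
  )
}

curve_start <- function(model, t, v, jitter = FALSE) {
  rng <- diff(range(t))
  start <- if (model == "logistic") {
    up <- stats::cor(t, v) >= 0
    list(asym = max(v) * 1.02,
         mid = stats::weighted.mean(t, w = abs(diff(c(v[1], v)))),
         rate = if (up) 4 / rng else -4 / rng)
  } else {
    list(ymax = max(v) * 1.05, r1 = 8 / rng, t1 = min(t) + rng / 4,
         r2 = 8 / rng, t2 = min(t) + 3 * rng / 4)
  }
  if (jitter) {
    start <- lapply(start, function(p) p * exp(rnorm(1, 0, 0.15)))
  }
  start
}

new_curve_fit <- function(model, pars, rmse, xy, origin, f) {
  structure(
    list(model = model, parameters = pars, rmse = rmse,
         support = range(xy$t), origin = origin,
         predict = function(days) f(days)),
    class = "curve_fit"
  )
}

#' Evaluate a fitted curve at dates
#'
#' @param fit A [fit_curve()] result.
#' @param dates Dates (or numeric days on the series' own time axis).
#' @return Fitted values.
#' @export
predict_curve <- function(fit, dates) {
  stopifnot(inherits(fit, "curve_fit"))
  t <- if (inherits(dates, "Date") || is.character(dates)) {
    as.numeric(as.Date(dates)) - fit$origin
  } else as.numeric(dates)
  fit$predict(t)
}

#' Date at which two treatments start to diverge
#'
#' Both series are linearly interpolated to a common daily grid; the
#' onset is the earliest day where `|a - b|` exceeds `delta` and stays
#' above it for at least `persistence` consecutive days. This is the
#' "when does the stress start to impact growth" indicator.
#'
#' @param a,b Trait series (e.g. the WW and WD means of one trait) with
#'   overlapping date supports.
#' @param delta Divergence threshold in trait units.
#' @param persistence Minimum days the divergence must persist.
#' @return The onset `Date`, or `NA` if the series never diverge.
#' @export
divergence_onset <- function(a, b, delta, persistence = 5) {
  xa <- series_xy(a); xb <- series_xy(b)
  lo <- max(min(xa$t), min(xb$t))
  hi <- min(max(xa$t), max(xb$t))
  if (hi <= lo) ct_domain_error("series supports are disjoint")
  days <- seq(lo, hi, by = 1)
  d <- abs(approx(xa$t, xa$v, days)$y - approx(xb$t, xb$v, days)$y)
  above <- d > delta
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths >= persistence)
  if (length(hit) == 0) return(as.Date(NA))
  as.Date(days[ends[hit[1]] - runs$lengths[hit[1]] + 1],
          origin = "1970-01-01")
}

#' Nitrogen quantity exported in grain
#'
#' `Nabs = GY x P x 10 / 5.7` (kg N per ha) for grain yield `gy` in t/ha
#' and protein content `p` in percent; 5.7 is the cereal
#' protein-to-nitrogen conversion and the factor 10 makes the units
#' consistent. `literal = TRUE` drops the unit factor (the bare
#' `GY x P / 5.7` form).
#'
#' @param gy Dry matter grain yield, t/ha, `>= 0`.
#' @param p Grain protein content, percent, in `[0, 100]`.
#' @param literal Drop the x10 unit factor.
#' @return kg N / ha.
#' @export
nitrogen_grain_quantity <- function(gy, p, literal = FALSE) {
  if (any(gy < 0)) ct_domain_error("grain yield must be >= 0")
  if (any(p < 0 | p > 100)) ct_domain_error("protein content must be in [0,100]")
  gy * p * (if (literal) 1 else 10) / 5.7
}

#' Relative loss of a stressed endpoint versus its reference
#'
#' `100 (reference - stressed) / reference`, e.g. the percentage yield
#' decrease of a water-deficit treatment against the well-watered one.
#'
#' @param reference Reference (unstressed) value, `> 0`.
#' @param stressed Stressed value.
#' @param digits Rounding for reporting; `NULL` keeps full precision.
#' @return Loss in percent.
#' @export
relative_loss <- function(reference, stressed, digits = NULL) {
  if (any(reference <= 0)) ct_domain_error("reference must be > 0")
  loss <- 100 * (reference - stressed) / reference
  if (!is.null(digits)) loss <- round(loss, digits)
  loss
}

#' Treatment group means, standard errors and Tukey letters
#'
#' Thin convenience wrapper over one-way ANOVA with Tukey HSD pairwise
#' comparisons at `alpha`; groups sharing a letter are not significantly
#' different.
#'
#' @param data Data frame of endpoint values.
#' @param response,group Column names (strings) of the response and the
#'   grouping factor.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `group`, `n`, `mean`, `se`, `letters`.
#' @export
treatment_summary <- function(data, response, group, alpha = 0.05) {
  data <- as.data.frame(data)
  data$.g <- factor(data[[group]])
  data$.y <- data[[response]]
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), .data$.g),
    n = dplyr::n(), mean = mean(.data$.y),
    se = sd(.data$.y) / sqrt(dplyr::n()), .groups = "drop"
  )
  if (any(stats_tbl$n < 2)) {
    warning("standard error undefined for single-replicate group(s)",
            call. = FALSE)
  }
  if (nlevels(data$.g) < 2) {
    letters_vec <- setNames("a", levels(data$.g))
  } else {
    fit <- aov(.y ~ .g, data = data)
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(.g = "Tukey"))
    letters_vec <- multcomp::cld(glht, level = alpha)$mcletters$Letters
  }
  stats_tbl$letters <- unname(letters_vec[as.character(stats_tbl$.g)])
  dplyr::rename(stats_tbl, group = ".g")
}
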
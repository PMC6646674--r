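# Soil water bucket accounting, tensiometer-threshold irrigation
# triggering (Irrinov-style), rainout-shelter interception efficiency
# and side effects, and TDR probe calibration.

#' Construct a layered soil profile
#'
#' Horizons follow the platform's pedology: LA (plowed), S (cambic), C1
#' and C2 (calcaric material). Water holding capacity is the summed
#' plant-available water between field capacity and wilting point.
#'
#' @param horizons Data frame with `label`, `thickness_cm`, `theta_fc`,
#'   `theta_wp` (volumetric water contents).
#' @return A `soil_profile`.
#' @export
soil_profile <- function(horizons) {
  horizons <- tibble::as_tibble(horizons)
  need <- c("label", "thickness_cm", "theta_fc", "theta_wp")
  if (!all(need %in% names(horizons))) {
    ct_schema_error("horizons need label, thickness_cm, theta_fc, theta_wp")
  }
  if (any(horizons$thickness_cm <= 0)) {
    ct_validation_error("horizon thickness must be > 0")
  }
  if (any(horizons$theta_fc <= horizons$theta_wp)) {
    ct_validation_error("theta_fc must exceed theta_wp")
  }
  structure(list(horizons = horizons), class = "soil_profile")
}

#' Water holding capacity of a profile
#'
#' `WHC = sum(thickness_cm x 10 x (theta_fc - theta_wp))` in mm.
#' Profiles outside the 102-275 mm range observed across deep-loam
#' platforms of this type get a range warning (they are still accepted).
#'
#' @param profile A [soil_profile()].
#' @return WHC in mm.
#' @export
whc <- function(profile) {
  stopifnot(inherits(profile, "soil_profile"))
  h <- profile$horizons
  total <- sum(h$thickness_cm * 10 * (h$theta_fc - h$theta_wp))
  if (total < 102 || total > 275) {
    warning(sprintf("WHC %.0f mm outside the typical 102-275 mm range", total),
            call. = FALSE)
  }
  total
}

#' One day of bucket accounting
#'
#' `storage' = clamp(storage + rain + irrigation - et, 0, WHC)`; inflow
#' beyond capacity goes to drainage, and evapotranspiration demand is
#' limited to the water actually available so the daily mass balance
#' `storage' - storage = rain + irrigation - et_actual - drainage`
#' closes exactly. Deficit is `WHC - storage'`.
#'
#' @param storage Storage at the start of the day (mm).
#' @param whc_mm Bucket capacity (mm).
#' @param rain,irrigation,et Daily water fluxes (mm, `>= 0`); `et` is
#'   the crop evapotranspiration demand.
#' @return List: `storage`, `drainage`, `et_actual`, `deficit`.
#' @export
step_budget <- function(storage, whc_mm, rain, irrigation, et) {
  if (any(c(rain, irrigation, et) < 0)) {
    ct_validation_error("daily water fluxes must be >= 0")
  }
  avail <- storage + rain + irrigation
  et_actual <- min(et, avail)
  s <- avail - et_actual
  drainage <- max(s - whc_mm, 0)
  s <- s - drainage
  list(storage = s, drainage = drainage, et_actual = et_actual,
       deficit = whc_mm - s)
}

#' Run the daily water budget over a season
#'
#' @param weather Data frame with `date`, `rain_mm`, `irrigation_mm`,
#'   `et_mm` (daily).
#' @param whc_mm Bucket capacity in mm (e.g. from [whc()]).
#' @param storage0 Initial storage in mm (default full: profile at field
#'   capacity at the start of protection).
#' @param stress_breakpoint Passed to [sinclair_stress_factor()] for the
#'   per-day stress factor column.
#' @return A `water_ledger` tibble: per day `storage`, `drainage`,
#'   `et_actual`, `deficit`, `stress_factor`.
#' @export
run_budget <- function(weather, whc_mm, storage0 = whc_mm,
                       stress_breakpoint = 0.4) {
  need <- c("date", "rain_mm", "irrigation_mm", "et_mm")
  if (!all(need %in% names(weather))) {
    ct_schema_error("weather needs date, rain_mm, irrigation_mm, et_mm")
  }
  n <- nrow(weather)
  storage <- drainage <- et_actual <- deficit <- numeric(n)
  s <- storage0
  for (i in seq_len(n)) {
    day <- step_budget(s, whc_mm, weather$rain_mm[i],
                       weather$irrigation_mm[i], weather$et_mm[i])
    storage[i] <- s <- day$storage
    drainage[i] <- day$drainage
    et_actual[i] <- day$et_actual
    deficit[i] <- day$deficit
  }
  out <- tibble::tibble(
    date = as.Date(weather$date), rain_mm = weather$rain_mm,
    irrigation_mm = weather$irrigation_mm, et_demand_mm = weather$et_mm,
    et_actual_mm = et_actual, storage_mm = storage,
    drainage_mm = drainage, deficit_mm = deficit,
    stress_factor = sinclair_stress_factor(storage / whc_mm,
                                           breakpoint = stress_breakpoint)
  )
  attr(out, "whc_mm") <- whc_mm
  attr(out, "storage0") <- storage0
  class(out) <- c("water_ledger", class(out))
  out
}

#' Sinclair-style water stress response
#'
#' Maps the available soil water fraction (`storage / WHC`) to a stress
#' factor between 1 (no stress) and 0 (maximum stress): 1 above the
#' breakpoint fraction, linearly decreasing to 0 at an empty bucket.
#'
#' @param available_fraction Fraction of WHC currently stored, in
#'   `[0, 1]`.
#' @param breakpoint Fraction below which stress sets in (default 0.4).
#' @return Stress factor in `[0, 1]`.
#' @export
sinclair_stress_factor <- function(available_fraction, breakpoint = 0.4) {
  if (any(available_fraction < 0 | available_fraction > 1)) {
    ct_domain_error("available fraction must lie in [0, 1]")
  }
  pmin(available_fraction / breakpoint, 1)
}

#' Construct a soil tension series
#'
#' Watermark-class tensiometers cannot record above 200 cbar: higher
#' values are capped at 200 and flagged censored.
#'
#' @param data Data frame with `date`, `depth_cm` (30/60/90),
#'   `tension_cbar`.
#' @return A `tension_series` tibble with a `censored` column.
#' @export
tension_series <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("date", "depth_cm", "tension_cbar")
  if (!all(need %in% names(data))) {
    ct_schema_error("tension data needs date, depth_cm, tension_cbar")
  }
  if (any(data$tension_cbar < 0)) {
    ct_validation_error("tension must be >= 0")
  }
  data$censored <- data$tension_cbar > 200
  data$tension_cbar <- pmin(data$tension_cbar, 200)
  data$date <- as.Date(data$date)
  class(data) <- c("tension_series", class(data))
  data
}

#' Default Irrinov-style tension thresholds
#'
#' Deep-soil wheat configuration: 100 cbar at 30 cm; at 60 cm, 80 cbar
#' before flag-leaf emergence (Z39) and 100 cbar after. Well-watered
#' management keeps 80 cbar at 60 cm throughout. 120 cbar at 60 cm is
#' the water-stress threshold (flagged, not a trigger).
#'
#' @param management `"WD"` (standard) or `"WW"` (override).
#' @return Threshold configuration list.
#' @export
irrinov_thresholds <- function(management = c("WD", "WW")) {
  management <- match.arg(management)
  list(
    d30 = 100,
    d60_pre_z39 = 80,
    d60_post_z39 = if (management == "WW") 80 else 100,
    stress_cbar = 120
  )
}

#' Irrigation trigger dates from tensiometer readings
#'
#' A day triggers irrigation when the measured tension at a monitored
#' depth reaches the threshold active for the current growth stage.
#'
#' @param tension A [tension_series()].
#' @param z39_date Date of flag-leaf emergence (Zadoks 39); readings
#'   before it use the pre-Z39 thresholds.
#' @param thresholds Configuration from [irrinov_thresholds()].
#' @return Tibble of trigger events: `date`, `depth_cm`,
#'   `tension_cbar`, `threshold`, `censored`, `water_stress` (tension at
#'   or beyond the 120 cbar stress threshold at 60 cm).
#' @export
irrigation_triggers <- function(tension, z39_date,
                                thresholds = irrinov_thresholds("WD")) {
  stopifnot(inherits(tension, "tension_series"))
  if (is.na(as.Date(z39_date))) ct_domain_error("unknown growth stage date")
  z39_date <- as.Date(z39_date)
  if (!all(tension$depth_cm %in% c(30, 60, 90))) {
    ct_validation_error("tensiometer depths must be 30, 60 or 90 cm")
  }
  pre <- tension$date < z39_date
  thr <- ifelse(tension$depth_cm == 30, thresholds$d30,
         ifelse(tension$depth_cm == 60,
                ifelse(pre, thresholds$d60_pre_z39, thresholds$d60_post_z39),
                Inf))  # 90 cm: monitoring only
  hit <- tension$tension_cbar >= thr
  out <- tension[hit, c("date", "depth_cm", "tension_cbar", "censored")]
  out$threshold <- thr[hit]
  out$water_stress <- out$depth_cm == 60 &
    out$tension_cbar >= thresholds$stress_cbar
  if (any(out$censored)) {
    warning("censored 200 cbar readings among triggers", call. = FALSE)
  }
  out
}

#' Rainfall interception efficiency of a shelter
#'
#' `100 (1 - mean(under) / reference)` where the reference is the
#' maximum (default) or mean of the pluviometer totals outside the
#' protected area.
#'
#' @param under Season totals (mm) of the pluviometers under the
#'   shelter.
#' @param outside Totals (mm) of the pluviometers outside, `> 0`.
#' @param reference `"max"` or `"mean"` of the outside totals.
#' @return List: `efficiency_pct` and the per-position `profile` of
#'   under-shelter efficiencies.
#' @export
interception_efficiency <- function(under, outside,
                                    reference = c("max", "mean")) {
  reference <- match.arg(reference)
  if (any(outside <= 0)) ct_domain_error("outside totals must be > 0")
  ref <- if (reference == "max") max(outside) else mean(outside)
  list(
    efficiency_pct = 100 * (1 - mean(under) / ref),
    profile = 100 * (1 - under / ref)
  )
}

#' Cumulative PAR and degree-day side effects of a shelter
#'
#' Cumulative PAR is the sum of daily PAR; cumulative degree-days are
#' the sum of daily `(Tmax + Tmin) / 2` above a 0 degC base, both from
#' the start of protection. Returns the percentage difference inside
#' versus outside the protected area.
#'
#' @param inside,outside Data frames with aligned `date`, `par`,
#'   `tmin`, `tmax` daily series.
#' @return List: `delta_cum_par_pct`, `delta_degree_days_pct`.
#' @export
shelter_side_effects <- function(inside, outside) {
  need <- c("date", "par", "tmin", "tmax")
  if (!all(need %in% names(inside)) || !all(need %in% names(outside))) {
    ct_schema_error("series need date, par, tmin, tmax")
  }
  if (!identical(as.Date(inside$date), as.Date(outside$date))) {
    ct_validation_error("inside and outside series are misaligned")
  }
  dd <- function(x) sum(pmax((x$tmax + x$tmin) / 2, 0))
  list(
    delta_cum_par_pct = 100 * (sum(inside$par) / sum(outside$par) - 1),
    delta_degree_days_pct = 100 * (dd(inside) / dd(outside) - 1)
  )
}

#' Daily degree-days
#'
#' @param tmax,tmin Daily maximum and minimum air temperature (degC).
#' @param base Base temperature (default 0).
#' @return Degree-days for the day.
#' @export
degree_day <- function(tmax, tmin, base = 0) {
  pmax((tmax + tmin) / 2 - base, 0)
}

#' Calibrate TDR readings against gravimetric water contents
#'
#' Ordinary least squares fit of gravimetric water content on the TDR
#' reading (the probes are linear but sensitive to their immediate
#' burial environment, so a site calibration is required).
#'
#' @param tdr TDR probe readings.
#' @param gravimetric Paired gravimetric water contents
#'   (`(fresh - dry) / dry` mass).
#' @return A `tdr_calibration`: `slope`, `intercept`, `r_squared` and a
#'   `transform(x)` function for subsequent readings.
#' @export
calibrate_tdr <- function(tdr, gravimetric) {
  if (length(tdr) != length(gravimetric) || length(tdr) < 3) {
    ct_validation_error("need at least 3 paired TDR/gravimetric samples")
  }
  if (var(tdr) == 0) ct_validation_error("TDR readings have zero variance")
  fit <- lm(gravimetric ~ tdr)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         transform = function(x) intercept + slope * x),
    class = "tdr_calibration"
  )
}
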
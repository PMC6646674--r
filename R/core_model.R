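# Core data model: trial design, phenology calendar and the long-format
# trait table that every other module reads and writes.

design_required_cols <- c(
  "plot_id", "genotype", "water_treatment", "nitrogen_treatment", "replicate"
)

phenology_stages <- c(
  "sowing", "emergence", "heading", "flowering", "maturity", "harvest"
)

#' Construct and validate a trial design table
#'
#' A trial design maps each microplot to a genotype, a water treatment
#' (`WW` well-watered / `WD` water-deficient), a nitrogen treatment
#' (`N+` optimal supply / `N0` none) and a replicate. Optional columns
#' `shelter` (1-8), `span` (1-2) and an axis-aligned plot rectangle
#' (`x`, `y`, `width`, `height`, metres, origin at the platform
#' south-west corner) are validated when present.
#'
#' @param data A data frame with at least `plot_id`, `genotype`,
#'   `water_treatment`, `nitrogen_treatment`, `replicate`.
#' @return A `trial_design` tibble.
#' @export
trial_design <- function(data) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(design_required_cols, names(data))
  if (length(missing) > 0) {
    ct_schema_error(paste0(
      "trial design is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(data$plot_id)) {
    ct_validation_error("duplicate plot_id in trial design")
  }
  if (!all(data$water_treatment %in% c("WW", "WD"))) {
    ct_validation_error("water_treatment must be 'WW' or 'WD'")
  }
  if (!all(data$nitrogen_treatment %in% c("N+", "N0"))) {
    ct_validation_error("nitrogen_treatment must be 'N+' or 'N0'")
  }
  geom_cols <- c("x", "y", "width", "height")
  if (all(geom_cols %in% names(data)) && nrow(data) > 1) {
    if (any(data$width <= 0) || any(data$height <= 0)) {
      ct_validation_error("plot rectangles must have positive extent")
    }
    if (rectangles_overlap(data$x, data$y, data$width, data$height)) {
      ct_validation_error("plot rectangles overlap")
    }
  }
  class(data) <- c("trial_design", class(data))
  data
}

# Pairwise open-interval overlap test for axis-aligned rectangles.
rectangles_overlap <- function(x, y, w, h) {
  n <- length(x)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    hit <- x[i] < x[j] + w[j] & x[j] < x[i] + w[i] &
      y[i] < y[j] + h[j] & y[j] < y[i] + h[i]
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Read a trial design from CSV
#'
#' @param path Path to a CSV with the columns documented in
#'   [trial_design()].
#' @return A validated `trial_design` tibble.
#' @export
load_design <- function(path) {
  if (!file.exists(path)) ct_schema_error(paste0("no such file: ", path))
  trial_design(readr::read_csv(path, show_col_types = FALSE))
}

#' Generate a factorial trial design
#'
#' Builds a complete genotype x water x nitrogen x replicate design with
#' non-overlapping 1 m x 6 m plot rectangles laid out in columns, the
#' geometry used on gantry platforms. With the defaults (22 genotypes,
#' 2 x 2 treatments, 3 replicates) this yields 264 plots.
#'
#' @param n_genotypes Number of genotypes (default 22).
#' @param n_replicates Biological replicates per treatment (default 3).
#' @param plot_width,plot_length Plot rectangle dimensions in metres.
#' @return A `trial_design` tibble.
#' @export
synthetic_design <- function(n_genotypes = 22, n_replicates = 3,
                             plot_width = 1, plot_length = 6) {
  grid <- tidyr::expand_grid(
    genotype = sprintf("G%02d", seq_len(n_genotypes)),
    water_treatment = c("WW", "WD"),
    nitrogen_treatment = c("N+", "N0"),
    replicate = seq_len(n_replicates)
  )
  n <- nrow(grid)
  per_row <- 48L  # one shelter of two 24-plot spans
  idx <- seq_len(n) - 1L
  grid$plot_id <- sprintf("P%03d", seq_len(n))
  grid$shelter <- (idx %/% per_row) %% 8L + 1L
  grid$span <- (idx %/% 24L) %% 2L + 1L
  grid$x <- (idx %% per_row) * plot_width
  grid$y <- (idx %/% per_row) * (plot_length + 1)
  grid$width <- plot_width
  grid$height <- plot_length
  trial_design(grid)
}

#' Construct a phenology calendar
#'
#' Stage dates for a plot or a treatment group. Dates present must be
#' strictly increasing in the order sowing, emergence, heading,
#' flowering, maturity, harvest.
#'
#' @param sowing,emergence,heading,flowering,maturity,harvest ISO dates
#'   (`Date` or parseable strings); all but `sowing` optional.
#' @param plot_id,treatment Optional scope labels. Plot-level calendars
#'   take precedence over treatment-level ones when both are supplied to
#'   a lookup.
#' @return A `phenology_calendar` object.
#' @export
phenology_calendar <- function(sowing, emergence = NULL, heading = NULL,
                               flowering = NULL, maturity = NULL,
                               harvest = NULL, plot_id = NULL,
                               treatment = NULL) {
  dates <- list(
    sowing = sowing, emergence = emergence, heading = heading,
    flowering = flowering, maturity = maturity, harvest = harvest
  )
  dates <- lapply(dates, function(d) if (is.null(d)) NULL else as.Date(d))
  present <- !vapply(dates, is.null, logical(1))
  if (!present[["sowing"]]) ct_validation_error("sowing date is required")
  seq_dates <- do.call(c, dates[present])
  if (any(diff(seq_dates) <= 0)) {
    ct_validation_error("phenology dates must be strictly increasing")
  }
  structure(
    list(dates = dates[present], plot_id = plot_id, treatment = treatment),
    class = "phenology_calendar"
  )
}

#' Growth stage active at a date
#'
#' Returns the latest stage whose date is on or before the query date
#' (piecewise-constant calendar).
#'
#' @param calendar A [phenology_calendar()].
#' @param date Query date.
#' @return Stage label, e.g. `"heading"`.
#' @export
stage_at <- function(calendar, date) {
  stopifnot(inherits(calendar, "phenology_calendar"))
  date <- as.Date(date)
  stage_dates <- do.call(c, calendar$dates)
  if (date < stage_dates[["sowing"]]) {
    ct_domain_error("query date is before sowing")
  }
  names(stage_dates)[max(which(stage_dates <= date))]
}

#' Days elapsed since sowing
#'
#' @param calendar A [phenology_calendar()].
#' @param date Date (or vector of dates).
#' @return Integer days after sowing.
#' @export
days_after_sowing <- function(calendar, date) {
  as.integer(as.Date(date) - calendar$dates$sowing)
}

#' Construct and validate a long-format trait table
#'
#' One row per (plot, trait, date); at most one value per key; rows are
#' sorted by plot, trait, date. This is the unit all temporal dynamics
#' operate on.
#'
#' @param data Data frame with `plot_id`, `trait`, `date`, `value` and
#'   optional `uncertainty`.
#' @return A `trait_series` tibble.
#' @export
trait_series <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("plot_id", "trait", "date", "value")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    ct_schema_error(paste0(
      "trait series is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (!"uncertainty" %in% names(data)) data$uncertainty <- NA_real_
  data$date <- as.Date(data$date)
  key <- paste(data$plot_id, data$trait, data$date)
  if (anyDuplicated(key)) {
    ct_validation_error("duplicate (plot_id, trait, date) in trait series")
  }
  data <- dplyr::arrange(data, .data$plot_id, .data$trait, .data$date)
  data <- data[, c("plot_id", "trait", "date", "value", "uncertainty")]
  class(data) <- c("trait_series", class(data))
  data
}

#' Read / write trait series CSV
#'
#' The on-disk format is `plot_id,trait,date,value,uncertainty` with ISO
#' dates. Writing then reading reproduces values bit-exactly (shortest
#' round-trippable decimal representation).
#'
#' @param path CSV path.
#' @return `read_trait_series()` returns a `trait_series` tibble.
#' @export
read_trait_series <- function(path) {
  trait_series(readr::read_csv(
    path,
    col_types = readr::cols(
      plot_id = readr::col_character(),
      trait = readr::col_character(),
      date = readr::col_date(),
      value = readr::col_double(),
      uncertainty = readr::col_double()
    )
  ))
}

#' @param series A `trait_series` tibble.
#' @rdname read_trait_series
#' @export
write_trait_series <- function(series, path) {
  stopifnot(inherits(series, "trait_series"))
  readr::write_csv(series, path)
  invisible(path)
}

#' Pivot a trait series to a wide convenience table
#'
#' @param series A `trait_series` tibble.
#' @return Tibble with one column per trait.
#' @export
trait_series_wide <- function(series) {
  tidyr::pivot_wider(
    dplyr::select(series, -"uncertainty"),
    names_from = "trait", values_from = "value"
  )
}
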
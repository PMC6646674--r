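# Small fixtures built in code, shared across test files.

toy_design_df <- function() {
  data.frame(
    plot_id = c("P1", "P2", "P3"),
    genotype = c("A", "A", "B"),
    water_treatment = c("WW", "WD", "WW"),
    nitrogen_treatment = c("N+", "N+", "N0"),
    replicate = c(1L, 1L, 1L)
  )
}

toy_calendar <- function() {
  phenology_calendar(
    sowing = "2016-10-20", emergence = "2016-11-05",
    heading = "2017-05-10", flowering = "2017-05-25",
    maturity = "2017-07-01", harvest = "2017-07-18"
  )
}

# A trait series on a numeric-friendly date axis.
toy_series <- function(days, values, plot = "P1", trait = "GF",
                       origin = as.Date("2017-03-01")) {
  trait_series(data.frame(
    plot_id = plot, trait = trait, date = origin + days, value = values
  ))
}

# Densely sampled spectra (0.1 nm) so Gaussian band supports are
# symmetric about their centres.
flat_spectrum <- function(level = 0.3, step = 0.1) {
  wl <- seq(380, 1100, by = step)
  structure(
    list(wavelengths = wl, reflectance = rep(level, length(wl)),
         snr_mask = wl >= 450 & wl <= 820),
    class = "spectrum"
  )
}

# Spectrum taking prescribed band values exactly: constant plateaus
# +-5 nm around each centre (wider than the 3 nm FWHM filter support),
# linear in between.
spectrum_with_bands <- function(values, step = 0.1) {
  wl <- seq(380, 1100, by = step)
  ctr <- as.numeric(names(values))
  knots <- c(rbind(ctr - 5, ctr + 5))
  vals <- rep(values, each = 2)
  refl <- approx(knots, vals, xout = wl, rule = 2)$y
  structure(
    list(wavelengths = wl, reflectance = refl,
         snr_mask = wl >= 450 & wl <= 820),
    class = "spectrum"
  )
}
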
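# Seeded synthetic-scene generators. Every generator is a pure function
# of (parameters, seed), records its ground truth alongside the
# artifact, and emulates one of the pipeline's sensor inputs: two-class
# image mosaics, Poisson gap fractions, two-endmember reflectance
# spectra, ground + canopy point clouds, logistic trait seasons.

#' Generate a green/soil mosaic image with known green fraction
#'
#' Pixels are assigned to the green class by seeded sampling so the
#' label fraction equals `gcf_true` to within one pixel of rounding;
#' green and soil pixels are drawn from two Gaussian colour
#' distributions around foliage and bare-soil tones.
#'
#' @param gcf_true Target green fraction in `[0, 1]`.
#' @param size Image height and width in pixels.
#' @param seed Integer seed.
#' @param noise_sd Per-channel colour noise SD.
#' @return List: `image` ([annotated_image()]), `labels` (logical
#'   matrix), `truth` (the exact label fraction).
#' @export
gen_mosaic <- function(gcf_true, size = c(64, 64), seed = 1L,
                       noise_sd = 0.05) {
  if (gcf_true < 0 || gcf_true > 1) {
    ct_domain_error("gcf_true must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    npix <- prod(size)
    n_green <- round(gcf_true * npix)
    labels <- matrix(FALSE, size[1], size[2])
    labels[sample.int(npix, n_green)] <- TRUE
    green_tone <- c(0.25, 0.55, 0.18)
    soil_tone <- c(0.50, 0.40, 0.28)
    px <- array(0, dim = c(size[1], size[2], 3))
    for (c in 1:3) {
      base <- ifelse(labels, green_tone[c], soil_tone[c])
      px[, , c] <- pmin(pmax(base + rnorm(npix, 0, noise_sd), 0), 1)
    }
    list(
      image = annotated_image(px, gray_panel_rgb = c(0.5, 0.5, 0.5)),
      labels = labels,
      truth = list(gcf = n_green / npix, seed = seed)
    )
  })
}

#' Generate multi-angle gap fractions from a known canopy
#'
#' Forward-model gap fractions with seeded multiplicative Gaussian
#' noise, clipped to (0, 1].
#'
#' @param gai,ala True canopy parameters.
#' @param angles View zenith angles (degrees).
#' @param noise_sd Multiplicative noise SD (0 gives exact forward
#'   values).
#' @param seed Integer seed.
#' @return A [canopy_observation()] with a `truth` attribute.
#' @export
gen_gap_fractions <- function(gai, ala, angles = c(0, 45), noise_sd = 0,
                              seed = 1L) {
  po0 <- forward_po(gai, ala, angles)
  po <- withr::with_seed(seed, po0 * (1 + rnorm(length(angles), 0, noise_sd)))
  po <- pmin(pmax(po, 1e-6), 1)
  obs <- canopy_observation(po, angles)
  attr(obs, "truth") <- list(gai = gai, ala = ala, seed = seed)
  obs
}

# Smooth built-in endmember reflectance templates: a leaf curve with a
# green bump, strong red absorption and a NIR plateau behind a logistic
# red edge, and a near-flat rising soil line.
leaf_template <- function(wl) {
  0.04 + 0.08 * exp(-((wl - 550) / 40)^2) + 0.46 / (1 + exp(-(wl - 720) / 12))
}

soil_template <- function(wl) {
  0.15 + 0.20 * (wl - 380) / 720
}

#' Generate a paired canopy/panel spectroradiometer scan
#'
#' Canopy digital numbers are the instrument sensitivity times a linear
#' mixture of the built-in leaf and soil endmember reflectances; the
#' panel scan is the same sensitivity times the panel reflectance
#' (0.99), so calibration recovers the mixture exactly at zero noise.
#'
#' @param mix_fraction Leaf endmember fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @param n_pixels Number of detector pixels over 380-1100 nm.
#' @param noise_sd Multiplicative DN noise SD.
#' @return List: `canopy`, `panel` ([raw_scan()]s), `truth`.
#' @export
gen_spectrum <- function(mix_fraction, seed = 1L, n_pixels = 256,
                         noise_sd = 0) {
  if (mix_fraction < 0 || mix_fraction > 1) {
    ct_domain_error("mix_fraction must lie in [0, 1]")
  }
  wl <- seq(380, 1100, length.out = n_pixels)
  refl <- mix_fraction * leaf_template(wl) +
    (1 - mix_fraction) * soil_template(wl)
  sens <- 2000 * exp(-((wl - 740) / 330)^2) + 200
  withr::with_seed(seed, {
    canopy_dn <- sens * refl * (1 + rnorm(n_pixels, 0, noise_sd))
    panel_dn <- sens * 0.99
    list(
      canopy = raw_scan(wl, pmax(canopy_dn, 0), role = "canopy"),
      panel = raw_scan(wl, panel_dn, role = "panel"),
      truth = list(mix_fraction = mix_fraction, reflectance = refl,
                   seed = seed)
    )
  })
}

#' Generate a ground + canopy LiDAR point cloud with known height
#'
#' Ground points are Gaussian around z = 0 (SD 5 mm); canopy point
#' heights follow `height_true x Beta(2, 1)` (density increasing toward
#' the canopy top). The recorded truth height is the 99.5% quantile of
#' that profile, `height_true x sqrt(0.995)`.
#'
#' @param height_true Canopy top height in metres, `>= 0` (0 gives a
#'   ground-only cloud).
#' @param n Total number of points.
#' @param veg_fraction Fraction of points on vegetation.
#' @param seed Integer seed.
#' @return List: `cloud` ([point_cloud()]), `labels` (TRUE =
#'   vegetation), `truth` (`height_m` at the 99.5% profile quantile).
#' @export
gen_cloud <- function(height_true, n = 20000, veg_fraction = 0.7,
                      seed = 1L) {
  if (height_true < 0) ct_domain_error("height_true must be >= 0")
  withr::with_seed(seed, {
    n_veg <- if (height_true == 0) 0L else round(n * veg_fraction)
    n_gnd <- n - n_veg
    z <- c(rnorm(n_gnd, 0, 0.005), height_true * rbeta(n_veg, 2, 1))
    labels <- c(rep(FALSE, n_gnd), rep(TRUE, n_veg))
    ord <- sample.int(n)  # shuffle so order carries no information
    df <- data.frame(x = runif(n, 0, 1), y = runif(n, 0, 6), z = z[ord])
    list(
      cloud = point_cloud(df),
      labels = labels[ord],
      truth = list(height_m = height_true * sqrt(0.995),
                   height_top_m = height_true, seed = seed)
    )
  })
}

#' Generate a season of trait series with treatment-dependent stress onset
#'
#' Green fraction rises logistically to a plateau and decays in
#' senescence; a stressed treatment follows the control curve until its
#' stress onset day, then decays faster, so treatment divergence begins
#' at the onset by construction. Height follows a saturating logistic
#' with a treatment-scaled maximum.
#'
#' @param onset_control Day after sowing when control senescence
#'   begins.
#' @param onset_stressed Stress onset day for the stressed treatment
#'   (earlier than `onset_control` for a real stress).
#' @param sowing Sowing date (ISO).
#' @param season_days Season length in days.
#' @param step_days Observation interval in days.
#' @param noise_sd Multiplicative observation noise SD.
#' @param seed Integer seed.
#' @return List: `series` (a [trait_series()] with plots `control` and
#'   `stressed`, traits `GF` and `height`), `truth`.
#' @export
gen_trait_season <- function(onset_control = 230, onset_stressed = 200,
                             sowing = "2016-10-20", season_days = 270,
                             step_days = 3, noise_sd = 0, seed = 1L) {
  if (onset_stressed > season_days || onset_control > season_days) {
    ct_domain_error("stress onset must fall within the season")
  }
  days <- seq(0, season_days, by = step_days)
  plateau <- 0.9 / (1 + exp(-(days - 60) / 10))
  gf_curve <- function(onset) {
    decay <- ifelse(days >= onset, exp(-0.15 * (days - onset)), 1)
    plateau * decay
  }
  height <- function(hmax) hmax / (1 + exp(-(days - 150) / 12))
  dates <- as.Date(sowing) + days
  withr::with_seed(seed, {
    noisy <- function(v) pmax(v * (1 + rnorm(length(v), 0, noise_sd)), 0)
    series <- dplyr::bind_rows(
      tibble::tibble(plot_id = "control", trait = "GF", date = dates,
                     value = noisy(gf_curve(onset_control))),
      tibble::tibble(plot_id = "stressed", trait = "GF", date = dates,
                     value = noisy(gf_curve(onset_stressed))),
      tibble::tibble(plot_id = "control", trait = "height", date = dates,
                     value = noisy(height(0.85))),
      tibble::tibble(plot_id = "stressed", trait = "height", date = dates,
                     value = noisy(height(0.70)))
    )
    list(
      series = trait_series(series),
      truth = list(onset_control = onset_control,
                   onset_stressed = onset_stressed,
                   sowing = as.Date(sowing), seed = seed)
    )
  })
}
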
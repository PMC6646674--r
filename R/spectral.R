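# Spectroradiometer processing: reflectance calibration against a
# characterised reference panel, SNR-based usable-band masking, Gaussian
# band resampling and the NDVI / MTCI / MCARI2 vegetation indices.

#' Construct a raw spectroradiometer scan
#'
#' @param wavelengths Wavelengths in nm, strictly increasing.
#' @param counts Digital numbers, `>= 0`.
#' @param role `"canopy"` or `"panel"`.
#' @param integration Optional metadata list.
#' @return A `raw_scan`.
#' @export
raw_scan <- function(wavelengths, counts, role = c("canopy", "panel"),
                     integration = list()) {
  role <- match.arg(role)
  if (length(wavelengths) != length(counts)) {
    ct_schema_error("wavelengths and counts must have the same length")
  }
  if (any(diff(wavelengths) <= 0)) {
    ct_validation_error("wavelengths must be strictly increasing")
  }
  if (any(counts < 0)) ct_validation_error("counts must be >= 0")
  structure(
    list(wavelengths = wavelengths, counts = counts, role = role,
         integration = integration),
    class = "raw_scan"
  )
}

#' Estimate per-wavelength SNR from repeated scans
#'
#' Signal-to-noise is the ratio of the mean to the standard deviation of
#' the digital numbers across a session's repeat scans.
#'
#' @param scans List of [raw_scan()]s on the same wavelength grid.
#' @return Numeric SNR per wavelength.
#' @export
estimate_snr <- function(scans) {
  mat <- scan_matrix(scans)
  mu <- colMeans(mat)
  s <- apply(mat, 2, sd)
  ifelse(s == 0, Inf, mu / s)
}

scan_matrix <- function(scans) {
  wl <- scans[[1]]$wavelengths
  for (s in scans) {
    if (!isTRUE(all.equal(s$wavelengths, wl))) {
      ct_validation_error("scans are not on a common wavelength grid")
    }
  }
  do.call(rbind, lapply(scans, `[[`, "counts"))
}

#' Average repeat scans with outlier rejection
#'
#' Scans whose median absolute deviation from the per-session median
#' spectrum exceeds 3 robust standard deviations are discarded before
#' averaging.
#'
#' @param scans List of [raw_scan()]s (typically the three acquisitions
#'   of a pass).
#' @return A single averaged `raw_scan`.
#' @export
average_scans <- function(scans, mad_limit = 3) {
  mat <- scan_matrix(scans)
  if (nrow(mat) > 2) {
    med <- apply(mat, 2, median)
    dev <- rowMeans(abs(sweep(mat, 2, med)))
    cut <- median(dev) + mad_limit * stats::mad(dev)
    keep <- dev <= cut | stats::mad(dev) == 0
    mat <- mat[keep, , drop = FALSE]
  }
  raw_scan(scans[[1]]$wavelengths, colMeans(mat), role = scans[[1]]$role,
           integration = scans[[1]]$integration)
}

#' Calibrate a canopy scan to reflectance
#'
#' `R(lambda) = canopy / panel * panel_reflectance(lambda)`. The usable
#' mask is true only inside `usable_range` (default 450-820 nm, where
#' the instrument's signal-to-noise exceeds 20) and, when an SNR vector
#' is supplied, where `snr >= snr_threshold`.
#'
#' @param canopy,panel [raw_scan()]s on the same wavelength grid.
#' @param panel_reflectance Scalar or per-wavelength panel reflectance
#'   factor (default 0.99, a Spectralon-class surface).
#' @param snr Optional per-wavelength SNR from [estimate_snr()].
#' @param snr_threshold SNR acceptance threshold (default 20).
#' @param usable_range Usable wavelength range in nm.
#' @return A `spectrum`: wavelengths, reflectance and `snr_mask`.
#' @export
calibrate_reflectance <- function(canopy, panel, panel_reflectance = 0.99,
                                  snr = NULL, snr_threshold = 20,
                                  usable_range = c(450, 820)) {
  stopifnot(inherits(canopy, "raw_scan"), inherits(panel, "raw_scan"))
  if (!isTRUE(all.equal(canopy$wavelengths, panel$wavelengths))) {
    ct_calibration_error("canopy and panel scans have mismatched grids")
  }
  wl <- canopy$wavelengths
  in_range <- wl >= usable_range[1] & wl <= usable_range[2]
  if (any(panel$counts[in_range] == 0)) {
    ct_calibration_error("zero panel count inside the usable range")
  }
  refl <- canopy$counts / panel$counts * panel_reflectance
  refl[!is.finite(refl)] <- NA_real_
  mask <- in_range & is.finite(refl)
  if (!is.null(snr)) mask <- mask & snr >= snr_threshold
  structure(
    list(wavelengths = wl, reflectance = refl, snr_mask = mask),
    class = "spectrum"
  )
}

#' Standard index band set
#'
#' Band centres (nm) needed by NDVI, MTCI and MCARI2, all sampled with a
#' 3 nm full width at half maximum Gaussian response.
#'
#' @param fwhm Full width at half maximum in nm.
#' @return Tibble of band centres and FWHM.
#' @export
band_set <- function(fwhm = 3) {
  if (fwhm <= 0) ct_validation_error("fwhm must be > 0")
  tibble::tibble(center = c(550, 670, 681, 709, 754, 800), fwhm = fwhm)
}

#' Sample a spectral band with a Gaussian response
#'
#' Gaussian-weighted mean with `sigma = fwhm / (2 sqrt(2 ln 2))`;
#' weights are renormalised over the unmasked samples inside the +-2
#' sigma support.
#'
#' @param spec A [calibrate_reflectance()] spectrum.
#' @param center Band centre in nm.
#' @param fwhm Full width at half maximum in nm.
#' @return Band reflectance (scalar).
#' @export
sample_band <- function(spec, center, fwhm = 3) {
  stopifnot(inherits(spec, "spectrum"))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  wl <- spec$wavelengths
  sel <- abs(wl - center) <= 2 * sigma & spec$snr_mask
  if (!any(sel)) {
    ct_domain_error(sprintf("band %g nm unusable: masked support", center))
  }
  w <- exp(-(wl[sel] - center)^2 / (2 * sigma^2))
  sum(w * spec$reflectance[sel]) / sum(w)
}

index_bands <- function(spec, centers, fwhm) {
  setNames(vapply(centers, sample_band, numeric(1), spec = spec,
                  fwhm = fwhm), paste0("R", centers))
}

#' Vegetation indices from a calibrated spectrum
#'
#' * `NDVI = (R800 - R670) / (R800 + R670)` — amount of vegetation;
#'   normalised, invariant to uniform scaling of the spectrum.
#' * `MTCI = (R754 - R709) / (R709 - R681)` — red-edge chlorophyll;
#'   also scale-invariant.
#' * `MCARI2 = 1.5 [2.5 (R800 - R670) - 1.3 (R800 - R550)] /
#'   (sqrt((2 R800 + 1)^2 - (6 R800 - 5 sqrt(R670))) - 0.5)` — green-LAI
#'   targeting; non-normalised, sensitive to spectrum intensity.
#'
#' @param spec A [calibrate_reflectance()] spectrum.
#' @param fwhm Band FWHM in nm (default 3).
#' @return Index value (scalar).
#' @export
ndvi <- function(spec, fwhm = 3) {
  b <- index_bands(spec, c(670, 800), fwhm)
  (b[["R800"]] - b[["R670"]]) / (b[["R800"]] + b[["R670"]])
}

#' @rdname ndvi
#' @export
mtci <- function(spec, fwhm = 3) {
  b <- index_bands(spec, c(681, 709, 754), fwhm)
  denom <- b[["R709"]] - b[["R681"]]
  if (abs(denom) < 1e-12) ct_domain_error("MTCI undefined: R709 equals R681")
  (b[["R754"]] - b[["R709"]]) / denom
}

#' @param literal If `TRUE`, use the denominator without the square
#'   root, i.e. `(2 R800 + 1)^2 - (6 R800 - 5 sqrt(R670)) - 0.5`, for
#'   comparison with the non-rooted variant sometimes typeset in the
#'   literature. Default `FALSE` (original published form).
#' @rdname ndvi
#' @export
mcari2 <- function(spec, fwhm = 3, literal = FALSE) {
  b <- index_bands(spec, c(550, 670, 800), fwhm)
  r800 <- b[["R800"]]; r670 <- b[["R670"]]; r550 <- b[["R550"]]
  num <- 1.5 * (2.5 * (r800 - r670) - 1.3 * (r800 - r550))
  inner <- (2 * r800 + 1)^2 - (6 * r800 - 5 * sqrt(r670))
  denom <- if (literal) inner - 0.5 else sqrt(inner) - 0.5
  num / denom
}

#' Plot-level spectrum from repeat scans
#'
#' Normalised (calibrated) reflectances are averaged first and indices
#' computed on the average — the default plot-level path. Set
#' `per_scan = TRUE` to instead average per-scan indices.
#'
#' @param canopy_scans List of canopy [raw_scan()]s.
#' @param panel Panel [raw_scan()].
#' @param per_scan Average indices instead of spectra (non-default
#'   path, exposed for comparison).
#' @inheritParams calibrate_reflectance
#' @return For the default path, a `spectrum`; with `per_scan = TRUE`, a
#'   named list of averaged index values.
#' @export
plot_reflectance <- function(canopy_scans, panel, panel_reflectance = 0.99,
                             per_scan = FALSE, ...) {
  specs <- lapply(canopy_scans, calibrate_reflectance, panel = panel,
                  panel_reflectance = panel_reflectance, ...)
  if (!per_scan) {
    avg <- specs[[1]]
    avg$reflectance <- rowMeans(
      do.call(cbind, lapply(specs, `[[`, "reflectance"))
    )
    return(avg)
  }
  vals <- lapply(specs, function(s) c(ndvi = ndvi(s), mtci = mtci(s),
                                      mcari2 = mcari2(s)))
  as.list(colMeans(do.call(rbind, vals)))
}

#' Read a spectrum CSV (`wavelength_nm,value`)
#'
#' Metadata header lines starting with `#` are skipped.
#'
#' @param path CSV path.
#' @param role Scan role.
#' @return A [raw_scan()].
#' @export
read_scan <- function(path, role = "canopy") {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  raw_scan(df$wavelength_nm, df$value, role = role)
}
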
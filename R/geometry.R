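# Acquisition-geometry calculators for the gantry sensor bay: ground
# sampling of the RGB cameras, LiDAR scan resolutions, spectroradiometer
# fibre field of view.

#' Camera pixel resolution in the object plane
#'
#' `fov_extent x 1000 / detector_pixels`, reported to 2 decimals.
#'
#' @param fov_extent Field-of-view extent in the object plane (m).
#' @param detector_pixels Detector pixels across that extent, `> 0`.
#' @param report Round to the reporting precision (default TRUE).
#' @return mm per pixel.
#' @export
pixel_resolution <- function(fov_extent, detector_pixels, report = TRUE) {
  if (any(detector_pixels <= 0)) ct_domain_error("detector_pixels must be > 0")
  res <- fov_extent * 1000 / detector_pixels
  if (report) round(res, 2) else res
}

#' LiDAR longitudinal and transversal scan resolutions
#'
#' Longitudinal: `speed / frequency` (metres travelled per scan line);
#' transversal: `distance x tan(angular_step)` (spot spacing at the
#' target). Reported to the nearest mm.
#'
#' @param speed Platform travel speed (m/s).
#' @param frequency Scan frequency (Hz), `> 0`.
#' @param distance Sensing distance (m).
#' @param angular_step Angular step between beams (degrees).
#' @param report Round to the nearest mm (default TRUE).
#' @return List: `longitudinal_mm`, `transversal_mm`.
#' @export
lidar_resolutions <- function(speed, frequency, distance, angular_step,
                              report = TRUE) {
  if (frequency <= 0) ct_domain_error("frequency must be > 0")
  lon <- speed / frequency * 1000
  trans <- distance * tan(angular_step * pi / 180) * 1000
  if (report) list(longitudinal_mm = round(lon), transversal_mm = round(trans))
  else list(longitudinal_mm = lon, transversal_mm = trans)
}

#' Fibre-fed spectroradiometer field of view
#'
#' Paraxial full extent `2 x distance x NA`. The exact trigonometric
#' form `2 x distance x tan(asin(NA))` differs by about 2% at NA 0.2
#' and is available via `exact = TRUE`.
#'
#' @param distance Sensing distance (m).
#' @param numerical_aperture Fibre numerical aperture, in (0, 1).
#' @param exact Use the exact trigonometric form.
#' @return Full field extent in metres.
#' @export
fiber_fov <- function(distance, numerical_aperture, exact = FALSE) {
  if (any(numerical_aperture <= 0 | numerical_aperture >= 1)) {
    ct_domain_error("numerical aperture must lie in (0, 1)")
  }
  if (exact) 2 * distance * tan(asin(numerical_aperture))
  else 2 * distance * numerical_aperture
}

#' Sensor-bay resolution table for a platform preset
#'
#' @param preset Currently `"phenofield-2017"`: 2044 px camera with a
#'   0.60 m field at 1.5 m, 290 Hz / 0.2 deg LiDAR at 0.3 m/s, NA 0.2
#'   fibre at 1.5 m.
#' @return Tibble of sensors and their resolution figures.
#' @export
resolution_table <- function(preset = "phenofield-2017") {
  if (preset != "phenofield-2017") ct_domain_error("unknown preset")
  lid <- lidar_resolutions(speed = 0.3, frequency = 290, distance = 1.5,
                           angular_step = 0.2)
  tibble::tibble(
    sensor = c("RGB camera", "LiDAR longitudinal", "LiDAR transversal",
               "Spectroradiometer fibre FOV"),
    value = c(pixel_resolution(0.60, 2044), lid$longitudinal_mm,
              lid$transversal_mm, fiber_fov(1.5, 0.2) * 100),
    unit = c("mm/pixel", "mm", "mm", "cm")
  )
}
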
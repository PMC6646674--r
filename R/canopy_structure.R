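# GAI / ALA retrieval from multi-angle gap fractions: Poisson
# turbid-medium forward model with an ellipsoidal leaf angle
# distribution, inverted by exhaustive look-up-table minimisation.

#' Ellipsoidal projection function G
#'
#' Projected leaf area per unit leaf area in the view direction, for a
#' canopy whose leaf normals follow the one-parameter ellipsoidal
#' distribution with shape `chi` (`chi = 1` is the spherical case).
#' Uses Campbell's extinction approximation
#' `K = sqrt(chi^2 + tan^2(theta)) / (chi + 1.774 (chi + 1.182)^-0.733)`
#' and returns `G = K cos(theta)`.
#'
#' @param theta_p View zenith angle in degrees, `0 <= theta_p < 90`.
#' @param chi Ellipsoidal shape parameter, `> 0`.
#' @return Projection value `G > 0`; vectorised over `theta_p`.
#' @export
g_function <- function(theta_p, chi) {
  if (any(chi <= 0)) ct_domain_error("chi must be > 0")
  if (any(theta_p < 0 | theta_p >= 90)) {
    ct_domain_error("theta_p must lie in [0, 90)")
  }
  th <- theta_p * pi / 180
  k <- sqrt(chi^2 + tan(th)^2) / (chi + 1.774 * (chi + 1.182)^(-0.733))
  k * cos(th)
}

#' Convert between the ellipsoidal shape parameter and the mean leaf angle
#'
#' The ellipsoidal distribution's mean leaf inclination (from
#' horizontal) is `ALA = 9.65 (3 + chi)^-1.65` radians; the inverse is
#' closed-form. Round trip is exact to numerical precision.
#'
#' @param chi Shape parameter `> 0`.
#' @return `ala_from_chi()`: mean leaf angle in degrees in (0, 90).
#' @export
ala_from_chi <- function(chi) {
  if (any(chi <= 0)) ct_domain_error("chi must be > 0")
  9.65 * (3 + chi)^(-1.65) * 180 / pi
}

#' @param ala Mean leaf angle in degrees, `0 < ala < 90`.
#' @rdname ala_from_chi
#' @export
chi_from_ala <- function(ala) {
  if (any(ala <= 0 | ala >= 90)) ct_domain_error("ala must lie in (0, 90)")
  chi <- (ala * pi / 180 / 9.65)^(-1 / 1.65) - 3
  if (any(chi <= 0)) ct_domain_error("ala out of the ellipsoidal domain")
  chi
}

#' Poisson gap fraction forward model
#'
#' `Po(theta_p) = exp(-G(theta_p, theta_l) * GAI / cos(theta_p))`: the
#' probability that a ray at view zenith `theta_p` traverses a turbid
#' canopy of green area index `gai` uninterrupted.
#'
#' @param gai Green area index, `>= 0` (m2 m-2).
#' @param ala Average leaf angle in degrees.
#' @param theta_p View zenith angle(s) in degrees.
#' @return Gap fraction(s) in (0, 1].
#' @export
forward_po <- function(gai, ala, theta_p) {
  if (any(gai < 0)) ct_domain_error("gai must be >= 0")
  chi <- chi_from_ala(ala)
  g <- g_function(theta_p, chi)
  exp(-g * gai / cos(theta_p * pi / 180))
}

#' Multi-angle gap fraction observation
#'
#' @param po Gap fractions in `[0,1]`, one per view angle
#'   (`Po = 1 - GCF`).
#' @param angles View zenith angles in degrees, in `[0, 75]`.
#' @param plot_id,date Optional identifiers.
#' @return A `canopy_observation`.
#' @export
canopy_observation <- function(po, angles, plot_id = NULL, date = NULL) {
  if (length(po) != length(angles) || length(po) == 0) {
    ct_schema_error("po and angles must be non-empty and the same length")
  }
  if (any(po < 0 | po > 1)) ct_validation_error("gap fractions must lie in [0,1]")
  if (any(angles < 0 | angles > 75)) {
    ct_validation_error("view angles must lie in [0, 75] degrees")
  }
  structure(
    list(po = as.numeric(po), angles = as.numeric(angles),
         plot_id = plot_id, date = date),
    class = "canopy_observation"
  )
}

#' Build the (GAI, ALA) look-up table
#'
#' Tabulates the forward gap fraction over a dense (GAI, ALA) grid for a
#' fixed set of view angles. Grid rows are ordered by GAI then ALA so
#' the inversion's tie-break (smaller GAI, then smaller ALA) is the
#' first minimum. Defaults: GAI 0-8 step 0.05, ALA 10-80 deg step 1.
#'
#' @param angles View zenith angles (degrees), non-empty.
#' @param gai_range,ala_range Length-2 ranges.
#' @param gai_step,ala_step Grid steps.
#' @return A `gai_lut` with the Po matrix (grid rows x angles), the grid
#'   and an `ala_weakly_identifiable` flag for single-angle tables.
#' @export
build_lut <- function(angles = c(0, 45), gai_range = c(0, 8),
                      ala_range = c(10, 80), gai_step = 0.05,
                      ala_step = 1) {
  if (length(angles) == 0) ct_validation_error("angle set must be non-empty")
  gais <- seq(gai_range[1], gai_range[2], by = gai_step)
  alas <- seq(ala_range[1], ala_range[2], by = ala_step)
  grid <- expand.grid(ala = alas, gai = gais)[, c("gai", "ala")]
  chi <- chi_from_ala(grid$ala)
  po <- vapply(angles, function(a) {
    exp(-g_function(a, chi) * grid$gai / cos(a * pi / 180))
  }, numeric(nrow(grid)))
  po <- matrix(po, nrow = nrow(grid),
               dimnames = list(NULL, as.character(angles)))
  structure(
    list(po = po, grid = tibble::as_tibble(grid), angles = angles,
         gai_step = gai_step, ala_step = ala_step,
         ala_weakly_identifiable = length(angles) < 2),
    class = "gai_lut"
  )
}

#' Invert gap fractions to a (GAI, ALA) estimate
#'
#' Exhaustive search for the LUT grid point minimising the RMSE between
#' observed and tabulated gap fractions over the observation's angles.
#' Ties are broken toward smaller GAI then smaller ALA. An observation
#' of `Po = 1` everywhere yields GAI 0 and is flagged non-identifiable.
#'
#' @param obs A [canopy_observation()] whose angles are a subset of the
#'   LUT angles.
#' @param lut A [build_lut()] result.
#' @param weights Optional per-angle weights for the cost (default
#'   unweighted).
#' @return A `canopy_estimate`: `gai`, `ala`, `chi`, `cost` (RMSE) and
#'   identifiability flags.
#' @export
invert_gai_ala <- function(obs, lut, weights = NULL) {
  stopifnot(inherits(obs, "canopy_observation"), inherits(lut, "gai_lut"))
  key <- as.character(obs$angles)
  if (!all(key %in% colnames(lut$po))) {
    ct_validation_error("observation angles are not all in the LUT")
  }
  tab <- lut$po[, key, drop = FALSE]
  if (is.null(weights)) weights <- rep(1, length(obs$po))
  w <- weights / sum(weights)
  sq <- sweep(tab, 2, obs$po)^2
  cost <- sqrt(as.vector(sq %*% w))
  best <- which.min(cost)  # first minimum: smallest GAI, then ALA
  gai <- lut$grid$gai[best]
  ala <- lut$grid$ala[best]
  structure(
    list(gai = gai, ala = ala, chi = chi_from_ala(ala), cost = cost[best],
         ala_non_identifiable = gai == 0 || lut$ala_weakly_identifiable,
         plot_id = obs$plot_id, date = obs$date),
    class = "canopy_estimate"
  )
}

#' Invert a table of green cover fractions to GAI/ALA series
#'
#' Convenience wrapper: converts GCF to gap fraction (`Po = 1 - GCF`),
#' groups by plot and date and inverts each multi-angle observation. The
#' retrieved index is labelled `GPAI` because green-only cover fractions
#' feed it.
#'
#' @param gcf Tibble with `plot_id`, `date`, `view_angle`, `gcf`.
#' @param lut A [build_lut()] covering the observed angles.
#' @return A [trait_series()] with traits `GPAI` and `ALA`.
#' @export
invert_gcf_table <- function(gcf, lut) {
  need <- c("plot_id", "date", "view_angle", "gcf")
  if (!all(need %in% names(gcf))) {
    ct_schema_error("gcf table needs plot_id, date, view_angle, gcf")
  }
  groups <- dplyr::group_split(dplyr::group_by(gcf, .data$plot_id, .data$date))
  rows <- lapply(groups, function(g) {
    obs <- canopy_observation(1 - g$gcf, g$view_angle,
                              plot_id = g$plot_id[1], date = g$date[1])
    est <- invert_gai_ala(obs, lut)
    tibble::tibble(
      plot_id = g$plot_id[1], trait = c("GPAI", "ALA"),
      date = as.Date(g$date[1]), value = c(est$gai, est$ala),
      uncertainty = NA_real_
    )
  })
  trait_series(dplyr::bind_rows(rows))
}
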
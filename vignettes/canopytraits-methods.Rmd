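---
title: "Methods: from gantry sensor data to canopy traits and stress indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gantry sensor data to canopy traits and stress indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopytraits)
```

`canopytraits` implements the trait-extraction and stress-monitoring
computations used on gantry-based field phenotyping platforms: microplot
RGB images, spectroradiometer scans and LiDAR point clouds on the way
in; green cover fraction, Green Area Index (GAI) and Average Leaf Angle
(ALA), vegetation indices, canopy height, trait-curve indicators and a
soil water budget on the way out. This vignette documents the models,
their assumptions, the tunable parameters and the design choices that
were genuinely open.

## Green cover fraction from RGB images

Images are stored as linear `[0, 1]` floats (8/16-bit inputs are
rescaled on read). White balance applies per-channel gains
$g_c = \bar p / p_c$ computed on a gray reference panel so the panel
becomes achromatic; this standardisation is what makes colour-based
classification robust across acquisition sessions.

Pixels are classified green / non-green by a linear support vector
machine over the feature vector $(R, G, B,\; 2G - R - B,\; \text{hue})$.
The field method's reference training set is proprietary to the
platform operators, so the classifier here is trained on labelled
synthetic mosaics (`gen_mosaic()`); the feature set is a declared
choice — the excess-green index $2G - R - B$ and hue carry most of the
separation between foliage and soil tones. A plain threshold on
excess-green (default 0.1) is kept as a parameter-free fallback
baseline. The green cover fraction (GCF) is the exact pixel count ratio,
so it is additive over image tiles and always in `[0, 1]`. Intra-plot
border removal is a configurable pixel-margin crop (default 0).

## GAI and ALA by gap-fraction inversion

The gap fraction at view zenith $\theta_p$ is $P_o = 1 - \mathrm{GCF}$.
The canopy is modelled as a turbid medium with Poisson-distributed
interceptions:

$$P_o(\theta_p) = \exp\!\left(-\frac{G(\theta_p, \theta_l)\,
\mathrm{GAI}}{\cos\theta_p}\right)$$

where $G$ is the projection function of an ellipsoidal leaf angle
distribution with shape parameter $\chi$, evaluated with Campbell's
extinction approximation

$$K(\theta_p, \chi) = \frac{\sqrt{\chi^2 + \tan^2\theta_p}}
{\chi + 1.774\,(\chi + 1.182)^{-0.733}}, \qquad
G = K \cos\theta_p,$$

and the mean leaf angle is $\theta_l = 9.65\,(3 + \chi)^{-1.65}$
radians. That map inverts in closed form, which is how `chi_from_ala()`
is implemented (round trip exact to machine precision). $\chi = 1$ is
the spherical case with $G \approx 0.5$ at nadir. At the
inclination-robust view angle 57.5° the projection is close to 0.5 for
any leaf angle distribution; note it is not *exactly* within 0.03 of
0.5 at extreme erectophile shapes — the exact ellipsoidal projection
reaches 0.532 at $\chi = 0.2$, an intrinsic property of the
distribution family, not of the approximation.

Inversion is an exhaustive look-up-table search. Defaults: GAI 0–8 in
steps of 0.05 and ALA 10–80° in steps of 1°, a grid finer than the
observation noise but small enough (11 431 rows) for brute-force search
in microseconds. The cost is the unweighted RMSE between observed and
tabulated gap fractions over the available view angles (per-angle
weights are accepted); ties break toward smaller GAI then smaller ALA,
a parsimony rule. With a single view angle ALA is weakly identifiable
and the LUT flags it; an all-ones observation (empty canopy) returns
GAI 0 with ALA pinned at the grid minimum and flagged
non-identifiable. When green-only cover fractions feed the inversion
the retrieved index is labelled GPAI, following field usage. Noiseless
forward-model observations invert to their generating grid point
exactly; at 1 % multiplicative noise the GAI bias at (3, 60°) stays
below 0.15 over 50 seeds.

## Spectral indices

Raw scans are digital numbers over 380–1100 nm (256 detector pixels).
Reflectance is the ratio to a panel scan times the panel's
characterised reflectance (default 0.99). The usable range is
450–820 nm, where the instrument's signal-to-noise ratio exceeds 20;
when a session provides repeat scans, `estimate_snr()` computes the
per-wavelength mean/SD ratio across repeats and the mask additionally
requires SNR ≥ 20. Repeat scans are averaged after discarding scans
whose deviation from the session median exceeds 3 robust SDs. Plot
values default to computing indices on the *average of the calibrated
reflectances*, not the average of per-scan indices; both paths are
exposed (`plot_reflectance(per_scan=)`) because they differ for
ratio-based indices.

Bands (550, 670, 681, 709, 754, 800 nm) are sampled with Gaussian
responses of 3 nm FWHM ($\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$),
renormalised over unmasked samples within ±2σ; a band whose support is
fully masked raises a "band unusable" error.

$$\mathrm{NDVI} = \frac{R_{800} - R_{670}}{R_{800} + R_{670}},\qquad
\mathrm{MTCI} = \frac{R_{754} - R_{709}}{R_{709} - R_{681}}$$

$$\mathrm{MCARI2} = \frac{1.5\,[2.5 (R_{800} - R_{670}) -
1.3 (R_{800} - R_{550})]}{\sqrt{(2 R_{800} + 1)^2 -
(6 R_{800} - 5\sqrt{R_{670}})} - 0.5}$$

Two typographical variants circulate in print: an NDVI denominator with
$R_{760}$, and an MCARI2 denominator without the square root. The
package implements the original published forms above (the variants are
inconsistent with the indices' source definitions); the non-rooted
MCARI2 is available behind `literal = TRUE` for comparison. NDVI and
MTCI are invariant to uniform scaling of the spectrum; MCARI2 is
intentionally not, being a non-normalised index.

## LiDAR canopy height

The elevation histogram of a plot's point cloud is split into ground
and vegetation with a 1-D Otsu threshold (the field method says only
"clustering"; Otsu is robust and parameter-free). If the two classes'
mean elevations are closer than 0.1 m the cloud is treated as unimodal
ground and the vegetation cluster is empty — this guard is what makes
bare-soil plots return height 0 instead of a spurious split. The
ground level is the modal 1 cm bin of the non-vegetation z histogram
(ties to the lowest bin). Vegetation heights are elevations minus
ground (negatives clamped to 0) and the plot height is the 99.5 %
linear-interpolation quantile of their cumulated distribution, in cm.
The estimate is invariant to z-translation and point order, monotone in
the quantile, and adding ground points can move it by at most one
histogram bin. Sensor-frame input (range below the gantry, valid
0.70–3.00 m) is converted to elevation on read given the gantry height;
out-of-range returns are dropped.

## Trait dynamics

The default temporal model is daily linear interpolation; parametric
fits are opt-in because no specific family is canonical for these
curves. `auc()` integrates the interpolant trapezoidally with
edge-interpolated boundary values, making it exact for the interpolant,
additive over subintervals and linear in the trait — the canonical use
is the AUC of MTCI between flowering and maturity as a grain-filling
nitrogen indicator. `fit_curve()` offers logistic and double-logistic
least squares (Levenberg–Marquardt, seeded multi-start of 5 jittered
initialisations); on noisy logistic series (σ = 5 % of range, 15 dates)
the midpoint date is recovered within 2 days in ≥ 90 % of seeds.
`divergence_onset()` interpolates two treatments to a daily grid and
reports the first day their absolute difference exceeds `delta` and
stays above it for `persistence` days (default 5), suppressing
single-day spikes.

Endpoint arithmetic: grain nitrogen export is
$N_{abs} = GY \times P \times 10 / 5.7$ kg N ha⁻¹ for yield in t ha⁻¹
and protein in % — the ×10 factor makes the conventional formula
dimensionally consistent and is applied by default (`literal = TRUE`
gives the bare form). `relative_loss()` is the percentage decrease
against a reference treatment. `treatment_summary()` is a thin wrapper
over one-way ANOVA with Tukey HSD compact letter displays at α = 0.05,
provided for convenience only.

## Water budget and irrigation triggers

The soil is a single bucket of capacity
$\mathrm{WHC} = \sum_h t_h \times 10 \times (\theta_{fc,h} -
\theta_{wp,h})$ mm over the profile's horizons. Each day,
$S' = \mathrm{clamp}(S + \text{rain} + \text{irrigation} -
\text{ET}, 0, \mathrm{WHC})$; inflow beyond capacity drains, and ET
demand is capped at the available water so the ledger's daily mass
balance closes exactly. This bucket plus a Sinclair-style stress factor
(1 above a 0.4 available-fraction breakpoint, linear to 0 at empty; the
breakpoint is a declared placeholder, not a calibrated value) is an
explicitly simplified stand-in for a full daily carbon/water/nitrogen
crop model, sufficient for the accounting computed here. ET is an input
series from weather files; no Penman–Monteith helper is included.

Irrigation triggering follows tensiometer thresholds for deep-soil
wheat: 100 cbar at 30 cm; 80 cbar at 60 cm before flag-leaf emergence
(Z39) and 100 cbar after; well-watered management keeps 80 cbar
throughout; 120 cbar at 60 cm marks water stress (flagged, not a
trigger). The probes saturate at 200 cbar, so higher values are stored
censored at 200 and triggers on censored readings carry a warning.
Shelter efficiency is $100 (1 - \overline{\text{under}} /
\text{reference})$ with the reference defaulting to the *maximum* of
the outside pluviometer totals (the mean is available); side effects
are percentage deltas of cumulative PAR and of degree-days
($(T_{max} + T_{min})/2$, base 0 °C) inside versus outside the
protected area. TDR probes are calibrated by ordinary least squares
against gravimetric water contents (≥ 3 pairs required).

## Synthetic scenes and what passing tests show

Every generator is a pure function of its parameters and a seed
(`withr::with_seed`, leaving the session RNG untouched) and records its
ground truth:

* `gen_mosaic()` — two Gaussian colour classes (foliage / soil tones,
  SD 0.05) with an exactly counted label fraction;
* `gen_gap_fractions()` — the forward Poisson model with multiplicative
  Gaussian noise, clipped to (0, 1];
* `gen_spectrum()` — a linear mixture of smooth built-in leaf and soil
  endmember curves (green bump, red absorption, logistic red edge to a
  NIR plateau) times an instrument sensitivity; the templates are
  synthetic by construction, not measured libraries;
* `gen_cloud()` — ground N(0, 5 mm) plus canopy heights
  $h \times \mathrm{Beta}(2, 1)$, truth recorded at the profile's
  99.5 % quantile $h\sqrt{0.995}$;
* `gen_trait_season()` — a logistic rise to plateau with senescence
  decay; a stressed treatment follows the control until its onset day
  and then decays faster, so divergence begins at the onset by
  construction.

Noise models are simple (multiplicative Gaussian for gap fractions and
spectra, additive Gaussian for point-cloud z). Passing the recovery
suite therefore demonstrates that the algorithms are correct and
well-conditioned under these idealised conditions; it does not
demonstrate robustness to the structure of real field data — specular
soil, mixed pixels, shadows, wind-blown canopies, multi-return LiDAR
artefacts or spatial field trends are all outside what the generators
emulate.

## Problem sizes and numerical choices

The shipped test-suite and acceptance-script configurations use 48–64
px mosaics, the default 11 431-row LUT, 256-pixel spectra, 20 000-point
clouds, 50-seed noise ensembles and 2–4-plot pipeline runs — sizes
chosen so each check isolates one property while the whole suite stays
interactive on a laptop. Degenerate inputs are handled explicitly:
empty canopies (GAI 0, ALA flagged), ground-only clouds (height 0 with
a warning), masked spectral bands (errors rather than NaN), ET demand
exceeding storage (capped), tensiometer saturation (censored). All
randomness in `run_pipeline()` descends from a single root seed via
deterministic child seeds, which is what makes end-to-end runs
bit-reproducible; per-plot failures are recorded and skipped rather
than aborting a multi-hundred-plot run.

## Known limitations

No clumping-index correction or multi-date constrained inversion (the
Poisson model assumes random dispersion, biasing GAI low in row crops);
no radiative-transfer inversion for chlorophyll; no red-edge position
beyond MTCI; no mixed-pixel unmixing or shadow modelling; no nitrogen
mineralisation, root-depth dynamics or kriged water-capacity maps; no
spatial mixed-model adjustment of field trends. Plot-level phenology
overrides treatment-level phenology when both are supplied, since
plot-level observation is the more specific record.
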
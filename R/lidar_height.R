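# Plot height from LiDAR point clouds: Otsu split of the elevation
# histogram into ground and vegetation, ground level as the modal
# z-bin, canopy height as the 99.5% quantile of vegetation heights.

#' Construct a LiDAR point cloud
#'
#' @param points Data frame or matrix with columns `x`, `y`, `z`
#'   (metres; z increases upward).
#' @param reflectance Optional per-point intensity.
#' @param plot_id,date Optional identifiers.
#' @return A `point_cloud`.
#' @export
point_cloud <- function(points, reflectance = NULL, plot_id = NULL,
                        date = NULL) {
  points <- as.data.frame(points)
  if (!all(c("x", "y", "z") %in% names(points))) {
    ct_schema_error("point cloud needs x, y, z columns")
  }
  if (nrow(points) < 1) ct_validation_error("point cloud is empty")
  if (!all(is.finite(as.matrix(points[, c("x", "y", "z")])))) {
    ct_validation_error("point coordinates must be finite")
  }
  structure(
    list(points = tibble::as_tibble(points[, c("x", "y", "z")]),
         reflectance = reflectance, plot_id = plot_id, date = date),
    class = "point_cloud"
  )
}

#' Read a point cloud from CSV or ASCII PLY
#'
#' CSV columns: `x,y,z[,intensity]`. PLY: ASCII format with x/y/z vertex
#' properties. When `gantry_height_m` is given, z is interpreted as a
#' sensor range (distance below the sensor, metres) and converted to
#' elevation `gantry_height_m - range`; returns outside the sensor's
#' 0.70-3.00 m valid range are dropped.
#'
#' @param path File path (`.csv` or `.ply`).
#' @param gantry_height_m Optional sensor elevation for range-to-z
#'   conversion.
#' @param valid_range_m Valid sensor range (metres).
#' @inheritParams point_cloud
#' @return A [point_cloud()].
#' @export
read_cloud <- function(path, gantry_height_m = NULL,
                       valid_range_m = c(0.70, 3.00), plot_id = NULL,
                       date = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE),
    ply = read_ascii_ply(path),
    ct_schema_error(paste0("unsupported cloud format: .", ext))
  )
  if (!is.null(gantry_height_m)) {
    rng <- df$z
    keep <- rng >= valid_range_m[1] & rng <= valid_range_m[2]
    df <- df[keep, , drop = FALSE]
    df$z <- gantry_height_m - df$z
  }
  point_cloud(df, reflectance = df[["intensity"]], plot_id = plot_id,
              date = date)
}

# Minimal ASCII PLY vertex reader (x, y, z and optional scalar props).
read_ascii_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(trimws(lines[1]), "ply")) ct_schema_error("not a PLY file")
  end <- match("end_header", trimws(lines))
  if (is.na(end)) ct_schema_error("PLY header not terminated")
  header <- trimws(lines[1:end])
  if (!any(grepl("^format ascii", header))) {
    ct_schema_error("only ASCII PLY is supported")
  }
  n <- as.integer(sub("^element vertex ", "",
                      grep("^element vertex ", header, value = TRUE)[1]))
  props <- sub("^property \\S+ ", "", grep("^property ", header, value = TRUE))
  body <- lines[(end + 1):(end + n)]
  mat <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                ncol = length(props), byrow = TRUE)
  colnames(mat) <- props
  as.data.frame(mat)
}

# 1-D Otsu threshold: maximises between-class variance of the histogram.
otsu_threshold <- function(z, nbins = 256) {
  h <- graphics::hist(z, breaks = nbins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Split a point cloud into ground and vegetation
#'
#' Two-component partition of the elevation histogram via an Otsu-style
#' threshold on z. When the two classes' mean elevations are closer than
#' `min_separation` the cloud is treated as unimodal and the vegetation
#' cluster is empty.
#'
#' @param cloud A [point_cloud()] with at least 50 points.
#' @param min_separation Minimum ground/canopy mean-z separation in
#'   metres to accept a split (default 0.1).
#' @return List with `ground` and `vegetation` point tibbles and the
#'   `threshold` used (`NA` for unimodal clouds).
#' @export
split_ground_vegetation <- function(cloud, min_separation = 0.1) {
  stopifnot(inherits(cloud, "point_cloud"))
  pts <- cloud$points
  if (nrow(pts) < 50) {
    ct_validation_error("need at least 50 points to split ground/vegetation")
  }
  thr <- otsu_threshold(pts$z)
  low <- pts$z <= thr
  if (!any(low) || all(low) ||
      mean(pts$z[!low]) - mean(pts$z[low]) < min_separation) {
    return(list(ground = pts, vegetation = pts[0, ], threshold = NA_real_))
  }
  list(ground = pts[low, ], vegetation = pts[!low, ], threshold = thr)
}

#' Ground elevation from ground-candidate points
#'
#' The modal bin of the z histogram (default 1 cm bins) is taken as the
#' ground level; ties break toward the lowest bin. Returns the bin
#' centre.
#'
#' @param ground Tibble of ground points (or numeric z values).
#' @param bin_width Histogram bin width in metres (default 0.01).
#' @return Ground elevation in metres.
#' @export
ground_level <- function(ground, bin_width = 0.01) {
  z <- if (is.data.frame(ground)) ground$z else ground
  if (length(z) == 0) ct_validation_error("no ground points")
  if (diff(range(z)) < bin_width) return(median(z))
  breaks <- seq(floor(min(z) / bin_width) * bin_width,
                max(z) + bin_width, by = bin_width)
  h <- graphics::hist(z, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]  # which.max returns the lowest tied bin
}

#' Per-plot canopy height from a point cloud
#'
#' Splits ground from vegetation, subtracts the ground level from the
#' vegetation elevations (negatives clamped to 0) and reports the
#' height at the 99.5% point of the cumulated height distribution
#' (linear-interpolation quantile), in cm.
#'
#' @param cloud A [point_cloud()].
#' @param quantile Cumulative fraction (default 0.995).
#' @param bin_width Ground-mode histogram bin width in metres.
#' @return A `height_estimate`: `height` (cm), `ground_z` (m),
#'   `n_vegetation_points`, `quantile` and an `empty_canopy` flag.
#' @export
plot_height <- function(cloud, quantile = 0.995, bin_width = 0.01) {
  if (quantile <= 0 || quantile > 1) {
    ct_domain_error("quantile must lie in (0, 1]")
  }
  split <- split_ground_vegetation(cloud)
  ground_z <- ground_level(split$ground, bin_width)
  veg <- split$vegetation
  if (nrow(veg) == 0) {
    warning("empty vegetation cluster: height set to 0", call. = FALSE)
    h <- 0
  } else {
    heights <- pmax(veg$z - ground_z, 0)
    h <- 100 * unname(stats::quantile(heights, quantile, type = 7))
  }
  structure(
    list(height = h, ground_z = ground_z,
         n_vegetation_points = nrow(veg), quantile = quantile,
         empty_canopy = nrow(veg) == 0, plot_id = cloud$plot_id,
         date = cloud$date),
    class = "height_estimate"
  )
}
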
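# Green cover fraction from RGB microplot images: white balance on a
# reference gray panel, pixel classification (SVM or excess-green
# threshold), exact per-image green fraction.

#' Construct an annotated microplot image
#'
#' @param pixels H x W x 3 numeric array, linear intensities in `[0,1]`.
#'   8/16-bit integer input is rescaled by its bit depth on construction.
#' @param view_angle View zenith angle in degrees from nadir (0 or 45 in
#'   the standard gantry configuration).
#' @param plot_id,date Optional identifiers.
#' @param gray_panel_rgb Optional length-3 mean panel intensities used by
#'   [white_balance()].
#' @return An `annotated_image`.
#' @export
annotated_image <- function(pixels, view_angle = 0, plot_id = NULL,
                            date = NULL, gray_panel_rgb = NULL) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    ct_schema_error("pixels must be an H x W x 3 array")
  }
  if (is.integer(pixels) || max(pixels) > 1) {
    depth <- if (max(pixels) > 255) 65535 else 255
    pixels <- pixels / depth
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    ct_validation_error("pixel intensities must lie in [0,1]")
  }
  structure(
    list(pixels = pixels, view_angle = view_angle, plot_id = plot_id,
         date = date, gray_panel_rgb = gray_panel_rgb),
    class = "annotated_image"
  )
}

#' Read a PNG or TIFF microplot image
#'
#' @param path Image path; extension selects the reader.
#' @inheritParams annotated_image
#' @return An `annotated_image` in linear `[0,1]` floats.
#' @export
read_image <- function(path, view_angle = 0, plot_id = NULL, date = NULL,
                       gray_panel_rgb = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    ct_schema_error(paste0("unsupported image format: .", ext))
  )
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]
  annotated_image(px, view_angle = view_angle, plot_id = plot_id,
                  date = date, gray_panel_rgb = gray_panel_rgb)
}

#' White-balance an image against its gray reference panel
#'
#' Applies per-channel gains `g_c = mean(panel) / panel_c` so the panel
#' becomes achromatic; output is clipped to `[0,1]`.
#'
#' @param img An [annotated_image()] with `gray_panel_rgb` set.
#' @return The white-balanced `annotated_image` (panel set to neutral).
#' @export
white_balance <- function(img) {
  stopifnot(inherits(img, "annotated_image"))
  panel <- img$gray_panel_rgb
  if (is.null(panel) || length(panel) != 3) {
    ct_calibration_error("gray_panel_rgb is required for white balance")
  }
  if (any(panel <= 0)) {
    ct_calibration_error("gray panel has a zero or negative channel")
  }
  gains <- mean(panel) / panel
  out <- img$pixels
  for (c in 1:3) out[, , c] <- out[, , c] * gains[c]
  out[out > 1] <- 1
  out[out < 0] <- 0
  img$pixels <- out
  img$gray_panel_rgb <- rep(mean(panel), 3)
  img
}

# Per-pixel colour features: raw channels, excess-green index 2G-R-B and
# hue. Returns an n x 5 matrix.
pixel_features <- function(pixels) {
  r <- as.vector(pixels[, , 1])
  g <- as.vector(pixels[, , 2])
  b <- as.vector(pixels[, , 3])
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  cbind(r = r, g = g, b = b, exg = 2 * g - r - b, hue = hsv[1, ])
}

#' Train the green/non-green pixel classifier
#'
#' Fits a linear maximum-margin (support vector) classifier over the
#' pixel colour-feature vector (R, G, B, excess-green, hue). Training is
#' deterministic for a fixed seed.
#'
#' @param pixels n x 3 matrix of RGB values in `[0,1]` (or an H x W x 3
#'   array).
#' @param labels Logical vector, `TRUE` for green pixels.
#' @param cost SVM cost parameter.
#' @param seed Integer seed.
#' @return A `pixel_classifier`.
#' @export
train_pixel_classifier <- function(pixels, labels, cost = 1, seed = 1L) {
  if (length(labels) == 0) ct_validation_error("empty training sample")
  if (length(dim(pixels)) == 3) {
    feats <- pixel_features(pixels)
  } else {
    px <- array(0, dim = c(nrow(pixels), 1, 3))
    px[, 1, ] <- as.matrix(pixels)
    feats <- pixel_features(px)
  }
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    ct_validation_error("training sample must contain both classes")
  }
  fit <- withr::with_seed(seed, e1071::svm(
    x = feats, y = factor(labels, levels = c(FALSE, TRUE)),
    kernel = "linear", cost = cost, scale = TRUE
  ))
  structure(
    list(model = fit, features = colnames(feats), trained = TRUE,
         version = 1L),
    class = "pixel_classifier"
  )
}

#' Persist / restore a trained pixel classifier
#'
#' @param classifier A `pixel_classifier`.
#' @param path File path.
#' @export
write_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "pixel_classifier")) {
    ct_schema_error("file does not contain a pixel classifier")
  }
  obj
}

#' Classify green pixels and compute the green cover fraction
#'
#' @param img A white-balanced [annotated_image()].
#' @param classifier A trained [train_pixel_classifier()] result, or
#'   `NULL` to use the excess-green threshold baseline.
#' @param border Pixel margin cropped from each side before counting
#'   (intra-plot border removal; default 0).
#' @param exg_threshold Threshold on 2G-R-B for the baseline classifier.
#' @return A `green_mask`: logical `labels` matrix and exact `gcf`
#'   (green pixels / total pixels).
#' @export
classify_green <- function(img, classifier = NULL, border = 0,
                           exg_threshold = 0.1) {
  stopifnot(inherits(img, "annotated_image"))
  px <- img$pixels
  if (border > 0) {
    d <- dim(px)
    if (2 * border >= min(d[1:2])) {
      ct_validation_error("border crop larger than image")
    }
    px <- px[(border + 1):(d[1] - border), (border + 1):(d[2] - border), ,
             drop = FALSE]
  }
  if (is.null(classifier)) {
    labels <- 2 * px[, , 2] - px[, , 1] - px[, , 3] > exg_threshold
  } else {
    if (!inherits(classifier, "pixel_classifier") || !isTRUE(classifier$trained)) {
      ct_state_error("classifier is not trained")
    }
    pred <- predict(classifier$model, pixel_features(px))
    labels <- matrix(pred == "TRUE", nrow = dim(px)[1])
  }
  structure(
    list(labels = labels, gcf = sum(labels) / length(labels),
         plot_id = img$plot_id, view_angle = img$view_angle,
         date = img$date),
    class = "green_mask"
  )
}
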
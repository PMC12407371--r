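# Half-width profile of the synthetic blade: an ellipse modulated by an
# exponential along-axis taper, w(t) = b * sqrt(1 - t^2) * exp(k*t) on
# t in [-1, 1]. k controls shape skewness (k = 0 gives a symmetric ellipse).
blade_half_width <- function(t, k) sqrt(pmax(0, 1 - t^2)) * exp(k * t)

# Skewness of the along-axis mass distribution implied by taper k.
blade_skew_of_k <- function(k) {
  t <- seq(-1, 1, length.out = 4001)
  f <- blade_half_width(t, k)
  f <- f / sum(f)
  m <- sum(t * f)
  v <- sum((t - m)^2 * f)
  sum((t - m)^3 * f) / v^1.5
}

# Invert blade_skew_of_k for a target skewness (monotone decreasing in k).
blade_k_for_skew <- function(s) {
  if (abs(s) < 1e-12) return(0)
  if (abs(s) > 1.55) stop("target skewness outside the renderer's range")
  stats::uniroot(function(k) blade_skew_of_k(k) - s, c(-14, 14),
                 tol = 1e-10)$root
}

#' Scaled leaf photograph container
#'
#' A grayscale raster (values in `[0, 1]`, quantized to 8 bits on disk)
#' plus the pixels-per-centimeter scale established from the ruler
#' graduations on the backing sheet.
#'
#' @param pixels Numeric matrix in `[0, 1]` (rows = y, columns = x).
#' @param px_per_cm Positive scale factor.
#' @param truth Optional ground-truth metadata list (renderer only).
#' @return An object of class `leaf_image`.
#' @export
leaf_image <- function(pixels, px_per_cm, truth = NULL) {
  stopifnot(is.matrix(pixels), length(pixels) > 0, px_per_cm > 0)
  structure(list(pixels = pixels, px_per_cm = px_per_cm, truth = truth),
            class = "leaf_image")
}

#' @export
print.leaf_image <- function(x, ...) {
  cat(sprintf("<leaf_image> %d x %d px at %.1f px/cm (%.1f x %.1f cm)\n",
              nrow(x$pixels), ncol(x$pixels), x$px_per_cm,
              ncol(x$pixels) / x$px_per_cm, nrow(x$pixels) / x$px_per_cm))
  invisible(x)
}

#' Render a synthetic leaf photograph
#'
#' Draws a dark leaf blade on a white background: an ellipse-based shape
#' whose along-axis exponential taper is solved numerically so the rendered
#' mask's shape skewness matches `features$skewness`, and whose axes are
#' scaled so its area matches `features$area`. The returned image embeds
#' ground-truth metadata — the exact pixel mask, the pixel-count area, the
#' continuous boundary arc length and the mask's along-axis skewness — for
#' use as an oracle when validating image morphometrics.
#'
#' @param features A [leaf_features()] (area and skewness are honored;
#'   perimeter is emergent from the shape family).
#' @param px_per_cm Rendering resolution (>= 10).
#' @param seed Integer; recorded for provenance (the render itself is
#'   deterministic in `features`).
#' @param aspect Major/minor axis ratio of the base ellipse (default 1.6).
#' @param canvas_cm Optional `(width, height)` in cm; errors if the blade
#'   does not fit. Auto-sized with a 1 cm margin when `NULL`.
#' @return A [leaf_image()] with `$truth` metadata.
#' @examples
#' img <- render_leaf_image(
#'   leaf_features(area = 47.12, perimeter = 26, thickness = 250,
#'                 skewness = 0),
#'   px_per_cm = 20)
#' img$truth$area_cm2
#' @export
render_leaf_image <- function(features, px_per_cm = 20, seed = 0,
                              aspect = 1.6, canvas_cm = NULL) {
  stopifnot(inherits(features, "leaf_features"))
  if (px_per_cm < 10) stop("px_per_cm must be >= 10")
  k <- blade_k_for_skew(features$skewness)

  # unit-shape area factor: 2 * integral of w(t) dt
  t <- seq(-1, 1, length.out = 4001)
  area_unit <- 2 * sum(blade_half_width(t, k)) * (t[2] - t[1])
  ab <- features$area / area_unit
  a <- sqrt(ab * aspect)
  b <- a / aspect
  b_max <- b * max(blade_half_width(t, k))

  margin <- 1
  if (is.null(canvas_cm)) {
    canvas_cm <- c(2 * a + 2 * margin, 2 * b_max + 2 * margin)
  } else if (2 * a > canvas_cm[1] || 2 * b_max > canvas_cm[2]) {
    stop("canvas overflow: blade (", sprintf("%.1f x %.1f", 2 * a, 2 * b_max),
         " cm) larger than canvas")
  }
  ncol_px <- ceiling(canvas_cm[1] * px_per_cm)
  nrow_px <- ceiling(canvas_cm[2] * px_per_cm)

  # pixel-center coordinates in cm, origin at canvas center
  xs <- (seq_len(ncol_px) - 0.5) / px_per_cm - canvas_cm[1] / 2
  ys <- (seq_len(nrow_px) - 0.5) / px_per_cm - canvas_cm[2] / 2
  tx <- xs / a
  w <- b * blade_half_width(tx, k)        # half-height at each column, cm
  mask <- outer(abs(ys), w, `<=`) & matrix(abs(tx) <= 1, nrow_px, ncol_px,
                                           byrow = TRUE)
  pixels <- matrix(1, nrow_px, ncol_px)
  pixels[mask] <- 0.2
  pixels <- round(pixels * 255) / 255      # 8-bit quantization

  # ground-truth boundary arc length of the continuous shape
  tt <- seq(-1, 1, length.out = 8001)
  bx <- a * tt
  by <- b * blade_half_width(tt, k)
  per <- 2 * sum(sqrt(diff(bx)^2 + diff(by)^2))

  # mask skewness along the major (x) axis at pixel resolution
  px_x <- rep(xs, each = nrow_px)[as.vector(mask)]
  mx <- mean(px_x)
  vx <- mean((px_x - mx)^2)
  skew_px <- mean((px_x - mx)^3) / vx^1.5

  leaf_image(pixels, px_per_cm,
             truth = list(mask = mask,
                          area_cm2 = sum(mask) / px_per_cm^2,
                          perimeter_cm = per,
                          skewness = skew_px,
                          taper_k = k, a_cm = a, b_cm = b, seed = seed))
}

#' Write a leaf image as 8-bit PNG with a JSON side-car
#'
#' @param img A [leaf_image()].
#' @param path Output PNG path; ground truth (minus the raster mask) and
#'   the scale go to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_leaf_image <- function(img, path) {
  stopifnot(inherits(img, "leaf_image"))
  png::writePNG(img$pixels, path)
  meta <- list(px_per_cm = img$px_per_cm)
  if (!is.null(img$truth)) {
    meta$truth <- img$truth[setdiff(names(img$truth), "mask")]
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a leaf photograph from PNG
#'
#' @param path PNG path; if `<path>.json` exists its `px_per_cm` is used.
#' @param px_per_cm Scale override (required without a side-car).
#' @return A [leaf_image()].
#' @export
read_leaf_image <- function(path, px_per_cm = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]  # collapse channels
  sidecar <- paste0(path, ".json")
  truth <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(px_per_cm)) px_per_cm <- meta$px_per_cm
    truth <- meta$truth
  }
  if (is.null(px_per_cm)) stop("px_per_cm not given and no side-car found")
  leaf_image(px, px_per_cm, truth = truth)
}
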
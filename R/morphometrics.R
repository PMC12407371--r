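#' Binary leaf mask
#'
#' Segmentation result: a logical foreground raster with the source
#' image's scale carried over.
#'
#' @param mask Logical matrix (TRUE = leaf).
#' @param px_per_cm Scale factor, > 0.
#' @return An object of class `leaf_mask`.
#' @export
leaf_mask <- function(mask, px_per_cm) {
  stopifnot(is.matrix(mask), is.logical(mask), px_per_cm > 0)
  if (!any(mask)) stop("segmentation empty: mask has no foreground pixels")
  structure(list(mask = mask, px_per_cm = px_per_cm), class = "leaf_mask")
}

#' Segment the leaf blade from a scaled photograph
#'
#' Global Otsu thresholding (the leaf-on-white-paper setting is strongly
#' bimodal), keeping pixels darker than the threshold (or brighter, with
#' `threshold_policy = "bright"`), followed by largest-connected-component
#' selection and hole filling.
#'
#' @param image A [leaf_image()].
#' @param threshold_policy `"dark"` (leaf darker than background, default)
#'   or `"bright"`.
#' @return A [leaf_mask()]. Warns if the blade touches three or more image
#'   borders (suspect framing).
#' @examples
#' img <- render_leaf_image(
#'   leaf_features(area = 30, perimeter = 22, thickness = 200,
#'                 skewness = 0.1))
#' m <- segment_leaf(img)
#' measure_area(m)
#' @export
segment_leaf <- function(image, threshold_policy = c("dark", "bright")) {
  stopifnot(inherits(image, "leaf_image"))
  threshold_policy <- match.arg(threshold_policy)
  px <- image$pixels
  if (diff(range(px)) < 1 / 255) {
    stop("segmentation empty: image has no contrast")
  }
  thr <- EBImage::otsu(EBImage::Image(px), range = c(0, 1))
  fg <- if (threshold_policy == "dark") px < thr else px > thr
  if (!any(fg)) stop("segmentation empty: no pixels beyond threshold")
  labels <- EBImage::bwlabel(EBImage::Image(fg * 1))
  tab <- tabulate(as.integer(labels)[as.integer(labels) > 0])
  keep <- which.max(tab)
  comp <- matrix(as.integer(labels) == keep, nrow(px), ncol(px))
  filled <- EBImage::fillHull(EBImage::Image(comp * 1))
  mask <- matrix(as.numeric(filled) > 0.5, nrow(px), ncol(px))
  touches <- sum(any(mask[1, ]), any(mask[nrow(mask), ]),
                 any(mask[, 1]), any(mask[, ncol(mask)]))
  if (touches >= 3) {
    warning("suspect framing: blade touches ", touches, " image borders")
  }
  leaf_mask(mask, image$px_per_cm)
}

#' Blade area from a mask
#'
#' Foreground pixel count divided by the squared scale.
#'
#' @param mask A [leaf_mask()].
#' @return Area in cm^2.
#' @export
measure_area <- function(mask) {
  stopifnot(inherits(mask, "leaf_mask"))
  sum(mask$mask) / mask$px_per_cm^2
}

# Ordered outer boundary of the mask via marching squares at level 0.5.
# Returns the longest closed contour as an n x 2 matrix (x, y) in pixels.
trace_boundary <- function(mask) {
  z <- mask * 1
  # pad so contours close even when the mask touches a border
  zp <- matrix(0, nrow(z) + 2, ncol(z) + 2)
  zp[2:(nrow(z) + 1), 2:(ncol(z) + 1)] <- z
  cl <- grDevices::contourLines(x = seq_len(nrow(zp)), y = seq_len(ncol(zp)),
                                z = zp, levels = 0.5)
  if (length(cl) == 0) stop("no boundary found")
  lens <- vapply(cl, function(cc) {
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2))
  }, numeric(1))
  cc <- cl[[which.max(lens)]]
  cbind(cc$x, cc$y)
}

#' Blade perimeter from a mask
#'
#' Boundary length estimated by tracing the mask's outer contour and
#' resampling it as a closed polygon at roughly 0.25 cm spacing before
#' summing chord lengths. The resampling suppresses the staircase bias of
#' raw pixel contours (which overestimates smooth boundaries) while
#' preserving true corners to within the sampling interval.
#'
#' @param mask A [leaf_mask()].
#' @param spacing_cm Chord spacing in cm (default 0.25).
#' @return Perimeter in cm.
#' @export
measure_perimeter <- function(mask, spacing_cm = 0.25) {
  stopifnot(inherits(mask, "leaf_mask"))
  b <- trace_boundary(mask$mask)
  if (any(b[1, ] != b[nrow(b), ])) b <- rbind(b, b[1, ])
  seg <- sqrt(diff(b[, 1])^2 + diff(b[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  spacing_px <- max(1, spacing_cm * mask$px_per_cm)
  n_chord <- max(8, round(total / spacing_px))
  s <- seq(0, total, length.out = n_chord + 1)
  xi <- stats::approx(cum, b[, 1], xout = s)$y
  yi <- stats::approx(cum, b[, 2], xout = s)$y
  sum(sqrt(diff(xi)^2 + diff(yi)^2)) / mask$px_per_cm
}

#' Blade shape skewness from a mask
#'
#' Third standardized moment of the foreground pixel coordinates projected
#' onto the mask's major principal axis. Sign convention: the axis is
#' oriented so its x-component is positive (falling back to positive y for
#' near-vertical axes), and positive skewness means the pixel mass leans
#' toward the axis-positive end with the longer tail on the negative side.
#'
#' @param mask A [leaf_mask()].
#' @return Unitless skewness.
#' @export
measure_skewness <- function(mask) {
  stopifnot(inherits(mask, "leaf_mask"))
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("undefined moment: mask has fewer than 3 pixels")
  # x = column, y = row
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  ev <- eigen(stats::cov(pc), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  if (abs(axis[1]) > 1e-8) {
    if (axis[1] < 0) axis <- -axis
  } else if (axis[2] < 0) axis <- -axis
  proj <- pc %*% axis
  v <- mean(proj^2)
  if (v < .Machine$double.eps) stop("undefined moment: degenerate mask")
  mean(proj^3) / v^1.5
}

#' Extract the five-feature condition vector from a photograph
#'
#' Segments the blade, measures area, perimeter and skewness, derives the
#' area-to-perimeter ratio, and attaches the separately measured caliper
#' thickness.
#'
#' @param image A [leaf_image()].
#' @param thickness Caliper thickness in um, > 0.
#' @param threshold_policy Passed to [segment_leaf()].
#' @return A [leaf_features()].
#' @examples
#' img <- render_leaf_image(
#'   leaf_features(area = 45, perimeter = 26, thickness = 250,
#'                 skewness = 0.2))
#' extract_features(img, thickness = 250)
#' @export
extract_features <- function(image, thickness, threshold_policy = "dark") {
  if (!(thickness > 0)) stop("thickness must be > 0")
  m <- segment_leaf(image, threshold_policy)
  leaf_features(area = measure_area(m),
                perimeter = measure_perimeter(m),
                thickness = thickness,
                skewness = measure_skewness(m))
}
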
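#' Leaf morphometric feature vector
#'
#' The five-feature condition vector used throughout the package: blade
#' area A (cm^2), perimeter P (cm), area-to-perimeter ratio A/P (cm),
#' thickness T (um, from a vernier caliper) and skewness S (unitless,
#' third standardized moment of the blade mass along its major principal
#' axis). The ratio is always derived from area and perimeter, never
#' supplied independently.
#'
#' @param area Blade area, cm^2.
#' @param perimeter Blade perimeter, cm.
#' @param thickness Blade thickness, um.
#' @param skewness Blade shape skewness, unitless.
#' @return An object of class `leaf_features`.
#' @examples
#' leaf_features(area = 16, perimeter = 16, thickness = 250, skewness = 0)
#' @export
leaf_features <- function(area, perimeter, thickness, skewness) {
  stopifnot(is.numeric(area), is.numeric(perimeter), is.numeric(thickness),
            length(area) == 1, length(perimeter) == 1,
            area > 0, perimeter > 0, thickness > 0)
  structure(
    list(area = area, perimeter = perimeter, ap_ratio = area / perimeter,
         thickness = thickness, skewness = skewness),
    class = "leaf_features"
  )
}

#' @export
print.leaf_features <- function(x, ...) {
  cat(sprintf(
    "<leaf_features> A=%.2f cm^2  P=%.2f cm  A/P=%.3f cm  T=%.0f um  S=%.3f\n",
    x$area, x$perimeter, x$ap_ratio, x$thickness, x$skewness))
  invisible(x)
}

#' @export
as.data.frame.leaf_features <- function(x, ...) {
  data.frame(area_cm2 = x$area, perimeter_cm = x$perimeter,
             ap_ratio_cm = x$ap_ratio, thickness_um = x$thickness,
             skewness = x$skewness)
}

# Stack a list of leaf_features into the n x 5 condition matrix.
features_matrix <- function(features) {
  stopifnot(length(features) >= 1)
  m <- t(vapply(features, function(f) {
    c(f$area, f$perimeter, f$ap_ratio, f$thickness, f$skewness)
  }, numeric(5)))
  colnames(m) <- c("area_cm2", "perimeter_cm", "ap_ratio_cm",
                   "thickness_um", "skewness")
  m
}
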
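#' Cultivar specification for the synthetic leaf generator
#'
#' A `cultivar_spec` bundles everything the simulator needs to emulate one
#' sweet potato cultivar: how many leaves its training library holds, the
#' plausible ranges of the five morphometric features, the voltage endpoints
#' of its characteristic curves, amplitude-group structure (the Honey
#' cultivar splits into two groups whose curves top out near 300 mV and
#' 600 mV respectively), and measurement-noise levels.
#'
#' @param name One of `"honey"`, `"japanese"`, `"orange"`.
#' @param n_default Number of leaves in the cultivar's default library.
#' @param feature_ranges Named list of `(low, high)` pairs for
#'   `area` (cm^2), `perimeter` (cm), `thickness` (um) and `skewness`
#'   (unitless). The area-to-perimeter ratio is never sampled; it is always
#'   recomputed as area/perimeter.
#' @param v_min_base,v_max_base Baseline curve endpoints in mV: the voltage
#'   at full turgor (`v_min_base`) and at complete dryness (`v_max_base`)
#'   before per-leaf modulation.
#' @param amplitude_groups List of `(weight, v_max_scale)` pairs; a leaf is
#'   assigned to a group at random (weights sum to 1) and its `v_max` is
#'   multiplied by the group's scale. Unimodal cultivars use a single group
#'   with scale 1.
#' @param noise_v_sd Gaussian noise sd on recorded V_TRx, mV.
#' @param noise_rwc_sd Gaussian noise sd on library RWC values, percentage
#'   points.
#' @param curve_shape_gamma_range `(low, high)` bounds of the curve shape
#'   exponent gamma (see [ground_truth_curve()]).
#'
#' @return An object of class `cultivar_spec`.
#' @seealso [sample_features()], [generate_library()]
#' @export
cultivar_spec <- function(name,
                          n_default,
                          feature_ranges,
                          v_min_base,
                          v_max_base,
                          amplitude_groups = list(c(weight = 1, v_max_scale = 1)),
                          noise_v_sd = 3,
                          noise_rwc_sd = 1,
                          curve_shape_gamma_range = c(0.6, 1.8)) {
  name <- match.arg(name, c("honey", "japanese", "orange"))
  stopifnot(n_default >= 1, v_min_base > 0, v_max_base > v_min_base,
            noise_v_sd >= 0, noise_rwc_sd >= 0,
            length(curve_shape_gamma_range) == 2,
            curve_shape_gamma_range[1] > 0,
            curve_shape_gamma_range[1] < curve_shape_gamma_range[2])
  needed <- c("area", "perimeter", "thickness", "skewness")
  if (!all(needed %in% names(feature_ranges))) {
    stop("feature_ranges must contain: ", paste(needed, collapse = ", "))
  }
  for (nm in needed) {
    rg <- feature_ranges[[nm]]
    if (length(rg) != 2 || !(rg[1] < rg[2])) {
      stop("feature range for '", nm, "' must be (low, high) with low < high")
    }
  }
  w <- vapply(amplitude_groups, function(g) g[["weight"]], numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("amplitude group weights must sum to 1")
  structure(
    list(name = name, n_default = n_default, feature_ranges = feature_ranges,
         v_min_base = v_min_base, v_max_base = v_max_base,
         amplitude_groups = amplitude_groups,
         noise_v_sd = noise_v_sd, noise_rwc_sd = noise_rwc_sd,
         curve_shape_gamma_range = curve_shape_gamma_range),
    class = "cultivar_spec"
  )
}

#' Built-in cultivar specifications
#'
#' Returns the shipped specification for one of the three sweet potato
#' cultivars. Library sizes follow the emulated acquisition campaign
#' (100 Honey, 50 Japanese, 50 Orange). Feature ranges are tuned so the
#' simulated relative spreads, `(max - min)/min * 100`, land near the
#' per-cultivar feature variations observed for these cultivars
#' (Honey: A 155, P 91, T 173, S 125%; Japanese: 302, 102, 54, 326%;
#' Orange: 141, 73, 72, 620%). Honey carries two equal-weight amplitude
#' groups scaling `v_max` by 1 and 2, reproducing its bimodal ~300/~600 mV
#' maximum-voltage split.
#'
#' @param name `"honey"`, `"japanese"` or `"orange"`.
#' @return A [cultivar_spec()] object.
#' @examples
#' sp <- builtin_cultivar("honey")
#' sp$n_default  # 100
#' @export
builtin_cultivar <- function(name) {
  name <- match.arg(name, c("honey", "japanese", "orange"))
  switch(name,
    honey = cultivar_spec(
      name = "honey", n_default = 100,
      feature_ranges = list(
        area      = c(40, 102),     # 155% spread
        perimeter = c(22, 42),      # 91%
        thickness = c(150, 410),    # 173%
        skewness  = c(0.20, 0.45)   # 125%
      ),
      v_min_base = 80, v_max_base = 300,
      amplitude_groups = list(c(weight = 0.5, v_max_scale = 1),
                              c(weight = 0.5, v_max_scale = 2))
    ),
    japanese = cultivar_spec(
      name = "japanese", n_default = 50,
      feature_ranges = list(
        area      = c(20, 80.4),    # 302%
        perimeter = c(18, 36.4),    # 102%
        thickness = c(200, 308),    # 54%
        skewness  = c(0.10, 0.426)  # 326%
      ),
      v_min_base = 120, v_max_base = 420
    ),
    orange = cultivar_spec(
      name = "orange", n_default = 50,
      feature_ranges = list(
        area      = c(25, 60.25),   # 141%
        perimeter = c(20, 34.6),    # 73%
        thickness = c(180, 309.6),  # 72%
        skewness  = c(0.05, 0.36)   # 620%
      ),
      v_min_base = 110, v_max_base = 400
    )
  )
}

#' @export
print.cultivar_spec <- function(x, ...) {
  cat("<cultivar_spec>", x$name, "\n")
  cat("  default library size:", x$n_default, "leaves\n")
  cat("  voltage endpoints:", x$v_min_base, "-", x$v_max_base, "mV",
      if (length(x$amplitude_groups) > 1) sprintf("(%d amplitude groups)",
                                                  length(x$amplitude_groups)),
      "\n")
  invisible(x)
}
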
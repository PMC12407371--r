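logistic <- function(x) 1 / (1 + exp(-x))

# Deterministic child seed for per-leaf randomness; kept within 32-bit range.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629)
}

# Normalize a feature value to [0, 1] by its spec range (clamped).
unit_scale <- function(x, range) {
  pmin(1, pmax(0, (x - range[1]) / (range[2] - range[1])))
}

#' Sample leaf feature vectors for a cultivar
#'
#' Draws `n` morphometric feature sets from a cultivar specification. Area,
#' thickness and skewness are uniform over their spec ranges; perimeter is
#' uniform but floored at 1.05 times the iso-area circle perimeter
#' `sqrt(4*pi*A)` so that every (A, P) pair is geometrically realizable.
#' The area-to-perimeter ratio is recomputed as A/P, never sampled.
#'
#' @param spec A [cultivar_spec()].
#' @param n Number of leaves (>= 1). Defaults to the spec's library size.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of `n` [leaf_features()] objects.
#' @examples
#' feats <- sample_features(builtin_cultivar("honey"), n = 5, seed = 1)
#' feats[[1]]
#' @export
sample_features <- function(spec, n = spec$n_default, seed = 0) {
  if (!inherits(spec, "cultivar_spec")) stop("unknown cultivar spec")
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  rg <- spec$feature_ranges
  area <- runif(n, rg$area[1], rg$area[2])
  per_raw <- runif(n, rg$perimeter[1], rg$perimeter[2])
  per <- pmin(rg$perimeter[2], pmax(per_raw, 1.05 * sqrt(4 * pi * area)))
  thick <- runif(n, rg$thickness[1], rg$thickness[2])
  skew <- runif(n, rg$skewness[1], rg$skewness[2])
  lapply(seq_len(n), function(i) {
    leaf_features(area = area[i], perimeter = per[i],
                  thickness = thick[i], skewness = skew[i])
  })
}

#' Ground-truth characteristic curve model
#'
#' The simulator's per-leaf voltage law: a two-endpoint power curve
#' `V(rwc) = v_max - (v_max - v_min) * (rwc/100)^gamma`, strictly
#' decreasing in RWC. `V(100) = v_min` (turgid, maximal acoustic
#' attenuation by water) and `V(0) = v_max` (dry, maximal transmission).
#'
#' @param v_min,v_max Curve endpoints in mV, `v_max > v_min > 0`.
#' @param gamma Shape exponent, > 0.
#' @return An object of class `truth_curve_model`.
#' @export
truth_curve_model <- function(v_min, v_max, gamma) {
  stopifnot(v_max > v_min, v_min > 0, gamma > 0)
  structure(list(v_min = v_min, v_max = v_max, gamma = gamma),
            class = "truth_curve_model")
}

#' Evaluate a ground-truth curve model
#'
#' @param model A [truth_curve_model()].
#' @param rwc Relative water content, percent (vectorized).
#' @return V_TRx in mV.
#' @export
eval_truth_curve <- function(model, rwc) {
  stopifnot(inherits(model, "truth_curve_model"))
  model$v_max - (model$v_max - model$v_min) * (rwc / 100)^model$gamma
}

#' Map leaf features to a ground-truth curve model
#'
#' Deterministic smooth maps from the normalized features to the curve
#' parameters, with fixed shipped coefficients so that parameter recovery by
#' the generative model is a well-posed test:
#' \itemize{
#'   \item `v_min = v_min_base * (0.75 + 0.5 * logistic(3*(uT - 0.5)))` —
#'     thicker blades transmit less at turgor;
#'   \item `v_max = v_max_base * (0.8 + 0.4 * logistic(3*(uAP - 0.5)))`,
#'     then multiplied by a seeded amplitude-group scale for bimodal
#'     cultivars;
#'   \item `gamma = g_lo + (g_hi - g_lo) * logistic(3*(uS + uA - 1))`.
#' }
#' `uT`, `uAP`, `uS`, `uA` are the features rescaled to `[0, 1]` by the
#' spec ranges (A/P by the range implied by the A and P bounds). Group
#' membership is drawn from the spec's amplitude-group weights and is
#' independent of the features.
#'
#' @param features A [leaf_features()] object.
#' @param spec The cultivar's [cultivar_spec()].
#' @param seed Integer seed controlling only the group assignment.
#' @return A [truth_curve_model()].
#' @export
ground_truth_curve <- function(features, spec, seed = 0) {
  stopifnot(inherits(features, "leaf_features"), inherits(spec, "cultivar_spec"))
  rg <- spec$feature_ranges
  uA <- unit_scale(features$area, rg$area)
  uT <- unit_scale(features$thickness, rg$thickness)
  uS <- unit_scale(features$skewness, rg$skewness)
  ap_range <- c(rg$area[1] / rg$perimeter[2], rg$area[2] / rg$perimeter[1])
  uAP <- unit_scale(features$ap_ratio, ap_range)

  v_min <- spec$v_min_base * (0.75 + 0.5 * logistic(3 * (uT - 0.5)))
  v_max0 <- spec$v_max_base * (0.8 + 0.4 * logistic(3 * (uAP - 0.5)))
  g <- spec$curve_shape_gamma_range
  gamma <- g[1] + (g[2] - g[1]) * logistic(3 * (uS + uA - 1))

  w <- vapply(spec$amplitude_groups, function(gr) gr[["weight"]], numeric(1))
  scales <- vapply(spec$amplitude_groups, function(gr) gr[["v_max_scale"]],
                   numeric(1))
  set.seed(seed)
  grp <- findInterval(runif(1), cumsum(w), left.open = TRUE) + 1L
  grp <- min(grp, length(scales))
  model <- truth_curve_model(v_min, v_max0 * scales[grp], gamma)
  model$group <- grp
  model
}

#' Assemble a synthetic leaf
#'
#' Bundles features, the ground-truth voltage law, reference masses and the
#' drying rate into one object. Dry mass is volumetric (area x thickness x
#' a nominal dry tissue density of 0.35 g cm^-3); turgid mass follows from a
#' seeded dry-matter fraction between 0.15 and 0.30, typical of
#' well-hydrated leaves. The per-loop water retention ratio is a
#' deterministic function of thickness (`0.5 + 0.25 * uT`): thicker blades
#' lose water more slowly in the fixed oven interval.
#'
#' @param features A [leaf_features()] object.
#' @param spec The cultivar's [cultivar_spec()].
#' @param seed Integer seed (group assignment and dry-matter fraction).
#' @return An object of class `synthetic_leaf`.
#' @export
synthetic_leaf <- function(features, spec, seed = 0) {
  truth <- ground_truth_curve(features, spec, seed = seed)
  set.seed(child_seed(seed, 1))
  dm_frac <- runif(1, 0.15, 0.30)
  dry <- features$area * (features$thickness * 1e-4) * 0.35
  turgid <- dry / dm_frac
  uT <- unit_scale(features$thickness, spec$feature_ranges$thickness)
  structure(
    list(cultivar = spec$name, features = features, truth = truth,
         turgid_mass = turgid, dry_mass = dry,
         decay_ratio = 0.5 + 0.25 * uT,
         noise_v_sd = spec$noise_v_sd),
    class = "synthetic_leaf"
  )
}

#' Simulate a stepwise oven-drying loop
#'
#' Emulates the curve-acquisition protocol: the leaf starts fully turgid,
#' and each loop iteration (oven interval) removes a fixed fraction of the
#' remaining water (geometric schedule), after which mass and V_TRx are
#' recorded. V_TRx is the truth curve evaluated at the current RWC plus
#' Gaussian measurement noise.
#'
#' @param leaf A [synthetic_leaf()].
#' @param n_iter Number of loop iterations (>= 2; the protocol uses 10).
#' @param seed Integer seed for the voltage noise.
#' @param noise_v_sd Noise sd in mV; defaults to the leaf's cultivar value.
#' @return A data.frame with columns `iteration` (0-based), `fresh_mass`
#'   (g) and `v_trx` (mV); the first row is the turgid reading.
#' @export
simulate_drying_loop <- function(leaf, n_iter = 10, seed = 0,
                                 noise_v_sd = leaf$noise_v_sd) {
  stopifnot(inherits(leaf, "synthetic_leaf"))
  if (n_iter < 2) stop("n_iter must be >= 2")
  water0 <- leaf$turgid_mass - leaf$dry_mass
  i <- seq_len(n_iter) - 1L
  water <- water0 * leaf$decay_ratio^i
  fresh <- leaf$dry_mass + water
  rwc <- 100 * leaf$decay_ratio^i
  set.seed(seed)
  v <- eval_truth_curve(leaf$truth, rwc) + rnorm(n_iter, 0, noise_v_sd)
  data.frame(iteration = i, fresh_mass = fresh, v_trx = pmax(v, 1e-3))
}

#' Generate a synthetic training library for one cultivar
#'
#' Runs the full acquisition emulation for `n` leaves: feature sampling,
#' ground-truth curve assignment, a 10-iteration drying loop with voltage
#' noise, and RWC computation from masses with additive RWC noise clamped
#' to `[0, 100]`. Output matrices use the training-library layout:
#' N x 10 voltage and RWC curve matrices plus an N x 5 feature matrix.
#'
#' @param spec A [cultivar_spec()].
#' @param n Number of leaves (>= 2); defaults to the spec's library size.
#' @param seed Integer master seed.
#' @param n_points Curve length (default 10).
#' @param noise_v_sd,noise_rwc_sd Override the spec's noise levels (mV and
#'   RWC percentage points); set both to 0 for a noiseless library.
#' @return A `training_library` (see [build_library()]) whose manifest
#'   records the spec name, seed and shapes, with the per-leaf ground-truth
#'   parameters attached as `$truth` for simulation studies.
#' @examples
#' lib <- generate_library(builtin_cultivar("japanese"), n = 5, seed = 1)
#' dim(lib$v_matrix)
#' @export
generate_library <- function(spec, n = spec$n_default, seed = 0,
                             n_points = 10,
                             noise_v_sd = spec$noise_v_sd,
                             noise_rwc_sd = spec$noise_rwc_sd) {
  if (!inherits(spec, "cultivar_spec")) stop("unknown cultivar spec")
  if (n < 2) stop("n must be >= 2")
  feats <- sample_features(spec, n, seed)
  v_mat <- matrix(NA_real_, n, n_points)
  rwc_mat <- matrix(NA_real_, n, n_points)
  truth <- data.frame(v_min = numeric(n), v_max = numeric(n),
                      gamma = numeric(n), group = integer(n),
                      decay_ratio = numeric(n),
                      turgid_mass = numeric(n), dry_mass = numeric(n))
  for (i in seq_len(n)) {
    leaf <- synthetic_leaf(feats[[i]], spec, seed = child_seed(seed, 2 * i))
    rec <- simulate_drying_loop(leaf, n_iter = n_points,
                                seed = child_seed(seed, 2 * i + 1),
                                noise_v_sd = noise_v_sd)
    curve <- assemble_curve(rec, leaf$turgid_mass, leaf$dry_mass)
    v_mat[i, ] <- curve$points$v_trx
    rwc_mat[i, ] <- curve$points$rwc
    truth[i, ] <- list(leaf$truth$v_min, leaf$truth$v_max, leaf$truth$gamma,
                       leaf$truth$group, leaf$decay_ratio,
                       leaf$turgid_mass, leaf$dry_mass)
  }
  if (noise_rwc_sd > 0) {
    set.seed(child_seed(seed, 999999))
    rwc_mat <- rwc_mat + matrix(rnorm(n * n_points, 0, noise_rwc_sd),
                                n, n_points)
    rwc_mat[] <- pmin(100, pmax(0, rwc_mat))
  }
  leaf_ids <- sprintf("%s-%d-%04d", spec$name, seed, seq_len(n))
  lib <- training_library(
    v_matrix = v_mat, rwc_matrix = rwc_mat,
    features = features_matrix(feats), cultivar = spec$name,
    leaf_ids = leaf_ids,
    manifest = list(spec = spec$name, seed = seed, n = n,
                    n_points = n_points,
                    noise_v_sd = noise_v_sd, noise_rwc_sd = noise_rwc_sd)
  )
  lib$truth <- truth
  lib
}
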
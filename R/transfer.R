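#' Fit a polynomial voltage-to-RWC transfer function
#'
#' Least-squares fit of `RWC = f(V_TRx)` as a raw polynomial of the given
#' degree through a characteristic curve's points, giving the continuous
#' dependency used to translate device voltages into hydration values. The
#' curve's voltage extrema define the validity range; outside it the
#' function clamps (see [voltage_to_rwc()]).
#'
#' @param curve A [characteristic_curve()].
#' @param degree Polynomial degree (default 3), `1 <= degree < n points`.
#' @return An object of class `transfer_function` with `coefficients`
#'   (intercept first), `degree`, `v_range`, `residual_rmse` and a
#'   `monotone` flag (whether the fit is monotone over `v_range`).
#' @examples
#' cc <- characteristic_curve(v_trx = seq(100, 400, length.out = 10),
#'                            rwc = seq(100, 5, length.out = 10))
#' tf <- fit_transfer(cc)
#' voltage_to_rwc(tf, 250)
#' @export
fit_transfer <- function(curve, degree = 3) {
  stopifnot(inherits(curve, "characteristic_curve"))
  n <- nrow(curve$points)
  if (degree < 1) stop("degree must be >= 1")
  if (degree >= n) {
    stop("underdetermined fit: degree ", degree, " needs more than ", n,
         " points")
  }
  v <- curve$points$v_trx
  r <- curve$points$rwc
  dup <- duplicated(v) | duplicated(v, fromLast = TRUE)
  if (any(dup) && stats::sd(r[dup]) > 1e-9) {
    warning("ill-conditioned fit: duplicate v_trx values with ",
            "conflicting rwc")
  }
  fit <- stats::lm(r ~ stats::poly(v, degree, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  coefs[is.na(coefs)] <- 0
  v_range <- range(v)
  pred <- drop(stats::predict(fit))
  grid <- seq(v_range[1], v_range[2], length.out = 200)
  deriv <- outer(grid, seq_len(degree) - 1, `^`) %*%
    (coefs[-1] * seq_len(degree))
  monotone <- all(deriv <= 1e-9) || all(deriv >= -1e-9)
  if (!monotone) {
    message("transfer function is non-monotone over its voltage range")
  }
  structure(
    list(coefficients = coefs, degree = degree, v_range = v_range,
         residual_rmse = sqrt(mean((pred - r)^2)), monotone = monotone,
         source = curve$cultivar),
    class = "transfer_function"
  )
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf(
    "<transfer_function> degree %d on V in [%.1f, %.1f] mV (RMSE %.3g%%%s)\n",
    x$degree, x$v_range[1], x$v_range[2], x$residual_rmse,
    if (x$monotone) "" else ", non-monotone"))
  invisible(x)
}

#' Translate a voltage into RWC
#'
#' Evaluates the transfer polynomial. Voltages outside the source curve's
#' range clamp to the nearest endpoint's value (polynomial extrapolation is
#' unbounded and physically meaningless); the output is clamped to
#' `[0, 100]`.
#'
#' @param tf A [fit_transfer()] object.
#' @param v Voltage(s), mV, > 0.
#' @return RWC in percent, in `[0, 100]`.
#' @export
voltage_to_rwc <- function(tf, v) {
  stopifnot(inherits(tf, "transfer_function"))
  if (any(v <= 0)) stop("v must be > 0")
  n_out <- sum(v < tf$v_range[1] | v > tf$v_range[2])
  if (n_out > 0) {
    message(n_out, " voltage reading(s) outside [",
            sprintf("%.1f, %.1f", tf$v_range[1], tf$v_range[2]),
            "] mV clamped to range endpoints")
  }
  vc <- pmin(tf$v_range[2], pmax(tf$v_range[1], v))
  val <- drop(outer(vc, seq_along(tf$coefficients) - 1, `^`) %*%
                tf$coefficients)
  pmin(100, pmax(0, val))
}

#' Translate a voltage time trace into an RWC series
#'
#' @param tf A [fit_transfer()] object.
#' @param trace data.frame with strictly increasing `time_h` and positive
#'   `v_trx_mv` columns (zero rows allowed).
#' @return data.frame with `time_h` and `rwc_pct`.
#' @export
translate_trace <- function(tf, trace) {
  stopifnot(all(c("time_h", "v_trx_mv") %in% names(trace)))
  if (nrow(trace) == 0) {
    return(data.frame(time_h = numeric(0), rwc_pct = numeric(0)))
  }
  if (any(diff(trace$time_h) <= 0)) stop("time_h must be strictly increasing")
  data.frame(time_h = trace$time_h,
             rwc_pct = voltage_to_rwc(tf, trace$v_trx_mv))
}

#' One-shot RWC measurement for a pre-characterized leaf
#'
#' The full translation chain for a single instantaneous reading: generate
#' the leaf's characteristic curve from its features (deterministic mode),
#' fit the polynomial transfer function, and evaluate it at the measured
#' voltage.
#'
#' @param gen A trained [train_cvae()] generator.
#' @param features The leaf's [leaf_features()].
#' @param v Measured V_TRx, mV.
#' @param degree Transfer polynomial degree.
#' @return RWC in percent, with the intermediate curve and transfer
#'   function attached as attributes `"curve"` and `"transfer"` for audit.
#' @export
one_shot_rwc <- function(gen, features, v, degree = 3) {
  curve <- predict_curve(gen, features, mode = "deterministic")
  tf <- fit_transfer(curve, degree = degree)
  out <- voltage_to_rwc(tf, v)
  attr(out, "curve") <- curve
  attr(out, "transfer") <- tf
  out
}

#' Root mean squared error
#'
#' @param predicted,truth Equal-length numeric vectors (length >= 1).
#' @return `sqrt(mean((predicted - truth)^2))`.
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 5))  # sqrt(4/3)
#' @export
rmse <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(predicted) < 1) {
    stop("predicted and truth must be equal-length, non-empty")
  }
  sqrt(mean((predicted - truth)^2))
}

#' Hold-out evaluation of a curve generator
#'
#' Predicts each test leaf's curve deterministically from its features and
#' scores it against the library's recorded voltage and RWC vectors.
#' The summary singles out the best (minimum-RMSE) leaf per metric
#' alongside the mean, mirroring best-of-k reporting as used in sensor
#' calibration work; "best" is a selection, not a typical-case figure.
#'
#' @param gen A trained [train_cvae()] generator.
#' @param test A [training_library()] disjoint from the training library
#'   (enforced via leaf ids when the generator's manifest carries them).
#' @param train_ids Optional character vector of training leaf ids for the
#'   leakage check.
#' @return An object of class `evaluation_report`: per-leaf data.frame
#'   `per_leaf` (`leaf_id`, `v_rmse_mv`, `rwc_rmse_pct`), `best`
#'   (named minima and their indices) and `mean` summaries.
#' @export
evaluate_holdout <- function(gen, test, train_ids = NULL) {
  stopifnot(inherits(test, "training_library"))
  if (!is.null(train_ids) && length(intersect(train_ids, test$leaf_ids))) {
    stop("leakage: test library shares leaf ids with the training set")
  }
  n <- nrow(test$v_matrix)
  v_rmse <- rwc_rmse <- numeric(n)
  for (i in seq_len(n)) {
    f <- test$features[i, ]
    feats <- leaf_features(area = f[["area_cm2"]],
                           perimeter = f[["perimeter_cm"]],
                           thickness = f[["thickness_um"]],
                           skewness = f[["skewness"]])
    pc <- predict_curve(gen, feats, mode = "deterministic")
    v_rmse[i] <- rmse(pc$points$v_trx, test$v_matrix[i, ])
    rwc_rmse[i] <- rmse(pc$points$rwc, test$rwc_matrix[i, ])
  }
  structure(
    list(per_leaf = data.frame(leaf_id = test$leaf_ids,
                               v_rmse_mv = v_rmse,
                               rwc_rmse_pct = rwc_rmse),
         best = list(v_rmse_mv = min(v_rmse),
                     v_leaf = test$leaf_ids[which.min(v_rmse)],
                     rwc_rmse_pct = min(rwc_rmse),
                     rwc_leaf = test$leaf_ids[which.min(rwc_rmse)]),
         mean = list(v_rmse_mv = mean(v_rmse),
                     rwc_rmse_pct = mean(rwc_rmse)),
         cultivar = gen$cultivar,
         config = gen$config),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$cultivar, "-", nrow(x$per_leaf),
      "held-out leaves\n")
  cat(sprintf("  best: V_TRx RMSE %.2f mV (%s), RWC RMSE %.2f%% (%s)\n",
              x$best$v_rmse_mv, x$best$v_leaf,
              x$best$rwc_rmse_pct, x$best$rwc_leaf))
  cat(sprintf("  mean: V_TRx RMSE %.2f mV, RWC RMSE %.2f%%\n",
              x$mean$v_rmse_mv, x$mean$rwc_rmse_pct))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An [evaluate_holdout()] report.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(
    list(cultivar = report$cultivar, best = report$best,
         mean = report$mean, per_leaf = report$per_leaf,
         config = unclass(report$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
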
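#' Relative water content from fresh, turgid and dry mass
#'
#' The standard gravimetric definition
#' `RWC = 100 * (fresh - dry) / (turgid - dry)`. Fresh masses slightly
#' outside the `[dry, turgid]` interval — routine balance noise — are
#' clamped to the interval with a warning rather than rejected.
#'
#' @param fresh_mass,turgid_mass,dry_mass Masses in g;
#'   `turgid_mass > dry_mass > 0`. `fresh_mass` may be vectorized.
#' @return RWC in percent, in `[0, 100]`.
#' @examples
#' compute_rwc(4, 6, 2)  # 50
#' @export
compute_rwc <- function(fresh_mass, turgid_mass, dry_mass) {
  if (!(dry_mass > 0)) stop("dry_mass must be > 0")
  if (!(turgid_mass > dry_mass)) {
    stop("degenerate calibration: turgid_mass must exceed dry_mass")
  }
  tol <- 1e-9 * turgid_mass
  out_of_range <- fresh_mass < dry_mass - tol | fresh_mass > turgid_mass + tol
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " fresh mass reading(s) outside [dry, turgid]; RWC clamped")
  }
  fresh <- pmin(turgid_mass, pmax(dry_mass, fresh_mass))
  100 * (fresh - dry_mass) / (turgid_mass - dry_mass)
}

#' Characteristic curve container
#'
#' An ordered set of (V_TRx, RWC) pairs in acquisition order
#' (turgid to dry, so RWC is non-increasing), normally 10 points.
#'
#' @param v_trx Voltages, mV (> 0).
#' @param rwc RWC values, percent, each in `[0, 100]`.
#' @param cultivar Optional cultivar tag.
#' @return An object of class `characteristic_curve` with a `points`
#'   data.frame.
#' @export
characteristic_curve <- function(v_trx, rwc, cultivar = NULL) {
  stopifnot(length(v_trx) == length(rwc), length(v_trx) >= 1)
  if (any(v_trx <= 0)) stop("all v_trx must be > 0")
  if (any(rwc < -1e-9 | rwc > 100 + 1e-9)) stop("all rwc must be in [0, 100]")
  structure(
    list(points = data.frame(v_trx = v_trx, rwc = pmin(100, pmax(0, rwc))),
         cultivar = cultivar),
    class = "characteristic_curve"
  )
}

#' @export
print.characteristic_curve <- function(x, ...) {
  cat("<characteristic_curve>", nrow(x$points), "points",
      if (!is.null(x$cultivar)) paste0("(", x$cultivar, ")"), "\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Assemble a characteristic curve from drying-loop records
#'
#' Converts each recorded (fresh mass, V_TRx) pair into a curve point,
#' computing RWC from the turgid and 24 h dry reference masses. Record
#' order is preserved.
#'
#' @param records data.frame with columns `iteration`, `fresh_mass` (g),
#'   `v_trx` (mV); at least 2 rows.
#' @param turgid_mass,dry_mass Reference masses, g.
#' @param cultivar Optional tag.
#' @return A [characteristic_curve()].
#' @examples
#' rec <- data.frame(iteration = 0:2, fresh_mass = c(6, 5, 4),
#'                   v_trx = c(100, 180, 240))
#' assemble_curve(rec, turgid_mass = 6, dry_mass = 2)
#' @export
assemble_curve <- function(records, turgid_mass, dry_mass, cultivar = NULL) {
  if (is.null(records) || nrow(records) == 0) stop("records must be non-empty")
  if (nrow(records) < 2) stop("need at least 2 drying records")
  stopifnot(all(c("fresh_mass", "v_trx") %in% names(records)))
  rwc <- compute_rwc(records$fresh_mass, turgid_mass, dry_mass)
  characteristic_curve(records$v_trx, rwc, cultivar = cultivar)
}

#' Average multi-region voltage readings per drying iteration
#'
#' Protocols that probe V_TRx at several blade positions (two regions for
#' Honey, four for Japanese/Orange) record multiple rows per loop
#' iteration; curve assembly expects one. This reduces each iteration's
#' readings to their mean voltage (and mean fresh mass, which should agree
#' across regions anyway).
#'
#' @param records data.frame with `iteration`, `fresh_mass`, `v_trx`,
#'   possibly repeated per iteration.
#' @return One row per iteration, ordered by iteration.
#' @export
average_regions <- function(records) {
  stopifnot(all(c("iteration", "fresh_mass", "v_trx") %in% names(records)))
  agg <- stats::aggregate(records[c("fresh_mass", "v_trx")],
                          by = records["iteration"], FUN = mean)
  agg[order(agg$iteration), , drop = FALSE]
}

#' Read a drying-loop CSV with its mass side-car
#'
#' Reads `<prefix>.csv` (columns `leaf_id`, `iteration`, `fresh_mass_g`,
#' `v_trx_mv`) and `<prefix>.json` (fields `turgid_mass_g`, `dry_mass_g`
#' per leaf id), returning per-leaf record tables ready for
#' [assemble_curve()]. Multi-region rows are averaged per iteration.
#'
#' @param prefix Path prefix of the two files.
#' @return Named list (by leaf id) of lists with `records`, `turgid_mass`,
#'   `dry_mass`.
#' @export
read_drying_loop <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"), stringsAsFactors = FALSE)
  masses <- jsonlite::read_json(paste0(prefix, ".json"),
                                simplifyVector = TRUE)
  out <- lapply(unique(df$leaf_id), function(id) {
    sub <- df[df$leaf_id == id, ]
    rec <- average_regions(data.frame(iteration = sub$iteration,
                                      fresh_mass = sub$fresh_mass_g,
                                      v_trx = sub$v_trx_mv))
    m <- masses[[id]]
    list(records = rec, turgid_mass = m$turgid_mass_g,
         dry_mass = m$dry_mass_g)
  })
  names(out) <- unique(df$leaf_id)
  out
}

#' Training library container
#'
#' Stacked per-cultivar training data: an N x 10 voltage matrix, an
#' N x 10 RWC matrix and an N x 5 feature matrix, with a provenance
#' manifest. Internal constructor shared by [build_library()] and
#' [generate_library()].
#'
#' @param v_matrix,rwc_matrix N x k numeric matrices (mV, percent).
#' @param features N x 5 numeric matrix.
#' @param cultivar Cultivar tag.
#' @param leaf_ids Character vector of N unique leaf identifiers.
#' @param manifest Provenance list.
#' @return An object of class `training_library`.
#' @export
training_library <- function(v_matrix, rwc_matrix, features, cultivar,
                             leaf_ids = NULL, manifest = list()) {
  if (!is.matrix(v_matrix) || !is.matrix(rwc_matrix)) {
    stop("v_matrix and rwc_matrix must be matrices")
  }
  n <- nrow(v_matrix)
  if (nrow(rwc_matrix) != n || nrow(features) != n) {
    stop("inconsistent library: row counts differ across blocks")
  }
  if (ncol(v_matrix) != ncol(rwc_matrix)) {
    stop("inconsistent library: curve matrices have different widths")
  }
  if (ncol(features) != 5) stop("feature matrix must have 5 columns")
  if (is.null(leaf_ids)) leaf_ids <- sprintf("%s-%04d", cultivar, seq_len(n))
  if (anyDuplicated(leaf_ids)) stop("leaf_ids must be unique")
  manifest$shapes <- list(v = dim(v_matrix), rwc = dim(rwc_matrix),
                          features = dim(features))
  structure(
    list(v_matrix = v_matrix, rwc_matrix = rwc_matrix,
         features = as.matrix(features), cultivar = cultivar,
         leaf_ids = leaf_ids, manifest = manifest),
    class = "training_library"
  )
}

#' @export
print.training_library <- function(x, ...) {
  cat("<training_library>", x$cultivar, ":", nrow(x$v_matrix), "leaves x",
      ncol(x$v_matrix), "curve points, 5 features\n")
  invisible(x)
}

#' Build a training library from curves and features
#'
#' @param curves List of [characteristic_curve()] objects of uniform length.
#' @param features List of [leaf_features()] objects, same length as
#'   `curves`.
#' @param cultivar Cultivar tag.
#' @param leaf_ids Optional leaf identifiers.
#' @return A [training_library()].
#' @export
build_library <- function(curves, features, cultivar, leaf_ids = NULL) {
  if (length(curves) != length(features)) {
    stop("inconsistent library: ", length(curves), " curves vs ",
         length(features), " feature sets")
  }
  lens <- vapply(curves, function(cv) nrow(cv$points), integer(1))
  if (length(unique(lens)) != 1) {
    stop("inconsistent library: curves of mixed length")
  }
  v <- t(vapply(curves, function(cv) cv$points$v_trx, numeric(lens[1])))
  r <- t(vapply(curves, function(cv) cv$points$rwc, numeric(lens[1])))
  training_library(v, r, features_matrix(features), cultivar,
                   leaf_ids = leaf_ids)
}

#' Relative percent change between two readings
#'
#' `100 * (final - initial) / initial`. With `integer = TRUE` the result is
#' truncated toward zero, matching how headline summaries are typically
#' reported (e.g. a 238 to 932 mV rise is a +291% change).
#'
#' @param initial,final Values; `initial` must be nonzero.
#' @param integer Truncate toward zero?
#' @return Percent change (positive = increase).
#' @examples
#' percent_change(238, 932, integer = TRUE)  # 291
#' @export
percent_change <- function(initial, final, integer = FALSE) {
  if (any(initial == 0)) stop("undefined baseline: initial value is 0")
  pc <- 100 * (final - initial) / initial
  if (integer) trunc(pc) else pc
}

#' Absolute change in percentage points
#'
#' Companion to [percent_change()] for quantities that are already
#' percentages (RWC): returns `final - initial` in points.
#'
#' @param initial,final Values in percent.
#' @param integer Truncate toward zero?
#' @return Change in percentage points.
#' @examples
#' points_change(100, 1.8, integer = TRUE)  # -98
#' @export
points_change <- function(initial, final, integer = FALSE) {
  d <- final - initial
  if (integer) trunc(d) else d
}

#' Write a training library to CSV + JSON manifest
#'
#' Writes `<prefix>_curves.csv` (long format: leaf_id, point_index,
#' v_trx_mv, rwc_pct), `<prefix>_features.csv` and `<prefix>_manifest.json`.
#' Numbers are written at 9 significant digits so a read/write round trip
#' is exact at that precision.
#'
#' @param lib A [training_library()].
#' @param prefix Path prefix for the three files.
#' @return Invisibly, the three file paths.
#' @export
write_library <- function(lib, prefix) {
  stopifnot(inherits(lib, "training_library"))
  n <- nrow(lib$v_matrix); k <- ncol(lib$v_matrix)
  fmt <- function(x) sprintf("%.9g", x)
  curves <- data.frame(
    leaf_id = rep(lib$leaf_ids, each = k),
    point_index = rep(seq_len(k), times = n),
    v_trx_mv = fmt(as.vector(t(lib$v_matrix))),
    rwc_pct = fmt(as.vector(t(lib$rwc_matrix)))
  )
  feats <- data.frame(leaf_id = lib$leaf_ids)
  for (j in seq_len(ncol(lib$features))) {
    feats[[colnames(lib$features)[j]]] <- fmt(lib$features[, j])
  }
  paths <- paste0(prefix, c("_curves.csv", "_features.csv", "_manifest.json"))
  utils::write.csv(curves, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(feats, paths[2], row.names = FALSE, quote = FALSE)
  manifest <- lib$manifest
  manifest$cultivar <- lib$cultivar
  jsonlite::write_json(manifest, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a training library written by [write_library()]
#'
#' @param prefix The prefix used when writing.
#' @return A [training_library()].
#' @export
read_library <- function(prefix) {
  curves <- utils::read.csv(paste0(prefix, "_curves.csv"),
                            stringsAsFactors = FALSE)
  feats <- utils::read.csv(paste0(prefix, "_features.csv"),
                           stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(paste0(prefix, "_manifest.json"),
                                  simplifyVector = TRUE)
  ids <- unique(curves$leaf_id)
  k <- sum(curves$leaf_id == ids[1])
  v <- matrix(as.numeric(curves$v_trx_mv), length(ids), k, byrow = TRUE)
  r <- matrix(as.numeric(curves$rwc_pct), length(ids), k, byrow = TRUE)
  fm <- as.matrix(feats[match(ids, feats$leaf_id), -1, drop = FALSE])
  rownames(fm) <- NULL
  training_library(v, r, fm, cultivar = manifest$cultivar,
                   leaf_ids = ids, manifest = manifest)
}
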
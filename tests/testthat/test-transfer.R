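test_that("polynomial fitting recovers a known cubic exactly", {
  v <- seq(100, 400, length.out = 10)
  coefs <- c(120, -0.5, 1.2e-3, -1.1e-6)
  r <- drop(outer(v, 0:3, `^`) %*% coefs)
  cc <- characteristic_curve(v, pmin(100, pmax(0, r)))
  tf <- fit_transfer(cc, degree = 3)
  expect_equal(tf$coefficients, coefs, tolerance = 1e-6)
  expect_lt(tf$residual_rmse, 1e-6)
  pred <- voltage_to_rwc(tf, v)
  expect_true(max(abs(pred - r)) < 1e-6)
})

test_that("degenerate and invalid fits are handled", {
  flat <- characteristic_curve(seq(100, 400, length.out = 10), rep(40, 10))
  tf <- fit_transfer(flat, degree = 3)
  expect_equal(voltage_to_rwc(tf, c(150, 250, 350)), rep(40, 3),
               tolerance = 1e-9)

  cc <- characteristic_curve(c(100, 200, 300), c(100, 50, 10))
  expect_error(fit_transfer(cc, degree = 3), "underdetermined")
  expect_error(fit_transfer(cc, degree = 0), "degree")

  dup <- characteristic_curve(c(100, 100, 200, 300, 400),
                              c(100, 60, 50, 30, 10))
  expect_warning(fit_transfer(dup, degree = 2), "ill-conditioned")
})

test_that("voltage_to_rwc clamps to the curve's range and to [0, 100]", {
  # linear transfer RWC = 100 - 0.1 V over [100, 900]
  cc <- characteristic_curve(seq(100, 900, length.out = 10),
                             100 - 0.1 * seq(100, 900, length.out = 10))
  tf <- fit_transfer(cc, degree = 1)
  expect_equal(voltage_to_rwc(tf, 300), 70, tolerance = 1e-9)
  # below v_lo: value at v_lo
  expect_equal(suppressMessages(voltage_to_rwc(tf, 5)),
               voltage_to_rwc(tf, 100), tolerance = 1e-9)
  vv <- seq(1, 2000, by = 13)
  out <- suppressMessages(voltage_to_rwc(tf, vv))
  expect_true(all(out >= 0 & out <= 100))
  expect_error(voltage_to_rwc(tf, -5), "v must be")
})

test_that("translate_trace preserves sample count and clamps", {
  cc <- characteristic_curve(seq(120, 420, length.out = 10),
                             seq(100, 2, length.out = 10))
  tf <- fit_transfer(cc)
  empty <- data.frame(time_h = numeric(0), v_trx_mv = numeric(0))
  expect_equal(nrow(translate_trace(tf, empty)), 0)

  const <- data.frame(time_h = 1:5, v_trx_mv = rep(200, 5))
  out <- translate_trace(tf, const)
  expect_equal(nrow(out), 5)
  expect_true(all(out$rwc_pct == out$rwc_pct[1]))

  jitter <- data.frame(time_h = seq(0, 24, by = 0.5),
                       v_trx_mv = 100 + 350 * abs(sin(seq(0, 6,
                                                          length.out = 49))))
  tr <- suppressMessages(translate_trace(tf, jitter))
  expect_true(all(tr$rwc_pct >= 0 & tr$rwc_pct <= 100))
  bad <- data.frame(time_h = c(1, 1), v_trx_mv = c(200, 210))
  expect_error(translate_trace(tf, bad), "strictly increasing")
})

test_that("a drying trace round-trips through its own curve's fit", {
  # truth curve, its 10-point sampling, and a continuous drying trace
  m <- truth_curve_model(v_min = 110, v_max = 380, gamma = 1.1)
  rwc10 <- 100 * 0.62^(0:9)
  cc <- characteristic_curve(eval_truth_curve(m, rwc10), rwc10)
  tf <- fit_transfer(cc, degree = 3)
  # transfer round trip at the curve's own points
  expect_lt(max(abs(voltage_to_rwc(tf, cc$points$v_trx) - cc$points$rwc)),
            2)
  # end-to-end on a dense trace from the same truth curve
  rwc_t <- seq(99, 1.5, length.out = 60)
  trace <- data.frame(time_h = seq(0, 30, length.out = 60),
                      v_trx_mv = eval_truth_curve(m, rwc_t))
  out <- translate_trace(tf, trace)
  expect_lt(max(abs(out$rwc_pct - rwc_t)), 3)
})

test_that("rmse matches hand computations", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(5, 6, 7), c(2, 3, 4)), 3)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 5)), sqrt(4 / 3))
  expect_error(rmse(1:3, 1:4), "equal-length")
})

test_that("one-shot measurement equals its three-step composition", {
  fx <- noiseless_generator()
  lib <- fx$lib
  f <- lib$features[2, ]
  feats <- leaf_features(area = f[["area_cm2"]],
                         perimeter = f[["perimeter_cm"]],
                         thickness = f[["thickness_um"]],
                         skewness = f[["skewness"]])
  v_probe <- mean(lib$v_matrix[2, 4:5])
  got <- suppressMessages(one_shot_rwc(fx$gen, feats, v_probe))
  curve <- predict_curve(fx$gen, feats, mode = "deterministic")
  tf <- fit_transfer(curve, degree = 3)
  manual <- suppressMessages(voltage_to_rwc(tf, v_probe))
  expect_equal(as.numeric(got), manual)
  expect_true(got >= 0 && got <= 100)

  # recovery: a voltage on a held-out leaf's truth curve maps to near the
  # true RWC
  test_lib <- generate_library(builtin_cultivar("orange"), n = 5,
                               seed = 3001, noise_v_sd = 0,
                               noise_rwc_sd = 0)
  tf_true <- truth_curve_model(test_lib$truth$v_min[1],
                               test_lib$truth$v_max[1],
                               test_lib$truth$gamma[1])
  rwc_true <- 45
  v_true <- eval_truth_curve(tf_true, rwc_true)
  g <- test_lib$features[1, ]
  feats_h <- leaf_features(area = g[["area_cm2"]],
                           perimeter = g[["perimeter_cm"]],
                           thickness = g[["thickness_um"]],
                           skewness = g[["skewness"]])
  est <- suppressMessages(one_shot_rwc(fx$gen, feats_h, v_true))
  expect_lt(abs(as.numeric(est) - rwc_true), 3)
})

test_that("hold-out evaluation reports best <= mean and blocks leakage", {
  fx <- small_generator()
  test_lib <- generate_library(builtin_cultivar("orange"), n = 5,
                               seed = 4001)
  rep <- evaluate_holdout(fx$gen, test_lib, train_ids = fx$lib$leaf_ids)
  expect_lte(rep$best$v_rmse_mv, rep$mean$v_rmse_mv)
  expect_lte(rep$best$rwc_rmse_pct, rep$mean$rwc_rmse_pct)
  expect_equal(nrow(rep$per_leaf), 5)

  one <- generate_library(builtin_cultivar("orange"), n = 2, seed = 5001)
  one$v_matrix <- one$v_matrix[1, , drop = FALSE]
  one$rwc_matrix <- one$rwc_matrix[1, , drop = FALSE]
  one$features <- one$features[1, , drop = FALSE]
  one$leaf_ids <- one$leaf_ids[1]
  r1 <- evaluate_holdout(fx$gen, one)
  expect_equal(r1$best$v_rmse_mv, r1$mean$v_rmse_mv)

  expect_error(evaluate_holdout(fx$gen, test_lib,
                                train_ids = test_lib$leaf_ids[3]),
               "leakage")
})

test_that("fixed seeds give identical evaluation reports end to end", {
  run <- function() {
    lib <- generate_library(builtin_cultivar("japanese"), n = 10, seed = 5)
    gen <- train_cvae(lib, cvae_config(epochs = 80, seed = 5))
    test_lib <- generate_library(builtin_cultivar("japanese"), n = 3,
                                 seed = 6001)
    evaluate_holdout(gen, test_lib, train_ids = lib$leaf_ids)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$per_leaf, r2$per_leaf)
})

test_that("degree-3 fits of monotone synthetic curves stay monotone", {
  lib <- generate_library(builtin_cultivar("japanese"), n = 60, seed = 17,
                          noise_v_sd = 0, noise_rwc_sd = 0)
  mono <- vapply(seq_len(60), function(i) {
    cc <- characteristic_curve(lib$v_matrix[i, ], lib$rwc_matrix[i, ])
    fit_transfer(cc, degree = 3)$monotone
  }, logical(1))
  expect_gte(mean(mono), 0.95)
})
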
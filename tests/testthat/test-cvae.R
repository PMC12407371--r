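test_that("a zero-weight network produces the standard-normal posterior", {
  sl <- cvae_slave(10, 5, cvae_config(), init = "zero")
  p <- cvae_encode(sl, runif(10), runif(5))
  expect_equal(as.vector(p$mu), c(0, 0))
  expect_equal(as.vector(p$log_var), c(0, 0))  # sigma^2 = 1

  # zero-weight decoder returns its (de-normalized) bias vector
  expect_equal(cvae_decode(sl, c(0, 0), runif(5)), rep(0, 10))
  sl$dec_out$b <- 1:10
  sl$denorm <- list(x_min = rep(100, 10), x_rng = rep(2, 10))
  expect_equal(cvae_decode(sl, c(0.3, -0.2), runif(5)), 100 + 2 * (1:10))

  # determinism and positivity of the variance
  set.seed(1)
  sl2 <- cvae_slave(10, 5, cvae_config(seed = 1), init = "xavier")
  x <- runif(10); cond <- runif(5)
  expect_identical(cvae_encode(sl2, x, cond), cvae_encode(sl2, x, cond))
  expect_true(all(exp(cvae_encode(sl2, x, cond)$log_var) > 0))
  expect_error(cvae_encode(sl2, runif(7), cond), "shape error")
})

test_that("reparameterization draws z = mu + sigma * eps", {
  p <- list(mu = matrix(c(1.5, -2), 1, 2), log_var = matrix(0, 1, 2))
  expect_equal(as.vector(reparameterize(p, eps = 0)), c(1.5, -2))

  p2 <- list(mu = matrix(0, 1, 1), log_var = matrix(log(4), 1, 1))
  expect_equal(as.vector(reparameterize(p2, eps = 1)), 2)

  # moments over 1e5 draws from N(0, 1)
  p3 <- list(mu = matrix(0, 1e5, 1), log_var = matrix(0, 1e5, 1))
  z <- reparameterize(p3, seed = 123)
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(stats::var(as.vector(z)) - 1), 0.05)
})

test_that("the ELBO matches closed forms and its KL is non-negative", {
  at_prior <- list(mu = matrix(0, 1, 2), log_var = matrix(0, 1, 2))
  l <- elbo_loss(1:10, 1:10, at_prior)
  expect_equal(unlist(l), c(recon = 0, kl = 0, total = 0))

  l2 <- elbo_loss(1:10, 1:10,
                  list(mu = matrix(1, 1, 1), log_var = matrix(0, 1, 1)))
  expect_equal(l2$kl, 0.5)  # -0.5 * (1 + 0 - 1 - 1)

  set.seed(42)
  for (i in 1:50) {
    p <- list(mu = matrix(rnorm(6), 2, 3),
              log_var = matrix(rnorm(6), 2, 3))
    expect_gte(elbo_loss(runif(20), runif(20), p)$kl, 0)
  }
  expect_error(elbo_loss(1:10, 1:9, at_prior), "shapes differ")
})

test_that("training is seeded-deterministic and reduces the loss", {
  sp <- builtin_cultivar("japanese")
  lib <- generate_library(sp, n = 8, seed = 2)
  cfg <- cvae_config(epochs = 60, seed = 3)
  g1 <- train_cvae(lib, cfg)
  g2 <- train_cvae(lib, cfg)
  expect_identical(g1$slave_v, g2$slave_v)
  expect_identical(g1$traces, g2$traces)

  for (tr in g1$traces) {
    expect_true(all(is.finite(tr$total)))
    expect_lt(tail(tr$total, 1), tr$total[1])
  }
  expect_equal(nrow(g1$traces$v), 60)
})

test_that("the loss trace plateaus: late moving average is non-increasing", {
  fx <- small_generator()
  for (tr in fx$gen$traces) {
    ma <- stats::filter(tr$total, rep(1 / 100, 100), sides = 1)
    ma <- ma[!is.na(ma)]
    late <- ma[seq(floor(length(ma) / 2), length(ma))]
    # tolerate wiggle of 1% of the total descent around the plateau
    expect_true(all(diff(late) <= 0.01 * (max(tr$total) - min(tr$total))))
  }
})

test_that("noiseless parameter recovery: held-out RWC RMSE below 2 points", {
  fx <- noiseless_generator()
  test_lib <- generate_library(builtin_cultivar("orange"), n = 10,
                               seed = 1021, noise_v_sd = 0,
                               noise_rwc_sd = 0)
  rep <- evaluate_holdout(fx$gen, test_lib, train_ids = fx$lib$leaf_ids)
  expect_lt(rep$mean$rwc_rmse_pct, 2)
  # per-leaf prediction against its own truth curve
  expect_lt(rep$best$rwc_rmse_pct, 2)
  expect_lte(rep$best$v_rmse_mv, rep$mean$v_rmse_mv)
})

test_that("prediction on a training leaf of a noiseless library is tight", {
  fx <- noiseless_generator()
  f <- fx$lib$features[1, ]
  feats <- leaf_features(area = f[["area_cm2"]],
                         perimeter = f[["perimeter_cm"]],
                         thickness = f[["thickness_um"]],
                         skewness = f[["skewness"]])
  pc <- predict_curve(fx$gen, feats, mode = "deterministic")
  expect_equal(nrow(pc$points), 10)
  expect_lt(rmse(pc$points$v_trx, fx$lib$v_matrix[1, ]), 5)
  expect_lt(rmse(pc$points$rwc, fx$lib$rwc_matrix[1, ]), 2)

  # deterministic mode is reproducible
  pc2 <- predict_curve(fx$gen, feats, mode = "deterministic")
  expect_identical(pc, pc2)

  untrained <- structure(list(trained = FALSE), class = "curve_generator")
  expect_error(predict_curve(untrained, feats), "not fitted")
})

test_that("conditioning matters: shuffled features degrade held-out RMSE", {
  fx <- noiseless_generator()
  test_lib <- generate_library(builtin_cultivar("orange"), n = 12,
                               seed = 2042, noise_v_sd = 0,
                               noise_rwc_sd = 0)
  correct <- evaluate_holdout(fx$gen, test_lib)
  shuffled <- test_lib
  set.seed(7)
  perm <- sample(nrow(shuffled$features))
  while (any(perm == seq_along(perm))) perm <- sample(length(perm))
  shuffled$features <- shuffled$features[perm, ]
  wrong <- evaluate_holdout(fx$gen, shuffled)
  expect_gte(wrong$mean$rwc_rmse_pct, 1.5 * correct$mean$rwc_rmse_pct)
})

test_that("sampled-mode curves average to the deterministic curve", {
  fx <- small_generator()
  f <- fx$lib$features[3, ]
  feats <- leaf_features(area = f[["area_cm2"]],
                         perimeter = f[["perimeter_cm"]],
                         thickness = f[["thickness_um"]],
                         skewness = f[["skewness"]])
  det <- predict_curve(fx$gen, feats, mode = "deterministic")
  draws <- vapply(1:200, function(s) {
    predict_curve(fx$gen, feats, mode = "sampled", seed = s)$points$v_trx
  }, numeric(10))
  m <- rowMeans(draws)
  se <- apply(draws, 1, stats::sd) / sqrt(ncol(draws))
  # sampling error plus a 0.5% allowance for the convexity bias of the
  # nonlinear decoder (the mean of a nonlinear map is not the map of the
  # mean, so a small systematic offset is expected and bounded)
  expect_true(all(abs(m - det$points$v_trx) <=
                    2 * se + 0.005 * abs(det$points$v_trx)))
})

test_that("generators survive a save/load round trip", {
  fx <- small_generator()
  path <- file.path(tempdir(), "gen.lpz.json")
  save_generator(fx$gen, path)
  back <- load_generator(path)
  f <- fx$lib$features[5, ]
  feats <- leaf_features(area = f[["area_cm2"]],
                         perimeter = f[["perimeter_cm"]],
                         thickness = f[["thickness_um"]],
                         skewness = f[["skewness"]])
  a <- predict_curve(fx$gen, feats)
  b <- predict_curve(back, feats)
  expect_equal(a$points, b$points, tolerance = 1e-12)
  file.remove(path)
})
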
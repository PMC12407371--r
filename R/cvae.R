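#' CVAE training configuration
#'
#' Hyperparameters of one conditional variational autoencoder slave pair.
#' Defaults: 2-dimensional latent, two hidden layers of 64 tanh units in
#' both encoder and decoder, Adam at learning rate 1e-3, full-batch
#' training, unit KL weight. The study schedule trains 20000 epochs for
#' Honey and 10000 for Japanese/Orange; reduced-epoch profiles (>= 2000)
#' reach the loss plateau on synthetic libraries and are used by the test
#' suite.
#'
#' @param latent_dim Latent dimension (>= 1).
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param epochs Training epochs (>= 1).
#' @param learning_rate Adam step size.
#' @param beta KL weight in the ELBO (>= 0).
#' @param seed Integer seed for initialization and reparameterization noise.
#' @return An object of class `cvae_config`.
#' @export
cvae_config <- function(latent_dim = 2, hidden_sizes = c(64, 64),
                        epochs = 2000, learning_rate = 1e-3,
                        beta = 1.0, seed = 0) {
  stopifnot(latent_dim >= 1, epochs >= 1, beta >= 0, learning_rate > 0,
            length(hidden_sizes) >= 1, all(hidden_sizes >= 1))
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_sizes = as.integer(hidden_sizes),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, beta = beta,
                 seed = as.integer(seed)),
            class = "cvae_config")
}

# Xavier-normal or zero initialization of one dense layer.
new_dense <- function(n_in, n_out, init) {
  W <- if (init == "zero") matrix(0, n_in, n_out) else {
    matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / (n_in + n_out))),
           n_in, n_out)
  }
  list(W = W, b = rep(0, n_out))
}

#' Construct one CVAE slave model
#'
#' A slave holds the encoder (tanh trunk plus linear mu / log-variance
#' heads) and decoder (tanh trunk plus linear output) weight matrices for
#' one target — the 10-point voltage vector or the 10-point RWC vector —
#' conditioned on the 5 leaf features. Freshly constructed slaves carry
#' identity de-normalization; [train_cvae()] replaces it with the
#' library's min-max statistics.
#'
#' @param input_dim Curve length (10).
#' @param cond_dim Condition length (5).
#' @param config A [cvae_config()].
#' @param init `"xavier"` (seeded random) or `"zero"`.
#' @return An object of class `cvae_slave`.
#' @export
cvae_slave <- function(input_dim = 10, cond_dim = 5,
                       config = cvae_config(), init = c("xavier", "zero")) {
  init <- match.arg(init)
  hs <- config$hidden_sizes
  ld <- config$latent_dim
  enc_dims <- c(input_dim + cond_dim, hs)
  dec_dims <- c(ld + cond_dim, hs)
  enc <- lapply(seq_along(hs), function(i) {
    new_dense(enc_dims[i], enc_dims[i + 1], init)
  })
  dec <- lapply(seq_along(hs), function(i) {
    new_dense(dec_dims[i], dec_dims[i + 1], init)
  })
  structure(
    list(enc = enc,
         enc_mu = new_dense(hs[length(hs)], ld, init),
         enc_lv = new_dense(hs[length(hs)], ld, init),
         dec = dec,
         dec_out = new_dense(hs[length(hs)], input_dim, init),
         input_dim = as.integer(input_dim), cond_dim = as.integer(cond_dim),
         latent_dim = ld,
         denorm = list(x_min = rep(0, input_dim), x_rng = rep(1, input_dim))),
    class = "cvae_slave"
  )
}

as_row <- function(x, d) {
  if (is.matrix(x)) {
    if (ncol(x) != d) stop("shape error: expected ", d, " columns")
    x
  } else {
    if (length(x) != d) stop("shape error: expected length ", d)
    matrix(x, 1, d)
  }
}

# Forward pass through the encoder; returns intermediate activations.
enc_forward <- function(slave, X, C) {
  A <- cbind(X, C)
  acts <- vector("list", length(slave$enc) + 1)
  acts[[1]] <- A
  for (i in seq_along(slave$enc)) {
    A <- tanh(sweep(A %*% slave$enc[[i]]$W, 2, slave$enc[[i]]$b, `+`))
    acts[[i + 1]] <- A
  }
  mu <- sweep(A %*% slave$enc_mu$W, 2, slave$enc_mu$b, `+`)
  lv <- sweep(A %*% slave$enc_lv$W, 2, slave$enc_lv$b, `+`)
  list(acts = acts, mu = mu, log_var = lv)
}

dec_forward <- function(slave, Z, C) {
  A <- cbind(Z, C)
  acts <- vector("list", length(slave$dec) + 1)
  acts[[1]] <- A
  for (i in seq_along(slave$dec)) {
    A <- tanh(sweep(A %*% slave$dec[[i]]$W, 2, slave$dec[[i]]$b, `+`))
    acts[[i + 1]] <- A
  }
  xr <- sweep(A %*% slave$dec_out$W, 2, slave$dec_out$b, `+`)
  list(acts = acts, x_recon = xr)
}

#' Encode a curve to its latent Gaussian parameters
#'
#' Maps a (normalized) 10-point curve plus its (normalized) 5-feature
#' condition through the encoder, returning the mean and log-variance of
#' the approximate posterior over the latent vector. Deterministic given
#' the weights and inputs.
#'
#' @param slave A [cvae_slave()].
#' @param curve Length-10 numeric vector (or n x 10 matrix), normalized.
#' @param condition Length-5 numeric vector (or n x 5 matrix), normalized.
#' @return List with `mu` and `log_var` (n x latent_dim matrices).
#' @export
cvae_encode <- function(slave, curve, condition) {
  stopifnot(inherits(slave, "cvae_slave"))
  X <- as_row(curve, slave$input_dim)
  C <- as_row(condition, slave$cond_dim)
  if (nrow(X) != nrow(C)) stop("curve and condition row counts differ")
  f <- enc_forward(slave, X, C)
  list(mu = f$mu, log_var = f$log_var)
}

#' Reparameterization: sample the latent vector
#'
#' `z = mu + exp(log_var / 2) * eps`, `eps ~ N(0, I)`. Supplying `eps`
#' overrides the draw (e.g. `eps = 0` gives `z = mu`).
#'
#' @param params List with `mu` and `log_var` as returned by
#'   [cvae_encode()].
#' @param eps Optional noise (matrix conformable with `mu`, or a scalar).
#' @param seed Optional integer seed for the draw.
#' @return Latent matrix `z` of the same shape as `mu`.
#' @export
reparameterize <- function(params, eps = NULL, seed = NULL) {
  mu <- as.matrix(params$mu)
  lv <- as.matrix(params$log_var)
  stopifnot(all(dim(mu) == dim(lv)))
  if (is.null(eps)) {
    if (!is.null(seed)) set.seed(seed)
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  } else if (length(eps) == 1) {
    eps <- matrix(eps, nrow(mu), ncol(mu))
  }
  mu + exp(lv / 2) * eps
}

#' Decode a latent vector to a curve
#'
#' Deterministic mean reconstruction: the latent vector concatenated with
#' the (normalized) condition passes through the decoder; the output is
#' de-normalized to mV or percent by the slave's stored statistics
#' (identity for freshly constructed slaves).
#'
#' @param slave A [cvae_slave()].
#' @param z Latent vector (or n x latent_dim matrix).
#' @param condition Length-5 vector (or n x 5 matrix), normalized.
#' @param denormalize De-normalize the output (default TRUE).
#' @return n x 10 matrix (a plain length-10 vector for single inputs).
#' @export
cvae_decode <- function(slave, z, condition, denormalize = TRUE) {
  stopifnot(inherits(slave, "cvae_slave"))
  Z <- as_row(z, slave$latent_dim)
  C <- as_row(condition, slave$cond_dim)
  if (nrow(Z) != nrow(C)) stop("z and condition row counts differ")
  xr <- dec_forward(slave, Z, C)$x_recon
  if (denormalize) {
    xr <- sweep(sweep(xr, 2, slave$denorm$x_rng, `*`), 2,
                slave$denorm$x_min, `+`)
  }
  if (nrow(xr) == 1) as.vector(xr) else xr
}

#' Evidence lower bound loss
#'
#' `recon` is the mean squared reconstruction error, `kl` the analytic KL
#' divergence of the diagonal-Gaussian posterior from the standard normal
#' prior, `-0.5 * sum(1 + log_var - mu^2 - exp(log_var))` averaged over
#' samples, and `total = recon + beta * kl`. The KL term is non-negative
#' for every input.
#'
#' @param x,x_recon Equal-length curve vectors or matrices.
#' @param params List with `mu`, `log_var`.
#' @param beta KL weight.
#' @return Named list `(recon, kl, total)`.
#' @examples
#' elbo_loss(1:10, 1:10, list(mu = matrix(0, 1, 2),
#'                            log_var = matrix(0, 1, 2)))
#' @export
elbo_loss <- function(x, x_recon, params, beta = 1.0) {
  x <- as.matrix(x); xr <- as.matrix(x_recon)
  if (!all(dim(x) == dim(xr))) stop("x and x_recon shapes differ")
  mu <- as.matrix(params$mu); lv <- as.matrix(params$log_var)
  recon <- mean((x - xr)^2)
  kl <- mean(-0.5 * rowSums(1 + lv - mu^2 - exp(lv)))
  list(recon = recon, kl = kl, total = recon + beta * kl)
}

# Named flat list of all trainable matrices/vectors of a slave.
slave_param_names <- function(slave) {
  c(unlist(lapply(seq_along(slave$enc), function(i) {
      paste0("enc", i, c("_W", "_b"))
    })),
    "enc_mu_W", "enc_mu_b", "enc_lv_W", "enc_lv_b",
    unlist(lapply(seq_along(slave$dec), function(i) {
      paste0("dec", i, c("_W", "_b"))
    })),
    "dec_out_W", "dec_out_b")
}

get_param <- function(slave, nm) {
  if (grepl("^enc_mu", nm)) return(slave$enc_mu[[sub("enc_mu_", "", nm)]])
  if (grepl("^enc_lv", nm)) return(slave$enc_lv[[sub("enc_lv_", "", nm)]])
  if (grepl("^dec_out", nm)) return(slave$dec_out[[sub("dec_out_", "", nm)]])
  i <- as.integer(sub("^(enc|dec)([0-9]+)_([Wb])$", "\\2", nm))
  part <- sub("^(enc|dec)([0-9]+)_([Wb])$", "\\1", nm)
  slot <- sub("^(enc|dec)([0-9]+)_([Wb])$", "\\3", nm)
  slave[[part]][[i]][[slot]]
}

set_param <- function(slave, nm, value) {
  if (grepl("^enc_mu", nm)) {
    slave$enc_mu[[sub("enc_mu_", "", nm)]] <- value
  } else if (grepl("^enc_lv", nm)) {
    slave$enc_lv[[sub("enc_lv_", "", nm)]] <- value
  } else if (grepl("^dec_out", nm)) {
    slave$dec_out[[sub("dec_out_", "", nm)]] <- value
  } else {
    i <- as.integer(sub("^(enc|dec)([0-9]+)_([Wb])$", "\\2", nm))
    part <- sub("^(enc|dec)([0-9]+)_([Wb])$", "\\1", nm)
    slot <- sub("^(enc|dec)([0-9]+)_([Wb])$", "\\3", nm)
    slave[[part]][[i]][[slot]] <- value
  }
  slave
}

# One full forward + backward pass; returns loss pieces and gradients
# (named like slave_param_names).
cvae_grad <- function(slave, X, C, eps, beta) {
  n <- nrow(X)
  ef <- enc_forward(slave, X, C)
  mu <- ef$mu; lv <- ef$log_var
  Z <- mu + exp(lv / 2) * eps
  df <- dec_forward(slave, Z, C)
  XR <- df$x_recon

  recon <- mean((XR - X)^2)
  kl <- mean(-0.5 * rowSums(1 + lv - mu^2 - exp(lv)))
  total <- recon + beta * kl

  g <- list()
  # decoder backward
  G <- 2 * (XR - X) / length(X)
  A_last <- df$acts[[length(df$acts)]]
  g$dec_out_W <- t(A_last) %*% G
  g$dec_out_b <- colSums(G)
  G <- (G %*% t(slave$dec_out$W)) * (1 - A_last^2)
  for (i in rev(seq_along(slave$dec))) {
    A_in <- df$acts[[i]]
    g[[paste0("dec", i, "_W")]] <- t(A_in) %*% G
    g[[paste0("dec", i, "_b")]] <- colSums(G)
    G <- G %*% t(slave$dec[[i]]$W)
    if (i > 1) G <- G * (1 - A_in^2)
  }
  dZ <- G[, seq_len(slave$latent_dim), drop = FALSE]

  dMU <- dZ + beta * mu / n
  dLV <- dZ * 0.5 * exp(lv / 2) * eps + beta * (exp(lv) - 1) / (2 * n)

  H_last <- ef$acts[[length(ef$acts)]]
  g$enc_mu_W <- t(H_last) %*% dMU
  g$enc_mu_b <- colSums(dMU)
  g$enc_lv_W <- t(H_last) %*% dLV
  g$enc_lv_b <- colSums(dLV)
  G <- (dMU %*% t(slave$enc_mu$W) + dLV %*% t(slave$enc_lv$W)) *
    (1 - H_last^2)
  for (i in rev(seq_along(slave$enc))) {
    A_in <- ef$acts[[i]]
    g[[paste0("enc", i, "_W")]] <- t(A_in) %*% G
    g[[paste0("enc", i, "_b")]] <- colSums(G)
    if (i > 1) G <- (G %*% t(slave$enc[[i]]$W)) * (1 - A_in^2)
  }
  list(recon = recon, kl = kl, total = total,
       col_mse = colMeans((XR - X)^2), grads = g)
}

min_max_stats <- function(M) {
  mn <- apply(M, 2, min)
  rng <- apply(M, 2, max) - mn
  rng[rng < 1e-12] <- 1
  list(min = mn, rng = rng)
}

apply_norm <- function(M, st) sweep(sweep(M, 2, st$min, `-`), 2, st$rng, `/`)

train_slave <- function(X_raw, C_norm, config) {
  st_x <- min_max_stats(X_raw)
  X <- apply_norm(X_raw, st_x)
  slave <- cvae_slave(ncol(X_raw), ncol(C_norm), config, init = "xavier")
  slave$denorm <- list(x_min = st_x$min, x_rng = st_x$rng)

  nms <- slave_param_names(slave)
  m_state <- v_state <- lapply(nms, function(nm) get_param(slave, nm) * 0)
  names(m_state) <- names(v_state) <- nms
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  n <- nrow(X)
  trace <- matrix(NA_real_, config$epochs, 4,
                  dimnames = list(NULL, c("recon", "kl", "total",
                                          "recon_denorm")))
  for (epoch in seq_len(config$epochs)) {
    eps <- matrix(stats::rnorm(n * slave$latent_dim), n, slave$latent_dim)
    res <- cvae_grad(slave, X, C_norm, eps, config$beta)
    if (!is.finite(res$total)) {
      stop("training diverged (non-finite loss) at epoch ", epoch)
    }
    for (nm in nms) {
      gr <- res$grads[[nm]]
      m_state[[nm]] <- b1 * m_state[[nm]] + (1 - b1) * gr
      v_state[[nm]] <- b2 * v_state[[nm]] + (1 - b2) * gr^2
      mh <- m_state[[nm]] / (1 - b1^epoch)
      vh <- v_state[[nm]] / (1 - b2^epoch)
      slave <- set_param(slave, nm,
                         get_param(slave, nm) - lr * mh / (sqrt(vh) + adam_eps))
    }
    trace[epoch, c("recon", "kl", "total")] <-
      c(res$recon, res$kl, res$total)
    trace[epoch, "recon_denorm"] <- mean(res$col_mse * st_x$rng^2)
  }
  list(slave = slave, trace = as.data.frame(trace))
}

#' Train the per-cultivar master model (two CVAE slaves)
#'
#' Trains the voltage slave on the library's N x 10 voltage matrix and the
#' RWC slave on its N x 10 RWC matrix, both conditioned on the same
#' min-max-normalized N x 5 feature matrix, full batch, with seeded
#' initialization and reparameterization noise. Curve columns are min-max
#' normalized to `[0, 1]`; the statistics are stored in the slaves so
#' predictions de-normalize back to mV and percent. Loss traces report the
#' normalized reconstruction MSE, the KL term, their beta-weighted total,
#' and the reconstruction MSE de-normalized to mV^2 / %^2.
#'
#' @param library A [training_library()].
#' @param config A [cvae_config()].
#' @return An object of class `curve_generator` with elements `slave_v`,
#'   `slave_rwc`, `config`, `norm` (feature statistics), `traces`
#'   (per-slave data.frames) and `manifest`.
#' @examples
#' \donttest{
#' lib <- generate_library(builtin_cultivar("orange"), n = 10, seed = 1)
#' gen <- train_cvae(lib, cvae_config(epochs = 200, seed = 1))
#' tail(gen$traces$rwc$total, 1) < gen$traces$rwc$total[1]
#' }
#' @export
train_cvae <- function(library, config = cvae_config()) {
  stopifnot(inherits(library, "training_library"),
            inherits(config, "cvae_config"))
  st_c <- min_max_stats(library$features)
  C <- apply_norm(library$features, st_c)
  set.seed(config$seed)
  sv <- train_slave(library$v_matrix, C, config)
  sr <- train_slave(library$rwc_matrix, C, config)
  structure(
    list(cultivar = library$cultivar,
         slave_v = sv$slave, slave_rwc = sr$slave,
         config = config,
         norm = list(c_min = st_c$min, c_rng = st_c$rng),
         traces = list(v = sv$trace, rwc = sr$trace),
         manifest = list(cultivar = library$cultivar,
                         seed = config$seed, epochs = config$epochs,
                         n_leaves = nrow(library$v_matrix),
                         library_fingerprint = sprintf(
                           "%dx%d:%.6g", nrow(library$v_matrix),
                           ncol(library$v_matrix), sum(library$v_matrix))),
         trained = TRUE),
    class = "curve_generator"
  )
}

#' @export
print.curve_generator <- function(x, ...) {
  cat("<curve_generator>", x$cultivar, "- trained", x$config$epochs,
      "epochs on", x$manifest$n_leaves, "leaves\n")
  cat(sprintf("  final losses: V %.4g, RWC %.4g (normalized total)\n",
              utils::tail(x$traces$v$total, 1),
              utils::tail(x$traces$rwc$total, 1)))
  invisible(x)
}

normalize_condition <- function(gen, features) {
  cvec <- c(features$area, features$perimeter, features$ap_ratio,
            features$thickness, features$skewness)
  (cvec - gen$norm$c_min) / gen$norm$c_rng
}

#' Generate the characteristic curve for an unseen leaf
#'
#' Conditions both slaves on the leaf's normalized features and decodes a
#' latent vector into the 10-point voltage and RWC vectors, zipped into a
#' characteristic curve. Deterministic mode uses the prior mean `z = 0`;
#' sampled mode draws `z ~ N(0, I)`.
#'
#' @param gen A trained [train_cvae()] generator.
#' @param features A [leaf_features()].
#' @param mode `"deterministic"` or `"sampled"`.
#' @param seed Integer seed for sampled mode.
#' @return A [characteristic_curve()]; RWC clamped to `[0, 100]`.
#' @export
predict_curve <- function(gen, features,
                          mode = c("deterministic", "sampled"), seed = 0) {
  if (!inherits(gen, "curve_generator") || !isTRUE(gen$trained)) {
    stop("not fitted: train_cvae() must be run first")
  }
  mode <- match.arg(mode)
  cn <- normalize_condition(gen, features)
  if (mode == "deterministic") {
    z <- rep(0, gen$config$latent_dim)
  } else {
    set.seed(seed)
    z <- stats::rnorm(gen$config$latent_dim)
  }
  v <- cvae_decode(gen$slave_v, z, cn)
  r <- cvae_decode(gen$slave_rwc, z, cn)
  characteristic_curve(pmax(v, 1e-6), pmin(100, pmax(0, r)),
                       cultivar = gen$cultivar)
}

slave_to_list <- function(slave) {
  nms <- slave_param_names(slave)
  params <- lapply(nms, function(nm) get_param(slave, nm))
  names(params) <- nms
  list(params = params, input_dim = slave$input_dim,
       cond_dim = slave$cond_dim, latent_dim = slave$latent_dim,
       n_hidden = length(slave$enc), denorm = slave$denorm)
}

slave_from_list <- function(sl, config) {
  slave <- cvae_slave(sl$input_dim, sl$cond_dim, config, init = "zero")
  for (nm in names(sl$params)) {
    p <- sl$params[[nm]]
    tmpl <- get_param(slave, nm)
    if (is.matrix(tmpl)) p <- matrix(unlist(p), nrow(tmpl), ncol(tmpl))
    else p <- as.numeric(unlist(p))
    slave <- set_param(slave, nm, p)
  }
  slave$denorm <- list(x_min = as.numeric(sl$denorm$x_min),
                       x_rng = as.numeric(sl$denorm$x_rng))
  slave
}

#' Save a trained generator to a single JSON archive
#'
#' Serializes both slaves' weights, the normalization statistics, the
#' configuration and the provenance manifest into one JSON file.
#'
#' @param gen A `curve_generator`.
#' @param path Output path (conventionally `.lpz.json`).
#' @return Invisibly, `path`.
#' @export
save_generator <- function(gen, path) {
  stopifnot(inherits(gen, "curve_generator"))
  obj <- list(format = "leafplp-generator-1",
              cultivar = gen$cultivar,
              config = unclass(gen$config),
              norm = gen$norm,
              manifest = gen$manifest,
              slave_v = slave_to_list(gen$slave_v),
              slave_rwc = slave_to_list(gen$slave_rwc))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a generator saved by [save_generator()]
#'
#' @param path JSON archive path.
#' @return A `curve_generator` (without training traces).
#' @export
load_generator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "leafplp-generator-1")) {
    stop("not a leafplp generator archive")
  }
  config <- do.call(cvae_config, obj$config[c("latent_dim", "hidden_sizes",
                                              "epochs", "learning_rate",
                                              "beta", "seed")])
  structure(
    list(cultivar = obj$cultivar,
         slave_v = slave_from_list(obj$slave_v, config),
         slave_rwc = slave_from_list(obj$slave_rwc, config),
         config = config,
         norm = list(c_min = as.numeric(obj$norm$c_min),
                     c_rng = as.numeric(obj$norm$c_rng)),
         traces = NULL, manifest = obj$manifest, trained = TRUE),
    class = "curve_generator"
  )
}
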
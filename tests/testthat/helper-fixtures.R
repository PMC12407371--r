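# Shared fixtures. Small trained generators are cached per test run so the
# CVAE and transfer suites do not retrain for every block.

.fixture_env <- new.env(parent = emptyenv())

# Synthetic square photograph: side_cm x side_cm dark square, centered.
square_image <- function(side_cm = 4, px_per_cm = 20, canvas_cm = 6) {
  n <- canvas_cm * px_per_cm
  px <- matrix(1, n, n)
  half <- side_cm * px_per_cm / 2
  lo <- floor(n / 2 - half) + 1
  hi <- floor(n / 2 + half)
  px[lo:hi, lo:hi] <- 0.2
  leaf_image(px, px_per_cm)
}

# Dark disk of radius r_cm.
circle_image <- function(r_cm = 3, px_per_cm = 20, canvas_cm = 8) {
  n <- canvas_cm * px_per_cm
  ctr <- (n + 1) / 2
  xs <- ((1:n) - ctr) / px_per_cm
  px <- outer(xs, xs, function(a, b) ifelse(a^2 + b^2 <= r_cm^2, 0.2, 1))
  leaf_image(px, px_per_cm)
}

# Small trained generator on a noisy orange library (shared fixture).
small_generator <- function() {
  if (is.null(.fixture_env$gen)) {
    sp <- builtin_cultivar("orange")
    lib <- generate_library(sp, n = 30, seed = 11)
    .fixture_env$lib <- lib
    .fixture_env$gen <- train_cvae(lib, cvae_config(epochs = 600, seed = 11))
  }
  list(gen = .fixture_env$gen, lib = .fixture_env$lib)
}

# Noiseless library + generator for parameter-recovery oracles.
noiseless_generator <- function() {
  if (is.null(.fixture_env$gen0)) {
    sp <- builtin_cultivar("orange")
    lib <- generate_library(sp, n = 40, seed = 21,
                            noise_v_sd = 0, noise_rwc_sd = 0)
    .fixture_env$lib0 <- lib
    .fixture_env$gen0 <- train_cvae(lib, cvae_config(epochs = 1000, seed = 21))
  }
  list(gen = .fixture_env$gen0, lib = .fixture_env$lib0)
}

ramanujan_ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}
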
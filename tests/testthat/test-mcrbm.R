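# independent naive implementations used as oracles throughout
oracle_energy_cov <- function(v, h_c, p) {
  D <- length(v)
  vh <- v / (sqrt(sum(v^2) / D) + 1e-8)
  e <- 0
  for (m in seq_along(h_c)) e <- e - p$d[m] * h_c[m]
  for (f in seq_len(ncol(p$C))) {
    u <- 0
    for (i in seq_len(D)) u <- u + vh[i] * p$C[i, f]
    for (m in seq_along(h_c)) e <- e - u^2 * p$P[f, m] * h_c[m]
  }
  e
}

oracle_energy_mean <- function(v, h_m, p) {
  q <- 0
  for (i in seq_along(v)) q <- q + (v[i] - p$b[i])^2
  e <- 0
  for (m in seq_along(h_m)) e <- e - 0.5 * q * p$c[m] * h_m[m]
  for (i in seq_along(v))
    for (m in seq_along(h_m)) e <- e - v[i] * p$W[i, m] * h_m[m]
  e
}

test_that("energies match the naive elementwise oracle on random instances", {
  set.seed(11)
  for (r in 1:25) {
    p <- random_params(D = 5, F = 4, Mc = 3, Mm = 3, seed = r)
    v <- rnorm(5)
    hc <- rbinom(3, 1, 0.5)
    hm <- rbinom(3, 1, 0.5)
    expect_equal(energy_cov(v, hc, p), oracle_energy_cov(v, hc, p),
                 tolerance = 1e-12)
    expect_equal(energy_mean(v, hm, p), oracle_energy_mean(v, hm, p),
                 tolerance = 1e-12)
    expect_identical(energy_total(v, hc, hm, p),
                     energy_cov(v, hc, p) + energy_mean(v, hm, p))
  }
})

test_that("energy special cases vanish as the algebra dictates", {
  p <- random_params(seed = 2)
  hc <- c(1, 0, 1); hm <- c(0, 1, 1)
  expect_equal(energy_cov(rep(0, 5), hc, p), -sum(p$d * hc))
  expect_equal(energy_cov(rnorm(5), rep(0, 3), p), 0)
  expect_equal(energy_mean(p$b, hm, p), -sum(p$b * (p$W %*% hm)))
  expect_equal(energy_mean(rnorm(5), rep(0, 3), p), 0)
})

test_that("shape mismatches error", {
  p <- random_params()
  expect_error(energy_cov(rnorm(4), c(1, 0, 1), p), "shape")
  expect_error(energy_mean(rnorm(5), c(1, 0), p), "shape")
  expect_error(conditional_gaussian(c(1, 0), c(1, 0, 0), p), "shape")
})

test_that("hidden inference matches closed forms and the naive oracle", {
  sg <- function(x) 1 / (1 + exp(-x))
  p <- random_params(seed = 3)
  expect_equal(infer_hidden_cov(rep(0, 5), p), sg(p$d))
  expect_equal(infer_hidden_mean(rep(0, 5), p), sg(p$c))

  p0 <- p
  p0$C[] <- 0; p0$d[] <- 0; p0$W[] <- 0; p0$c[] <- 0
  expect_equal(infer_hidden_cov(rnorm(5), p0), rep(0.5, 3))
  expect_equal(infer_hidden_mean(rnorm(5), p0), rep(0.5, 3))

  for (r in 1:25) {
    p <- random_params(seed = 100 + r)
    v <- rnorm(5)
    vh <- v / (sqrt(sum(v^2) / 5) + 1e-8)
    u <- as.numeric(t(p$C) %*% vh)
    expect_equal(infer_hidden_cov(v, p),
                 sg(p$d + as.numeric(t(p$P) %*% u^2)), tolerance = 1e-12)
    expect_equal(infer_hidden_mean(v, p),
                 sg(p$c + as.numeric(t(p$W) %*% v)), tolerance = 1e-12)
  }
})

test_that("activation probabilities are strict and monotone in the biases", {
  set.seed(12)
  for (r in 1:20) {
    p <- random_params(seed = 300 + r)
    v <- rnorm(5, sd = 2)
    pc <- infer_hidden_cov(v, p)
    pm <- infer_hidden_mean(v, p)
    expect_true(all(pc > 0 & pc < 1))
    expect_true(all(pm > 0 & pm < 1))
    p2 <- p
    p2$d <- p$d + runif(3, 0, 2)
    p2$c <- p$c + runif(3, 0, 2)
    expect_true(all(infer_hidden_cov(v, p2) >= pc))
    expect_true(all(infer_hidden_mean(v, p2) >= pm))
  }
})

test_that("the identity-parameter conditional Gaussian is exact", {
  p <- structure(list(C = diag(11), P = -diag(11), d = numeric(11),
                      W = matrix(0, 11, 10), c = numeric(10),
                      b = numeric(11)), class = "mcrbm_params")
  g <- conditional_gaussian(rep(1, 11), rep(0, 10), p)
  expect_equal(g$sigma, diag(11), tolerance = 1e-14)
  expect_equal(g$mean, rep(0, 11), tolerance = 1e-14)
})

test_that("scaling P scales the conditional covariance inversely", {
  p <- random_params(D = 4, F = 4, Mc = 3, Mm = 3, seed = 5)
  hc <- c(1, 1, 1); hm <- c(0, 1, 0)
  g1 <- conditional_gaussian(hc, hm, p)
  p2 <- p; p2$P <- 3 * p$P
  g2 <- conditional_gaussian(hc, hm, p2)
  expect_equal(g2$sigma, g1$sigma / 3, tolerance = 1e-10)
})

test_that("conditional Gaussian matches a dense-inverse oracle and is SPD", {
  for (r in 1:25) {
    p <- random_params(D = 6, F = 6, Mc = 4, Mm = 3, seed = 400 + r)
    hc <- rbinom(4, 1, 0.7)
    if (all(hc == 0)) hc[1] <- 1
    hm <- rbinom(3, 1, 0.5)
    g <- conditional_gaussian(hc, hm, p)
    prec <- p$C %*% diag(as.numeric(-p$P %*% hc)) %*% t(p$C)
    expect_equal(g$sigma, solve(prec), tolerance = 1e-8)
    expect_lt(max(abs(g$sigma - t(g$sigma))), 1e-10)
    expect_gt(min(eigen(g$sigma, symmetric = TRUE)$values), 0)
    expect_equal(g$mean, as.numeric(solve(prec, p$W %*% hm)),
                 tolerance = 1e-8)
  }
})

test_that("the all-zero covariance configuration is degenerate", {
  p <- random_params(seed = 6)
  expect_error(conditional_gaussian(rep(0, 3), c(1, 0, 0), p),
               "degenerate-state")
})

test_that("visible sampling is reproducible and has the right moments", {
  p <- structure(list(C = diag(4), P = -diag(4), d = numeric(4),
                      W = matrix(0.5, 4, 2), c = numeric(2),
                      b = numeric(4)), class = "mcrbm_params")
  hc <- rep(1, 4); hm <- c(1, 0)
  a <- sample_visible(hc, hm, p, n = 1, seed = 9)
  b <- sample_visible(hc, hm, p, n = 1, seed = 9)
  expect_identical(a, b)

  g <- conditional_gaussian(hc, hm, p)
  x <- sample_visible(hc, hm, p, n = 10000, seed = 10)
  # CLT band: 4 sigma / sqrt(n) per coordinate
  expect_true(all(abs(colMeans(x) - g$mean) < 4 / sqrt(10000)))
  expect_true(all(abs(apply(x, 2, var) - 1) < 0.06))
})

test_that("zero training epochs return the seeded initialisation", {
  mx <- make_mixture(K = 2, n = 600, seed = 13)
  cfg <- train_config(epochs = 0, seed = 77, minibatch_size = 100)
  fit <- mcrbm_train(mx$x, cfg)
  expect_equal(fit$params,
               mcrbm_params(D = 11, seed = 77,
                            mean_bias = cfg$mean_bias))
  expect_length(fit$recon, 0)
})

test_that("training is bit-reproducible for a fixed seed", {
  mx <- make_mixture(K = 3, n = 4000, seed = 14)
  cfg <- train_config(epochs = 2, seed = 5)
  f1 <- mcrbm_train(mx$x, cfg)
  f2 <- mcrbm_train(mx$x, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$recon, f2$recon)
})

test_that("training a separable mixture yields informative latent states", {
  mx <- make_mixture(K = 3, n = 20000, sep = 5, seed = 15)
  fit <- mcrbm_train(mx$x, train_config(epochs = 8, seed = 3))
  keys <- encode_dataset(mx$x, fit)
  expect_gte(nmi_labels(keys, mx$modes), 0.8)
  # reconstruction error roughly non-increasing over the last half
  rec <- fit$recon
  lastq <- rec[ceiling(length(rec) / 2):length(rec)]
  expect_true(all(diff(lastq) <= 0.1 * head(lastq, -1)))
  # separable modes collapse onto a handful of configurations
  tab <- sort(table(keys), decreasing = TRUE)
  expect_lte(sum(cumsum(tab) / length(keys) < 0.99) + 1, 32)
})

test_that("mode-to-state maps are injective for K = 2, 3, 5 mixtures", {
  for (K in c(2, 3, 5)) {
    mx <- make_mixture(K = K, n = 12000, sep = 5, seed = 20 + K)
    fit <- mcrbm_train(mx$x, train_config(epochs = 6, seed = 1,
                                          restarts = 2))
    keys <- encode_dataset(mx$x, fit)
    top <- tapply(keys, mx$modes,
                  function(k) names(sort(table(k), decreasing = TRUE))[1])
    expect_equal(length(unique(top)), K)
    covered <- mean(keys == as.integer(top[mx$modes]))
    expect_gte(covered, 0.95)
  }
})

test_that("encoding is deterministic with ties binarised to one", {
  p <- random_params(seed = 8)
  x <- matrix(rnorm(20), 4, 5)
  x <- x[c(1, 2, 1, 3), ]            # duplicated row
  k <- encode_dataset(x, p)
  expect_identical(k[1], k[3])
  # a probability of exactly 0.5 (zero weights, zero bias) maps to 1
  p0 <- p
  p0$C[] <- 0; p0$d[] <- 0; p0$W[] <- 0; p0$c[] <- 0
  k0 <- encode_dataset(matrix(rnorm(5), 1), p0)
  expect_equal(k0, config_to_key(rep(1, 3), rep(1, 3)))
})

test_that("latent keys pack and unpack bijectively", {
  set.seed(16)
  for (r in 1:50) {
    hc <- rbinom(11, 1, 0.5)
    hm <- rbinom(10, 1, 0.5)
    k <- config_to_key(hc, hm)
    cf <- key_to_config(k, 11, 10)
    expect_identical(cf$h_c, as.integer(hc))
    expect_identical(cf$h_m, as.integer(hm))
  }
})

test_that("model checkpoints survive a JSON round trip", {
  mx <- make_mixture(K = 2, n = 2000, seed = 17)
  fit <- mcrbm_train(mx$x, train_config(epochs = 1, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_mcrbm(fit, path)
  back <- read_mcrbm(path)
  expect_equal(back$params$C, fit$params$C)
  expect_equal(back$params$P, fit$params$P)
  expect_equal(back$params$c, fit$params$c)
  expect_equal(encode_dataset(mx$x, back), encode_dataset(mx$x, fit))
})

test_that("diverging training reports the epoch", {
  mx <- make_mixture(K = 2, n = 2000, seed = 18)
  expect_error(
    mcrbm_train(mx$x, train_config(epochs = 3, seed = 1,
                                   learning_rate = 1e160)),
    "diverged")
})
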
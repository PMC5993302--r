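# fixtures built in code; no data files

make_recording <- function(seconds = 40, fs = 500, start_zt = 0,
                           subject_id = "s1", seed = 1) {
  set.seed(seed)
  n <- round(seconds * fs)
  t <- (0:(n - 1)) / fs
  eeg <- sin(2 * pi * 3 * t) + 0.5 * sin(2 * pi * 7 * t) + rnorm(n, 0, 0.3)
  emg <- abs(rnorm(n, 0, 2)) + 0.1
  raw_recording(eeg, emg, fs, start_zt = start_zt, subject_id = subject_id)
}

make_epoch_table <- function(n = 20, subject_id = "s1", seed = 1,
                             start_zt = 0) {
  set.seed(seed)
  df <- data.frame(
    subject_id = subject_id, epoch_index = 0:(n - 1),
    zt = (start_zt + (0:(n - 1)) * 4 / 3600) %% 24,
    delta = exp(rnorm(n)), theta = exp(rnorm(n)), alpha = exp(rnorm(n)),
    beta = exp(rnorm(n)), gamma = exp(rnorm(n)),
    emg_integral = exp(rnorm(n)), artifact = FALSE,
    stage = sample(c("W", "NR", "R"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  class(df) <- c("epoch_features", "data.frame")
  df
}

# small separable Gaussian-mixture feature matrix with known modes
make_mixture <- function(K = 3, n = 6000, D = 11, sep = 5, sd = 0.25,
                         seed = 1) {
  set.seed(seed)
  repeat {
    mu <- matrix(rnorm(K * D, sd = sep * sd), K, D)
    if (K < 2 || min(dist(mu)) >= sep * sd) break
  }
  modes <- sample.int(K, n, replace = TRUE)
  x <- mu[modes, , drop = FALSE] + matrix(rnorm(n * D, 0, sd), n, D)
  x <- scale(x, scale = FALSE)
  attr(x, "scaled:center") <- NULL
  list(x = x, modes = modes, mu = mu)
}

random_params <- function(D = 5, F = 4, Mc = 3, Mm = 3, seed = 1) {
  set.seed(seed)
  structure(list(
    C = matrix(rnorm(D * F), D, F),
    P = -matrix(abs(rnorm(F * Mc)), F, Mc),
    d = rnorm(Mc),
    W = matrix(rnorm(D * Mm), D, Mm),
    c = rnorm(Mm),
    b = rnorm(D)), class = "mcrbm_params")
}

subject_groups <- function(truth) {
  u <- unique(truth[, c("subject_id", "group")])
  stats::setNames(u$group, u$subject_id)
}
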
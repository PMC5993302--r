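#' Initialise mean-covariance RBM parameters
#'
#' The model has `D` visible units (the 11 log band-ratio / log-EMG
#' features), `n_factors` covariance factors, `n_cov` binary covariance
#' hidden units and `n_mean` binary mean hidden units. `C` (D x F) maps
#' visibles to factors, `P` (F x Mc, constrained nonpositive) maps factors to
#' covariance units, `W` (D x Mm) connects visibles to mean units; `d`, `c`
#' and `b` are the covariance-hidden, mean-hidden and visible biases.
#' `C` and `W` start at small seeded Gaussian values, `P` at a negative
#' identity pattern; the covariance and visible biases start at zero and
#' the mean-hidden bias at `mean_bias` (slightly negative, so mean units
#' start selective rather than at the symmetric saddle point of zero-mean
#' inputs).
#'
#' @param D number of visible units
#' @param n_factors number of covariance factors (F)
#' @param n_cov number of hidden covariance units (Mc)
#' @param n_mean number of hidden mean units (Mm)
#' @param seed RNG seed for the weight initialisation
#' @param init_sd standard deviation of the Gaussian weight initialisation
#' @param mean_bias initial mean-hidden bias (scalar or length `n_mean`)
#' @return an object of class `mcrbm_params`
#' @export
mcrbm_params <- function(D = 11, n_factors = 11, n_cov = 11, n_mean = 10,
                         seed = 1, init_sd = 0.02, mean_bias = -2) {
  set.seed(seed)
  C <- matrix(rnorm(D * n_factors, 0, init_sd), D, n_factors)
  W <- matrix(rnorm(D * n_mean, 0, init_sd), D, n_mean)
  P <- matrix(0, n_factors, n_cov)
  for (f in seq_len(n_factors)) P[f, (f - 1) %% n_cov + 1] <- -1
  structure(list(C = C, P = P, d = numeric(n_cov), W = W,
                 c = rep(mean_bias, length.out = n_mean), b = numeric(D)),
            class = "mcrbm_params")
}

check_params <- function(params) {
  stopifnot(inherits(params, "mcrbm_params") || is.list(params))
  with(params, {
    stopifnot(nrow(P) == ncol(C), length(d) == ncol(P),
              nrow(W) == nrow(C), length(c) == ncol(W),
              length(b) == nrow(C))
  })
  if (any(params$P > 0)) stop("P must have nonpositive entries")
  invisible(params)
}

dims_of <- function(params)
  list(D = nrow(params$C), F = ncol(params$C), Mc = ncol(params$P),
       Mm = ncol(params$W))

#' Covariance-unit energy
#'
#' Energy of the covariance group for a visible vector and a binary
#' covariance-hidden configuration, using the normalised visible vector
#' `v / (||v||/sqrt(D) + 1e-8)`:
#' `E_c = -d'h_c - ((v_hat' C)^2) P h_c` (elementwise square).
#'
#' @param v visible vector (length D)
#' @param h_c binary covariance-hidden vector (length Mc)
#' @param params [mcrbm_params()]
#' @return scalar energy
#' @export
energy_cov <- function(v, h_c, params) {
  check_params(params)
  dm <- dims_of(params)
  if (length(v) != dm$D || length(h_c) != dm$Mc)
    stop("shape mismatch in energy_cov")
  vh <- v / (sqrt(sum(v^2) / dm$D) + 1e-8)
  u <- drop(crossprod(params$C, vh))
  -sum(params$d * h_c) - sum(u^2 * drop(params$P %*% h_c))
}

#' Mean-unit energy
#'
#' `E_m = -1/2 (v-b)'(v-b) c'h_m - v' W h_m`.
#'
#' @param v visible vector
#' @param h_m binary mean-hidden vector (length Mm)
#' @param params [mcrbm_params()]
#' @return scalar energy
#' @export
energy_mean <- function(v, h_m, params) {
  check_params(params)
  dm <- dims_of(params)
  if (length(v) != dm$D || length(h_m) != dm$Mm)
    stop("shape mismatch in energy_mean")
  r <- v - params$b
  -0.5 * sum(r^2) * sum(params$c * h_m) - sum(v * drop(params$W %*% h_m))
}

#' Total mcRBM energy
#'
#' Sum of the covariance and mean group energies.
#'
#' @inheritParams energy_cov
#' @inheritParams energy_mean
#' @return scalar energy
#' @export
energy_total <- function(v, h_c, h_m, params)
  energy_cov(v, h_c, params) + energy_mean(v, h_m, params)

#' Covariance-unit activation probabilities
#'
#' `p(h_c | v) = sigma(d + ((v_hat' C)^2 P)')` componentwise, with the same
#' visible normalisation as [energy_cov()]. Accepts a single vector or a
#' matrix with one visible vector per row.
#'
#' @param v visible vector, or n x D matrix
#' @param params [mcrbm_params()]
#' @return probabilities in (0,1); a vector, or an n x Mc matrix
#' @export
infer_hidden_cov <- function(v, params) {
  check_params(params)
  one <- is.null(dim(v))
  V <- if (one) matrix(v, nrow = 1) else as.matrix(v)
  if (ncol(V) != nrow(params$C)) stop("shape mismatch in infer_hidden_cov")
  U <- normalize_rows(V) %*% params$C
  p <- sigmoid(sweep((U * U) %*% params$P, 2, params$d, "+"))
  if (one) drop(p) else p
}

#' Mean-unit activation probabilities
#'
#' `p(h_m | v) = sigma(c + W'v)` componentwise.
#'
#' @inheritParams infer_hidden_cov
#' @return probabilities in (0,1); a vector, or an n x Mm matrix
#' @export
infer_hidden_mean <- function(v, params) {
  check_params(params)
  one <- is.null(dim(v))
  V <- if (one) matrix(v, nrow = 1) else as.matrix(v)
  if (ncol(V) != nrow(params$W)) stop("shape mismatch in infer_hidden_mean")
  p <- sigmoid(sweep(V %*% params$W, 2, params$c, "+"))
  if (one) drop(p) else p
}

#' Gaussian visible conditional of a latent configuration
#'
#' Given binary hidden states, the visible conditional is (approximately)
#' Gaussian with precision `C diag(-P'h_c) C'` and mean `Sigma W h_m`. The
#' precision is inverted via Cholesky; if the factorisation fails (e.g. rank
#' deficiency from few active covariance units) a relative ridge
#' `1e-6 * trace/D` is added and the inversion retried, so well-posed states
#' are returned exactly. A state whose precision is singular even after the
#' ridge (notably the all-zero `h_c` state) errors with "degenerate-state".
#'
#' @param h_c binary covariance-hidden vector
#' @param h_m binary mean-hidden vector
#' @param params [mcrbm_params()]
#' @return list with `mean` (length D) and `sigma` (D x D symmetric positive
#'   definite covariance)
#' @export
conditional_gaussian <- function(h_c, h_m, params) {
  check_params(params)
  dm <- dims_of(params)
  if (length(h_c) != dm$Mc || length(h_m) != dm$Mm)
    stop("shape mismatch in conditional_gaussian")
  s <- drop(-params$P %*% h_c)          # F-vector, nonnegative
  prec <- params$C %*% (s * t(params$C))
  R <- tryCatch(chol(prec), error = function(e) NULL)
  if (is.null(R)) {
    eps <- 1e-6 * (sum(diag(prec)) / dm$D)
    if (eps <= 0) stop("degenerate-state: singular precision")
    R <- tryCatch(chol(prec + diag(eps, dm$D)), error = function(e) NULL)
    if (is.null(R)) stop("degenerate-state: singular precision")
  }
  sigma <- chol2inv(R)
  sigma <- (sigma + t(sigma)) / 2
  list(mean = drop(sigma %*% (params$W %*% h_m)), sigma = sigma)
}

#' Draw a visible vector for a latent configuration
#'
#' Samples from the Gaussian conditional of [conditional_gaussian()];
#' reproducible for a fixed seed.
#'
#' @inheritParams conditional_gaussian
#' @param n number of draws
#' @param seed optional RNG seed
#' @return an n x D matrix of draws (a vector if `n = 1`)
#' @export
sample_visible <- function(h_c, h_m, params, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- conditional_gaussian(h_c, h_m, params)
  R <- chol(g$sigma)
  z <- matrix(rnorm(n * length(g$mean)), n)
  out <- sweep(z %*% R, 2, g$mean, "+")
  if (n == 1) drop(out) else out
}

#' Training configuration
#'
#' @param minibatch_size data points per stochastic-gradient minibatch
#' @param learning_rate gradient step size
#' @param epochs full passes over the data
#' @param seed RNG seed covering initialisation, minibatch order and all
#'   sampling
#' @param sampler `"gibbs-cd"` (CD-1 with Gaussian visible resampling;
#'   default, CPU-deterministic) or `"hmc-pcd"` (persistent chains updated
#'   by leapfrog HMC on the free energy)
#' @param n_factors,n_cov,n_mean model sizes (see [mcrbm_params()])
#' @param normalize_C renormalise columns of `C` to unit norm after each
#'   update (standard practice for the normalised covariance energy)
#' @param init_sd,mean_bias initialisation; see [mcrbm_params()]
#' @param sparsity_target,sparsity_lambda optional sparsity regulariser on
#'   the mean-hidden biases (off by default)
#' @param lr_decay multiplicative learning-rate decay per epoch
#' @param learn_P update `P` during training; by default `P` keeps its
#'   fixed negative-identity topology, which preserves the factor-to-unit
#'   specialisation of the covariance code (a learned dense `P` makes the
#'   covariance-unit input constant under the normalised energy and the
#'   code uninformative)
#' @param init `"data"` (default) anchors mean-unit hyperplanes and factor
#'   directions on random epochs so every hidden unit starts responsive to
#'   populated regions; `"gaussian"` uses pure `init_sd` noise
#' @param restarts number of seeded training restarts; the fit with the
#'   lowest final reconstruction error is kept
#' @param polish after training, move each unit's binarisation crossing to
#'   the nearest low-density valley of its activation argument (stabilises
#'   the deterministic encoding; see [encode_dataset()])
#' @param hmc_steps,hmc_eps leapfrog steps and step size for `"hmc-pcd"`
#' @return a `train_config` list
#' @export
train_config <- function(minibatch_size = 256, learning_rate = 1e-2,
                         epochs = 10, seed = 1, sampler = "gibbs-cd",
                         n_factors = 11, n_cov = 11, n_mean = 10,
                         normalize_C = TRUE, init_sd = 0.02,
                         mean_bias = -2, sparsity_target = 0.1,
                         sparsity_lambda = 0, lr_decay = 1,
                         learn_P = FALSE, init = "data", restarts = 1,
                         polish = TRUE, hmc_steps = 20, hmc_eps = 0.05) {
  init <- match.arg(init, c("data", "gaussian"))
  stopifnot(minibatch_size >= 1, learning_rate > 0, epochs >= 0)
  sampler <- match.arg(sampler, c("gibbs-cd", "hmc-pcd"))
  structure(list(minibatch_size = as.integer(minibatch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), sampler = sampler,
                 n_factors = n_factors, n_cov = n_cov, n_mean = n_mean,
                 normalize_C = normalize_C, init_sd = init_sd,
                 mean_bias = mean_bias, sparsity_target = sparsity_target,
                 sparsity_lambda = sparsity_lambda, lr_decay = lr_decay,
                 learn_P = learn_P, init = init,
                 restarts = as.integer(restarts), polish = polish,
                 hmc_steps = hmc_steps,
                 hmc_eps = hmc_eps), class = "train_config")
}

# Move each hidden unit's binarisation crossing to the nearest low-density
# point of its activation argument. CD leaves some hyperplanes crossing a
# populated mode (the unit then flickers across the 0.5 threshold within
# that mode); shifting the bias to the closest valley of the 1-D projection
# density keeps every real separation while stabilising the encoding.
polish_thresholds <- function(params, x, span = 1, nbins = 41) {
  shift_to_valley <- function(bias, arg) {
    br <- seq(-span, span, length.out = nbins + 1)
    inw <- arg >= -span & arg <= span
    if (!any(inw)) return(bias)
    cnt <- tabulate(findInterval(arg[inw], br, rightmost.closed = TRUE),
                    nbins)
    mid <- (br[-1] + br[-length(br)]) / 2
    # prefer the shallowest valley closest to the current crossing
    best <- which(cnt == min(cnt))
    m <- mid[best[which.min(abs(mid[best]))]]
    bias - m
  }
  Vh <- normalize_rows(x)
  Ac <- sweep(((Vh %*% params$C)^2) %*% params$P, 2, params$d, "+")
  for (j in seq_along(params$d))
    params$d[j] <- shift_to_valley(params$d[j], Ac[, j])
  Am <- sweep(x %*% params$W, 2, params$c, "+")
  for (j in seq_along(params$c))
    params$c[j] <- shift_to_valley(params$c[j], Am[, j])
  params
}

as_feature_rows <- function(X) {
  if (inherits(X, "feature_matrix")) X$x else as.matrix(X)
}

# mean-field reconstruction error: one inference pass (probabilities), then
# the deterministic conditional mean of the visibles
recon_error <- function(x, params) {
  phc <- infer_hidden_cov(x, params)
  phm <- infer_hidden_mean(x, params)
  vrec <- cpp_sample_visible(phc, phm, params$C, params$P, params$W,
                             matrix(0, nrow(x), ncol(x)), 1e-6, TRUE)
  mean((x - vrec)^2)
}

free_energy_grad <- function(V, params) {
  # d/dv of -log p*(v): quadratic anchor + softplus terms of both groups
  D <- ncol(V)
  Vh <- normalize_rows(V)
  U <- Vh %*% params$C
  Phc <- sigmoid(sweep((U * U) %*% params$P, 2, params$d, "+"))
  Phm <- sigmoid(sweep(V %*% params$W, 2, params$c, "+"))
  # treat the normalisation as a fixed preprocessing when differentiating
  Gc <- -2 * (U * (Phc %*% t(params$P))) %*% t(params$C)
  sweep(V, 2, params$b) - Phm %*% t(params$W) + Gc
}

#' Train an mcRBM by stochastic gradient contrastive divergence
#'
#' Fits the model to the rows of a feature matrix using minibatch CD. With
#' the default `"gibbs-cd"` sampler each update performs one alternating
#' Gibbs step: hidden units are sampled from their conditionals, visibles
#' are resampled from the per-sample Gaussian conditional (with unit
#' precision added as the proper-density anchor), and gradients contrast
#' data and reconstruction statistics computed from activation
#' probabilities. `P` is projected onto the nonpositive orthant after every
#' update and columns of `C` are renormalised to unit norm. The `"hmc-pcd"`
#' sampler instead maintains persistent fantasy particles updated by
#' leapfrog dynamics on the free energy. The visible bias `b` is held at
#' zero (inputs are per-subject mean-centred). Fully seeded and
#' CPU-deterministic under `"gibbs-cd"`.
#'
#' @param X a `feature_matrix` from [build_feature_matrix()] or a plain
#'   numeric matrix (rows = epochs)
#' @param config a [train_config()]
#' @return an object of class `mcrbm`: list with `params`
#'   ([mcrbm_params()]), `recon` (per-epoch mean-field reconstruction MSE)
#'   and `config`
#' @export
mcrbm_train <- function(X, config = train_config()) {
  restarts <- config$restarts %||% 1L
  if (restarts > 1) {
    # seeded restarts; keep the fit with the lowest final reconstruction
    # error (an unsupervised criterion: runs whose latent codes merge
    # distinct modes reconstruct them to a common midpoint and score worse)
    fits <- lapply(seq_len(restarts) - 1L, function(k) {
      cfg_k <- config
      cfg_k$seed <- config$seed + k
      cfg_k$restarts <- 1L
      mcrbm_train(X, cfg_k)
    })
    err <- vapply(fits, function(f) tail(f$recon, 1), 0)
    best <- fits[[which.min(err)]]
    best$restart_errors <- err
    return(best)
  }
  x <- as_feature_rows(X)
  storage.mode(x) <- "double"
  n <- nrow(x)
  D <- ncol(x)
  cfg <- config
  if (n < cfg$minibatch_size)
    stop("need at least one full minibatch (", cfg$minibatch_size, " rows)")
  params <- mcrbm_params(D = D, n_factors = cfg$n_factors,
                         n_cov = cfg$n_cov, n_mean = cfg$n_mean,
                         seed = cfg$seed, init_sd = cfg$init_sd %||% 0.02,
                         mean_bias = cfg$mean_bias %||% -2)
  if (cfg$epochs == 0)
    return(structure(list(params = params, recon = numeric(0),
                          config = cfg), class = "mcrbm"))
  set.seed(cfg$seed)
  if ((cfg$init %||% "gaussian") == "data") {
    # anchor mean-unit hyperplanes halfway between the origin and random
    # epochs, and covariance factors on random data directions, so every
    # hidden unit starts responsive to some populated region
    idx <- sample.int(n, cfg$n_mean, replace = cfg$n_mean > n)
    params$W <- t(x[idx, , drop = FALSE]) / 2
    params$c <- -colSums(params$W^2) / 2 + params$c
    fdx <- sample.int(n, cfg$n_factors, replace = cfg$n_factors > n)
    Cd <- t(normalize_rows(x[fdx, , drop = FALSE]))
    params$C <- Cd / rep(sqrt(colSums(Cd^2)), each = D)
  }
  lr <- cfg$learning_rate
  bs <- cfg$minibatch_size
  nb <- floor(n / bs)
  Mc <- cfg$n_cov; Mm <- cfg$n_mean
  recon_rows <- if (n > 8192) sample.int(n, 8192) else seq_len(n)
  recon <- numeric(cfg$epochs)
  fantasy <- NULL
  if (cfg$sampler == "hmc-pcd")
    fantasy <- x[sample.int(n, bs), , drop = FALSE]

  for (ep in seq_len(cfg$epochs)) {
    lr <- cfg$learning_rate * (cfg$lr_decay %||% 1)^(ep - 1)
    ord <- sample.int(n)
    for (bidx in seq_len(nb)) {
      rows <- ord[((bidx - 1) * bs + 1):(bidx * bs)]
      V <- x[rows, , drop = FALSE]
      Vh <- normalize_rows(V)
      U <- Vh %*% params$C
      Phc <- sigmoid(sweep((U * U) %*% params$P, 2, params$d, "+"))
      Phm <- sigmoid(sweep(V %*% params$W, 2, params$c, "+"))

      if (cfg$sampler == "gibbs-cd") {
        Hc <- (matrix(runif(bs * Mc), bs) < Phc) + 0
        Hm <- (matrix(runif(bs * Mm), bs) < Phm) + 0
        Z <- matrix(rnorm(bs * D), bs)
        Vn <- tryCatch(
          cpp_sample_visible(Hc, Hm, params$C, params$P, params$W, Z,
                             1e-6, TRUE),
          error = function(e) stop("diverged at epoch ", ep, call. = FALSE))
      } else {
        for (ls in seq_len(cfg$hmc_steps)) {
          if (ls == 1) mom <- matrix(rnorm(bs * D), bs)
          mom <- mom - 0.5 * cfg$hmc_eps * free_energy_grad(fantasy, params)
          fantasy <- fantasy + cfg$hmc_eps * mom
          mom <- mom - 0.5 * cfg$hmc_eps * free_energy_grad(fantasy, params)
        }
        Vn <- fantasy
      }
      Vnh <- normalize_rows(Vn)
      Un <- Vnh %*% params$C
      Pnc <- sigmoid(sweep((Un * Un) %*% params$P, 2, params$d, "+"))
      Pnm <- sigmoid(sweep(Vn %*% params$W, 2, params$c, "+"))

      Hp <- Phc %*% t(params$P)
      Hpn <- Pnc %*% t(params$P)
      dC <- 2 * (crossprod(Vh, U * Hp) - crossprod(Vnh, Un * Hpn)) / bs
      dP <- (crossprod(U * U, Phc) - crossprod(Un * Un, Pnc)) / bs
      dd <- colMeans(Phc) - colMeans(Pnc)
      dW <- (crossprod(V, Phm) - crossprod(Vn, Pnm)) / bs
      dc <- colMeans(Phm) - colMeans(Pnm)

      params$C <- params$C + lr * dC
      if (isTRUE(cfg$learn_P))
        params$P <- pmin(params$P + lr * dP, 0)
      params$d <- params$d + lr * dd
      params$W <- params$W + lr * dW
      params$c <- params$c + lr * dc +
        lr * cfg$sparsity_lambda * (cfg$sparsity_target - colMeans(Phm))
      if (cfg$normalize_C) {
        nrm <- sqrt(colSums(params$C^2))
        nrm[nrm < 1e-12] <- 1
        params$C <- sweep(params$C, 2, nrm, "/")
      }
    }
    if (any(!is.finite(unlist(params[c("C", "P", "d", "W", "c")]))))
      stop("diverged at epoch ", ep)
    recon[ep] <- recon_error(x[recon_rows, , drop = FALSE], params)
  }
  if (isTRUE(cfg$polish))
    params <- polish_thresholds(params, x[recon_rows, , drop = FALSE])
  structure(list(params = params, recon = recon, config = cfg),
            class = "mcrbm")
}

#' @export
print.mcrbm <- function(x, ...) {
  dm <- dims_of(x$params)
  cat(sprintf(
    "<mcrbm> D=%d, F=%d, Mc=%d, Mm=%d; %d training epoch(s), final recon MSE %.4g\n",
    dm$D, dm$F, dm$Mc, dm$Mm, length(x$recon),
    if (length(x$recon)) x$recon[length(x$recon)] else NA))
  invisible(x)
}

#' Encode a dataset into binary latent configurations
#'
#' Computes activation probabilities of both hidden groups for every epoch
#' and binarises them at `threshold` (probability exactly at the threshold
#' is set to 1). Encoding is deterministic, so identical feature rows always
#' yield identical configurations.
#'
#' @param X a `feature_matrix` or plain matrix of visible rows
#' @param model an `mcrbm` fit or an `mcrbm_params` object
#' @param threshold binarisation threshold in (0,1)
#' @return if `X` is a `feature_matrix`, a `latent_codes` data frame with
#'   columns `subject_id`, `epoch_index`, `zt`, `stage`, `key`; otherwise an
#'   integer vector of keys. The key packs the `(h_c, h_m)` bits via
#'   [config_to_key()].
#' @export
encode_dataset <- function(X, model, threshold = 0.5) {
  params <- if (inherits(model, "mcrbm")) model$params else model
  check_params(params)
  x <- as_feature_rows(X)
  dm <- dims_of(params)
  bc <- (infer_hidden_cov(x, params) >= threshold) + 0L
  bm <- (infer_hidden_mean(x, params) >= threshold) + 0L
  bits <- cbind(bc, bm)
  nb <- ncol(bits)
  keys <- as.integer(bits %*% 2^((nb - 1):0))
  if (inherits(X, "feature_matrix")) {
    out <- cbind(X$index_map, key = keys)
    attr(out, "n_cov") <- dm$Mc
    attr(out, "n_mean") <- dm$Mm
    class(out) <- c("latent_codes", "data.frame")
    out
  } else keys
}

#' Save / load an mcRBM checkpoint as JSON
#'
#' @param model an `mcrbm` fit or `mcrbm_params`
#' @param path path to a JSON file
#' @return `read_mcrbm` returns an `mcrbm` object
#' @export
write_mcrbm <- function(model, path) {
  params <- if (inherits(model, "mcrbm")) model$params else model
  obj <- list(params = lapply(unclass(params), identity),
              recon = if (inherits(model, "mcrbm")) model$recon else NULL,
              config = if (inherits(model, "mcrbm"))
                unclass(model$config) else NULL)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_mcrbm
#' @export
read_mcrbm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$params
  for (nm in c("C", "P", "W")) p[[nm]] <- as.matrix(p[[nm]])
  for (nm in c("d", "c", "b")) p[[nm]] <- as.numeric(p[[nm]])
  params <- structure(p[c("C", "P", "d", "W", "c", "b")],
                      class = "mcrbm_params")
  check_params(params)
  structure(list(params = params, recon = as.numeric(obj$recon %||% numeric(0)),
                 config = obj$config), class = "mcrbm")
}
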
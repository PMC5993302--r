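#' Synthetic cohort configuration
#'
#' Defines a multi-subject, multi-group cohort of epoch-feature series with
#' known ground truth: `K` substage modes (Gaussian emissions in the 5-D
#' log space of Delta/Alpha/Beta/Gamma band power relative to Theta plus the
#' log EMG integral), Markov dynamics built from a macro-stage chain whose
#' stationary distribution equals `stage_mix`, per-substage circadian
#' modulation of the transition columns, per-group occupancy multipliers and
#' phase shifts, and an optional 6-h sleep-deprivation / rebound scenario.
#'
#' The substage chain takes one of two moves per 4-s epoch: with
#' probability `rho` it stays in the current substage; otherwise it draws a
#' macro stage from `S = (1 - macro_move) I + macro_move (1 pi')` (so `pi =
#' stage_mix` is the exact macro stationary distribution) and then a
#' substage within that stage from the group's within-stage weights. The
#' substage stationary distribution is therefore
#' `stage_mix[stage] * cond(k | stage)` in closed form.
#'
#' @param K number of substages
#' @param means K x 5 matrix of emission means (log Delta, log Alpha,
#'   log Beta, log Gamma power with Theta = 1 as ratio reference, log EMG)
#' @param sds K x 5 matrix of emission standard deviations
#' @param macro character vector of length K assigning substages to
#'   `W`/`NR`/`R`
#' @param within_weights base within-stage substage weights (length K)
#' @param stage_mix target stationary macro-stage proportions (W, NR, R)
#' @param rho substage persistence probability per epoch
#' @param macro_move mixing weight of the macro chain
#' @param modulation data frame with per-substage `amplitude` (in `[0,1)`)
#'   and `phase` (peak ZT) of the sinusoidal occupancy multiplier
#'   `1 + a cos(2 pi (t - phase)/24)` applied to transition columns
#' @param groups named list; each entry a list with `multiplier` (length-K
#'   occupancy multipliers; planting group-specific substages), `phase_shift`
#'   (hours added to every modulation phase) and `rebound_scale`
#' @param subjects_per_group,hours cohort size (hours per subject)
#' @param epoch_s epoch duration (s)
#' @param start_zt recording start (ZT hours)
#' @param deprivation `NULL`, or a list with `day` (0-based recording day of
#'   the deprivation), `duration_h`, and `rebound` (list with length-K
#'   `amplitude`, `peak` ZT and `width` hours of the Gaussian rebound bump
#'   multiplying sleep-substage columns during recovery)
#' @param seed default RNG seed for [generate_cohort()]
#' @return a `synthetic_config`
#' @export
synthetic_config <- function(K, means, sds, macro, within_weights,
                             stage_mix = c(W = 0.563, NR = 0.3809,
                                           R = 0.0561),
                             rho = 0.8, macro_move = 0.4,
                             modulation = NULL, groups = list(
                               g1 = list(multiplier = rep(1, K))),
                             subjects_per_group = 5, hours = 24,
                             epoch_s = 4, start_zt = 0, deprivation = NULL,
                             seed = 1) {
  means <- as.matrix(means)
  sds <- as.matrix(sds)
  stopifnot(nrow(means) == K, ncol(means) == 5, all(dim(sds) == dim(means)),
            length(macro) == K, all(macro %in% stage_levels),
            length(within_weights) == K, all(within_weights > 0),
            rho >= 0, rho < 1, macro_move > 0, macro_move <= 1)
  stage_mix <- stage_mix / sum(stage_mix)
  if (is.null(modulation))
    modulation <- data.frame(amplitude = rep(0, K), phase = rep(0, K))
  stopifnot(nrow(modulation) == K,
            all(modulation$amplitude >= 0), all(modulation$amplitude < 1))
  for (g in groups)
    stopifnot(length(g$multiplier) == K, all(g$multiplier >= 0))
  structure(list(K = K, means = means, sds = sds, macro = macro,
                 within_weights = within_weights, stage_mix = stage_mix,
                 rho = rho, macro_move = macro_move,
                 modulation = modulation, groups = groups,
                 subjects_per_group = subjects_per_group, hours = hours,
                 epoch_s = epoch_s, start_zt = start_zt,
                 deprivation = deprivation, seed = seed),
            class = "synthetic_config")
}

# within-stage substage conditional for one group
group_conditional <- function(cfg, g) {
  w <- cfg$within_weights * cfg$groups[[g]]$multiplier
  cond <- numeric(cfg$K)
  for (s in stage_levels) {
    i <- cfg$macro == s
    if (any(i)) cond[i] <- w[i] / sum(w[i])
  }
  cond
}

#' Stationary substage distribution of a group's base chain
#'
#' Closed-form stationary distribution (modulation off):
#' `stage_mix[stage_k] * cond(k | stage_k)`.
#'
#' @param cfg a [synthetic_config()]
#' @param group group name
#' @return probability vector over the K substages
#' @export
synthetic_stationary <- function(cfg, group = names(cfg$groups)[1]) {
  cond <- group_conditional(cfg, group)
  unname(cfg$stage_mix[cfg$macro]) * cond
}

# base substage transition matrix for one group (no modulation)
base_transition <- function(cfg, g) {
  K <- cfg$K
  S <- (1 - cfg$macro_move) * diag(3) +
    cfg$macro_move * matrix(cfg$stage_mix, 3, 3, byrow = TRUE)
  dimnames(S) <- list(stage_levels, stage_levels)
  cond <- group_conditional(cfg, g)
  B <- matrix(0, K, K)
  for (i in seq_len(K)) B[i, ] <- S[cfg$macro[i], cfg$macro] * cond
  cfg$rho * diag(K) + (1 - cfg$rho) * B
}

mod_multiplier <- function(cfg, g, t) {
  ph <- cfg$modulation$phase + (cfg$groups[[g]]$phase_shift %||% 0)
  1 + cfg$modulation$amplitude * cos(2 * pi * (t - ph) / 24)
}

apply_column_mod <- function(Tb, m) {
  Tm <- sweep(Tb, 2, m, "*")
  rs <- rowSums(Tm)
  if (any(rs <= 0)) stop("invalid stochastic matrix after modulation")
  Tm / rs
}

#' Generate a synthetic cohort
#'
#' Samples every subject's substage sequence from the group's
#' time-inhomogeneous Markov chain (transition columns scaled by the
#' circadian modulation evaluated at the current hour, rows renormalised),
#' then draws the epoch features from the substage's emission Gaussian and
#' exponentiates them back to strictly positive band powers (Theta = 1) and
#' EMG integrals. During a deprivation window the columns of sleep-assigned
#' substages are zeroed (forcing wakefulness); during the same day's
#' recovery the sleep-substage columns are additionally scaled by the
#' configured rebound bump. Fully seeded and reproducible.
#'
#' @param cfg a [synthetic_config()]
#' @param seed RNG seed (defaults to `cfg$seed`)
#' @param emissions draw feature emissions (set `FALSE` when only the state
#'   sequences are needed; the feature tables are then omitted)
#' @return a `synthetic_cohort`: list with `tables` (per-subject
#'   `epoch_features`), `truth` (data frame: `subject_id`, `group`,
#'   `epoch_index`, `zt`, `day`, `key` = true substage index, `stage`),
#'   `config`
#' @export
generate_cohort <- function(cfg, seed = NULL, emissions = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed %||% cfg$seed)
  K <- cfg$K
  n_ep <- as.integer(round(cfg$hours * 3600 / cfg$epoch_s))
  per_h <- as.integer(round(3600 / cfg$epoch_s))
  elapsed_h <- (0:(n_ep - 1)) * cfg$epoch_s / 3600
  zt <- (cfg$start_zt + elapsed_h) %% 24
  day <- floor((cfg$start_zt + elapsed_h) / 24)
  hour <- floor(zt)

  dep <- cfg$deprivation
  sleep_cols <- cfg$macro != "W"
  tables <- list()
  truth <- list()
  for (g in names(cfg$groups)) {
    Tb <- base_transition(cfg, g)
    slices <- array(0, c(K, K, 48))
    for (h in 0:23) {
      m <- mod_multiplier(cfg, g, h + 0.5)
      slices[, , h + 1] <- apply_column_mod(Tb, m)
      # recovery-day variant: deprivation window, then rebound bump
      m2 <- m
      if (!is.null(dep)) {
        if (h + 0.5 < dep$duration_h) {
          m2[sleep_cols] <- 0
        } else {
          rb <- dep$rebound
          sc <- cfg$groups[[g]]$rebound_scale %||% 1
          bump <- 1 + sc * rb$amplitude *
            exp(-((h + 0.5) - rb$peak)^2 / (2 * rb$width^2))
          m2[sleep_cols] <- m2[sleep_cols] * bump[sleep_cols]
        }
      }
      slices[, , 24 + h + 1] <- apply_column_mod(Tb, m2)
    }
    cum <- slices
    for (s in seq_len(dim(cum)[3]))
      cum[, , s] <- t(apply(slices[, , s], 1, cumsum))
    idx <- hour + 1L
    if (!is.null(dep)) idx[day == dep$day] <- idx[day == dep$day] + 24L
    statn <- synthetic_stationary(cfg, g)
    for (sj in seq_len(cfg$subjects_per_group)) {
      sid <- sprintf("%s_s%02d", g, sj)
      init <- sample.int(K, 1, prob = statn)
      st <- cpp_markov_chain(cum, as.integer(idx), runif(n_ep), init)
      truth[[length(truth) + 1]] <- data.frame(
        subject_id = sid, group = g, epoch_index = 0:(n_ep - 1), zt = zt,
        day = day, key = st, stage = cfg$macro[st],
        stringsAsFactors = FALSE)
      if (emissions) {
        z <- matrix(rnorm(n_ep * 5), n_ep)
        x <- cfg$means[st, , drop = FALSE] + z * cfg$sds[st, , drop = FALSE]
        tables[[sid]] <- new_epoch_features(data.frame(
          subject_id = sid, epoch_index = 0:(n_ep - 1), zt = zt,
          delta = exp(x[, 1]), theta = 1, alpha = exp(x[, 2]),
          beta = exp(x[, 3]), gamma = exp(x[, 4]),
          emg_integral = exp(x[, 5]), artifact = FALSE,
          stage = cfg$macro[st], stringsAsFactors = FALSE))
      }
    }
  }
  truth <- do.call(rbind, truth)
  structure(list(tables = if (emissions) tables else NULL, truth = truth,
                 config = cfg), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects x %d epochs, %d group(s), K=%d substages\n",
    length(unique(x$truth$subject_id)),
    sum(x$truth$subject_id == x$truth$subject_id[1]),
    length(x$config$groups), x$config$K))
  invisible(x)
}

#' Ground-truth tables of a synthetic cohort
#'
#' Per-epoch true substage (as `key`) and macro stage, aligned with the
#' cohort's feature tables and shaped like a `latent_codes` table so it can
#' be fed directly to the catalog, transition and profile functions.
#'
#' @param cohort a [generate_cohort()] result
#' @return data frame with `subject_id`, `group`, `epoch_index`, `zt`,
#'   `day`, `key`, `stage`
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort$truth
}

default_substages <- function() {
  list(
    names = c("W1", "W2", "W3", "W4", "NR1", "NR2", "NR3", "NR4", "R1"),
    macro = c("W", "W", "W", "W", "NR", "NR", "NR", "NR", "R"),
    means = matrix(c(
      -1.2,  0.2,  0.6,  1.0,  2.4,   # W1 shared active wake
       0.2,  1.4,  1.6, -0.2,  0.8,   # W2 quiet wake, theta-leaning
       0.8, -0.8,  1.2,  2.2,  2.0,   # W3 high-gamma exploratory wake
      -2.2,  1.8, -0.4,  0.6,  0.2,   # W4 alpha-rich drowsy wake
       1.8, -0.4, -1.0, -1.6, -1.8,   # NR1 shared deep NREM
       0.6,  0.8, -0.2, -0.8, -0.8,   # NR2 light NREM
       2.8, -1.4, -0.4, -2.4, -1.0,   # NR3 delta-dominant NREM
       1.2,  1.2, -1.8, -0.6, -2.4,   # NR4 spindle-like NREM
      -1.0, -0.6, -0.8, -0.4, -2.8),  # R1 theta-dominant REM, atonia
      ncol = 5, byrow = TRUE),
    sds = matrix(c(
      0.30, 0.25, 0.25, 0.30, 0.35,   # active wake: broad, variable EMG
      0.18, 0.15, 0.20, 0.15, 0.20,
      0.25, 0.20, 0.15, 0.25, 0.15,
      0.15, 0.22, 0.18, 0.15, 0.25,
      0.22, 0.15, 0.15, 0.15, 0.12,
      0.12, 0.18, 0.15, 0.12, 0.15,
      0.18, 0.12, 0.20, 0.18, 0.12,
      0.15, 0.15, 0.12, 0.20, 0.18,
      0.20, 0.18, 0.15, 0.15, 0.10),  # REM: tight muscle atonia
      ncol = 5, byrow = TRUE),
    within = c(0.55, 0.15, 0.15, 0.15, 0.55, 0.15, 0.15, 0.15, 1),
    modulation = data.frame(
      amplitude = c(0.25, 0.3, 0.3, 0.3, 0.25, 0.3, 0.3, 0.3, 0.3),
      phase = c(18, 15, 20, 22, 5, 3, 8, 6, 9))
  )
}

#' Scenario presets
#'
#' Seeded configurations mirroring the package's three validation designs:
#'
#' * `"three-groups"`: 3 groups x 5 subjects x 24 h, K = 9 substages
#'   (3 shared + 2 group-specific per group, planted via occupancy
#'   multipliers), suitable for parameter-recovery and discrimination
#'   checks.
#' * `"circadian-mutant"`: 2 groups x 7 subjects x 24 h sharing all
#'   substages, the mutant group's modulation phase advanced by 2 h.
#' * `"deprivation"`: 2 groups x 7 subjects x 72 h — two baseline days,
#'   sleep deprivation over ZT 0-6 of day 3, then recovery with
#'   per-substage rebound bumps (immediate / intermediate / late peaks;
#'   attenuated in the mutant group).
#'
#' @param name preset name
#' @param subjects_per_group,hours,seed optional overrides
#' @return a [synthetic_config()]
#' @export
scenario_presets <- function(name, subjects_per_group = NULL, hours = NULL,
                             seed = 1) {
  known <- c("three-groups", "circadian-mutant", "deprivation")
  if (!name %in% known)
    stop("unknown preset '", name, "'; available: ",
         paste(known, collapse = ", "))
  ss <- default_substages()
  spec_mult <- function(own) {
    m <- rep(1, 9)
    specifics <- list(c(2, 6), c(3, 7), c(4, 8))  # (W, NR) pairs per group
    for (i in 1:3) m[specifics[[i]]] <- if (i == own) 1 else 0.05
    m
  }
  if (name == "three-groups") {
    cfg <- synthetic_config(
      K = 9, means = ss$means, sds = ss$sds, macro = ss$macro,
      within_weights = ss$within, modulation = ss$modulation,
      groups = list(A = list(multiplier = spec_mult(1)),
                    B = list(multiplier = spec_mult(2)),
                    C = list(multiplier = spec_mult(3))),
      subjects_per_group = subjects_per_group %||% 5,
      hours = hours %||% 24, seed = seed)
  } else if (name == "circadian-mutant") {
    cfg <- synthetic_config(
      K = 9, means = ss$means, sds = ss$sds, macro = ss$macro,
      within_weights = ss$within, modulation = ss$modulation,
      groups = list(wt = list(multiplier = rep(1, 9), phase_shift = 0),
                    mut = list(multiplier = rep(1, 9), phase_shift = -2)),
      subjects_per_group = subjects_per_group %||% 7,
      hours = hours %||% 24, seed = seed)
  } else {
    rebound <- list(
      amplitude = c(0, 0, 0, 0, 1.5, 1.5, 1.5, 0.8, 1.2),
      peak = c(0, 0, 0, 0, 6.5, 9.5, 14.5, 9.5, 10.5),
      width = 0.8)
    cfg <- synthetic_config(
      K = 9, means = ss$means, sds = ss$sds, macro = ss$macro,
      within_weights = ss$within, modulation = ss$modulation,
      groups = list(wt = list(multiplier = rep(1, 9), rebound_scale = 1),
                    mut = list(multiplier = rep(1, 9), rebound_scale = 0.4)),
      subjects_per_group = subjects_per_group %||% 7,
      hours = hours %||% 72,
      deprivation = list(day = 2, duration_h = 6, rebound = rebound),
      seed = seed)
  }
  cfg
}
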
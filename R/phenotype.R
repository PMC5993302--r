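#' Per-subject occupancy distributions over latent states
#'
#' Represents each subject as a discrete probability distribution over the
#' catalog's states (normalised epoch counts); states a subject never
#' visits get probability 0.
#'
#' @param codes a `latent_codes` data frame (`subject_id`, `key`)
#' @param states fixed state set (defaults to all observed keys)
#' @param groups named vector or data frame (`subject_id`, `group`) mapping
#'   subjects to groups
#' @return an `occupancy` object: list with `P` (subjects x states
#'   probability matrix), `counts` (same shape, epoch counts) and `group`
#'   (per-subject factor, possibly NA)
#' @export
occupancy <- function(codes, states = NULL, groups = NULL) {
  stopifnot(is.data.frame(codes))
  if (nrow(codes) == 0) stop("no epochs")
  states <- states %||% sort(unique(codes$key))
  subj <- unique(codes$subject_id)
  counts <- table(factor(codes$subject_id, levels = subj),
                  factor(codes$key, levels = states))
  counts <- matrix(counts, nrow = length(subj),
                   dimnames = list(subj, states))
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("subject with zero epochs: ",
                          paste(subj[tot == 0], collapse = ", "))
  P <- counts / tot
  grp <- rep(NA_character_, length(subj))
  if (!is.null(groups)) {
    if (is.data.frame(groups))
      grp <- groups$group[match(subj, groups$subject_id)]
    else grp <- unname(groups[subj])
  }
  structure(list(P = P, counts = counts, group = factor(grp)),
            class = "occupancy")
}

pooled_t <- function(x1, x2, var_equal = TRUE) {
  n1 <- length(x1); n2 <- length(x2)
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    if (m1 == m2) return(list(t = 0, p = 1, df = df))
    warning("zero pooled variance with unequal means; reporting p = 0")
    return(list(t = sign(m1 - m2) * Inf, p = 0, df = df))
  }
  t <- (m1 - m2) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Two-sample comparison of a state's occupancy between groups
#'
#' Classical two-sample independent t test (pooled variance by default;
#' Welch via `var_equal = FALSE`) comparing per-subject epoch counts — or
#' per-subject proportions — in one latent state across two groups. Zero
#' pooled variance with equal means yields `t = 0, p = 1`; with unequal
#' means the degenerate complete-separation case is reported as a `p = 0`
#' sentinel with a warning.
#'
#' @param occ an [occupancy()] object with group labels
#' @param state_key the latent state to test
#' @param groups character vector of the two group names
#' @param measure `"count"` (default) or `"proportion"`
#' @param var_equal pooled-variance t (default) or Welch
#' @param alpha significance level for the `significant` flag
#' @return list with `t`, `p`, `df`, `significant`, and the group samples
#' @export
compare_groups <- function(occ, state_key, groups, measure = "count",
                           var_equal = TRUE, alpha = 0.05) {
  stopifnot(inherits(occ, "occupancy"), length(groups) == 2)
  measure <- match.arg(measure, c("count", "proportion"))
  M <- if (measure == "count") occ$counts else occ$P
  col <- match(as.character(state_key), colnames(M))
  if (is.na(col)) stop("unknown state key: ", state_key)
  x1 <- M[occ$group == groups[1], col]
  x2 <- M[occ$group == groups[2], col]
  if (length(x1) < 2 || length(x2) < 2)
    stop("need >= 2 subjects per group")
  r <- pooled_t(x1, x2, var_equal)
  list(state_key = state_key, groups = groups, t = r$t, p = r$p, df = r$df,
       significant = r$p < alpha, x1 = x1, x2 = x2)
}

#' Per-state group tests over a whole catalog
#'
#' Runs [compare_groups()] for every state and every pair of groups,
#' without multiple-testing correction by default (raw p < 0.05 flags);
#' Benjamini-Hochberg adjusted p values are added when requested.
#'
#' @inheritParams compare_groups
#' @param adjust `"none"` (default) or `"BH"`
#' @return data frame with `state_key`, `group1`, `group2`, `t`, `p`
#'   (optionally `p_adj`), `significant`
#' @export
substage_tests <- function(occ, measure = "count", var_equal = TRUE,
                           alpha = 0.05, adjust = "none") {
  adjust <- match.arg(adjust, c("none", "BH"))
  gl <- levels(droplevels(occ$group))
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  rows <- list()
  for (sk in colnames(occ$counts)) {
    for (pr in pairs) {
      r <- suppressWarnings(
        compare_groups(occ, sk, pr, measure, var_equal, alpha))
      rows[[length(rows) + 1]] <- data.frame(
        state_key = as.integer(sk), group1 = pr[1], group2 = pr[2],
        t = r$t, p = r$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, "BH")
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out
}

nn1_predict <- function(train, labels, test) {
  # deterministic 1-NN: Euclidean distance, first index wins ties
  apply(test, 1, function(z) {
    d <- colSums((t(train) - z)^2)
    labels[which.min(d)]
  })
}

lda_predict <- function(train, labels, test) {
  # project onto principal components first: occupancy vectors are high-
  # dimensional and collinear relative to the number of subjects, which
  # plain lda() rejects
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  keep <- which(pc$sdev > 1e-8)
  keep <- head(keep, max(1, nrow(train) - nlevels(factor(labels))))
  tr <- pc$x[, keep, drop = FALSE]
  te <- scale(test, center = pc$center, scale = FALSE) %*%
    pc$rotation[, keep, drop = FALSE]
  fit <- tryCatch(suppressWarnings(MASS::lda(tr, grouping = labels)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate within-group covariance: fall back to nearest centroid
    cen <- do.call(rbind, lapply(split(as.data.frame(tr), labels), colMeans))
    return(rownames(cen)[apply(te, 1, function(z)
      which.min(colSums((t(cen) - z)^2)))])
  }
  as.character(stats::predict(fit, te)$class)
}

svm_predict <- function(train, labels, test) {
  fit <- e1071::svm(train, factor(labels), kernel = "linear", scale = FALSE)
  as.character(stats::predict(fit, test))
}

#' Leave-one-subject-out group classification
#'
#' Classifies each subject's group from its latent-state occupancy
#' distribution with an ensemble of a linear SVM, an LDA (on a PCA
#' reduction) and a deterministic 1-nearest-neighbour classifier, combined
#' by majority vote; when all three disagree the SVM (the large-margin
#' linear member) decides. Training uses the other N-1 subjects, iterated
#' over all N.
#'
#' @param occ an [occupancy()] object with >= 2 groups of >= 2 subjects
#' @return a `loso_result`: list with `predictions` (data frame: `subject`,
#'   `group`, `svm`, `lda`, `nn`, `vote`), `accuracy`, `confusion`
#' @export
loso_classify <- function(occ) {
  stopifnot(inherits(occ, "occupancy"))
  grp <- as.character(occ$group)
  if (anyNA(grp)) stop("all subjects need a group label")
  sizes <- table(grp)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 2))
    stop("loso-undersized: group(s) with a single subject: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  X <- occ$P
  n <- nrow(X)
  preds <- data.frame(subject = rownames(X), group = grp,
                      svm = NA_character_, lda = NA_character_,
                      nn = NA_character_, vote = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    te <- X[i, , drop = FALSE]
    lab <- factor(grp[-i])
    p_svm <- svm_predict(tr, lab, te)
    p_lda <- lda_predict(tr, lab, te)
    p_nn <- nn1_predict(tr, as.character(lab), te)
    votes <- c(p_svm, p_lda, p_nn)
    tab <- sort(table(votes), decreasing = TRUE)
    vote <- if (tab[1] >= 2) names(tab)[1] else p_svm
    preds[i, c("svm", "lda", "nn", "vote")] <- c(p_svm, p_lda, p_nn, vote)
  }
  confusion <- table(true = preds$group, predicted = preds$vote)
  structure(list(predictions = preds,
                 accuracy = mean(preds$vote == preds$group),
                 confusion = confusion), class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> accuracy %.1f%% (%d/%d subjects)\n",
              100 * x$accuracy, sum(x$predictions$vote == x$predictions$group),
              nrow(x$predictions)))
  print(x$confusion)
  invisible(x)
}

#' Daily (circadian) occupancy profile of a latent state
#'
#' Histogram of the state's 4-s epochs in 1-hour zeitgeber-time bins
#' (half-open `[h, h+1)`, ZT 0 = lights on), with a least-squares
#' polynomial fit (degree 6 by default: the lowest even degree able to
#' express two peaks across 24 bins) describing the daily oscillation. The
#' peak is the argmax of the fitted curve evaluated on a 0.1-h grid over
#' the window; the raw histogram argmax is reported alongside.
#'
#' @param codes a `latent_codes` data frame carrying a `zt` column
#' @param state_key latent state to profile
#' @param subjects optional subject subset (e.g. one group)
#' @param window ZT window `[lo, hi)` in hours over which to fit
#' @param degree polynomial degree
#' @return a `daily_profile`: list with `bins` (24 hourly counts, ZT
#'   0-23), `fit` (fitted values per bin), `peak_zt`, `peak_zt_hist`,
#'   `state_key`, `window`
#' @export
daily_profile <- function(codes, state_key, subjects = NULL,
                          window = c(0, 24), degree = 6) {
  stopifnot(is.data.frame(codes), "zt" %in% names(codes))
  df <- codes
  if (!is.null(subjects)) df <- df[df$subject_id %in% subjects, ]
  zt <- df$zt[df$key == state_key]
  bins <- as.integer(table(factor(floor(zt), levels = 0:23)))
  names(bins) <- 0:23
  inw <- (0:23) >= window[1] & (0:23) < window[2]
  out <- list(state_key = state_key, bins = bins, window = window,
              fit = rep(NA_real_, 24), peak_zt = NA_real_,
              peak_zt_hist = NA_real_)
  if (sum(bins[inw]) == 0) {
    class(out) <- "daily_profile"
    return(out)
  }
  h <- (0:23)[inw] + 0.5
  y <- bins[inw]
  deg <- min(degree, length(h) - 1)
  fit <- stats::lm(y ~ stats::poly(h, deg))
  grid <- seq(window[1] + 0.05, window[2] - 0.05, by = 0.1)
  yy <- stats::predict(fit, newdata = data.frame(h = grid))
  out$fit[inw] <- stats::predict(fit)
  out$peak_zt <- grid[which.max(yy)]
  out$peak_zt_hist <- as.numeric(names(bins[inw])[which.max(y)])
  class(out) <- "daily_profile"
  out
}

#' @export
print.daily_profile <- function(x, ...) {
  cat(sprintf("<daily_profile> state %s: %d epochs, fitted peak ZT %.1f\n",
              as.character(x$state_key), sum(x$bins),
              x$peak_zt %||% NA))
  invisible(x)
}

#' Classify a profile peak within the light phase
#'
#' Splits the light phase (ZT 0-12) at ZT 6: fitted peaks before ZT 6 are
#' "first-half", peaks in ZT 6-12 "second-half". A peak outside the light
#' phase errors with "not-light-phase".
#'
#' @param profile a [daily_profile()]
#' @return `"first-half"` or `"second-half"`
#' @export
peak_half <- function(profile) {
  pk <- profile$peak_zt
  if (is.na(pk) || pk < 0 || pk >= 12)
    stop("not-light-phase: fitted peak at ZT ",
         if (is.na(pk)) "none" else sprintf("%.2f", pk))
  if (pk < 6) "first-half" else "second-half"
}

#' Sleep-deprivation rebound of a latent state
#'
#' Compares a recovery day (sleep deprivation occupying ZT 0-6) against the
#' subject-matched baseline day: for every ZT hour in `[6, 24)`,
#' `delta(h) = recovery epochs - baseline epochs` in the state. The peak
#' timing class follows the argmax of the differences: "immediate" at the
#' ZT-6 bin, "intermediate" within ZT 6-12, "late" beyond ZT 12, and
#' "none" when no difference is positive.
#'
#' @param baseline `latent_codes` (with `zt`) for the baseline day
#' @param recovery `latent_codes` for the recovery day
#' @param state_key latent state to analyse
#' @param subjects optional subject subset
#' @return a `rebound_result`: list with `delta` (named vector, ZT 6-23),
#'   `peak_zt`, `class`, `state_key`
#' @export
rebound_analysis <- function(baseline, recovery, state_key,
                             subjects = NULL) {
  get_bins <- function(df) {
    if (!is.null(subjects)) df <- df[df$subject_id %in% subjects, ]
    zt <- df$zt[df$key == state_key]
    as.integer(table(factor(floor(zt), levels = 6:23)))
  }
  cover <- function(df) {
    if (!is.null(subjects)) df <- df[df$subject_id %in% subjects, ]
    length(unique(floor(df$zt[df$zt >= 6]))) == 18
  }
  if (!cover(baseline)) stop("missing baseline coverage of ZT 6-24")
  if (!cover(recovery)) stop("missing recovery coverage of ZT 6-24")
  delta <- get_bins(recovery) - get_bins(baseline)
  names(delta) <- 6:23
  if (max(delta) <= 0) {
    cls <- "none"
    pk <- NA_real_
  } else {
    pk <- as.numeric(names(delta)[which.max(delta)])
    cls <- if (pk == 6) "immediate" else if (pk <= 12) "intermediate"
      else "late"
  }
  structure(list(state_key = state_key, delta = delta, peak_zt = pk,
                 class = cls), class = "rebound_result")
}

#' @export
print.rebound_result <- function(x, ...) {
  cat(sprintf("<rebound_result> state %s: %s rebound%s\n",
              as.character(x$state_key), x$class,
              if (is.na(x$peak_zt)) "" else
                sprintf(" (peak ZT %g, +%d epochs)", x$peak_zt,
                        max(x$delta))))
  invisible(x)
}
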
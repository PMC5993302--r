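#' Shannon entropy of a stage-probability row
#'
#' `H = -sum p log2 p` in bits, with `0 log 0 := 0`. For the three vigilance
#' stages the value lies in `[0, log2 3]`.
#'
#' @param p probability vector (must sum to 1 within 1e-9)
#' @return entropy in bits
#' @export
state_entropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("p must be a probability vector")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information of a joint distribution
#'
#' `I(X;Y) = sum p(x,y) log2[p(x,y) / (p(x) p(y))]` in bits; zero cells are
#' skipped. Rows index the latent states X, columns the stages Y.
#'
#' @param joint nonnegative matrix summing to 1
#' @return mutual information in bits (nonnegative)
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < 0)) stop("joint must be nonnegative")
  if (abs(sum(joint) - 1) > 1e-9) stop("joint must sum to 1")
  px <- rowSums(joint)
  py <- colSums(joint)
  idx <- which(joint > 0, arr.ind = TRUE)
  pj <- joint[idx]
  sum(pj * log2(pj / (px[idx[, 1]] * py[idx[, 2]])))
}

#' Normalised mutual information
#'
#' `I_n = I(X;Y) / H(X)` where `H(X)` is the entropy of the latent-state
#' marginal (rows). Lies in `[0, 1]`; equals 1 under a perfect state-stage
#' correspondence and 0 under independence.
#'
#' @inheritParams mutual_information
#' @return dimensionless value in `[0, 1]`
#' @export
normalized_mi <- function(joint) {
  joint <- as.matrix(joint)
  hx <- state_entropy(rowSums(joint) / sum(joint))
  if (hx == 0) stop("degenerate-marginal: single latent state")
  mutual_information(joint) / hx
}

#' Normalised mutual information of two label sequences
#'
#' Convenience wrapper building the empirical joint distribution of two
#' aligned discrete sequences and evaluating [normalized_mi()] with the
#' first sequence as the latent-state variable X.
#'
#' @param x,y aligned discrete label vectors
#' @return NMI in `[0, 1]`
#' @export
nmi_labels <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  tab <- table(x[keep], y[keep])
  normalized_mi(tab / sum(tab))
}

#' Classify a latent state's stage role
#'
#' A state is assigned the vigilance stage whose probability reaches the
#' threshold (boundary inclusive); states below the threshold for every
#' stage have no clear mapping and are "transitional".
#'
#' @param p named probability row over `W`, `NR`, `R`
#' @param threshold role threshold (default 0.6)
#' @return one of `"W"`, `"NR"`, `"R"`, `"transitional"`
#' @export
classify_state_role <- function(p, threshold = 0.6) {
  p <- unlist(p)[stage_levels]
  if (anyNA(p)) return(NA_character_)
  i <- which.max(p)
  if (p[i] >= threshold) stage_levels[i] else "transitional"
}

#' Build the latent-state catalog and stage-probability matrix
#'
#' Tallies every observed latent configuration, its cohort-wide and
#' per-subject epoch counts, and (for states with manually labelled epochs)
#' the probability of each vigilance stage within the state:
#' `p_L(y) = #epochs of state L labelled y / #labelled epochs of state L`.
#' Each labelled row sums to 1; states with no labelled epochs get an NA
#' row and are flagged. Per-state entropy (bits), the stage role at the 0.6
#' threshold, and a rare flag (`count < min_count`) are attached. When
#' model parameters are supplied, the per-state Gaussian descriptor
#' (conditional mean and covariance over the input features) is stored too.
#'
#' @param codes a `latent_codes` data frame from [encode_dataset()] (or an
#'   integer key vector)
#' @param labels optional stage labels aligned with `codes` (taken from the
#'   `stage` column when absent)
#' @param params optional [mcrbm_params()] for Gaussian descriptors
#' @param min_count rare-state threshold (cohort-wide epochs)
#' @return a `state_catalog`: list with `table` (one row per state: `key`,
#'   `count`, `n_labeled`, `p_W`, `p_NR`, `p_R`, `entropy_bits`, `role`,
#'   `rare`), `joint` (state x stage joint distribution over labelled
#'   epochs), `subject_counts` (state x subject matrix, when subject ids are
#'   available) and `descriptors`
#' @export
build_catalog <- function(codes, labels = NULL, params = NULL,
                          min_count = 10) {
  if (is.data.frame(codes)) {
    keys <- codes$key
    if (is.null(labels)) labels <- codes$stage
    subjects <- codes$subject_id
  } else {
    keys <- as.integer(codes)
    subjects <- NULL
  }
  if (is.null(labels)) labels <- rep(NA_character_, length(keys))
  stopifnot(length(labels) == length(keys))
  bad <- !is.na(labels) & !(labels %in% stage_levels)
  if (any(bad))
    stop("bad-stage-label: ", paste(unique(labels[bad]), collapse = ", "))
  if (all(is.na(labels))) stop("no-labels: no manually scored epochs")

  uk <- sort(unique(keys))
  count <- as.integer(table(factor(keys, levels = uk)))
  lab <- factor(labels, levels = stage_levels)
  cont <- table(factor(keys, levels = uk), lab)   # states x stages counts
  n_labeled <- rowSums(cont)
  pmat <- cont / ifelse(n_labeled > 0, n_labeled, NA)
  pmat <- matrix(pmat, ncol = 3, dimnames = list(uk, stage_levels))
  joint <- cont / sum(cont)

  ent <- apply(pmat, 1, function(p) {
    if (anyNA(p)) NA_real_ else state_entropy(p)
  })
  role <- apply(pmat, 1, classify_state_role)
  tab <- data.frame(key = uk, count = count,
                    n_labeled = as.integer(n_labeled),
                    p_W = pmat[, "W"], p_NR = pmat[, "NR"],
                    p_R = pmat[, "R"], entropy_bits = ent, role = role,
                    rare = count < min_count, row.names = NULL,
                    stringsAsFactors = FALSE)
  subject_counts <- NULL
  if (!is.null(subjects)) {
    subject_counts <- table(factor(keys, levels = uk), subjects)
    subject_counts <- matrix(subject_counts, nrow = length(uk),
                             dimnames = list(uk, colnames(subject_counts)))
  }
  descriptors <- NULL
  if (!is.null(params)) {
    check_params(params)
    dm <- dims_of(params)
    descriptors <- lapply(uk, function(k) {
      cf <- key_to_config(k, dm$Mc, dm$Mm)
      tryCatch(conditional_gaussian(cf$h_c, cf$h_m, params),
               error = function(e) NULL)
    })
    names(descriptors) <- uk
  }
  structure(list(table = tab, joint = as.matrix(joint),
                 subject_counts = subject_counts,
                 descriptors = descriptors, min_count = min_count),
            class = "state_catalog")
}

#' @export
print.state_catalog <- function(x, ...) {
  cat(sprintf("<state_catalog> %d latent states over %d epochs (%d rare)\n",
              nrow(x$table), sum(x$table$count), sum(x$table$rare)))
  cat(sprintf("  roles: %s\n",
              paste(names(table(x$table$role)), table(x$table$role),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Information summary of a catalog
#'
#' Global informativeness of the latent states about the manual stages:
#' latent-state entropy `H(X)`, stage entropy `H(Y)`, their mutual
#' information and the normalised MI `I(X;Y)/H(X)`, plus the per-stage MI
#' decomposition `I_y = sum_x p(x,y) log2[p(x,y)/(p(x)p(y))]` (one reading
#' of a per-stage informativeness bar; the per-state quantity is the
#' `entropy_bits` column of the catalog).
#'
#' @param catalog a `state_catalog`
#' @return list with `H_states`, `H_stages`, `mi_bits`, `nmi`,
#'   `mi_per_stage`
#' @export
catalog_information <- function(catalog) {
  joint <- catalog$joint
  keep <- rowSums(joint) > 0
  joint <- joint[keep, , drop = FALSE]
  px <- rowSums(joint)
  py <- colSums(joint)
  per_stage <- vapply(seq_len(ncol(joint)), function(j) {
    pj <- joint[, j]
    nz <- pj > 0
    sum(pj[nz] * log2(pj[nz] / (px[nz] * py[j])))
  }, 0)
  names(per_stage) <- colnames(joint)
  list(H_states = state_entropy(px), H_stages = state_entropy(py),
       mi_bits = mutual_information(joint), nmi = normalized_mi(joint),
       mi_per_stage = per_stage)
}

#' Per-state Gaussian descriptor
#'
#' The multivariate normal over the input features associated with one
#' binary latent configuration; delegates to [conditional_gaussian()].
#'
#' @param key integer state key, or a list with `h_c`/`h_m`
#' @param params [mcrbm_params()]
#' @return list with `mean` and `sigma`
#' @export
state_descriptor <- function(key, params) {
  check_params(params)
  dm <- dims_of(params)
  cf <- if (is.list(key)) key else key_to_config(key, dm$Mc, dm$Mm)
  conditional_gaussian(cf$h_c, cf$h_m, params)
}

#' Export a catalog table as CSV
#'
#' @param catalog a `state_catalog`
#' @param path output path
#' @export
write_catalog_csv <- function(catalog, path) {
  utils::write.csv(catalog$table, path, row.names = FALSE)
  invisible(path)
}
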
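#' EEG frequency bands
#'
#' The five canonical rodent EEG bands used throughout the pipeline, as
#' half-open intervals `[lo, hi)` in Hz so shared endpoints are counted once:
#' Delta 0.25-5, Theta 5-9, Alpha 9-12, Beta 12-20, Gamma 20-50.
#'
#' @format a data frame with columns `name`, `lo`, `hi`
#' @export
eeg_bands <- data.frame(
  name = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
  lo = c(0.25, 5, 9, 12, 20),
  hi = c(5, 9, 12, 20, 50)
)

new_epoch_features <- function(df) {
  class(df) <- c("epoch_features", "data.frame")
  df
}

epoch_csv_columns <- c("subject_id", "epoch_index", "zt", "delta", "theta",
                       "alpha", "beta", "gamma", "emg_integral", "artifact",
                       "stage")

#' Per-epoch EEG band powers and EMG tone
#'
#' Segments a recording into fixed-length epochs (4 s by default) and
#' computes, for every complete epoch, the spectral power in each of the five
#' EEG bands plus the rectified-EMG integral. Power spectra use Welch
#' averaging of 50%-overlapping Hann-windowed segments whose length is the
#' largest power of two not exceeding 2.048 s of samples, which at 500 Hz
#' gives 1024-sample windows and the 0.48-Hz bin resolution conventional for
#' this preparation. Band power is the sum of power-spectral values over the
#' band's bins (bands half-open `[lo, hi)`); a trailing partial epoch is
#' dropped.
#'
#' @param rec a [raw_recording()]
#' @param epoch_s epoch duration in seconds
#' @return an `epoch_features` data frame with columns `subject_id`,
#'   `epoch_index` (0-based), `zt`, `delta`, `theta`, `alpha`, `beta`,
#'   `gamma`, `emg_integral`, `artifact` (all `FALSE`; artifact flags are a
#'   manual-annotation input, not detected here), `stage` (`NA`)
#' @export
epoch_band_powers <- function(rec, epoch_s = 4) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate
  if (length(rec$eeg) == 0) stop("empty-input: recording has no samples")
  if (fs < 100)
    stop("nyquist: sampling rate ", fs,
         " Hz cannot resolve the Gamma band (20-50 Hz)")
  n_per <- round(fs * epoch_s)
  n_ep <- floor(length(rec$eeg) / n_per)
  if (n_ep < 1) stop("empty-input: recording shorter than one epoch")

  L <- 2^floor(log2(fs * 2.048))
  L <- min(L, n_per)
  starts <- seq(1L, n_per - L + 1L, by = max(1L, L %/% 2L))
  h <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  freqs <- (0:(L %/% 2)) * fs / L
  band_sel <- lapply(seq_len(nrow(eeg_bands)), function(b)
    which(freqs >= eeg_bands$lo[b] & freqs < eeg_bands$hi[b]))
  # one-sided PSD scaling; constant factors cancel in the downstream ratios
  scale <- 1 / (fs * sum(h^2))
  dbl <- rep(2, L %/% 2 + 1)
  dbl[1] <- 1
  if (L %% 2 == 0) dbl[length(dbl)] <- 1

  eeg <- matrix(rec$eeg[seq_len(n_per * n_ep)], nrow = n_per)
  bp <- matrix(0, nrow = n_ep, ncol = 5)
  chunk <- 2048L
  for (i0 in seq(1L, n_ep, by = chunk)) {
    cols <- i0:min(i0 + chunk - 1L, n_ep)
    acc <- matrix(0, L %/% 2 + 1, length(cols))
    for (s in starts) {
      seg <- eeg[s:(s + L - 1L), cols, drop = FALSE] * h
      ft <- stats::mvfft(seg)
      acc <- acc + Mod(ft[seq_len(L %/% 2 + 1L), , drop = FALSE])^2
    }
    psd <- acc * (scale * dbl / length(starts))
    for (b in 1:5) bp[cols, b] <- colSums(psd[band_sel[[b]], , drop = FALSE])
  }

  zt <- (rec$start_zt + (0:(n_ep - 1)) * epoch_s / 3600) %% 24
  new_epoch_features(data.frame(
    subject_id = rec$subject_id,
    epoch_index = 0:(n_ep - 1),
    zt = zt,
    delta = bp[, 1], theta = bp[, 2], alpha = bp[, 3],
    beta = bp[, 4], gamma = bp[, 5],
    emg_integral = emg_integral(rec, epoch_s),
    artifact = FALSE,
    stage = NA_character_,
    stringsAsFactors = FALSE))
}

#' Rectified-EMG integral per epoch
#'
#' Integrates `|emg|` over each complete epoch by the trapezoidal rule on
#' the sample grid. Each epoch is integrated over its full nominal span:
#' the first sample of the following epoch closes the trapezoid (the final
#' epoch reuses its own last sample), so per-epoch integrals add up to the
#' whole-recording integral and a constant signal of a microvolts over a
#' 4-s epoch yields exactly 4a microvolt-seconds.
#'
#' @inheritParams epoch_band_powers
#' @return numeric vector of per-epoch integrals (microvolt-seconds), aligned
#'   with the rows of [epoch_band_powers()]
#' @export
emg_integral <- function(rec, epoch_s = 4) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate
  if (length(rec$emg) == 0) stop("empty-input: recording has no samples")
  n_per <- round(fs * epoch_s)
  n_ep <- floor(length(rec$emg) / n_per)
  if (n_ep < 1) stop("empty-input: recording shorter than one epoch")
  a <- abs(rec$emg[seq_len(n_per * n_ep)])
  dt <- 1 / fs
  s <- colSums(matrix(a, nrow = n_per))
  first <- a[seq(1L, by = n_per, length.out = n_ep)]
  nxt <- c(a[seq(n_per + 1L, by = n_per, length.out = n_ep - 1L)],
           a[n_per * n_ep])
  dt * (s + (nxt - first) / 2)
}

ratio_pairs <- function() {
  nm <- eeg_bands$name
  out <- list()
  for (i in 1:4) for (j in (i + 1):5) out[[length(out) + 1]] <- c(nm[i], nm[j])
  out
}

#' Build the model input matrix from epoch feature tables
#'
#' Turns one table per subject into the visible-layer matrix of the model:
#' artifact epochs are dropped, the ten pairwise band ratios are formed with
#' the numerator preceding the denominator in band order
#' (Delta/Theta, Delta/Alpha, ..., Beta/Gamma), the natural log is taken of
#' the ratios and of the EMG integral, and every column is mean-centred
#' within each subject separately. The result is invariant to any
#' per-subject global gain on the EEG, and the per-subject centring removes
#' gain differences on the EMG as well.
#'
#' @param tables an `epoch_features` table or a list of them (one per
#'   subject)
#' @return a `feature_matrix`: list with `x` (rows = retained epochs,
#'   11 columns), `col_names`, `index_map` (data frame mapping rows to
#'   `subject_id`/`epoch_index`), and `subjects` (per-row subject factor)
#' @export
build_feature_matrix <- function(tables) {
  if (inherits(tables, "epoch_features")) tables <- list(tables)
  pairs <- ratio_pairs()
  col_names <- c(vapply(pairs, function(p) paste(p, collapse = "/"), ""),
                 "EMG")
  blocks <- list()
  maps <- list()
  band_cols <- c(Delta = "delta", Theta = "theta", Alpha = "alpha",
                 Beta = "beta", Gamma = "gamma")
  for (tab in tables) {
    stopifnot(is.data.frame(tab))
    keep <- !tab$artifact
    tab2 <- tab[keep, , drop = FALSE]
    if (nrow(tab2) == 0) next
    vals <- as.matrix(tab2[, c(band_cols, "emg_integral")])
    bad <- which(vals <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      r <- bad[1, 1]
      stop(sprintf("nonpositive-feature: subject %s epoch %d",
                   tab2$subject_id[r], tab2$epoch_index[r]))
    }
    lp <- log(vals[, 1:5, drop = FALSE])
    m <- matrix(0, nrow(tab2), 11)
    for (k in seq_along(pairs)) {
      i <- match(pairs[[k]][1], names(band_cols))
      j <- match(pairs[[k]][2], names(band_cols))
      m[, k] <- lp[, i] - lp[, j]
    }
    m[, 11] <- log(vals[, 6])
    m <- sweep(m, 2, colMeans(m))
    blocks[[length(blocks) + 1]] <- m
    maps[[length(maps) + 1]] <- data.frame(
      subject_id = tab2$subject_id, epoch_index = tab2$epoch_index,
      zt = tab2$zt, stage = tab2$stage, stringsAsFactors = FALSE)
  }
  if (length(blocks) == 0) stop("empty-input: no non-artifact epochs")
  x <- do.call(rbind, blocks)
  colnames(x) <- col_names
  index_map <- do.call(rbind, maps)
  rownames(index_map) <- NULL
  structure(list(x = x, col_names = col_names, index_map = index_map,
                 subjects = factor(index_map$subject_id,
                                   levels = unique(index_map$subject_id))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features, %d subject(s)\n",
              nrow(x$x), ncol(x$x), nlevels(x$subjects)))
  invisible(x)
}

#' Read / write per-epoch feature tables as CSV
#'
#' The CSV schema has one row per 4-s epoch and the columns `subject_id`,
#' `epoch_index`, `zt`, `delta`, `theta`, `alpha`, `beta`, `gamma`,
#' `emg_integral`, `artifact` (0/1) and `stage` (`W`/`NR`/`R` or empty).
#' Numeric values are written at full precision so a write/read cycle is
#' lossless.
#'
#' @param path path to a CSV file
#' @return `read_epoch_csv` returns an `epoch_features` data frame
#' @export
read_epoch_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  missing <- setdiff(epoch_csv_columns, names(df))
  if (length(missing) > 0)
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  df <- df[, epoch_csv_columns]
  df$stage <- as.character(df$stage)
  df$stage[!is.na(df$stage) & df$stage == ""] <- NA_character_
  bad <- !is.na(df$stage) & !(df$stage %in% stage_levels)
  if (any(bad))
    stop("bad-stage-label: ", paste(unique(df$stage[bad]), collapse = ", "))
  df$artifact <- as.logical(df$artifact)
  new_epoch_features(df)
}

#' @rdname read_epoch_csv
#' @param table an `epoch_features` data frame
#' @export
write_epoch_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(epoch_csv_columns, names(table))
  if (length(missing) > 0)
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  out <- table[, epoch_csv_columns]
  for (cc in c("zt", "delta", "theta", "alpha", "beta", "gamma",
               "emg_integral"))
    out[[cc]] <- sprintf("%.17g", out[[cc]])
  out$artifact <- as.integer(out$artifact)
  out$stage[is.na(out$stage)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a feature matrix as CSV
#'
#' One row per retained epoch: the index-map columns (`subject_id`,
#' `epoch_index`, `zt`, `stage`) followed by the 11 feature columns.
#'
#' @param fm a `feature_matrix`
#' @param path path to a CSV file
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- as.data.frame(fm$x)
  names(x) <- fm$col_names
  out <- cbind(fm$index_map, x)
  out$stage[is.na(out$stage)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = c(subject_id = "character"))
  meta <- c("subject_id", "epoch_index", "zt", "stage")
  missing <- setdiff(meta, names(df))
  if (length(missing) > 0)
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  df$stage <- as.character(df$stage)
  df$stage[!is.na(df$stage) & df$stage == ""] <- NA_character_
  x <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  structure(list(x = x, col_names = colnames(x),
                 index_map = df[, meta],
                 subjects = factor(df$subject_id,
                                   levels = unique(df$subject_id))),
            class = "feature_matrix")
}
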
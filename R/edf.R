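#' Construct a raw EEG/EMG recording
#'
#' Container for a single subject's telemetry: one EEG and one EMG voltage
#' series sampled at a common rate, plus the zeitgeber time at which the
#' recording starts (ZT 0 = lights on; light phase ZT 0-12).
#'
#' @param eeg numeric vector, EEG in microvolts
#' @param emg numeric vector, EMG in microvolts, same length as `eeg`
#' @param sampling_rate sampling rate in Hz (nominally 500)
#' @param start_zt recording start in zeitgeber hours, in `[0, 24)`
#' @param subject_id opaque subject identifier
#' @return an object of class `raw_recording`
#' @export
raw_recording <- function(eeg, emg, sampling_rate, start_zt = 0,
                          subject_id = "subject") {
  if (length(eeg) != length(emg))
    stop("eeg and emg must have the same length")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (start_zt < 0 || start_zt >= 24)
    stop("start_zt must lie in [0, 24)")
  structure(list(eeg = as.numeric(eeg), emg = as.numeric(emg),
                 sampling_rate = sampling_rate, start_zt = start_zt,
                 subject_id = as.character(subject_id)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s: %.1f s at %g Hz, start ZT %.2f\n",
              x$subject_id, length(x$eeg) / x$sampling_rate,
              x$sampling_rate, x$start_zt))
  invisible(x)
}

# numeric header fields are 8 ASCII chars; shrink precision until it fits
edf_num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8) return(s)
  }
  s
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Read an EDF recording
#'
#' Minimal reader for standard (16-bit) European Data Format files. The file
#' must contain at least two signals whose labels match "EEG" and "EMG"
#' (case-insensitive); the first match of each is used. Digital values are
#' rescaled to physical units using the per-signal calibration fields.
#'
#' @param path path to an EDF file
#' @param start_zt zeitgeber time of the first sample (hours in `[0,24)`)
#' @param subject_id subject identifier; defaults to the EDF patient field
#' @return a [raw_recording()]
#' @export
read_edf <- function(path, start_zt = 0, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) rawToChar(readBin(con, "raw", n))
  version <- rd_str(8)
  patient <- trimws(rd_str(80))
  rd_str(80)                       # recording id
  rd_str(8); rd_str(8)             # start date / time
  rd_str(8)                        # header bytes
  rd_str(44)                       # reserved
  n_rec <- as.integer(rd_str(8))
  rec_dur <- as.numeric(rd_str(8))
  ns <- as.integer(rd_str(4))
  if (is.na(ns) || ns < 2) stop("EDF must contain EEG and EMG signals")
  fields <- function(w) vapply(seq_len(ns), function(i) rd_str(w), "")
  labels <- trimws(fields(16))
  fields(80); fields(8)            # transducer, dimension
  phys_min <- as.numeric(fields(8)); phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8)); dig_max <- as.numeric(fields(8))
  fields(80)                       # prefilter
  spr <- as.integer(fields(8))     # samples per record
  fields(32)                       # reserved
  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- numeric(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], size = 2, endian = "little",
                   signed = TRUE)
      sig[[i]][(r - 1) * spr[i] + seq_len(spr[i])] <- d
    }
  }
  scale_sig <- function(i) {
    g <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    phys_min[i] + g * (sig[[i]] - dig_min[i])
  }
  i_eeg <- grep("EEG", labels, ignore.case = TRUE)[1]
  i_emg <- grep("EMG", labels, ignore.case = TRUE)[1]
  if (is.na(i_eeg) || is.na(i_emg))
    stop("EDF must contain EEG and EMG signals")
  fs_eeg <- spr[i_eeg] / rec_dur
  fs_emg <- spr[i_emg] / rec_dur
  if (fs_eeg != fs_emg)
    stop("EEG and EMG sampling rates differ")
  raw_recording(scale_sig(i_eeg), scale_sig(i_emg), fs_eeg,
                start_zt = start_zt,
                subject_id = subject_id %||%
                  (if (nzchar(patient)) patient else "subject"))
}

#' Write a recording to EDF
#'
#' Standard 16-bit EDF writer used mainly to materialise recordings for
#' external tools (and to build test fixtures in code). Signals are scaled
#' to the full digital range per channel; the trailing partial data record
#' is zero-padded.
#'
#' @param rec a [raw_recording()]
#' @param path output path
#' @param record_duration EDF data-record duration in seconds
#' @return `path`, invisibly
#' @export
write_edf <- function(rec, path, record_duration = 1) {
  fs <- rec$sampling_rate
  spr <- as.integer(round(fs * record_duration))
  n_rec <- as.integer(ceiling(length(rec$eeg) / spr))
  sigs <- list(EEG = rec$eeg, EMG = rec$emg)
  ns <- 2L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(edf_pad(x, w)), con)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr("sleepstates export", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(format(record_duration), 8)
  wr(ns, 4)
  rng <- lapply(sigs, function(x) {
    r <- range(x)
    if (r[1] == r[2]) r <- r + c(-1, 1)
    # store the header's (precision-limited) values so the scaling the
    # reader reconstructs is exactly the scaling used to digitise
    c(as.numeric(edf_num8(r[1])), as.numeric(edf_num8(r[2])))
  })
  for (nm in names(sigs)) wr(nm, 16)
  for (i in 1:ns) wr("", 80)
  for (i in 1:ns) wr("uV", 8)
  for (i in 1:ns) wr(edf_num8(rng[[i]][1]), 8)
  for (i in 1:ns) wr(edf_num8(rng[[i]][2]), 8)
  for (i in 1:ns) wr("-32768", 8)
  for (i in 1:ns) wr("32767", 8)
  for (i in 1:ns) wr("", 80)
  for (i in 1:ns) wr(spr, 8)
  for (i in 1:ns) wr("", 32)
  dig <- lapply(seq_along(sigs), function(i) {
    x <- sigs[[i]]
    x <- c(x, numeric(n_rec * spr - length(x)))
    g <- (rng[[i]][2] - rng[[i]][1]) / 65535
    pmax(pmin(as.integer(round((x - rng[[i]][1]) / g) - 32768), 32767L),
         -32768L)
  })
  for (r in seq_len(n_rec)) {
    for (i in 1:ns) {
      writeBin(dig[[i]][(r - 1) * spr + seq_len(spr)], con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
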
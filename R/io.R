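# Recording bundle I/O. EEG travels in EDF (16-bit, continuous); vital signs
# (IP, ECG) and annotations in tidy CSV with a header declaring the sampling
# rate; per-recording metadata in JSON. All downstream stages consume the
# in-memory types, never files.

EEG_CHANNELS <- c("Cz", "CPz", "C3", "C4", "Oz", "FCz", "T3", "T4")

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width = 8L) {
  s <- formatC(x, width = width, format = "g", digits = 6)
  substr(s, 1L, width)
}

#' Write a multichannel time series to an EDF file
#'
#' Minimal continuous EDF: all channels share the sampling rate, samples are
#' scaled to 16-bit integers per channel. The start offset `t0` is encoded in
#' the recording-identification header field so that [read_edf()] restores it.
#' Quantisation limits round-trip accuracy to about 1/65000 of each channel's
#' amplitude range.
#'
#' @param ts a [time_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(ts, path) {
  stopifnot(inherits(ts, "respac_ts"))
  fs <- ts$fs
  rec_dur <- NA
  for (d in c(1L, 2L, 4L, 5L, 8L, 10L)) {
    if (abs(fs * d - round(fs * d)) < 1e-9) { rec_dur <- d; break }
  }
  if (is.na(rec_dur)) stop("sampling rate has no whole-sample record duration")
  npr <- as.integer(round(fs * rec_dur))
  n <- nrow(ts$samples)
  n_rec <- ceiling(n / npr)
  ns <- ncol(ts$samples)

  x <- ts$samples
  x[is.na(x)] <- 0
  if (n_rec * npr > n) x <- rbind(x, matrix(0, n_rec * npr - n, ns))

  # physical min/max as stored (8-char ASCII), re-parsed so writer and reader
  # use identical scaling
  pmin_c <- pmax_c <- character(ns)
  pmin_v <- pmax_v <- numeric(ns)
  for (j in seq_len(ns)) {
    rng <- range(x[, j])
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    margin <- 1e-3 * diff(rng)
    pmin_c[j] <- edf_num(rng[1] - margin)
    pmax_c[j] <- edf_num(rng[2] + margin)
    pmin_v[j] <- as.numeric(pmin_c[j])
    pmax_v[j] <- as.numeric(pmax_c[j])
  }
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(pad_field("0", 8), con, eos = NULL)
  writeChar(pad_field("X X X X", 80), con, eos = NULL)
  writeChar(pad_field(sprintf("Startdate 01-JAN-2026 t0=%.9g", ts$t0), 80),
            con, eos = NULL)
  writeChar(pad_field("01.01.26", 8), con, eos = NULL)
  writeChar(pad_field("00.00.00", 8), con, eos = NULL)
  writeChar(pad_field(256L * (ns + 1L), 8), con, eos = NULL)
  writeChar(pad_field("", 44), con, eos = NULL)
  writeChar(pad_field(n_rec, 8), con, eos = NULL)
  writeChar(pad_field(rec_dur, 8), con, eos = NULL)
  writeChar(pad_field(ns, 4), con, eos = NULL)
  writeChar(paste0(vapply(ts$labels, pad_field, "", 16L), collapse = ""),
            con, eos = NULL)
  writeChar(strrep(" ", 80 * ns), con, eos = NULL)           # transducer
  writeChar(paste0(rep(pad_field("uV", 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmin_c, pad_field, "", 8L), collapse = ""),
            con, eos = NULL)
  writeChar(paste0(vapply(pmax_c, pad_field, "", 8L), collapse = ""),
            con, eos = NULL)
  writeChar(paste0(rep(pad_field(dmin, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field(dmax, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 80 * ns), con, eos = NULL)           # prefiltering
  writeChar(paste0(rep(pad_field(npr, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 32 * ns), con, eos = NULL)           # reserved

  dig <- matrix(0L, n_rec * npr, ns)
  for (j in seq_len(ns)) {
    sc <- (dmax - dmin) / (pmax_v[j] - pmin_v[j])
    dig[, j] <- as.integer(round((x[, j] - pmin_v[j]) * sc + dmin))
  }
  # interleave per record: record r holds npr samples of ch1, then ch2, ...
  idx <- matrix(seq_len(n_rec * npr), nrow = npr)
  out <- integer(n_rec * npr * ns)
  pos <- 1L
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      out[pos:(pos + npr - 1L)] <- dig[idx[, r], j]
      pos <- pos + npr
    }
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports continuous EDF with a common sampling rate across channels.
#'
#' @param path EDF file path.
#' @return a [time_series()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (substr(hdr, 1, 1) != "0") stop("not an EDF file: ", path)
  rec_id <- substr(hdr, 89, 168)
  t0 <- 0
  m <- regmatches(rec_id, regexec("t0=([-0-9.eE+]+)", rec_id))[[1]]
  if (length(m) == 2) t0 <- as.numeric(m[2])
  n_rec <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  fld <- function(width, offset) {
    vapply(seq_len(ns), function(j) {
      substr(sig, offset + (j - 1) * width + 1, offset + j * width)
    }, "")
  }
  off <- 0
  labels <- trimws(fld(16, off)); off <- off + 16 * ns
  off <- off + 80 * ns                                   # transducer
  off <- off + 8 * ns                                    # dimension
  pmin <- as.numeric(fld(8, off)); off <- off + 8 * ns
  pmax <- as.numeric(fld(8, off)); off <- off + 8 * ns
  dmin <- as.numeric(fld(8, off)); off <- off + 8 * ns
  dmax <- as.numeric(fld(8, off)); off <- off + 8 * ns
  off <- off + 80 * ns                                   # prefiltering
  npr <- as.integer(fld(8, off))
  if (length(unique(npr)) != 1L) stop("per-channel sampling rates unsupported")
  npr <- npr[1]
  fs <- npr / rec_dur
  raw <- readBin(con, "integer", n = n_rec * npr * ns, size = 2L,
                 signed = TRUE, endian = "little")
  dat <- matrix(0, n_rec * npr, ns)
  pos <- 1L
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * npr + 1L):(r * npr)
    for (j in seq_len(ns)) {
      dat[rows, j] <- raw[pos:(pos + npr - 1L)]
      pos <- pos + npr
    }
  }
  for (j in seq_len(ns)) {
    sc <- (pmax[j] - pmin[j]) / (dmax[j] - dmin[j])
    dat[, j] <- (dat[, j] - dmin[j]) * sc + pmin[j]
  }
  time_series(dat, fs = fs, t0 = t0, labels = labels)
}

#' Write/read a single-channel signal as tidy CSV
#'
#' Header comment lines (`# fs=`, `# t0=`, `# label=`) declare the sampling
#' rate, start offset and channel name; the body is one `value` column.
#' Round-trips at full double precision.
#'
#' @param ts single-channel [time_series()].
#' @param path CSV file path.
#' @return `path` invisibly (write) or a `respac_ts` (read).
#' @export
write_signal_csv <- function(ts, path) {
  stopifnot(inherits(ts, "respac_ts"), ncol(ts$samples) == 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%.17g", ts$fs),
    sprintf("# t0=%.17g", ts$t0),
    sprintf("# label=%s", ts$labels[1]),
    "value"
  ), con)
  writeLines(sprintf("%.17g", ts$samples[, 1]), con)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 3)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, "="), lines, value = TRUE)
    if (!length(ln)) stop("CSV header missing '", key, "': ", path)
    sub(paste0("^# ", key, "="), "", ln[1])
  }
  vals <- utils::read.csv(path, comment.char = "#")$value
  time_series(vals, fs = as.numeric(get("fs")), t0 = as.numeric(get("t0")),
              labels = get("label"))
}

#' Write/read an annotation set as CSV
#'
#' @param ann an [annotation_set()].
#' @param path CSV file path.
#' @return `path` invisibly (write) or an `annotation_set` (read).
#' @export
write_annotations_csv <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  utils::write.csv(
    data.frame(id = ann$ids, time_s = sprintf("%.17g", ann$times)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  annotation_set(df$time_s, df$id)
}

#' Write/read recording metadata as JSON
#'
#' @param meta a [recording_meta()].
#' @param path JSON file path.
#' @return `path` invisibly (write) or a `recording_meta` (read).
#' @export
write_meta_json <- function(meta, path) {
  stopifnot(inherits(meta, "recording_meta"))
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_meta_json
#' @export
read_meta_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  recording_meta(m$infant_id, m$pma_weeks, m$ventilation_mode, m$caffeine,
                 m$vitals_hours)
}

eeg_annotation_path <- function(eeg_path) {
  paste0(sub("\\.edf$", "", eeg_path), "_annotations.csv")
}

#' Write a full recording bundle to disk
#'
#' The EEG (eight scalp channels plus the EEG-side ECG) goes to `eeg_path` as
#' EDF with a sidecar `<stem>_annotations.csv`; IP, vitals-side ECG and
#' vitals-side annotations go to `vitals_dir` as `ip.csv`, `ecg.csv`,
#' `annotations.csv`; metadata to `meta_path` as JSON.
#'
#' @param recording a list with elements `eeg`, `ecg_eeg`, `ip`, `ecg_vitals`
#'   ([time_series()]), `annotations_eeg`, `annotations_vitals`
#'   ([annotation_set()]) and `meta` ([recording_meta()]).
#' @param eeg_path EDF output path.
#' @param vitals_dir directory for the vitals CSVs (created if needed).
#' @param meta_path JSON output path.
#' @return invisibly, the three paths.
#' @export
write_recording <- function(recording, eeg_path, vitals_dir, meta_path) {
  dir.create(vitals_dir, showWarnings = FALSE, recursive = TRUE)
  eeg_all <- time_series(
    cbind(recording$eeg$samples, ECG = ts_channel(recording$ecg_eeg, 1)),
    fs = recording$eeg$fs, t0 = recording$eeg$t0,
    labels = c(recording$eeg$labels, "ECG")
  )
  write_edf(eeg_all, eeg_path)
  write_annotations_csv(recording$annotations_eeg, eeg_annotation_path(eeg_path))
  write_signal_csv(recording$ip, file.path(vitals_dir, "ip.csv"))
  write_signal_csv(recording$ecg_vitals, file.path(vitals_dir, "ecg.csv"))
  write_annotations_csv(recording$annotations_vitals,
                        file.path(vitals_dir, "annotations.csv"))
  write_meta_json(recording$meta, meta_path)
  invisible(list(eeg = eeg_path, vitals = vitals_dir, meta = meta_path))
}

#' Read a recording bundle from disk
#'
#' Native sampling rates are preserved; no resampling is performed. The EEG
#' container must hold the eight named scalp channels (Cz, CPz, C3, C4, Oz,
#' FCz, T3, T4) plus the EEG-side ECG.
#'
#' @param eeg_path EDF file with the EEG and EEG-side ECG.
#' @param vitals_dir directory with `ip.csv`, `ecg.csv`, `annotations.csv`.
#' @param meta_path metadata JSON.
#' @return a recording bundle list (see [write_recording()]).
#' @export
read_recording <- function(eeg_path, vitals_dir, meta_path) {
  eeg_all <- read_edf(eeg_path)
  missing <- setdiff(c(EEG_CHANNELS, "ECG"), eeg_all$labels)
  if (length(missing)) {
    stop("EEG file lacks channel(s): ", paste(missing, collapse = ", "))
  }
  for (f in c("ip.csv", "ecg.csv", "annotations.csv")) {
    if (!file.exists(file.path(vitals_dir, f))) {
      stop("vitals directory lacks ", f)
    }
  }
  list(
    eeg = time_series(eeg_all$samples[, EEG_CHANNELS, drop = FALSE],
                      fs = eeg_all$fs, t0 = eeg_all$t0, labels = EEG_CHANNELS),
    ecg_eeg = time_series(eeg_all$samples[, "ECG"], fs = eeg_all$fs,
                          t0 = eeg_all$t0, labels = "ECG"),
    ip = read_signal_csv(file.path(vitals_dir, "ip.csv")),
    ecg_vitals = read_signal_csv(file.path(vitals_dir, "ecg.csv")),
    annotations_eeg = read_annotations_csv(eeg_annotation_path(eeg_path)),
    annotations_vitals = read_annotations_csv(
      file.path(vitals_dir, "annotations.csv")
    ),
    meta = read_meta_json(meta_path)
  )
}
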
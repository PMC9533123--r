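#' Multichannel EEG recording container
#'
#' Bundles a channels-by-samples signal matrix (microvolts) with its sampling
#' rate and 10-20 electrode labels. Channels are stored in canonical montage
#' order (see [montage_1020()]) regardless of the order supplied.
#'
#' @param data Numeric matrix, one row per channel, in the order of `labels`.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Character vector of electrode labels, a subset of the 10-20
#'   montage; `nrow(data)` must equal `length(labels)`.
#' @param subject_id Subject identifier string.
#' @param meta Optional named list of free-text acquisition metadata (e.g.
#'   reference scheme); carried along, never interpreted.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels, subject_id = "", meta = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (nrow(data) != length(labels))
    stop("nrow(data) (", nrow(data), ") != number of labels (",
         length(labels), ")", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicated electrode labels", call. = FALSE)
  if (!all(is.finite(data)))
    stop("signal matrix contains non-finite samples", call. = FALSE)
  canon <- check_montage(labels)
  data <- data[match(canon, labels), , drop = FALSE]
  rownames(data) <- canon
  structure(list(data = data, fs = fs, labels = canon,
                 subject_id = as.character(subject_id), meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
      "\n  ", length(x$labels), "channels x", ncol(x$data), "samples @",
      x$fs, "Hz (", round(ncol(x$data) / x$fs, 2), "s )\n  channels:",
      paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Read / write delimited EEG matrices
#'
#' Plain-text exchange format: '#'-prefixed header lines `# fs=<Hz>` and
#' `# labels=<comma-separated labels>`, followed by one comma-separated row of
#' samples per channel (row order given by the labels header). Values
#' round-trip to better than 1e-9 relative precision.
#'
#' @param path File path.
#' @param require_full If `TRUE` (default) the file must contain all 19
#'   montage electrodes; otherwise any montage subset is accepted.
#' @param subject_id Subject identifier to attach to the recording.
#' @return `read_delimited_matrix()` returns an [eeg_recording()];
#'   `write_delimited_matrix()` returns `path` invisibly.
#' @export
read_delimited_matrix <- function(path, require_full = TRUE, subject_id = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), lines[hdr], value = TRUE)
    if (length(hit) != 1L)
      stop("header must contain exactly one '# ", key, "=' line", call. = FALSE)
    sub(paste0("^#\\s*", key, "="), "", hit)
  }
  fs <- suppressWarnings(as.numeric(get_field("fs")))
  if (is.na(fs) || fs <= 0)
    stop("invalid sampling rate in header: fs=", get_field("fs"), call. = FALSE)
  labels <- trimws(strsplit(get_field("labels"), ",")[[1]])
  check_montage(labels, require_full = require_full)
  body_idx <- setdiff(seq_along(lines), hdr)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (length(body_idx) != length(labels))
    stop("expected ", length(labels), " channel rows, found ", length(body_idx),
         call. = FALSE)
  rows <- lapply(seq_along(body_idx), function(i) {
    ln <- body_idx[i]
    vals <- suppressWarnings(as.numeric(strsplit(lines[ln], ",")[[1]]))
    if (anyNA(vals))
      stop("non-numeric value on line ", ln, call. = FALSE)
    vals
  })
  nsamp <- lengths(rows)
  if (length(unique(nsamp)) != 1L)
    stop("row-length mismatch: line ", body_idx[which(nsamp != nsamp[1])[1]],
         " has ", nsamp[nsamp != nsamp[1]][1], " values, expected ", nsamp[1],
         call. = FALSE)
  eeg_recording(do.call(rbind, rows), fs = fs, labels = labels,
                subject_id = subject_id)
}

#' @param rec An [eeg_recording()].
#' @rdname read_delimited_matrix
#' @export
write_delimited_matrix <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# fs=", format(rec$fs, digits = 15)),
               paste0("# labels=", paste(rec$labels, collapse = ","))), con)
  for (i in seq_len(nrow(rec$data)))
    writeLines(paste(sprintf("%.12g", rec$data[i, ]), collapse = ","), con)
  invisible(path)
}

# ---- EDF (European Data Format) ----------------------------------------------
# Minimal continuous-recording EDF support: fixed-layout ASCII header plus
# little-endian 16-bit data records. One-second records; all channels share the
# sampling rate. Physical unit is assumed to be microvolts; any other unit
# string in the file triggers a warning and the values are passed through.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Read / write EDF files
#'
#' A minimal reader/writer for continuous EDF (European Data Format)
#' recordings. The writer emits one-second data records with 16-bit samples
#' scaled per channel to the physical min/max; trailing samples that do not
#' fill a whole record are dropped with a warning. The reader remaps channels
#' to canonical montage order, drops unknown channels with a warning, and
#' fails if montage electrodes are absent (unless `require_full = FALSE`).
#' Round-trip accuracy is limited by the 16-bit quantization.
#'
#' @inheritParams read_delimited_matrix
#' @return `read_edf()` returns an [eeg_recording()]; `write_edf()` returns
#'   `path` invisibly.
#' @export
read_edf <- function(path, require_full = TRUE, subject_id = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) rawToChar(readBin(con, "raw", w))
  version <- trimws(rd(8))
  if (version != "0") stop("not an EDF file (version field '", version, "')",
                           call. = FALSE)
  patient <- trimws(rd(80)); recording <- trimws(rd(80))
  rd(8); rd(8)                               # start date/time, unused
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)                                     # reserved
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns)) || ns < 1 || rec_dur <= 0)
    stop("corrupt EDF header", call. = FALSE)
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- trimws(fld(16)); fld(80)
  units <- trimws(fld(8))
  phys_lo <- as.numeric(fld(8)); phys_hi <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (anyNA(c(phys_lo, phys_hi, dmin, dmax, spr)))
    stop("corrupt EDF signal header", call. = FALSE)
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported", call. = FALSE)
  if (any(units != "uV" & nzchar(units)))
    warning("EDF physical unit(s) ", paste(unique(units[units != "uV"]),
            collapse = ", "), " assumed equivalent to uV (values passed through)")
  fs <- spr[1] / rec_dur
  dat <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
      phys <- phys_lo[s] + (dig - dmin[s]) * (phys_hi[s] - phys_lo[s]) / (dmax[s] - dmin[s])
      dat[s, ((r - 1) * spr[1] + 1):(r * spr[1])] <- phys
    }
  }
  known <- labels %in% montage_1020()
  if (any(!known))
    warning("dropping non-montage channel(s): ",
            paste(labels[!known], collapse = ", "))
  dat <- dat[known, , drop = FALSE]
  labels <- labels[known]
  check_montage(labels, require_full = require_full)
  eeg_recording(dat, fs = fs, labels = labels, subject_id = subject_id,
                meta = list(patient = patient, recording = recording))
}

#' @inheritParams write_delimited_matrix
#' @rdname read_edf
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (abs(rec$fs - round(rec$fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  spr <- as.integer(round(rec$fs))           # samples per 1 s record
  n <- ncol(rec$data)
  n_rec <- n %/% spr
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)", call. = FALSE)
  if (n %% spr != 0)
    warning("dropping ", n %% spr, " trailing sample(s) not filling a record")
  ns <- nrow(rec$data)
  phys_lo <- apply(rec$data, 1, min); phys_hi <- apply(rec$data, 1, max)
  flat <- phys_hi - phys_lo <= 0
  phys_lo[flat] <- phys_lo[flat] - 1; phys_hi[flat] <- phys_hi[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(edf_pad(x, w)), con)
  wr("0", 8)
  wr(if (nzchar(rec$subject_id)) rec$subject_id else "X", 80)
  wr("eegmse export", 80)
  wr("01.01.2000", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8); wr("", 44)
  wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  num8 <- function(v) vapply(v, function(z) edf_pad(formatC(z, format = "g",
                                                            digits = 6), 8), character(1))
  for (s in rec$labels) wr(s, 16)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr("uV", 8)
  for (v in num8(phys_lo)) writeBin(charToRaw(v), con)
  for (v in num8(phys_hi)) writeBin(charToRaw(v), con)
  for (s in seq_len(ns)) wr("-32768", 8)
  for (s in seq_len(ns)) wr("32767", 8)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr(spr, 8)
  for (s in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((rec$data[s, idx] - phys_lo[s]) / (phys_hi[s] - phys_lo[s]) * 65535 - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
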
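#' Zero-phase band-pass filter
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to every
#' channel. The band defaults to the clinical 1-60 Hz acquisition band. The
#' high-pass and low-pass sections are applied separately, which keeps the
#' very low normalized corner frequency of the 1 Hz edge numerically stable.
#'
#' @param rec An [eeg_recording()].
#' @param lo,hi Band edges in Hz; `0 < lo < hi < fs/2`.
#' @param order Butterworth order of each section (default 4).
#' @return A filtered [eeg_recording()].
#' @export
bandpass <- function(rec, lo = 1, hi = 60, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi <= lo || hi >= nyq)
    stop("band edges must satisfy 0 < lo < hi < fs/2 (= ", nyq, " Hz)",
         call. = FALSE)
  bh <- signal::butter(order, lo / nyq, type = "high")
  bl <- signal::butter(order, hi / nyq, type = "low")
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    x <- signal::filtfilt(bh, rec$data[i, ])
    out$data[i, ] <- signal::filtfilt(bl, x)
  }
  out
}

#' Downsample a recording
#'
#' Fourier-domain resampling of every channel to a lower sampling rate: the
#' spectrum is truncated at the new Nyquist frequency and inverse-transformed
#' at the new length (the standard FFT resampling method; exact in amplitude
#' and phase for band-limited signals, with periodic boundary assumptions at
#' the edges). The default target of 200 Hz makes coarse-graining scale tau
#' correspond to exactly tau x 5 ms. Upsampling is refused.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate in Hz, `<= rec$fs`.
#' @return An [eeg_recording()] at `target_fs` with
#'   `round(n * target_fs / fs)` samples per channel.
#' @export
resample_recording <- function(rec, target_fs = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("`target_fs` must be a single positive number", call. = FALSE)
  if (target_fs > rec$fs)
    stop("upsampling (", rec$fs, " -> ", target_fs, " Hz) is not supported",
         call. = FALSE)
  if (target_fs == rec$fs) return(rec)
  n <- ncol(rec$data)
  n_out <- round(n * target_fs / rec$fs)
  if (abs(n * target_fs / rec$fs - n_out) > 1e-6)
    n_out <- floor(n * target_fs / rec$fs)
  half <- n_out %/% 2L
  dat <- matrix(0, nrow = nrow(rec$data), ncol = n_out)
  for (i in seq_len(nrow(rec$data))) {
    X <- fft(rec$data[i, ])
    Y <- complex(real = rep(0, n_out))
    Y[1] <- X[1]
    if (half >= 1) {
      Y[2:(half + 1)] <- X[2:(half + 1)]
      Y[n_out - seq_len(half - (n_out %% 2L == 0L)) + 1L] <-
        X[n - seq_len(half - (n_out %% 2L == 0L)) + 1L]
      if (n_out %% 2L == 0L)                 # new Nyquist bin must be real
        Y[half + 1L] <- complex(real = Re(X[half + 1L]))
    }
    dat[i, ] <- Re(fft(Y, inverse = TRUE)) / n
  }
  eeg_recording(dat, fs = target_fs, labels = rec$labels,
                subject_id = rec$subject_id, meta = rec$meta)
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of `epoch_len`
#' seconds; a trailing remainder shorter than one epoch is dropped. The epoch
#' must be long enough that the series coarse-grained at the largest scale
#' still supports sample-entropy estimation:
#' `floor(epoch_len * fs / max_scale) >= m + 2`.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_len Epoch length in seconds (default 20).
#' @param max_scale Largest coarse-graining scale the epochs must support
#'   (default 40).
#' @param m Embedding dimension the epochs must support (default 2).
#' @return An object of class `epoch_set`: channels x samples x epochs array
#'   plus bookkeeping (`fs`, `epoch_len`, `kept`, `rejected`, `subject_id`).
#' @export
segment <- function(rec, epoch_len = 20, max_scale = 40, m = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(epoch_len) || length(epoch_len) != 1L || epoch_len <= 0)
    stop("`epoch_len` must be a single positive number", call. = FALSE)
  spe <- floor(epoch_len * rec$fs)           # samples per epoch
  if (floor(spe / max_scale) < m + 2)
    stop("epoch too short: ", spe, " samples gives scale-", max_scale,
         " series of ", floor(spe / max_scale), " points (< m + 2 = ", m + 2, ")",
         call. = FALSE)
  n_ep <- ncol(rec$data) %/% spe
  if (n_ep < 1) stop("recording shorter than one epoch", call. = FALSE)
  arr <- array(0, dim = c(nrow(rec$data), spe, n_ep),
               dimnames = list(rec$labels, NULL, NULL))
  for (e in seq_len(n_ep))
    arr[, , e] <- rec$data[, ((e - 1) * spe + 1):(e * spe)]
  structure(list(epochs = arr, fs = rec$fs, epoch_len = epoch_len,
                 labels = rec$labels, kept = seq_len(n_ep),
                 rejected = integer(0), subject_id = rec$subject_id),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
      "\n  ", dim(x$epochs)[1], "channels,", length(x$kept), "kept /",
      dim(x$epochs)[3], "epochs of", x$epoch_len, "s @", x$fs, "Hz\n")
  invisible(x)
}

#' Amplitude-threshold epoch rejection
#'
#' Automated surrogate for manual artifact screening: an epoch is rejected
#' when the absolute amplitude on any channel exceeds `amp_thresh` microvolts
#' (default 100, the common clinical convention). Rejection indices are
#' recorded; rejecting every epoch is an error so that an unusable subject is
#' flagged rather than silently dropped.
#'
#' @param es An `epoch_set` from [segment()].
#' @param amp_thresh Peak-amplitude threshold in microvolts (> 0).
#' @return The `epoch_set` with updated `kept` / `rejected` indices.
#' @export
reject_epochs <- function(es, amp_thresh = 100) {
  stopifnot(inherits(es, "epoch_set"))
  if (!is.numeric(amp_thresh) || length(amp_thresh) != 1L || amp_thresh <= 0)
    stop("`amp_thresh` must be a single positive number", call. = FALSE)
  peaks <- apply(abs(es$epochs), 3, max)
  bad <- which(peaks > amp_thresh)
  bad <- union(es$rejected, intersect(bad, es$kept))
  kept <- setdiff(seq_len(dim(es$epochs)[3]), bad)
  if (length(kept) == 0)
    stop("all epochs rejected for subject '", es$subject_id,
         "' at threshold ", amp_thresh, " uV", call. = FALSE)
  es$kept <- kept
  es$rejected <- sort(bad)
  es
}
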
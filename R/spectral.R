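#' Welch power spectral density of an epoch set
#'
#' Averaged modified periodogram per electrode: each kept epoch is split into
#' Hanning windows of `window_sec` seconds (default 2.0) with `overlap`
#' fractional overlap (default 0.5), the one-sided periodograms are averaged
#' and converted to dB relative to 1 microvolt^2/Hz. The native frequency
#' resolution `1/window_sec` Hz is reduced onto the reporting grid `fmin` to
#' `fmax` in steps of `df` (default 2-60 Hz by 1 Hz, 59 points) either by
#' taking the native bin at each grid frequency (`regrid = "decimate"`,
#' default) or by averaging the native bins nearest each grid point
#' (`regrid = "band_average"`).
#'
#' @param es An `epoch_set`.
#' @param window_sec Window length in seconds; epochs must be at least this
#'   long and `fs * window_sec` must be a whole number of samples.
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @param fmin,fmax,df Reporting grid (Hz); all grid frequencies must be
#'   multiples of the native resolution for `regrid = "decimate"`.
#' @param regrid `"decimate"` or `"band_average"`.
#' @return Object of class `subject_psd`: electrodes x frequencies matrix of
#'   PSD in dB/Hz with attribute `freq` (Hz).
#' @export
welch_psd <- function(es, window_sec = 2, overlap = 0.5, fmin = 2, fmax = 60,
                      df = 1, regrid = c("decimate", "band_average")) {
  stopifnot(inherits(es, "epoch_set"))
  regrid <- match.arg(regrid)
  nwin <- round(window_sec * es$fs)
  spe <- dim(es$epochs)[2]
  if (spe < nwin)
    stop("epoch (", spe / es$fs, " s) shorter than the Welch window (",
         window_sec, " s)", call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("`overlap` must be in [0, 1)", call. = FALSE)
  if (fmax > es$fs / 2)
    stop("`fmax` exceeds the Nyquist frequency", call. = FALSE)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, spe - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))   # Hanning
  u <- sum(w^2)
  f_native <- (seq_len(nwin %/% 2)) * es$fs / nwin            # one-sided, no DC
  nch <- dim(es$epochs)[1]
  acc <- matrix(0, nch, length(f_native))
  nseg <- 0L
  for (e in es$kept) {
    for (s0 in starts) {
      seg <- matrix(es$epochs[, s0:(s0 + nwin - 1L), e], nrow = nch)
      seg <- seg - rowMeans(seg)
      sw <- sweep(seg, 2, w, `*`)
      ft <- t(stats::mvfft(t(sw)))
      pxx <- 2 * Mod(ft[, 2:(nwin %/% 2 + 1), drop = FALSE])^2 / (es$fs * u)
      if (nwin %% 2 == 0) pxx[, ncol(pxx)] <- pxx[, ncol(pxx)] / 2  # Nyquist
      acc <- acc + pxx
      nseg <- nseg + 1L
    }
  }
  pxx <- acc / nseg
  f_grid <- seq(fmin, fmax, by = df)
  if (regrid == "decimate") {
    idx <- match(round(f_grid * window_sec), round(f_native * window_sec))
    if (anyNA(idx))
      stop("reporting grid is not a subset of the native ",
           signif(1 / window_sec, 3), " Hz resolution", call. = FALSE)
    out <- pxx[, idx, drop = FALSE]
  } else {
    out <- vapply(f_grid, function(f) {
      sel <- which(abs(f_native - f) <= df / 2)
      rowMeans(pxx[, sel, drop = FALSE])
    }, numeric(nch))
    if (is.null(dim(out))) out <- matrix(out, nrow = nch)
  }
  vals <- 10 * log10(out)
  dimnames(vals) <- list(es$labels, f_grid)
  structure(vals, freq = f_grid, fs = es$fs, subject_id = es$subject_id,
            class = "subject_psd")
}

#' Assemble per-subject PSDs into a cohort matrix
#'
#' @param psds Named list of `subject_psd` matrices on identical grids.
#' @return Object of class `psd_matrix`: subjects x electrodes x frequencies
#'   array (dB/Hz) with attribute `freq`.
#' @export
psd_matrix <- function(psds) {
  stopifnot(length(psds) >= 1,
            all(vapply(psds, inherits, logical(1), "subject_psd")))
  ids <- names(psds)
  if (is.null(ids)) ids <- paste0("S", seq_along(psds))
  arr <- array(NA_real_, dim = c(length(psds), dim(psds[[1]])),
               dimnames = c(list(ids), dimnames(psds[[1]])))
  for (i in seq_along(psds)) arr[i, , ] <- unclass(psds[[i]])
  structure(arr, freq = attr(psds[[1]], "freq"), class = "psd_matrix")
}

#' @export
print.psd_matrix <- function(x, ...) {
  d <- dim(x)
  f <- attr(x, "freq")
  cat("<psd_matrix> ", d[1], " subjects x ", d[2], " electrodes x ", d[3],
      " frequency bins (", f[1], "-", f[length(f)], " Hz)\n", sep = "")
  invisible(x)
}

#' @rdname as.data.frame.mse_profile
#' @export
as.data.frame.psd_matrix <- function(x, row.names = NULL, optional = FALSE, ...) {
  dn <- dimnames(x)
  out <- expand.grid(subject = dn[[1]], electrode = dn[[2]],
                     freq_hz = attr(x, "freq"), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$psd_db <- as.vector(unclass(x))
  out
}
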
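#' Multiscale-entropy configuration
#'
#' Parameters of the multiscale entropy computation: embedding dimension `m`,
#' tolerance `r`, the scale axis and the scale-bin width. Defaults follow the
#' standard EEG convention: `m = 2`, `r = 0.2`, scales 1..40 reduced to 8 bins
#' of 5 scales.
#'
#' @param m Embedding dimension (integer >= 1).
#' @param r Matching tolerance. With `r_mode = "per_scale"` (default) each
#'   coarse-grained series is z-scored before matching, so `r` is in SD units
#'   of that normalized series and white noise has a scale-free entropy. With
#'   `r_mode = "global"` the tolerance is fixed at `r` times the SD of the
#'   scale-1 series (the original multiscale-entropy convention).
#' @param scales Integer vector of coarse-graining scale factors.
#' @param bin_width Number of consecutive scales averaged per bin;
#'   `length(scales)` must be divisible by it.
#' @param r_mode `"per_scale"` or `"global"` (see `r`).
#' @return An object of class `mse_config`.
#' @export
mse_config <- function(m = 2, r = 0.2, scales = 1:40, bin_width = 5,
                       r_mode = c("per_scale", "global")) {
  r_mode <- match.arg(r_mode)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("`m` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a single positive number", call. = FALSE)
  if (!is.numeric(scales) || any(scales < 1) || any(scales != round(scales)) ||
      anyDuplicated(scales))
    stop("`scales` must be distinct positive integers", call. = FALSE)
  structure(list(m = as.integer(m), r = r, scales = as.integer(scales),
                 bin_width = as.integer(bin_width), r_mode = r_mode),
            class = "mse_config")
}

#' Coarse-grain a series
#'
#' Replaces non-overlapping windows of `tau` consecutive samples by their
#' mean, producing the scale-`tau` series of length `floor(length(x)/tau)`;
#' element `j` is the mean of `x[(j-1)*tau + 1] .. x[j*tau]`.
#'
#' @param x Numeric vector.
#' @param tau Scale factor (integer, `1 <= tau <= length(x)`).
#' @return Numeric vector of length `floor(length(x)/tau)`.
#' @export
#' @examples
#' coarse_grain(c(1, 2, 3, 4, 5, 6), 2)  # 1.5 3.5 5.5
coarse_grain <- function(x, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau < 1 || tau != round(tau) || tau > length(x))
    stop("`tau` must be a single integer in [1, length(x)]", call. = FALSE)
  tau <- as.integer(tau)
  n <- length(x) %/% tau
  if (tau == 1L) return(x[seq_len(n)])
  colMeans(matrix(x[seq_len(n * tau)], nrow = tau))
}

#' Z-score a series (population-SD convention)
#'
#' Centers and scales to mean 0, SD 1 using the divide-by-N population SD.
#' A constant series has no scale and yields `NULL`, the package's
#' undefined-entry sentinel, which downstream entropy averaging masks out
#' rather than raising an error.
#'
#' @param y Numeric vector.
#' @return Normalized vector, or `NULL` for a constant input.
#' @export
zscore_series <- function(y) {
  mu <- mean(y)
  s <- sqrt(mean((y - mu)^2))
  if (!is.finite(s) || s == 0) return(NULL)
  (y - mu) / s
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B), where `B` counts pairs of length-`m` embedding
#' vectors within Chebyshev (max-coordinate) distance `r` and `A` counts the
#' pairs still within `r` when extended to length `m + 1`. Templates run over
#' the first `length(y) - m` positions for both counts, pairs `i < j` are
#' counted once (self-matches excluded), and matching uses the strict
#' inequality `< r`. The pair-normalizing constants of the two match
#' probabilities cancel in the ratio. Returns `NA` (undefined) when either
#' count is zero.
#'
#' @param y Numeric vector of length >= `m + 2`.
#' @param m Embedding dimension.
#' @param r Tolerance, on the scale of `y`.
#' @return Entropy in nats, or `NA_real_` when undefined.
#' @export
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(2000), m = 2, r = 0.2)  # ~ -log(erf(0.1)) = 2.18
sample_entropy <- function(y, m = 2, r = 0.2) {
  if (!is.numeric(y)) stop("`y` must be numeric", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("`m` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a single positive number", call. = FALSE)
  if (length(y) < m + 2)
    stop("series length ", length(y), " < m + 2 = ", m + 2, call. = FALSE)
  ab <- sampen_counts_cpp(as.numeric(y), as.integer(m), r)
  if (ab[1] == 0 || ab[2] == 0) return(NA_real_)
  -log(ab[1] / ab[2])
}

# SampEn of one coarse-grained, normalized series; r_ref is the absolute
# tolerance used in global mode. NA when the coarse series is constant or
# matching degenerates.
scale_entropy <- function(x, tau, cfg, r_ref) {
  y <- coarse_grain(x, tau)
  if (length(y) < cfg$m + 2) return(NA_real_)
  if (cfg$r_mode == "per_scale") {
    y <- zscore_series(y)
    if (is.null(y)) return(NA_real_)
    sample_entropy(y, cfg$m, cfg$r)
  } else {
    sample_entropy(y, cfg$m, r_ref)
  }
}

#' Multiscale entropy of an epoch set
#'
#' For every channel and scale factor: coarse-grain each kept epoch, z-score
#' (per-scale tolerance mode), compute sample entropy, and average over
#' epochs, ignoring undefined (masked) epoch entries. An entry that is
#' undefined in every epoch stays `NA` with a warning.
#'
#' @param es An `epoch_set` from [segment()] / [reject_epochs()].
#' @param cfg An [mse_config()].
#' @return Object of class `subject_mse`: electrodes x scales matrix of
#'   epoch-averaged sample entropy (nats), with attributes `n_epochs_used`
#'   (epochs contributing per cell, same shape) and `fs`, `subject_id`, `cfg`.
#' @export
epoch_mse <- function(es, cfg = mse_config()) {
  stopifnot(inherits(es, "epoch_set"), inherits(cfg, "mse_config"))
  if (length(es$kept) < 1) stop("no kept epochs", call. = FALSE)
  nch <- dim(es$epochs)[1]
  vals <- matrix(NA_real_, nch, length(cfg$scales),
                 dimnames = list(es$labels, cfg$scales))
  nuse <- matrix(0L, nch, length(cfg$scales),
                 dimnames = dimnames(vals))
  for (ch in seq_len(nch)) {
    per_epoch <- matrix(NA_real_, length(es$kept), length(cfg$scales))
    for (ei in seq_along(es$kept)) {
      x <- es$epochs[ch, , es$kept[ei]]
      r_ref <- cfg$r * sqrt(mean((x - mean(x))^2))
      per_epoch[ei, ] <- mse_scales_cpp(x, cfg$scales, cfg$m, cfg$r,
                                        cfg$r_mode == "per_scale", r_ref)
    }
    vals[ch, ] <- colMeans(per_epoch, na.rm = TRUE)
    nuse[ch, ] <- colSums(!is.na(per_epoch))
  }
  vals[nuse == 0L] <- NA_real_
  if (any(nuse == 0L))
    warning(sum(nuse == 0L), " (electrode, scale) cell(s) undefined in every ",
            "epoch for subject '", es$subject_id, "'")
  structure(vals, n_epochs_used = nuse, fs = es$fs,
            subject_id = es$subject_id, cfg = cfg, class = "subject_mse")
}

#' Assemble per-subject entropy matrices into a cohort profile
#'
#' @param profiles Named list of `subject_mse` matrices (names = subject ids),
#'   all computed with the same configuration.
#' @return Object of class `mse_profile`: subjects x electrodes x scales
#'   array with attributes `cfg`, `fs` and `n_epochs_used`.
#' @export
mse_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "subject_mse")))
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("S", seq_along(profiles))
  d1 <- dim(profiles[[1]])
  arr <- array(NA_real_, dim = c(length(profiles), d1),
               dimnames = c(list(ids), dimnames(profiles[[1]])))
  for (i in seq_along(profiles)) arr[i, , ] <- unclass(profiles[[i]])
  structure(arr, cfg = attr(profiles[[1]], "cfg"),
            fs = attr(profiles[[1]], "fs"),
            n_epochs_used = lapply(profiles, attr, "n_epochs_used"),
            class = "mse_profile")
}

#' Average scales into bins
#'
#' Reduces the scale axis of a cohort entropy profile to consecutive bins of
#' `bin_width` scales (default 8 bins of 5 for scales 1..40): bin `k` is the
#' unweighted mean of the defined entries at scales `5k-4 .. 5k`. Each bin is
#' labeled with its scale range and the corresponding time range in
#' milliseconds (`tau * 1000 / fs` per scale step).
#'
#' @param p An `mse_profile` (or a single `subject_mse`).
#' @param bin_width Scales per bin; must divide the number of scales.
#' @return Object of class `scale_bin_profile`: subjects x electrodes x bins
#'   array, with a `bins` attribute data frame (bin, tau_lo, tau_hi, ms_lo,
#'   ms_hi).
#' @export
bin_scales <- function(p, bin_width = NULL) {
  if (inherits(p, "subject_mse")) p <- mse_profile(stats::setNames(list(p), attr(p, "subject_id")))
  stopifnot(inherits(p, "mse_profile"))
  cfg <- attr(p, "cfg")
  if (is.null(bin_width)) bin_width <- cfg$bin_width
  ns <- dim(p)[3]
  if (ns %% bin_width != 0)
    stop("number of scales (", ns, ") not divisible by bin width (",
         bin_width, ")", call. = FALSE)
  nb <- ns %/% bin_width
  scales <- cfg$scales
  dt_ms <- 1000 / attr(p, "fs")
  arr <- array(NA_real_, dim = c(dim(p)[1:2], nb),
               dimnames = c(dimnames(p)[1:2], list(paste0("bin", seq_len(nb)))))
  bins <- data.frame(bin = seq_len(nb), tau_lo = NA_integer_,
                     tau_hi = NA_integer_, ms_lo = NA_real_, ms_hi = NA_real_)
  for (k in seq_len(nb)) {
    idx <- ((k - 1) * bin_width + 1):(k * bin_width)
    arr[, , k] <- apply(p[, , idx, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
    bins$tau_lo[k] <- scales[idx[1]]
    bins$tau_hi[k] <- scales[idx[bin_width]]
    bins$ms_lo[k] <- scales[idx[1]] * dt_ms
    bins$ms_hi[k] <- scales[idx[bin_width]] * dt_ms
  }
  arr[is.nan(arr)] <- NA_real_
  structure(arr, bins = bins, cfg = cfg, fs = attr(p, "fs"),
            class = "scale_bin_profile")
}

#' @export
print.mse_profile <- function(x, ...) {
  d <- dim(x)
  cat("<mse_profile> ", d[1], " subjects x ", d[2], " electrodes x ", d[3],
      " scales; ", sum(is.na(x)), " undefined entries\n", sep = "")
  invisible(x)
}

#' @export
print.scale_bin_profile <- function(x, ...) {
  d <- dim(x)
  b <- attr(x, "bins")
  cat("<scale_bin_profile> ", d[1], " subjects x ", d[2], " electrodes x ",
      d[3], " bins (", b$ms_lo[1], "-", b$ms_hi[1], " ms ... ",
      b$ms_lo[d[3]], "-", b$ms_hi[d[3]], " ms)\n", sep = "")
  invisible(x)
}

#' Tidy data frame of an entropy profile
#'
#' @param x An `mse_profile` or `scale_bin_profile`.
#' @param row.names,optional Unused, for generic compatibility.
#' @param ... Unused.
#' @return Long data frame (subject, electrode, scale or bin, value).
#' @export
as.data.frame.mse_profile <- function(x, row.names = NULL, optional = FALSE, ...) {
  dn <- dimnames(x)
  out <- expand.grid(subject = dn[[1]], electrode = dn[[2]],
                     scale = as.integer(dn[[3]]), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$value <- as.vector(unclass(x))
  out
}

#' @rdname as.data.frame.mse_profile
#' @export
as.data.frame.scale_bin_profile <- function(x, row.names = NULL, optional = FALSE, ...) {
  dn <- dimnames(x)
  out <- expand.grid(subject = dn[[1]], electrode = dn[[2]],
                     bin = seq_along(dn[[3]]), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$value <- as.vector(unclass(x))
  out
}

#' Plot multiscale-entropy curves
#'
#' Draws the electrode-mean entropy curve over scale factors for each subject
#' (thin lines) and the grand mean (thick line), optionally split by a group
#' factor.
#'
#' @param x An `mse_profile`.
#' @param groups Optional factor of group labels, one per subject.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.mse_profile <- function(x, groups = NULL, ...) {
  scales <- as.integer(dimnames(x)[[3]])
  subj_curves <- apply(x, c(1, 3), mean, na.rm = TRUE)   # subject x scale
  cols <- if (is.null(groups)) rep("grey60", nrow(subj_curves)) else
    c("firebrick", "steelblue")[as.integer(factor(groups))]
  graphics::matplot(scales, t(subj_curves), type = "l", lty = 1, col = cols,
                    xlab = "scale factor (tau)", ylab = "SampEn (nats)", ...)
  graphics::lines(scales, colMeans(subj_curves, na.rm = TRUE), lwd = 3)
  if (!is.null(groups))
    graphics::legend("bottomright", legend = levels(factor(groups)),
                     col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}
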
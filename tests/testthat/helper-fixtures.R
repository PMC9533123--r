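# Shared fixtures and independent oracles. Everything is generated in code;
# sizes are kept small so the whole suite runs in minutes.

# Naive O(n^2) sample entropy, written directly from the definition (vector
# max-norm over explicit windows); the independent reference for the compiled
# kernel. Same conventions: templates 1..n-m, pairs once, strict < r.
naive_sampen <- function(y, m, r) {
  N <- length(y) - m
  A <- 0L; B <- 0L
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      if (max(abs(y[i:(i + m - 1)] - y[j:(j + m - 1)])) < r) {
        B <- B + 1L
        if (abs(y[i + m] - y[j + m]) < r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# Brute-force Benjamini-Hochberg by subset enumeration: the rejection set is
# the largest subset S with max(p[S]) <= q * |S| / M.
bh_enumerate <- function(p, q) {
  M <- length(p)
  best <- logical(M)
  for (mask_int in seq_len(2^M) - 1L) {
    S <- as.logical(bitwAnd(mask_int, 2^(seq_len(M) - 1L)) > 0)
    if (sum(S) > sum(best) && all(p[S] <= q * sum(S) / M)) best <- S
  }
  best
}

# A white-noise recording: channels x samples at fs, unit-free amplitude.
white_recording <- function(n_ch = 2, n = 4000, fs = 200, amp = 10,
                            labels = c("Fp1", "Pz"), seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * n), n_ch, n) * amp, fs = fs,
                labels = labels[seq_len(n_ch)], subject_id = "W01")
}

# Epoch set built directly from a matrix of per-epoch channel data.
epochs_from_matrix <- function(x_list, fs = 200, labels = "Fp1") {
  spe <- length(x_list[[1]][1, ])
  arr <- array(0, dim = c(nrow(x_list[[1]]), spe, length(x_list)),
               dimnames = list(labels, NULL, NULL))
  for (e in seq_along(x_list)) arr[, , e] <- x_list[[e]]
  structure(list(epochs = arr, fs = fs, epoch_len = spe / fs, labels = labels,
                 kept = seq_along(x_list), rejected = integer(0),
                 subject_id = "T01"), class = "epoch_set")
}

# A small scale_bin_profile with known group structure for the stats tests.
toy_binned <- function(n = 10, E = 3, B = 2, labels = c("Fp1", "F3", "Pz"),
                       shift = 0, seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(n * E * B), dim = c(n, E, B),
               dimnames = list(sprintf("S%02d", seq_len(n)), labels,
                               paste0("bin", seq_len(B))))
  arr[seq_len(n / 2), , ] <- arr[seq_len(n / 2), , ] + shift
  structure(arr, bins = data.frame(bin = seq_len(B)),
            cfg = mse_config(scales = seq_len(5 * B)), fs = 200,
            class = "scale_bin_profile")
}

toy_subjects <- function(n = 10, seed = 2) {
  set.seed(seed)
  data.frame(subject_id = sprintf("S%02d", seq_len(n)),
             group = rep(c("high", "low"), each = n / 2),
             age = round(rnorm(n, 72, 4)),
             sex = sample(c("M", "F"), n, replace = TRUE))
}

# Reduced-size study configurations used by the replicate-based checks: the
# generator parameters are the package defaults (the study conditions); only
# recording length, epoch count and (for the null runs) the montage are scaled
# down so that hundreds of replicates fit in the test budget.
recovery_config <- function(seed) list(
  seed = seed,
  cohort = list(fs = 200, duration = 24, epoch_len = 8,
                n_epochs_range = c(3, 3)),
  preprocess = list(epoch_len = 8))

null_config <- function(seed) list(
  seed = seed,
  cohort = list(fs = 200, duration = 4, epoch_len = 2,
                n_epochs_range = c(2, 2), effect_size = 0,
                montage = c("Fp1", "F3", "C3", "T5", "O1", "Pz"),
                effect_electrodes = c("Fp1", "Pz")),
  preprocess = list(epoch_len = 2),
  mse = list(max_scale = 10, bin_width = 5))

quiet_pipeline <- function(cfg) {
  suppressWarnings(suppressMessages(run_pipeline(cfg)))
}
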
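# Calibration constant: high-minus-low difference of slow-scale (bins 3-8)
# sample entropy, in nats, produced by the full coherence contrast of the slow
# rhythm (coherence 1 vs 0) at the default rhythm amplitude, measured once on
# the default generation + preprocessing path (1-60 Hz acquisition band,
# 200 Hz analysis rate, scales 1..40, per-scale z-scoring). `effect_size`
# is translated into the low group's rhythm coherence through this constant.
SLOW_COHERENCE_EFFECT <- 0.07

#' Default effect electrodes
#'
#' The 13 electrodes where the synthetic group effect is injected by default:
#' frontal, parietal and temporal sites (the montage minus C3, C4, O1, O2,
#' F8, Fz).
#'
#' @return Character vector of 13 electrode labels.
#' @export
effect_electrodes_default <- function() {
  c("Fp1", "Fp2", "F3", "F4", "P3", "P4", "F7", "T3", "T4", "T5", "T6",
    "Cz", "Pz")
}

#' Noise-mixture description of one electrode's signal
#'
#' The generative model of a synthetic channel: a 1/f^beta colored background
#' with a white-noise admixture (`white_frac` of the background variance), an
#' alpha-band narrowband rhythm, and a slow (sub-2 Hz) rhythm whose
#' *coherence* interpolates between phase-diffuse narrowband noise
#' (`slow_coherence = 0`) and a pure periodic waveform (`slow_coherence = 1`).
#' The coherent slow rhythm models stereotyped slow-wave activity: it lowers
#' slow-scale sample entropy while leaving the 2-60 Hz power spectrum
#' essentially unchanged (equal rhythm power; only the sub-2 Hz line width
#' differs).
#'
#' @param beta Spectral exponent of the colored background (>= 0).
#' @param alpha_freq Alpha rhythm center frequency in Hz, inside 1-60 Hz.
#' @param alpha_amp Alpha rhythm RMS relative to the unit-SD background (>= 0).
#' @param white_frac Fraction of background variance that is white, in [0, 1].
#' @param alpha_bw Alpha rhythm spectral half-width (Hz).
#' @param slow_freq Slow rhythm center frequency (Hz); kept below the 2 Hz
#'   lower edge of the PSD reporting grid.
#' @param slow_amp Slow rhythm RMS relative to the unit-SD background.
#' @param slow_bw Spectral half-width of the incoherent slow rhythm (Hz).
#' @param slow_coherence Fraction of slow-rhythm variance that is phase-locked
#'   (pure tone), in [0, 1].
#' @return Object of class `noise_mix`.
#' @export
noise_mix <- function(beta = 1.5, alpha_freq = 9.5, alpha_amp = 0.8,
                      white_frac = 0.15, alpha_bw = 1,
                      slow_freq = 1.4, slow_amp = 0.9, slow_bw = 0.35,
                      slow_coherence = 0) {
  if (!is.finite(beta) || beta < 0)
    stop("`beta` must be finite and >= 0", call. = FALSE)
  if (!is.finite(white_frac) || white_frac < 0 || white_frac > 1)
    stop("`white_frac` must be in [0, 1]", call. = FALSE)
  if (!is.finite(alpha_freq) || alpha_freq < 1 || alpha_freq > 60)
    stop("`alpha_freq` must lie in the 1-60 Hz pass-band", call. = FALSE)
  if (!is.finite(alpha_amp) || alpha_amp < 0)
    stop("`alpha_amp` must be >= 0", call. = FALSE)
  if (!is.finite(slow_coherence) || slow_coherence < 0 || slow_coherence > 1)
    stop("`slow_coherence` must be in [0, 1]", call. = FALSE)
  if (!is.finite(slow_amp) || slow_amp < 0)
    stop("`slow_amp` must be >= 0", call. = FALSE)
  structure(list(beta = beta, alpha_freq = alpha_freq, alpha_amp = alpha_amp,
                 white_frac = white_frac, alpha_bw = alpha_bw,
                 slow_freq = slow_freq, slow_amp = slow_amp,
                 slow_bw = slow_bw, slow_coherence = slow_coherence),
            class = "noise_mix")
}

#' Synthetic-cohort configuration
#'
#' Study conditions for the two-group synthetic EEG cohort. Defaults mirror
#' the clinical design being emulated: 22 high / 21 low cognitive-function
#' subjects, 19-channel 10-20 montage, 500 Hz eyes-closed recordings of at
#' least 180 s acquired through a 1-60 Hz band, and 8-16 artifact-free 20 s
#' epochs per subject (mean ~12). The group effect is a slow-scale complexity
#' reduction in the LOW group at 13 frontal/parietal/temporal electrodes,
#' injected by making that group's sub-2 Hz rhythm phase-coherent
#' (stereotyped) there; rhythm amplitudes and all spectral envelopes on the
#' 2-60 Hz analysis grid are drawn identically in both groups, so the groups'
#' power spectra are matched by construction.
#'
#' @param n_high,n_low Group sizes (>= 2 each).
#' @param fs Sampling rate in Hz.
#' @param duration Minimum recording length in seconds; a warning is given
#'   below the 180 s eyes-closed standard. Per subject the recording is
#'   extended to `n_epochs * epoch_len` when that is longer.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration.
#' @param effect_electrodes Electrodes carrying the group effect.
#' @param effect_size Target high-minus-low difference of slow-scale (bins
#'   3-8) sample entropy in nats at the effect electrodes, mapped to the low
#'   group's rhythm coherence through the calibrated full-contrast value
#'   (0.07 nats at the default rhythm amplitude). The default is the full
#'   contrast, which yields an omnibus group effect of the magnitude the
#'   emulated study reports (a large partial eta^2); values above the
#'   calibrated maximum are rejected.
#' @param montage Electrode labels to generate (default: all 19).
#' @param epoch_len Epoch length in seconds used to size recordings.
#' @param n_epochs_range Inclusive range the per-subject epoch count is drawn
#'   from (default 8-16, mean ~12).
#' @param base_mix `noise_mix` of the background common to both groups.
#' @param beta_sd Between-subject/electrode SD of the spectral exponent.
#' @param alpha_amp_sdlog,gain_sdlog,electrode_gain_sdlog,slow_amp_sdlog
#'   Log-scale SDs of the per-subject alpha amplitude factor, the per-subject
#'   overall amplitude gain, the per-electrode gain (placement/impedance
#'   variation, independent across electrodes), and the per-electrode slow
#'   rhythm amplitude. Gain draws are truncated at 2 SD so that clean
#'   recordings stay below the clinical 100 microvolt rejection threshold.
#' @param acquisition_band Hardware band-pass emulated at generation time
#'   (Hz); `NULL` for broadband synthesis.
#' @param sd_uv Target channel SD in microvolts before the subject gain.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_high = 22, n_low = 21, fs = 500, duration = 180,
                          seed = 1,
                          effect_electrodes = effect_electrodes_default(),
                          effect_size = 0.07,
                          montage = montage_1020(), epoch_len = 20,
                          n_epochs_range = c(8, 16),
                          base_mix = noise_mix(),
                          beta_sd = 0.1, alpha_amp_sdlog = 0.15,
                          gain_sdlog = 0.2, electrode_gain_sdlog = 0.2,
                          slow_amp_sdlog = 0.2,
                          acquisition_band = c(1, 60), sd_uv = 8) {
  if (n_high < 2 || n_low < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (duration < 180)
    warning("duration ", duration,
            " s is below the 180 s eyes-closed recording standard")
  montage <- check_montage(montage)
  if (!all(effect_electrodes %in% montage))
    stop("effect electrodes outside the configured montage: ",
         paste(setdiff(effect_electrodes, montage), collapse = ", "),
         call. = FALSE)
  if (effect_size < 0 || effect_size > SLOW_COHERENCE_EFFECT + 1e-9)
    stop("`effect_size` must lie in [0, ", SLOW_COHERENCE_EFFECT,
         "], the range the slow-rhythm coherence contrast can produce at the ",
         "default amplitude", call. = FALSE)
  stopifnot(inherits(base_mix, "noise_mix"),
            length(n_epochs_range) == 2, n_epochs_range[1] >= 1,
            n_epochs_range[2] >= n_epochs_range[1])
  structure(list(n_high = n_high, n_low = n_low, fs = fs, duration = duration,
                 seed = as.integer(seed),
                 effect_electrodes = effect_electrodes,
                 effect_size = effect_size, montage = montage,
                 epoch_len = epoch_len,
                 n_epochs_range = as.integer(n_epochs_range),
                 base_mix = base_mix, beta_sd = beta_sd,
                 alpha_amp_sdlog = alpha_amp_sdlog, gain_sdlog = gain_sdlog,
                 electrode_gain_sdlog = electrode_gain_sdlog,
                 slow_amp_sdlog = slow_amp_sdlog,
                 acquisition_band = acquisition_band, sd_uv = sd_uv),
            class = "cohort_config")
}

# Posterior electrodes get the full alpha amplitude; anterior sites half.
alpha_topography <- function(labels) {
  posterior <- c("P3", "P4", "O1", "O2", "T5", "T6", "Pz")
  ifelse(labels %in% posterior, 1, 0.5)
}

# Draw the per-subject specification: demographics and per-electrode mixes.
# Group-dependent pieces follow the emulated cohort: age ~ N(70, 4.3) (high)
# vs N(74.14, 5.22) (low), male fractions 6/22 vs 7/21, Five-Cog-like totals
# N(168.27, 10.04) vs N(142.52, 8.28). The low group's slow rhythm is
# phase-coherent at the effect electrodes (coherence = effect_size /
# calibrated maximum); everything else is drawn identically in both groups.
generate_subject_spec <- function(i, group, cfg) {
  high <- group == "high"
  age <- min(85, max(65, round(rnorm(1, if (high) 70 else 74.14,
                                     if (high) 4.30 else 5.22))))
  sex <- if (runif(1) < (if (high) 6 / 22 else 7 / 21)) "M" else "F"
  score <- rnorm(1, if (high) 168.27 else 142.52, if (high) 10.04 else 8.28)
  n_epochs <- sample(seq(cfg$n_epochs_range[1], cfg$n_epochs_range[2]), 1)
  coher <- cfg$effect_size / SLOW_COHERENCE_EFFECT
  alpha_freq <- min(13, max(7, rnorm(1, cfg$base_mix$alpha_freq, 0.8)))
  slow_freq <- min(1.65, max(1.2, rnorm(1, cfg$base_mix$slow_freq, 0.1)))
  trunc2 <- function(k, sdlog) exp(pmin(pmax(rnorm(k, 0, sdlog),
                                             -2 * sdlog), 2 * sdlog))
  alpha_factor <- exp(rnorm(1, 0, cfg$alpha_amp_sdlog))
  gain <- trunc2(1, cfg$gain_sdlog)
  egain <- trunc2(length(cfg$montage), cfg$electrode_gain_sdlog)
  names(egain) <- cfg$montage
  topo <- alpha_topography(cfg$montage)
  mixes <- vector("list", length(cfg$montage))
  names(mixes) <- cfg$montage
  for (k in seq_along(cfg$montage)) {
    lab <- cfg$montage[k]
    mixes[[k]] <- noise_mix(
      beta = max(0, cfg$base_mix$beta + rnorm(1, 0, cfg$beta_sd)),
      alpha_freq = alpha_freq,
      alpha_amp = cfg$base_mix$alpha_amp * topo[k] * alpha_factor,
      white_frac = cfg$base_mix$white_frac,
      alpha_bw = cfg$base_mix$alpha_bw,
      slow_freq = slow_freq,
      slow_amp = cfg$base_mix$slow_amp * exp(rnorm(1, 0, cfg$slow_amp_sdlog)),
      slow_bw = cfg$base_mix$slow_bw,
      slow_coherence = if (!high && lab %in% cfg$effect_electrodes) coher
                       else 0)
  }
  list(subject_id = sprintf("S%03d", i), group = group, age = age, sex = sex,
       score = score, n_epochs = n_epochs, gain = gain,
       electrode_gain = egain, per_electrode_mix = mixes,
       seed = child_seed(cfg$seed, i))
}

# Real-valued random-phase synthesis from a one-sided amplitude envelope
# evaluated on the positive FFT frequencies; returns a unit-SD series.
spectral_noise <- function(n, fs, envelope) {
  nf <- n %/% 2L
  f <- seq_len(nf) * fs / n
  amp <- envelope(f)
  if (all(amp == 0)) return(rep(0, n))
  ph <- runif(nf) * 2 * pi
  full <- complex(real = rep(0, n))
  if (n %% 2L == 0L) {
    full[2:nf] <- complex(modulus = amp[-nf], argument = ph[-nf])
    full[nf + 1L] <- complex(real = amp[nf] * sign(cos(ph[nf])))
    full[seq(n, nf + 2L)] <- Conj(full[2:nf])
  } else {
    full[2:(nf + 1L)] <- complex(modulus = amp, argument = ph)
    full[seq(n, nf + 2L)] <- Conj(full[2:(nf + 1L)])
  }
  x <- Re(fft(full, inverse = TRUE))
  x / sd(x)
}

# One channel realization of a noise_mix at sampling rate fs (unit SD).
synthesize_channel <- function(n, fs, mix, band = c(1, 60)) {
  in_band <- if (is.null(band)) function(f) rep(TRUE, length(f))
             else function(f) f >= band[1] & f <= band[2]
  bg <- spectral_noise(n, fs, function(f)
    ifelse(in_band(f), f^(-mix$beta / 2), 0))
  wh <- spectral_noise(n, fs, function(f) as.numeric(in_band(f)))
  sig <- sqrt(1 - mix$white_frac) * bg + sqrt(mix$white_frac) * wh
  if (mix$alpha_amp > 0)
    sig <- sig + mix$alpha_amp *
      spectral_noise(n, fs, function(f)
        exp(-(f - mix$alpha_freq)^2 / (2 * mix$alpha_bw^2)) * in_band(f))
  if (mix$slow_amp > 0) {
    coh <- mix$slow_coherence
    slow <- 0
    if (coh < 1)
      slow <- sqrt(1 - coh) *
        spectral_noise(n, fs, function(f)
          exp(-(f - mix$slow_freq)^2 / (2 * mix$slow_bw^2)) *
            as.numeric(f >= if (is.null(band)) 0 else band[1]))
    if (coh > 0)
      slow <- slow + sqrt(coh) * sqrt(2) *
        sin(2 * pi * mix$slow_freq * seq_len(n) / fs + runif(1) * 2 * pi)
    sig <- sig + mix$slow_amp * slow
  }
  sig / sd(sig)
}

#' Generate one subject's synthetic recording
#'
#' Builds the channels-by-samples signal for a subject specification: per
#' electrode an independent realization of the subject's noise mixture
#' (colored + white background, alpha rhythm, slow rhythm), synthesized
#' within the emulated 1-60 Hz acquisition band and scaled to the configured
#' microvolt amplitude times the subject and electrode gains. The recording
#' is a deterministic function of the spec's stored seed.
#'
#' @param spec A subject specification from [generate_cohort()] (element of
#'   `$specs`).
#' @param cfg The [cohort_config()] the spec was drawn under.
#' @return An [eeg_recording()].
#' @export
generate_subject_recording <- function(spec, cfg) {
  if (!all(names(spec$per_electrode_mix) %in% cfg$montage))
    stop("unknown electrode label(s) in spec: ",
         paste(setdiff(names(spec$per_electrode_mix), cfg$montage),
               collapse = ", "), call. = FALSE)
  dur <- max(cfg$duration, spec$n_epochs * cfg$epoch_len)
  n <- round(dur * cfg$fs)
  with_seed(spec$seed, {
    dat <- matrix(0, length(cfg$montage), n)
    for (k in seq_along(cfg$montage)) {
      mix <- spec$per_electrode_mix[[cfg$montage[k]]]
      sig <- synthesize_channel(n, cfg$fs, mix, cfg$acquisition_band)
      dat[k, ] <- sig * cfg$sd_uv * spec$gain *
        spec$electrode_gain[[cfg$montage[k]]]
    }
    eeg_recording(dat, fs = cfg$fs, labels = cfg$montage,
                  subject_id = spec$subject_id)
  })
}

#' Generate a two-group synthetic cohort
#'
#' Draws `n_high + n_low` subject specifications (demographics, cognitive
#' scores, per-electrode noise mixes with the slow-scale complexity effect at
#' the configured electrodes) and, optionally, their recordings. Identical
#' configurations (including seed) give byte-identical cohorts.
#'
#' @param cfg A [cohort_config()].
#' @param recordings Generate the signal matrices (default `TRUE`). With
#'   `FALSE` only the subject table and specs are returned; recordings can be
#'   created one at a time with [generate_subject_recording()], which keeps
#'   memory flat for long recordings.
#' @return List with `subjects` (data frame: subject_id, group, age, sex,
#'   score, n_epochs), `specs` (per-subject generative specifications) and
#'   `recordings` (named list of [eeg_recording()], or `NULL`).
#' @export
generate_cohort <- function(cfg, recordings = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  groups <- rep(c("high", "low"), c(cfg$n_high, cfg$n_low))
  specs <- with_seed(cfg$seed,
    lapply(seq_along(groups), function(i)
      generate_subject_spec(i, groups[i], cfg)))
  names(specs) <- vapply(specs, `[[`, character(1), "subject_id")
  subjects <- do.call(rbind, lapply(specs, function(s)
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, score = s$score, n_epochs = s$n_epochs)))
  rownames(subjects) <- NULL
  recs <- NULL
  if (recordings) {
    recs <- lapply(specs, generate_subject_recording, cfg = cfg)
    names(recs) <- names(specs)
  }
  list(subjects = subjects, specs = specs, recordings = recs)
}

#' Median split of cognitive scores
#'
#' Assigns `high` to scores strictly above the sample median and `low`
#' otherwise; scores tied with the median go to the low group (with a
#' warning), which keeps the split deterministic.
#'
#' @param scores Numeric vector of at least 2 finite totals.
#' @return Character vector of `"high"` / `"low"` labels.
#' @export
#' @examples
#' median_split(c(140, 150, 160, 170))
median_split <- function(scores) {
  if (!is.numeric(scores) || length(scores) < 2 || any(!is.finite(scores)))
    stop("`scores` must be >= 2 finite numbers", call. = FALSE)
  med <- median(scores)
  if (all(scores == med)) {
    warning("all scores tie at the median; assigning every subject to 'low'")
    return(rep("low", length(scores)))
  }
  if (any(scores == med))
    warning(sum(scores == med), " score(s) tie at the median; assigned to 'low'")
  ifelse(scores > med, "high", "low")
}

#' Write a cohort to disk as delimited fixtures
#'
#' One delimited matrix file per subject (see [write_delimited_matrix()])
#' plus `subjects.csv`; the exchange format consumed by the pipeline's
#' `matrix_dir` input mode. Set `format = "edf"` for EDF export instead.
#'
#' @param cohort Result of [generate_cohort()] (with recordings).
#' @param dir Output directory (created if needed).
#' @param format `"matrix"` (default) or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("matrix", "edf")) {
  format <- match.arg(format)
  if (is.null(cohort$recordings))
    stop("cohort has no recordings (generate with recordings = TRUE)",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (id in names(cohort$recordings)) {
    rec <- cohort$recordings[[id]]
    if (format == "matrix")
      write_delimited_matrix(rec, file.path(dir, paste0(id, ".csv")))
    else
      write_edf(rec, file.path(dir, paste0(id, ".edf")))
  }
  invisible(dir)
}
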
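pipeline_defaults <- function() {
  list(
    input = list(mode = "synthetic", dir = NULL),
    seed = 1,
    cohort = list(n_high = 22, n_low = 21, fs = 500, duration = 180,
                  effect_electrodes = effect_electrodes_default(),
                  effect_size = 0.07, montage = montage_1020(),
                  epoch_len = 20, n_epochs_range = c(8, 16),
                  beta = 1.5, alpha_freq = 9.5, alpha_amp = 0.8,
                  white_frac = 0.15, alpha_bw = 1, slow_freq = 1.4,
                  slow_amp = 0.9, slow_bw = 0.35,
                  beta_sd = 0.1, alpha_amp_sdlog = 0.15,
                  gain_sdlog = 0.2, electrode_gain_sdlog = 0.2,
                  slow_amp_sdlog = 0.2, acquisition_band = c(1, 60),
                  sd_uv = 8),
    preprocess = list(lo = 1, hi = 60, target_fs = 200, epoch_len = 20,
                      amp_thresh = 100),
    mse = list(m = 2, r = 0.2, max_scale = 40, bin_width = 5,
               r_mode = "per_scale"),
    welch = list(window_sec = 2, overlap = 0.5, fmin = 2, fmax = 60, df = 1,
                 regrid = "decimate"),
    stats = list(covariates = c("age", "sex"), q = 0.05, var_equal = TRUE),
    output_dir = NULL)
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Pipeline configuration
#'
#' Builds and schema-validates the configuration of the end-to-end analysis.
#' Accepts a YAML file path or a named list; unknown keys are rejected and
#' basic value constraints are checked before any computation. Sections:
#' `input` (mode: synthetic / matrix_dir / edf_dir, plus dir), `cohort`
#' (generator settings, used in synthetic mode), `preprocess` (band edges,
#' analysis rate, epoch length, amplitude threshold), `mse`, `welch`, `stats`,
#' `output_dir` and the mandatory `seed`.
#'
#' @param config YAML file path or named list of overrides (may be empty).
#' @return Object of class `pipeline_config` (a validated nested list).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML file path",
                             call. = FALSE)
  cfg <- merge_config(pipeline_defaults(), config)
  if (!cfg$input$mode %in% c("synthetic", "matrix_dir", "edf_dir"))
    stop("input.mode must be synthetic, matrix_dir or edf_dir", call. = FALSE)
  if (cfg$input$mode != "synthetic" && is.null(cfg$input$dir))
    stop("input.dir is required for mode '", cfg$input$mode, "'", call. = FALSE)
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    stop("a finite seed is mandatory", call. = FALSE)
  with(cfg$cohort, {
    if (!is.numeric(fs) || fs <= 0) stop("cohort.fs must be > 0", call. = FALSE)
    if (duration <= 0) stop("cohort.duration must be > 0", call. = FALSE)
  })
  with(cfg$preprocess, {
    if (lo <= 0 || hi <= lo) stop("preprocess band edges invalid", call. = FALSE)
    if (target_fs <= 2 * hi) stop("preprocess.target_fs must exceed 2*hi",
                                  call. = FALSE)
  })
  if (cfg$mse$max_scale %% cfg$mse$bin_width != 0)
    stop("mse.max_scale must be divisible by mse.bin_width", call. = FALSE)
  structure(cfg, class = c("pipeline_config", "list"))
}

cohort_config_from_pipeline <- function(cfg) {
  cc <- cfg$cohort
  cohort_config(n_high = cc$n_high, n_low = cc$n_low, fs = cc$fs,
                duration = cc$duration, seed = cfg$seed,
                effect_electrodes = cc$effect_electrodes,
                effect_size = cc$effect_size, montage = cc$montage,
                epoch_len = cc$epoch_len, n_epochs_range = cc$n_epochs_range,
                base_mix = noise_mix(beta = cc$beta,
                                     alpha_freq = cc$alpha_freq,
                                     alpha_amp = cc$alpha_amp,
                                     white_frac = cc$white_frac,
                                     alpha_bw = cc$alpha_bw,
                                     slow_freq = cc$slow_freq,
                                     slow_amp = cc$slow_amp,
                                     slow_bw = cc$slow_bw),
                beta_sd = cc$beta_sd, alpha_amp_sdlog = cc$alpha_amp_sdlog,
                gain_sdlog = cc$gain_sdlog,
                electrode_gain_sdlog = cc$electrode_gain_sdlog,
                slow_amp_sdlog = cc$slow_amp_sdlog,
                acquisition_band = cc$acquisition_band,
                sd_uv = cc$sd_uv)
}

stage <- function(name, subject, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed",
         if (nzchar(subject)) paste0(" for subject '", subject, "'"),
         ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' One call from configuration to results: obtain the cohort (synthetic
#' generation or reading a directory of per-subject files plus
#' `subjects.csv`), band-pass filter, downsample to the analysis rate,
#' segment into epochs and reject by amplitude, compute the multiscale
#' entropy profile and its scale-bin reduction, the Welch PSD matrix, the
#' mixed-design repeated-measures ANCOVA, and the FDR-controlled post-hoc
#' grids for both the entropy and PSD analyses. Deterministic given the
#' configured seed. When `output_dir` is set, writes `mse_profile.csv`,
#' `binned_profile.csv`, `psd.csv`, `ancova_table.csv`, `posthoc_mse.csv`,
#' `posthoc_psd.csv` and `run_log.txt`.
#'
#' @param config A [pipeline_config()], a named list of overrides, or a YAML
#'   file path.
#' @return Object of class `mse_pipeline_result`: list with `subjects`,
#'   `profile`, `binned`, `psd`, `ancova`, `posthoc_mse`, `posthoc_psd`,
#'   `rejections`, and the resolved `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  pp <- cfg$preprocess
  mse_cfg <- mse_config(m = cfg$mse$m, r = cfg$mse$r,
                        scales = seq_len(cfg$mse$max_scale),
                        bin_width = cfg$mse$bin_width, r_mode = cfg$mse$r_mode)

  if (cfg$input$mode == "synthetic") {
    ccfg <- cohort_config_from_pipeline(cfg)
    cohort <- stage("cohort", "", generate_cohort(ccfg, recordings = FALSE))
    subjects <- cohort$subjects
    get_rec <- function(id) generate_subject_recording(cohort$specs[[id]], ccfg)
  } else {
    tab_path <- file.path(cfg$input$dir, "subjects.csv")
    if (!file.exists(tab_path))
      stop("stage 'load' failed: missing ", tab_path, call. = FALSE)
    subjects <- read.csv(tab_path, stringsAsFactors = FALSE)
    ext <- if (cfg$input$mode == "edf_dir") ".edf" else ".csv"
    get_rec <- function(id) {
      f <- file.path(cfg$input$dir, paste0(id, ext))
      if (ext == ".edf") read_edf(f, require_full = FALSE, subject_id = id)
      else read_delimited_matrix(f, require_full = FALSE, subject_id = id)
    }
  }

  profiles <- list(); psds <- list(); rejections <- integer(0)
  for (id in subjects$subject_id) {
    rec <- stage("load", id, get_rec(id))
    rec <- stage("bandpass", id, bandpass(rec, pp$lo, pp$hi))
    if (pp$target_fs < rec$fs)
      rec <- stage("resample", id, resample_recording(rec, pp$target_fs))
    es <- stage("segment", id,
                segment(rec, pp$epoch_len, max_scale = cfg$mse$max_scale,
                        m = cfg$mse$m))
    es <- stage("reject_epochs", id, reject_epochs(es, pp$amp_thresh))
    rejections[id] <- length(es$rejected)
    profiles[[id]] <- stage("mse", id, epoch_mse(es, mse_cfg))
    psds[[id]] <- stage("welch", id,
                        welch_psd(es, cfg$welch$window_sec, cfg$welch$overlap,
                                  cfg$welch$fmin, cfg$welch$fmax, cfg$welch$df,
                                  cfg$welch$regrid))
  }
  profile <- mse_profile(profiles)
  binned <- bin_scales(profile)
  psd <- psd_matrix(psds)
  ancova <- stage("ancova", "",
                  fit_rm_ancova(binned, subjects, cfg$stats$covariates))
  ph_mse <- stage("posthoc", "",
                  posthoc_ttests(binned, subjects, cfg$stats$q,
                                 cfg$stats$var_equal))
  ph_psd <- stage("posthoc_psd", "",
                  psd_pointwise_tests(psd, subjects, cfg$stats$q,
                                      cfg$stats$var_equal))
  res <- structure(list(subjects = subjects, profile = profile,
                        binned = binned, psd = psd, ancova = ancova,
                        posthoc_mse = ph_mse, posthoc_psd = ph_psd,
                        rejections = rejections, config = cfg),
                   class = "mse_pipeline_result")
  if (!is.null(cfg$output_dir)) write_pipeline_outputs(res, cfg$output_dir)
  res
}

posthoc_long <- function(ph) {
  axis_vals <- if (ph$axis == "scale_bin") seq_len(ncol(ph$t)) else ph$freq
  out <- expand.grid(electrode = rownames(ph$t), axis = axis_vals,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(out)[2] <- if (ph$axis == "scale_bin") "scale_bin" else "freq_hz"
  out$t <- as.vector(ph$t)
  out$p <- as.vector(ph$p)
  out$significant <- as.vector(ph$mask)
  out
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(as.data.frame(res$profile), "mse_profile.csv")
  wr(as.data.frame(res$binned), "binned_profile.csv")
  wr(as.data.frame(res$psd), "psd.csv")
  wr(res$ancova$effects, "ancova_table.csv")
  wr(posthoc_long(res$posthoc_mse), "posthoc_mse.csv")
  wr(posthoc_long(res$posthoc_psd), "posthoc_psd.csv")
  log_lines <- c(
    paste0("eegmse ", as.character(utils::packageVersion("eegmse"))),
    paste0("seed: ", res$config$seed),
    paste0("subjects: ", nrow(res$subjects)),
    paste0("listwise dropped: ", res$ancova$n_dropped),
    "rejected epochs per subject:",
    paste0("  ", names(res$rejections), ": ", res$rejections),
    "config:",
    paste0("  ", strsplit(yaml::as.yaml(unclass(res$config)), "\n")[[1]]))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.mse_pipeline_result <- function(x, ...) {
  cat("<mse_pipeline_result> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$group == "high"), " high / ",
      sum(x$subjects$group == "low"), " low)\n\n", sep = "")
  print(x$ancova)
  cat("\nPost-hoc entropy grid: ")
  print(x$posthoc_mse)
  cat("PSD control grid: ")
  print(x$posthoc_psd)
  invisible(x)
}

#' Diverging-palette heatmap of a post-hoc t grid
#'
#' Two-panel figure: the raw t-values per electrode and scale bin (or
#' frequency point), and the FDR-masked version showing only cells passing
#' the q threshold. Warm colors mean a higher value in the high
#' cognitive-function group. The device is chosen from the file extension
#' (pdf, png or svg).
#'
#' @param grid A `posthoc_grid`.
#' @param path Output file path ending in .pdf, .png or .svg.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(grid, path) {
  stopifnot(inherits(grid, "posthoc_grid"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdf = grDevices::pdf(path, width = 9, height = 5),
         png = grDevices::png(path, width = 900, height = 500),
         svg = grDevices::svg(path, width = 9, height = 5),
         stop("unsupported figure format: .", ext, call. = FALSE))
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  lim <- max(abs(grid$t), na.rm = TRUE)
  xs <- if (grid$axis == "scale_bin") seq_len(ncol(grid$t)) else grid$freq
  xlab <- if (grid$axis == "scale_bin") "scale bin" else "frequency (Hz)"
  draw <- function(z, main) {
    graphics::image(xs, seq_len(nrow(z)), t(z), zlim = c(-lim, lim),
                    col = pal, xlab = xlab, ylab = "", yaxt = "n", main = main)
    graphics::axis(2, at = seq_len(nrow(z)), labels = rownames(grid$t),
                   las = 2, cex.axis = 0.6)
  }
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 3, 3, 1))
  on.exit(graphics::par(old), add = TRUE)
  draw(grid$t, "t (high - low)")
  masked <- grid$t
  masked[!grid$mask] <- NA
  draw(masked, paste0("FDR q < ", grid$q))
  invisible(path)
}
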
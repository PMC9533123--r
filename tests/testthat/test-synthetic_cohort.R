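test_that("noise mixes and cohort configurations validate their invariants", {
  expect_error(noise_mix(beta = -1), "beta")
  expect_error(noise_mix(white_frac = 1.5), "white_frac")
  expect_error(noise_mix(alpha_freq = 0.5), "pass-band")
  expect_error(noise_mix(slow_coherence = 2), "slow_coherence")
  expect_error(suppressWarnings(cohort_config(n_high = 1)), "2 subjects")
  expect_error(cohort_config(effect_electrodes = c("Fp1", "XX")),
               "outside the configured montage")
  expect_error(suppressWarnings(
    cohort_config(montage = c("Fp1", "Pz"), effect_electrodes = "Cz")),
    "outside the configured montage")
  expect_error(suppressWarnings(cohort_config(montage = c("Fp1", "QQ"))),
               "unknown electrode")
  expect_error(cohort_config(effect_size = 0.5), "effect_size")
  expect_warning(cohort_config(duration = 20, effect_size = 0), "180 s")
})

test_that("identical configurations give byte-identical cohorts", {
  cfg <- suppressWarnings(cohort_config(
    n_high = 3, n_low = 3, fs = 200, duration = 4, epoch_len = 2,
    n_epochs_range = c(2, 2), montage = c("Fp1", "Pz"),
    effect_electrodes = "Fp1", seed = 99))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$recordings[["S001"]]$data, b$recordings[["S001"]]$data)
  expect_identical(nrow(a$subjects), 6L)
  expect_identical(unname(c(table(a$subjects$group)[c("high", "low")])),
                   c(3L, 3L))

  cfg2 <- suppressWarnings(cohort_config(
    n_high = 3, n_low = 3, fs = 200, duration = 4, epoch_len = 2,
    n_epochs_range = c(2, 2), montage = c("Fp1", "Pz"),
    effect_electrodes = "Fp1", seed = 100))
  c2 <- generate_cohort(cfg2, recordings = FALSE)
  r2 <- generate_subject_recording(c2$specs[[1]], cfg2)
  expect_false(isTRUE(all.equal(a$recordings[["S001"]]$data, r2$data)))
})

test_that("the default study design has 43 subjects and ~12 epochs each", {
  cfg <- cohort_config(seed = 3)
  co <- generate_cohort(cfg, recordings = FALSE)
  expect_identical(nrow(co$subjects), 43L)
  expect_identical(sum(co$subjects$group == "high"), 22L)
  expect_identical(sum(co$subjects$group == "low"), 21L)
  expect_true(all(co$subjects$n_epochs >= 8 & co$subjects$n_epochs <= 16))
  expect_true(all(co$subjects$age >= 65 & co$subjects$age <= 85))
  # age distributions differ by group as in the emulated cohort
  expect_lt(mean(co$subjects$age[co$subjects$group == "high"]),
            mean(co$subjects$age[co$subjects$group == "low"]) + 2)
})

test_that("generated channels hit their amplitude targets exactly", {
  cfg <- suppressWarnings(cohort_config(
    n_high = 2, n_low = 2, fs = 200, duration = 10, epoch_len = 5,
    n_epochs_range = c(2, 2), montage = c("Fp1", "O1", "Pz"),
    effect_electrodes = "Fp1", seed = 7))
  co <- generate_cohort(cfg, recordings = FALSE)
  for (s in co$specs[1:2]) {
    rec <- generate_subject_recording(s, cfg)
    target <- cfg$sd_uv * s$gain * s$electrode_gain[rec$labels]
    got <- apply(rec$data, 1, function(x) sqrt(mean((x - mean(x))^2)))
    expect_true(all(abs(got / target - 1) < 0.05))
  }
  expect_error(
    generate_subject_recording(
      within(co$specs[[1]], names(per_electrode_mix)[1] <- "QQ"), cfg),
    "unknown electrode")
})

test_that("pure white mixes give flat entropy profiles (broadband synthesis)", {
  cfg <- suppressWarnings(cohort_config(
    n_high = 2, n_low = 2, fs = 200, duration = 240, epoch_len = 20,
    n_epochs_range = c(12, 12), montage = "Cz", effect_electrodes = "Cz",
    effect_size = 0,
    base_mix = noise_mix(beta = 0, white_frac = 1, alpha_amp = 0,
                         slow_amp = 0),
    beta_sd = 0, acquisition_band = NULL, seed = 8))
  co <- generate_cohort(cfg, recordings = FALSE)
  rec <- generate_subject_recording(co$specs[[1]], cfg)
  prof <- mse_profile(list(S1 = epoch_mse(segment(rec, 20), mse_config())))
  binned <- as.vector(bin_scales(prof)[1, 1, ])
  analytic <- -log(2 * pnorm(0.1 * sqrt(2)) - 1)
  expect_lt(max(binned) - min(binned), 0.3)
  expect_lt(abs(mean(binned) - analytic), 0.05)
})

test_that("a strong alpha mix puts the Welch peak at the alpha frequency", {
  cfg <- suppressWarnings(cohort_config(
    n_high = 2, n_low = 2, fs = 200, duration = 20, epoch_len = 10,
    n_epochs_range = c(2, 2), montage = c("Fp1", "O1"),
    effect_electrodes = "Fp1", effect_size = 0,
    base_mix = noise_mix(alpha_amp = 8, alpha_freq = 10, alpha_bw = 0.3),
    alpha_amp_sdlog = 0, seed = 9))
  co <- generate_cohort(cfg, recordings = FALSE)
  rec <- generate_subject_recording(co$specs[[1]], cfg)
  psd <- welch_psd(segment(rec, 10))
  f <- attr(psd, "freq")
  expect_true(all(f[apply(psd, 1, which.max)] == 10))
})

test_that("median split follows the strict-majority rule with low-group ties", {
  expect_identical(median_split(c(140, 150, 160, 170)),
                   c("low", "low", "high", "high"))
  set.seed(61)
  scores <- c(rnorm(21, 168.27, 10.04), rnorm(22, 142.52, 8.28))
  split <- suppressWarnings(median_split(scores))
  expect_gt(mean(split[1:21] == "high"), 0.85)      # recovers the clusters
  expect_gt(mean(split[22:43] == "low"), 0.85)
  expect_warning(out <- median_split(c(150, 150, 150)), "tie")
  expect_identical(out, rep("low", 3))
  expect_error(median_split(150), "2 finite")
})

test_that("the injected effect raises high-group slow-scale entropy", {
  eff <- c("Fp1", "F3", "T5", "Pz")
  wins <- 0
  for (s in 1:20) {
    cfg <- suppressWarnings(cohort_config(
      n_high = 12, n_low = 12, fs = 200, duration = 24, epoch_len = 8,
      n_epochs_range = c(3, 3), montage = c("Fp1", "F3", "T5", "Pz", "O1", "Cz"),
      effect_electrodes = eff, seed = 500 + s))
    co <- generate_cohort(cfg, recordings = FALSE)
    slow <- vapply(co$specs, function(sp) {
      rec <- generate_subject_recording(sp, cfg)
      prof <- suppressWarnings(epoch_mse(segment(rec, 8), mse_config()))
      mean(prof[eff, 11:40], na.rm = TRUE)
    }, numeric(1))
    g <- co$subjects$group
    wins <- wins + (mean(slow[g == "high"]) > mean(slow[g == "low"]))
  }
  expect_gte(wins, 19)
})

test_that("cohorts round-trip through the delimited fixture format", {
  cfg <- suppressWarnings(cohort_config(
    n_high = 2, n_low = 2, fs = 200, duration = 4, epoch_len = 2,
    n_epochs_range = c(2, 2), montage = c("Fp1", "Pz"),
    effect_electrodes = "Fp1", seed = 10))
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  back <- read_delimited_matrix(file.path(dir, "S001.csv"),
                                require_full = FALSE, subject_id = "S001")
  expect_equal(back$data, co$recordings[["S001"]]$data, tolerance = 1e-9)
})
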
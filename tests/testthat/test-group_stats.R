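test_that("Greenhouse-Geisser epsilon hits its analytic limits", {
  k <- 5
  cs <- matrix(0.3, k, k); diag(cs) <- 1          # compound symmetry
  expect_equal(greenhouse_geisser_epsilon(cs), 1)

  v <- seq_len(4)
  expect_equal(greenhouse_geisser_epsilon(tcrossprod(v)), 1 / 3)

  # random PSD matrix vs the textbook formula on orthonormalized contrasts
  set.seed(41)
  A <- matrix(rnorm(16), 4)
  S <- crossprod(A)
  M <- qr.Q(qr(cbind(1, contr.helmert(4))))[, -1]
  Sc <- t(M) %*% S %*% M
  eps_direct <- sum(diag(Sc))^2 / (3 * sum(diag(Sc %*% Sc)))
  expect_equal(greenhouse_geisser_epsilon(S), eps_direct, tolerance = 1e-10)

  expect_error(greenhouse_geisser_epsilon(matrix(1, 1, 1)), "dimension")
  expect_error(greenhouse_geisser_epsilon(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("the mixed ANCOVA engine matches car::Anova (type III) exactly", {
  binned <- toy_binned(n = 10, E = 3, B = 2, seed = 42)
  subj <- toy_subjects(n = 10, seed = 43)
  fit <- fit_rm_ancova(binned, subj)

  Y <- matrix(unclass(binned), 10, 6)
  idata <- expand.grid(node = factor(dimnames(binned)[[2]],
                                     levels = dimnames(binned)[[2]]),
                       scale = factor(1:2))
  df <- data.frame(group = factor(subj$group, levels = c("low", "high")),
                   age = subj$age - mean(subj$age),
                   sex = as.numeric(factor(subj$sex)) - 1)
  mod <- lm(Y ~ age + sex + group, data = df,
            contrasts = list(group = "contr.sum"))
  s <- suppressWarnings(
    summary(car::Anova(mod, idata = idata, idesign = ~ node * scale,
                       type = 3), multivariate = FALSE))
  ref <- s$univariate.tests
  expect_equal(fit$effects$F,
               unname(ref[c("group", "group:scale", "group:node",
                            "group:node:scale"), "F value"]),
               tolerance = 1e-6)
  expect_equal(fit$effects$p,
               unname(ref[c("group", "group:scale", "group:node",
                            "group:node:scale"), "Pr(>F)"]),
               tolerance = 1e-6)
  adj <- s$pval.adjustments
  expect_equal(fit$effects$gg_epsilon[3], unname(adj["group:node", "GG eps"]),
               tolerance = 1e-6)
  expect_equal(fit$effects$gg_p[3], unname(adj["group:node", "Pr(>F[GG])"]),
               tolerance = 1e-6)
  expect_equal(fit$effects$gg_p[4],
               unname(adj["group:node:scale", "Pr(>F[GG])"]), tolerance = 1e-6)
})

test_that("sphericity violation pushes epsilon below 1 and inflates p", {
  set.seed(44)
  n <- 16; B <- 4
  base <- rnorm(n)
  # heteroscedastic, correlated bins -> non-spherical within covariance
  arr <- array(NA_real_, c(n, 2, B),
               dimnames = list(sprintf("S%02d", 1:n), c("Fp1", "Pz"),
                               paste0("bin", 1:B)))
  for (b in 1:B) arr[, , b] <- cbind(base * b + rnorm(n, sd = 0.3 * b),
                                     base * b + rnorm(n, sd = 0.3 * b))
  binned <- structure(arr, bins = data.frame(bin = 1:B),
                      cfg = mse_config(scales = 1:(5 * B)), fs = 200,
                      class = "scale_bin_profile")
  fit <- fit_rm_ancova(binned, toy_subjects(n = 16, seed = 45))
  expect_lt(fit$effects$gg_epsilon[2], 1)
  up <- fit$effects$F >= 1 & !is.na(fit$effects$gg_epsilon)
  expect_true(all(fit$effects$gg_p[up] >= fit$effects$p[up] - 1e-12))
})

test_that("singular between-subject designs fail informatively", {
  binned <- toy_binned(n = 8, seed = 46)
  subj <- toy_subjects(n = 8, seed = 47)
  subj$sex <- "F"                                   # constant covariate column
  expect_error(fit_rm_ancova(binned, subj), "singular")
})

test_that("subjects with undefined cells are dropped listwise with a message", {
  binned <- toy_binned(n = 10, seed = 48)
  binned[3, 1, 1] <- NA
  expect_message(fit <- fit_rm_ancova(binned, toy_subjects(n = 10, seed = 49)),
                 "listwise")
  expect_identical(fit$n_subjects, 9L)
  expect_identical(fit$n_dropped, 1L)
})

test_that("BH step-up matches its definition, p.adjust and enumeration", {
  out <- bh_fdr(c(0.001, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(out$mask))
  expect_equal(out$critical_p, 0.04)

  out <- bh_fdr(rep(0.5, 152), 0.05)
  expect_false(any(out$mask))
  expect_equal(out$critical_p, 0)

  expect_true(bh_fdr(0.01, 0.05)$mask)
  expect_false(bh_fdr(0.06, 0.05)$mask)

  set.seed(51)
  for (i in 1:20) {
    p <- runif(sample(5:40, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    mask <- bh_fdr(p, q)$mask
    expect_identical(mask, unname(p.adjust(p, "BH") <= q) & TRUE)
    o <- sample(seq_along(p))
    expect_identical(bh_fdr(p[o], q)$mask, mask[o])  # order invariance
  }

  set.seed(52)
  for (i in 1:5) {
    p <- round(runif(8), 3)
    expect_identical(bh_fdr(p, 0.05)$mask, bh_enumerate(p, 0.05))
  }

  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("post-hoc grids have the study shape and sign convention", {
  n <- 12
  arr <- array(rnorm(n * 19 * 8), c(n, 19, 8),
               dimnames = list(sprintf("S%02d", 1:n), montage_1020(),
                               paste0("bin", 1:8)))
  binned <- structure(arr, bins = data.frame(bin = 1:8),
                      cfg = mse_config(), fs = 200,
                      class = "scale_bin_profile")
  subj <- toy_subjects(n = n, seed = 53)
  ph <- posthoc_ttests(binned, subj)
  expect_identical(dim(ph$t), c(19L, 8L))
  expect_identical(ph$n_tests, 152L)

  # raise the high group at one cell -> positive t there
  shifted <- binned
  shifted[subj$group == "high", "Fz", 2] <- shifted[subj$group == "high", "Fz", 2] + 10
  ph2 <- posthoc_ttests(shifted, subj)
  expect_gt(ph2$t["Fz", 2], 5)

  # identical samples in both groups -> t = 0, p = 1
  same <- binned
  same[subj$group == "low", , ] <- same[subj$group == "high", , ]
  ph3 <- posthoc_ttests(same, subj)
  expect_true(all(abs(ph3$t) < 1e-12))
  expect_true(all(ph3$p > 1 - 1e-12))
})

test_that("PSD pointwise grid covers 19 x 59 tests and an empty-null mask", {
  n <- 10
  arr <- array(rnorm(n * 19 * 59), c(n, 19, 59),
               dimnames = list(sprintf("S%02d", 1:n), montage_1020(),
                               seq(2, 60)))
  psd <- structure(arr, freq = seq(2, 60), class = "psd_matrix")
  subj <- toy_subjects(n = n, seed = 54)
  ph <- psd_pointwise_tests(psd, subj)
  expect_identical(ph$n_tests, 1121L)
  same <- psd
  same[subj$group == "low", , ] <- same[subj$group == "high", , ]
  expect_false(any(psd_pointwise_tests(same, subj)$mask))
})

test_that("long tables carry one row per subject-electrode-bin cell", {
  binned <- toy_binned(n = 6, E = 3, B = 2, seed = 55)
  tbl <- make_long_table(binned, toy_subjects(n = 6, seed = 56))
  expect_identical(nrow(tbl), 6L * 3L * 2L)
  expect_true(all(c("subject_id", "group", "age", "sex", "electrode",
                    "scale_bin", "value") %in% names(tbl)))
  expect_identical(sum(tbl$subject_id == "S01"), 6L)
})
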
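test_that("coarse-graining implements non-overlapping window means", {
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  x <- rnorm(17)
  expect_identical(coarse_grain(x, 1), x)
  expect_equal(coarse_grain(c(2, 4, 6, 8), 3), 4)     # remainder dropped
  expect_error(coarse_grain(x, 0), "tau")
  expect_error(coarse_grain(x, 18), "tau")
})

test_that("z-scoring uses the population SD and masks constant series", {
  z <- zscore_series(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)
  expect_null(zscore_series(c(5, 5, 5)))
  x <- rnorm(50)
  expect_equal(zscore_series(zscore_series(x)), zscore_series(x))
})

test_that("sample entropy matches the quadratic-time reference exactly", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(30:300, 1)
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 0.5)
    y <- rnorm(n)
    a <- sample_entropy(y, m, r)
    b <- naive_sampen(y, m, r)
    if (is.na(b)) expect_true(is.na(a)) else expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("sample entropy behaves at analytic and degenerate limits", {
  set.seed(5)
  y <- zscore_series(rnorm(10000))
  analytic <- -log(2 * pnorm(0.1 * sqrt(2)) - 1)     # -ln(erf(0.1))
  expect_equal(sample_entropy(y, 2, 0.2), analytic, tolerance = 0.1)

  alt <- rep(c(0, 1), 100)                            # perfect regularity
  expect_equal(sample_entropy(alt, 2, 0.2), 0)

  expect_true(is.na(sample_entropy(c(0, 10, -10, 20, -20), 2, 0.2)))
  expect_error(sample_entropy(rnorm(3), 2, 0.2), "length")
})

test_that("entropy decreases as the tolerance grows", {
  set.seed(9)
  y <- zscore_series(rnorm(5000))
  e <- vapply(c(0.1, 0.2, 0.5), function(r) sample_entropy(y, 2, r), numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("the batched per-scale path equals the composed operations", {
  set.seed(21)
  x <- rnorm(1500)
  for (mode in c("per_scale", "global")) {
    cfg <- mse_config(scales = 1:20, r_mode = mode)
    r_ref <- 0.2 * sqrt(mean((x - mean(x))^2))
    batched <- eegmse:::mse_scales_cpp(x, cfg$scales, cfg$m, cfg$r,
                                       mode == "per_scale", r_ref)
    composed <- vapply(cfg$scales, function(tau)
      eegmse:::scale_entropy(x, tau, cfg, r_ref), numeric(1))
    expect_equal(batched, composed, tolerance = 1e-12)
  }
})

test_that("epoch averaging is the identity for one epoch and for duplicates", {
  set.seed(3)
  x <- matrix(rnorm(2 * 1000), 2, 1000)
  cfg <- mse_config(scales = 1:10)
  one <- epoch_mse(epochs_from_matrix(list(x), labels = c("Fp1", "Pz")), cfg)
  direct <- t(vapply(1:2, function(ch) {
    r_ref <- cfg$r * sqrt(mean((x[ch, ] - mean(x[ch, ]))^2))
    vapply(cfg$scales, function(tau)
      eegmse:::scale_entropy(x[ch, ], tau, cfg, r_ref), numeric(1))
  }, numeric(10)))
  expect_equal(unname(unclass(one)), direct, tolerance = 1e-12,
               ignore_attr = TRUE)

  two <- epoch_mse(epochs_from_matrix(list(x, x), labels = c("Fp1", "Pz")), cfg)
  expect_equal(unclass(two), unclass(one), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(attr(two, "n_epochs_used") == 2))
})

test_that("scale-40 coarse series of a 4000-sample epoch has exactly 100 points", {
  expect_length(coarse_grain(rnorm(4000), 40), 100)
})

test_that("scale bins average five scales and carry time-range labels", {
  set.seed(13)
  profs <- list(S1 = epoch_mse(epochs_from_matrix(list(matrix(rnorm(4000), 1))),
                               mse_config()))
  prof <- mse_profile(profs)
  binned <- bin_scales(prof)
  expect_identical(dim(binned)[3], 8L)
  b <- attr(binned, "bins")
  expect_equal(b$ms_lo, c(5, 30, 55, 80, 105, 130, 155, 180))
  expect_equal(b$ms_hi, c(25, 50, 75, 100, 125, 150, 175, 200))
  expect_equal(unname(binned[1, 1, 3]), mean(prof[1, 1, 11:15]))

  const <- prof
  const[, , ] <- 1.7
  expect_true(all(abs(bin_scales(const) - 1.7) < 1e-12))

  expect_error(bin_scales(prof, 7), "not divisible")
})

test_that("white-noise binned profiles are flat and near the analytic level", {
  set.seed(17)
  eps <- lapply(1:12, function(e) matrix(rnorm(4000), 1))
  prof <- mse_profile(list(S1 = epoch_mse(epochs_from_matrix(eps),
                                          mse_config())))
  binned <- as.vector(bin_scales(prof)[1, 1, ])
  analytic <- -log(2 * pnorm(0.1 * sqrt(2)) - 1)
  expect_lt(max(binned) - min(binned), 0.3)
  expect_lt(max(abs(binned - analytic)), 0.3)
  expect_lt(abs(mean(binned) - analytic), 0.05)
})
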
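test_that("a single factor recovers a rank-1 relationship exactly", {
  set.seed(51)
  n <- 15; p <- 40
  b <- rnorm(p)
  X <- matrix(rnorm(n * p), n, p)
  y <- as.vector(X %*% b) # X itself full rank; y exactly linear in X
  # rank-1 X: scores along one direction
  t1 <- rnorm(n)
  X1 <- outer(t1, b)
  y1 <- 3 * t1
  m <- fit_mpls(X1, y1, 1)
  expect_lt(max(abs(y1 - m$fitted)), 1e-8)
})

test_that("with unit scalings MPLS equals the kernel PLS1 oracle", {
  set.seed(52)
  for (i in 1:8) {
    n <- sample(8:20, 1); p <- sample(10:50, 1)
    A <- sample(1:min(6, n - 2), 1)
    X <- matrix(rnorm(n * p), n, p); y <- rnorm(n)
    Xn <- matrix(rnorm(4 * p), 4, p)
    m <- fit_mpls(X, y, A, scale = FALSE)
    expect_lt(max(abs(predict(m, Xn) - kernel_pls1_predict(X, y, A, Xn))),
              1e-8)
  }
})

test_that("prediction is consistent with fitting and centering", {
  set.seed(53)
  X <- matrix(rnorm(12 * 30), 12, 30); y <- rnorm(12)
  m <- fit_mpls(X, y, 3)
  expect_equal(unname(predict(m, X)), unname(m$fitted), tolerance = 1e-12)
  expect_equal(unname(predict(m, matrix(m$x_mean, 1))), m$y_mean,
               tolerance = 1e-10)
  two <- predict(m, X[c(4, 4), , drop = FALSE])
  expect_equal(two[1], two[2])
  m0 <- fit_mpls(X, y, 0)
  expect_equal(unname(predict(m0, X)), rep(mean(y), 12))
  expect_error(predict(m, X[, 1:10]), "wavelengths")
})

test_that("training RSQ never decreases with more factors", {
  set.seed(54)
  X <- matrix(rnorm(20 * 35), 20, 35); y <- rnorm(20)
  rsqs <- vapply(1:8, function(a)
    cor(y, fit_mpls(X, y, a)$fitted)^2, numeric(1))
  expect_true(all(diff(rsqs) > -1e-10))
})

test_that("cross-validation chooses factors by minimum SECV", {
  set.seed(55)
  X <- matrix(rnorm(24 * 30), 24, 30); y <- rnorm(24)
  cv1 <- choose_factors_cv(X, y, 1)
  expect_equal(cv1$chosen, 1L)
  expect_named(cv1$secv, "1")
  # pure noise: SECV at 1 factor stays near sd(y)
  secvs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    Xr <- matrix(rnorm(80 * 20), 80, 20); yr <- rnorm(80)
    choose_factors_cv(Xr, yr, 1)$secv[[1]] / sd(yr)
  }, numeric(1))
  expect_true(all(abs(secvs - 1) < 0.2))
  # groups are systematic (index modulo)
  expect_equal(cv1$groups, ((seq_len(24) - 1L) %% 4L) + 1L)
})

test_that("CV finds at least the true dimension of multi-component data", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(200 + s)
    n <- 36; p <- 40
    Tsc <- matrix(rnorm(n * 3), n, 3)
    L <- matrix(rnorm(3 * p), 3, p)
    X <- Tsc %*% L + matrix(rnorm(n * p, 0, 0.01), n, p)
    y <- Tsc %*% c(1, -0.5, 0.25) + rnorm(n, 0, 0.01)
    cv <- choose_factors_cv(X, as.vector(y), 6)
    if (cv$chosen >= 3L) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("outlier elimination removes gross y-errors and honours the cap", {
  set.seed(57)
  n <- 60; p <- 50
  Tsc <- matrix(rnorm(n * 2), n, 2)
  X <- Tsc %*% matrix(rnorm(2 * p), 2, p) + matrix(rnorm(n * p, 0, 0.01), n, p)
  y <- as.vector(Tsc %*% c(2, 1)) + rnorm(n, 0, 0.05)
  ids <- sprintf("s%02d", seq_len(n))
  clean <- eliminate_outliers(X, y, ids = ids)
  expect_equal(nrow(clean$report), 0L)
  expect_equal(clean$passes, 1L)
  # corrupt one sample by +10 sd(y)
  y_bad <- y; y_bad[17] <- y[17] + 10 * sd(y)
  res <- eliminate_outliers(X, y_bad, ids = ids)
  expect_true("s17" %in% res$report$sample_id)
  expect_equal(res$report$pass[res$report$sample_id == "s17"], 1L)
  expect_true(all(abs(res$report$t) > 2.5))
  # 20 corrupted samples: removals stop at the cap of 10
  y_many <- y
  y_many[1:20] <- y[1:20] + 10 * sd(y)
  many <- eliminate_outliers(X, y_many, ids = ids, max_passes = 5)
  expect_lte(nrow(many$report), 10L)
})

test_that("predictions are invariant to pre-SNV gain and offset", {
  set.seed(58)
  cfg <- synthetic_config(40, seed = 58, noise_sd = 1e-4)
  refs <- simulate_concentrations(40, cfg$traits, seed = 58)
  sp <- simulate_spectra(refs, cfg, seed = NA)
  tr <- parse_math_treatment("2,4,6,1", scatter = "snv-dt")
  Xt <- apply_pretreatment(sp, tr)$absorbance
  y <- refs$protein
  m <- fit_mpls(Xt, y, 4)
  scaled <- spectra_set(1.7 * sp$absorbance + 0.3, sp$wavelengths_nm,
                        sample_ids(sp))
  Xt2 <- apply_pretreatment(scaled, tr)$absorbance
  expect_lt(max(abs(predict(m, Xt2) - predict(m, Xt))), 1e-8)
})

test_that("models survive the JSON round trip bit-stably", {
  set.seed(59)
  X <- matrix(rnorm(15 * 25), 15, 25); y <- rnorm(15)
  m <- fit_mpls(X, y, 3)
  m$trait <- "protein"
  m$treatment <- parse_math_treatment("2,4,6,1", "snv-dt")
  m$wavelengths <- seq(1000, by = 2, length.out = 25)
  path <- withr::local_tempfile(fileext = ".json")
  write_mpls_model(m, path)
  back <- read_mpls_model(path)
  expect_lt(max(abs(predict(back, X) - predict(m, X))), 1e-10)
  expect_equal(back$trait, "protein")
  expect_equal(format(back$treatment), "2,4,6,1")
  expect_error(read_mpls_model(
    withr::local_tempfile(lines = "{\"format\": \"other\"}",
                          fileext = ".json")), "not an MPLS")
})

test_that("calibrate_trait reports the table fields of its chain", {
  cfg <- synthetic_config(81, seed = 61)
  refs <- simulate_concentrations(81, cfg$traits, seed = 61)
  sp <- simulate_spectra(refs, cfg, seed = NA)
  res <- calibrate_trait(sp, refs, "protein", "2,4,6,1")
  expect_s3_class(res, "calibration_result")
  expect_equal(res$treatment, "2,4,6,1")
  kept <- refs$protein[match(res$calibration_ids, refs$sample_id)]
  expect_equal(res$range, c(min(kept), max(kept)))
  expect_equal(res$n, length(res$calibration_ids))
  expect_gte(res$rsq, 0.95) # low-noise parameter recovery
  expect_equal(res$one_minus_vr,
               1 - res$secv^2 * res$n / sum((kept - mean(kept))^2),
               tolerance = 1e-10)
  expect_error(calibrate_trait(sp, refs[1:10, ], "protein", "2,4,6,1"),
               "need >= 20")
})
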
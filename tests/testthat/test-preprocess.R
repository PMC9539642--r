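test_that("math-treatment codes parse into derivative/gap/smoothing fields", {
  tr <- parse_math_treatment("2,4,6,1", scatter = "snv-dt")
  expect_equal(tr[c("derivative", "gap", "smooth1", "smooth2")],
               list(derivative = 2L, gap = 4L, smooth1 = 6L, smooth2 = 1L))
  expect_equal(tr$scatter, "snv-dt")
  expect_equal(format(parse_math_treatment("3,4,4,1")), "3,4,4,1")
  ident <- parse_math_treatment("0,0,1,1")
  expect_equal(ident$derivative, 0L)
  expect_error(parse_math_treatment("2,4,6"), "four")
  expect_error(parse_math_treatment("2,-1,6,1"), "non-negative")
  expect_error(parse_math_treatment("2,0,6,1"), "gap")
})

test_that("SNV standardises to population mean 0 / sd 1 and is affine-invariant", {
  set.seed(3)
  x <- runif(200, 0.1, 1.2)
  z <- snv(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-12)
  expect_equal(snv(3.7 * x + 0.42), z, tolerance = 1e-12)
  expect_equal(snv(z), z, tolerance = 1e-10) # idempotent
  # frozen hand case, population (n-denominator) convention:
  # sd_pop(1:4) = sqrt(1.25), so (1 - 2.5)/sqrt(1.25) = -1.3416408
  expect_equal(snv(c(1, 2, 3, 4)),
               c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)
  expect_error(snv(rep(0.3, 50)), "zero-variance")
})

test_that("detrend removes exactly the fitted polynomial", {
  g <- seq(400, 2498, by = 2)
  quad <- 2 + 0.001 * g - 2e-7 * g^2
  expect_lt(max(abs(detrend(quad, g))), 1e-8)
  band <- 0.5 * exp(-(g - 1600)^2 / (2 * 40^2))
  resid <- as.vector(detrend(quad + band, g))
  # orthogonal to the polynomial basis (after column scaling)
  basis <- cbind(1, poly(g, 2))
  expect_lt(max(abs(crossprod(basis, resid))), 1e-8)
  # band preserved up to the quadratic component an independent fit removes
  oracle <- residuals(lm(band ~ g + I(g^2)))
  expect_equal(resid, unname(oracle), tolerance = 1e-8)
  expect_error(detrend(c(1, 2, 3), c(400, 400, 404)), "repeated")
})

test_that("gap-segment derivative has exact finite-difference behaviour", {
  g <- seq(400, 598, by = 2)
  const <- rep(0.7, length(g))
  for (code in c("1,4,1,1", "2,4,6,1", "3,4,4,1")) {
    tr <- parse_math_treatment(code)
    out <- gap_segment_derivative(const, tr, g)
    expect_lt(max(abs(out$absorbance)), 1e-14)
  }
  # line: first derivative with even gap g equals g * step * slope
  slope <- 0.003
  lin <- 0.1 + slope * g
  for (gap in c(2, 4, 8)) {
    tr <- math_treatment(1, gap, 1, 1)
    out <- gap_segment_derivative(lin, tr, g)
    expect_equal(out$absorbance,
                 rep(gap * 2 * slope, length(out$absorbance)),
                 tolerance = 1e-12)
  }
  # quadratic under "2,4,1,1": both difference passes shift by
  # ceiling(4/2) = 2 points, so the exact value is the second central
  # difference with offset 4 points (8 nm)
  quad <- 1e-5 * g^2
  tr <- parse_math_treatment("2,4,1,1")
  out <- gap_segment_derivative(quad, tr, g)
  i <- seq(5, length(g) - 4)
  oracle <- quad[i + 4] - 2 * quad[i] + quad[i - 4]
  expect_equal(out$absorbance, oracle, tolerance = 1e-12)
  expect_equal(out$wavelengths, g[i])
})

test_that("the treated grid shrinks by the documented margin", {
  g <- seq(400, 598, by = 2)
  x <- runif(length(g))
  cases <- list(c("0,0,1,1", 0), c("2,4,6,1", 2 * 2 + 3), c("2,8,8,1", 2 * 4 + 4),
                c("2,4,4,1", 2 * 2 + 2), c("3,4,4,1", 3 * 2 + 2),
                c("1,3,5,3", 2 + 2 + 1))
  for (cs in cases) {
    tr <- parse_math_treatment(cs[[1]])
    expect_equal(treatment_margin(tr), as.integer(cs[[2]]), label = cs[[1]])
    out <- gap_segment_derivative(x, tr, g)
    expect_length(out$absorbance, length(g) - 2 * treatment_margin(tr))
  }
  expect_error(gap_segment_derivative(runif(5), parse_math_treatment("2,8,8,1")),
               "shorter")
})

test_that("the derivative operator is linear", {
  set.seed(21)
  g <- seq(400, 798, by = 2)
  x <- runif(length(g)); y <- runif(length(g))
  tr <- parse_math_treatment("2,4,6,1")
  lhs <- gap_segment_derivative(2.5 * x - 1.3 * y, tr, g)$absorbance
  rhs <- 2.5 * gap_segment_derivative(x, tr, g)$absorbance -
         1.3 * gap_segment_derivative(y, tr, g)$absorbance
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("apply_pretreatment chains scatter correction and derivative", {
  set <- random_spectra_set(n = 3, p = 80, seed = 5)
  ident <- math_treatment(0, 0, 1, 1, scatter = "none")
  expect_equal(apply_pretreatment(set, ident)$absorbance, set$absorbance)
  # gain/offset nuisance collapses under SNV-DT
  g <- set$wavelengths_nm
  x <- set$absorbance[1, ]
  pair <- spectra_set(rbind(x, 1.8 * x + 0.25), g, c("u", "v"))
  tr <- parse_math_treatment("2,4,4,1", scatter = "snv-dt")
  treated <- apply_pretreatment(pair, tr)
  expect_lt(max(abs(treated$absorbance[1, ] - treated$absorbance[2, ])), 1e-10)
  expect_equal(length(treated$wavelengths_nm),
               length(g) - 2 * treatment_margin(tr))
})

test_that("pretreatment shrinks between-replicate scatter variance", {
  # replicates of one sample differing only by the nuisance model
  cfg <- synthetic_config(1, seed = 303)
  refs <- simulate_concentrations(1, cfg$traits, seed = 303)
  refs <- refs[rep(1, 24), ]
  refs$sample_id <- sprintf("rep%02d", 1:24)
  reps <- simulate_spectra(refs, synthetic_config(
    24, seed = 304, scatter_mult_sd = 0.1, baseline_offset_sd = 0.05,
    baseline_tilt_sd = 0.05, noise_sd = 1e-4))
  tr <- parse_math_treatment("2,4,6,1", scatter = "snv-dt")
  treated <- apply_pretreatment(reps, tr)
  # dispersion between replicates, relative to the signal energy, must
  # shrink once the gain/offset/tilt nuisance is corrected away
  rel_disp <- function(M) mean(apply(M, 2, var)) / mean(M^2)
  expect_lt(rel_disp(treated$absorbance), rel_disp(reps$absorbance) / 10)
})
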
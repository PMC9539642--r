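test_that("default trait specs carry the panel's descriptive statistics", {
  specs <- default_trait_specs()
  expect_named(specs, c("protein", "starch", "tdf", "phenols", "phytate"))
  expect_equal(specs$protein$mean, 24.0)
  expect_equal(specs$protein$sd, 1.54)
  expect_equal(c(specs$phenols$min, specs$phenols$max), c(0.03, 0.832))
  for (sp in specs) {
    expect_lte(sp$min, sp$mean)
    expect_lte(sp$mean, sp$max)
    expect_gt(sp$sd, 0)
  }
  expect_error(trait_spec("x", 5, 1, 6, 7, list(component_band(1500, 10, 1))),
               "min <= mean")
  expect_error(component_band(1500, -1, 1), "width")
})

test_that("simulated concentrations respect truncation, seed and moments", {
  specs <- default_trait_specs()
  refs <- simulate_concentrations(500, specs, seed = 81)
  for (tr in names(specs)) {
    expect_true(all(refs[[tr]] >= specs[[tr]]$min))
    expect_true(all(refs[[tr]] <= specs[[tr]]$max))
  }
  expect_identical(refs, simulate_concentrations(500, specs, seed = 81))
  big <- simulate_concentrations(10000, specs["protein"], seed = 82)
  expect_lt(abs(mean(big$protein) - 24.0), 0.1)
  bad <- specs
  bad$protein$max <- 10 # infeasible truncation window
  expect_error(simulate_concentrations(5, bad["protein"], seed = 83),
               "rejection failed")
})

test_that("clean spectra are linear (Beer-Lambert) in concentrations", {
  specs <- default_trait_specs()["protein"]
  cfg <- synthetic_config(2, seed = 84, traits = specs,
                          scatter_mult_sd = 0, baseline_offset_sd = 0,
                          baseline_tilt_sd = 0, noise_sd = 0,
                          matrix_bands = NULL)
  refs <- data.frame(sample_id = c("a", "b"), protein = c(10, 20))
  sp <- simulate_spectra(refs, cfg)
  expect_equal(sp$absorbance[2, ], 2 * sp$absorbance[1, ], tolerance = 1e-12)
  # superposition across two traits
  cfg2 <- synthetic_config(3, seed = 85, scatter_mult_sd = 0,
                           baseline_offset_sd = 0, baseline_tilt_sd = 0,
                           noise_sd = 0, matrix_bands = NULL)
  r3 <- data.frame(sample_id = c("p", "q", "pq"),
                   protein = c(20, 0, 20), starch = c(0, 30, 30),
                   tdf = 0, phenols = 0, phytate = 0)
  s3 <- simulate_spectra(r3, cfg2)
  expect_equal(s3$absorbance["pq", ],
               s3$absorbance["p", ] + s3$absorbance["q", ],
               tolerance = 1e-12)
})

test_that("SNV-DT cancels the generator's nuisance model exactly", {
  cfg <- synthetic_config(12, seed = 86, scatter_mult_sd = 0.1,
                          baseline_offset_sd = 0.05, baseline_tilt_sd = 0.05,
                          noise_sd = 0)
  refs <- simulate_concentrations(1, cfg$traits, seed = 86)
  refs <- refs[rep(1, 12), ]
  refs$sample_id <- sprintf("r%02d", 1:12)
  sp <- simulate_spectra(refs, cfg, seed = NA)
  treated <- apply_pretreatment(sp, parse_math_treatment("2,4,6,1", "snv-dt"))
  spread <- apply(treated$absorbance, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-8)
})

test_that("noiseless mixtures are exactly recoverable by MPLS", {
  cfg <- synthetic_config(40, seed = 87, scatter_mult_sd = 0,
                          baseline_offset_sd = 0, baseline_tilt_sd = 0,
                          noise_sd = 0, matrix_bands = NULL)
  refs <- simulate_concentrations(40, cfg$traits, seed = 87)
  sp <- simulate_spectra(refs, cfg, seed = NA)
  m <- fit_mpls(sp$absorbance, refs$protein, length(cfg$traits))
  expect_lt(max(abs(refs$protein - m$fitted)), 1e-6)
})

test_that("make_study reproduces the germplasm design arithmetic", {
  # full design: many accessions scanned, a diverse subset modelled
  cfg <- synthetic_config(180, seed = 88,
                          grid = seq(1100, 2498, by = 4))
  st <- small <- make_study(cfg, n_select = 60)
  expect_length(st$selection$ids, 60L)
  expect_equal(length(st$spectra), 60L)
  expect_named(st$splits, names(cfg$traits))
  expect_length(st$splits$protein$calibration_ids, 40L)
  expect_length(st$splits$protein$validation_ids, 20L)
  # per-trait splits differ because sorting differs per trait
  expect_false(identical(st$splits$protein$validation_ids,
                         st$splits$starch$validation_ids))
  cfg30 <- synthetic_config(30, seed = 89, grid = seq(1100, 2498, by = 4))
  st30 <- make_study(cfg30)
  expect_length(st30$splits$protein$calibration_ids, 20L)
  expect_length(st30$splits$protein$validation_ids, 10L)
  # determinism of the whole triple
  again <- make_study(cfg30)
  expect_identical(st30$refs, again$refs)
  expect_identical(st30$spectra$absorbance, again$spectra$absorbance)
})

test_that("more noise never improves median external accuracy", {
  grid <- seq(1100, 2498, by = 4)
  run_rsq <- function(noise_frac, seed) {
    cfg <- synthetic_config(48, seed = seed, grid = grid, noise_sd = 0)
    set.seed(seed)
    refs <- simulate_concentrations(48, cfg$traits, seed = NULL)
    sp0 <- simulate_spectra(refs, cfg, seed = NA)
    noise_sd <- noise_frac * median(sp0$absorbance)
    sp <- spectra_set(sp0$absorbance +
                        matrix(rnorm(length(sp0$absorbance), 0, noise_sd),
                               nrow(sp0$absorbance)),
                      grid, sample_ids(sp0))
    plan <- rank_order_split(refs, "protein")
    tr <- parse_math_treatment("2,4,6,1", "snv-dt")
    Xc <- apply_pretreatment(subset_spectra(sp, plan$calibration_ids), tr)
    Xv <- apply_pretreatment(subset_spectra(sp, plan$validation_ids), tr)
    yc <- refs$protein[match(plan$calibration_ids, refs$sample_id)]
    yv <- refs$protein[match(plan$validation_ids, refs$sample_id)]
    cv <- choose_factors_cv(Xc$absorbance, yc, 6)
    m <- fit_mpls(Xc$absorbance, yc, cv$chosen)
    cor(yv, predict(m, Xv$absorbance))^2
  }
  med <- vapply(c(0.001, 0.05, 0.5), function(nf)
    median(vapply(1:5, function(s) run_rsq(nf, 900 + s), numeric(1))),
    numeric(1))
  expect_true(all(diff(med) <= 1e-6),
              label = paste("median RSQ by rising noise:",
                            paste(round(med, 3), collapse = " ")))
})
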
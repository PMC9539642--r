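test_that("wide CSV on the instrument grid parses to the right shape", {
  grid <- default_grid()
  expect_length(grid, 1050L)
  path <- withr::local_tempfile(fileext = ".csv")
  header <- paste(c("sample_id", grid), collapse = ",")
  rows <- vapply(1:2, function(i)
    paste(c(sprintf("acc%d", i), rep(0.1 * i, length(grid))), collapse = ","),
    character(1))
  writeLines(c(header, rows), path)
  set <- read_spectra_table(path, "wide-csv")
  expect_s3_class(set, "spectra_set")
  expect_equal(length(set), 2L)
  expect_equal(set$wavelengths_nm, grid)
  expect_equal(unname(set$absorbance[2, 7]), 0.2)
})

test_that("wide and long dialects round-trip and agree with each other", {
  set <- random_spectra_set(n = 3, p = 25, seed = 4)
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(set, wide, "wide-csv")
  write_spectra_table(set, long, "long-csv")
  from_wide <- read_spectra_table(wide, "wide-csv")
  from_long <- read_spectra_table(long, "long-csv")
  expect_equal(from_wide$absorbance, set$absorbance, tolerance = 1e-12)
  expect_equal(from_long$absorbance, set$absorbance, tolerance = 1e-12)
  expect_equal(from_long$wavelengths_nm, from_wide$wavelengths_nm)
  # single spectrum -> single data row
  one <- subset_spectra(set, sample_ids(set)[1])
  write_spectra_table(one, wide, "wide-csv")
  expect_length(readLines(wide), 2L)
})

test_that("malformed spectra files fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,400,402", "a,0.1,oops", "b,0.2,0.3"), path)
  expect_error(read_spectra_table(path, "wide-csv"), "oops")
  expect_error(read_spectra_table(path, "wide-csv"), "402")
  writeLines(c("sample_id,400,402", "a,0.1,0.2", "a,0.2,0.3"), path)
  expect_error(read_spectra_table(path, "wide-csv"), "duplicate")
  # long dialect: one sample missing a wavelength -> grid mismatch
  writeLines(c("sample_id,wavelength,absorbance",
               "a,400,0.1", "a,402,0.2", "b,400,0.3"), path)
  expect_error(read_spectra_table(path, "long-csv"), "grid mismatch")
  expect_error(write_spectra_table(
    spectra_set(matrix(numeric(0), 0, 3), c(1, 2, 3), character(0)),
    path), "empty")
})

test_that("the JCAMP-DX subset reads (X++(Y..Y)) blocks and nothing else", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=flour-01", "##JCAMP-DX=4.24", "##XUNITS=NANOMETERS",
               "##YUNITS=ABSORBANCE", "##FIRSTX=400", "##LASTX=408",
               "##NPOINTS=5", "##XFACTOR=1", "##YFACTOR=0.001",
               "##XYDATA=(X++(Y..Y))",
               "400 100 200 300", "406 400 500", "##END="), path)
  set <- read_spectra_table(path, "jcamp-dx")
  expect_equal(sample_ids(set), "flour-01")
  expect_equal(set$wavelengths_nm, seq(400, 408, by = 2))
  expect_equal(unname(set$absorbance[1, ]), c(0.1, 0.2, 0.3, 0.4, 0.5))
  writeLines(c("##TITLE=x", "##XYDATA=(XY..XY)", "400,1", "##END="), path)
  expect_error(read_spectra_table(path, "jcamp-dx"), "only \\(X\\+\\+\\(Y")
  writeLines(c("##TITLE=x", "##FIRSTX=400", "##LASTX=404", "##NPOINTS=3",
               "##XYDATA=(X++(Y..Y))", "400 A100J200", "##END="), path)
  expect_error(read_spectra_table(path, "jcamp-dx"), "compressed")
})

test_that("spectra_set enforces one grid, unique ids, finite values", {
  g <- seq(400, 418, by = 2)
  s1 <- spectrum("a", g, rep(1, 10))
  s2 <- spectrum("b", g + c(rep(0, 9), 2), rep(1, 10))
  expect_error(spectra_set(list(s1, s2)), "grid mismatch")
  expect_error(spectra_set(matrix(1, 2, 10), g, c("a", "a")), "duplicate")
  expect_error(spectrum("a", g, c(rep(1, 9), NA)), "non-finite")
  expect_error(spectrum("a", rev(g), rep(1, 10)), "strictly increasing")
})

test_that("reference tables validate values and permit missing entries", {
  df <- data.frame(sample_id = c("a", "b"), protein = c(24, NA),
                   starch = c(31, 33))
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_table(df, path)
  back <- read_reference_table(path)
  expect_equal(back$protein, c(24, NA))
  expect_error(validate_reference_table(
    data.frame(sample_id = c("a", "a"), protein = 1:2)), "duplicate")
  expect_error(validate_reference_table(
    data.frame(sample_id = "a", protein = -1)), "negative")
  expect_error(validate_reference_table(data.frame(sample_id = "a")),
               "no trait columns")
})

test_that("average_scans is the pointwise mean and order-invariant", {
  g <- seq(400, 498, by = 2)
  base <- spectrum("s", g, 0.5 + 0.3 * sin(g / 50))
  expect_equal(average_scans(rep(list(base), 32L)), base)
  flipped <- spectrum("s2", g, 2 - base$absorbance)
  expect_equal(average_scans(list(base, flipped))$absorbance,
               rep(1, length(g)))
  set.seed(9)
  noise_sd <- 0.01
  scans <- lapply(1:32, function(i)
    spectrum("s", g, base$absorbance + rnorm(length(g), 0, noise_sd)))
  avg <- average_scans(scans)
  direct <- colMeans(do.call(rbind, lapply(scans, `[[`, "absorbance")))
  expect_equal(avg$absorbance, direct)
  expect_lt(max(abs(avg$absorbance - base$absorbance)),
            5 * noise_sd / sqrt(32))
  expect_equal(average_scans(rev(scans))$absorbance, avg$absorbance)
  expect_error(average_scans(list(base, spectrum("t", g + 2, base$absorbance))),
               "grid mismatch")
})
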
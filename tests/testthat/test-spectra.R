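test_that("spectrum construction validates its invariants", {
  expect_s3_class(spectrum(c(400, 500), c(0, 1), "reflectance"), "spectrum")
  expect_error(spectrum(400, 1, "reflectance"), "at least 2")
  expect_error(spectrum(c(400, 400), c(0, 1), "reflectance"), "increasing")
  expect_error(spectrum(c(400, 500), c(-0.1, 1), "reflectance"), "negative")
  expect_error(spectrum(c(400, 500), c(0.2, 1.5), "reflectance"), "> 1")
  # non-reflectance kinds may exceed 1
  expect_silent(spectrum(c(400, 500), c(0.2, 1.5), "fluorescence"))
})

test_that("read_spectrum parses two-column files with delimiter detection", {
  for (delim in c(",", "\t", ";")) {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(paste("wavelength", "value", sep = delim),
                 paste(c(350, 351), c(0.1, 0.2), sep = delim)), path)
    s <- read_spectrum(path, kind = "reflectance")
    expect_equal(nrow(s), 2L)
    expect_equal(s$value, c(0.1, 0.2))
  }
  # bound violation reported with the offending location
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("350,0.5", "360,1.5"), bad)
  expect_error(read_spectrum(bad, kind = "reflectance"), "1.5")
  # malformed row named by line
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("350,0.5", "360,abc"), bad2)
  expect_error(read_spectrum(bad2), "line 2")
  # duplicate wavelengths averaged with a warning
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("350,0.2", "350,0.4", "360,0.5"), dup)
  expect_warning(s <- read_spectrum(dup, kind = "reflectance"), "duplicate")
  expect_equal(s$value[1], 0.3)
})

test_that("write/read round trip is lossless to 1e-12 on random spectra", {
  set.seed(1)
  for (k in 1:5) {
    s <- random_spectrum(30)
    path <- withr::local_tempfile(fileext = ".csv")
    write_spectrum(s, path)
    s2 <- read_spectrum(path, kind = "fluorescence")
    expect_equal(s2$wavelength_nm, s$wavelength_nm, tolerance = 1e-12)
    expect_equal(s2$value, s$value, tolerance = 1e-12)
  }
})

test_that("resample_spectrum matches a pointwise interpolation oracle", {
  s <- spectrum(c(400, 500), c(0, 1), "reflectance")
  expect_equal(resample_spectrum(s, 450)$value, 0.5)
  # identity on own grid
  expect_equal(resample_spectrum(s, s$wavelength_nm)$value, s$value)
  expect_error(resample_spectrum(s, c(350, 450)), "extrapolation")
  set.seed(2)
  for (k in 1:5) {
    s <- random_spectrum(15)
    grid <- sort(runif(40, min(s$wavelength_nm), max(s$wavelength_nm)))
    got <- resample_spectrum(s, grid)$value
    oracle <- vapply(grid, function(x) {
      i <- max(which(s$wavelength_nm <= x))
      if (i == nrow(s)) return(s$value[i])
      w0 <- s$wavelength_nm[i]; w1 <- s$wavelength_nm[i + 1]
      s$value[i] + (s$value[i + 1] - s$value[i]) * (x - w0) / (w1 - w0)
    }, numeric(1))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # exact on piecewise-linear inputs sampled at breakpoints
  s <- spectrum(c(400, 450, 500), c(0, 1, 0.5), "fluorescence")
  expect_equal(resample_spectrum(s, c(425, 475))$value, c(0.5, 0.75))
})

test_that("phantom recipes reproduce the five-phantom validation table", {
  tab <- validation_phantoms()
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$hb_mg_per_ml, c(0.25, 0.50, 1.00, 0.50, 1.00))
  expect_equal(tab$polystyrene_pct, c(0.50, 0.25, 0.15, 0.50, 0.25))
  expect_equal(tab$nadh_ug_per_ml, c(0.50, 1.00, 1.50, 1.00, 1.00))
  expect_equal(tab$carbostyril_ug_per_ml, c(1.50, 1.00, 0.50, 1.00, 1.00))
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_recipe(recipe_row(3), path)
  back <- read_recipe(path)
  expect_equal(back$hb_mg_per_ml, 1.0)
  expect_equal(back$polystyrene_pct, 0.15)
})
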
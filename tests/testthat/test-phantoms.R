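test_that("library spectra carry the documented spectral features", {
  lib <- lib_cached()
  hb <- lib$extinction$hb
  peak <- hb$wavelength_nm[which.max(hb$value)]
  expect_gte(peak, 400); expect_lte(peak, 430) # Soret maximum
  # secondary structure in the Q-band window: a local maximum within 520-580
  win <- hb$wavelength_nm >= 520 & hb$wavelength_nm <= 580
  inner <- hb$value[win]
  expect_gt(max(inner), hb$value[hb$wavelength_nm == 600])
  # fluorophores: peaks and yields as documented
  expect_equal(lib$fluorophores$nadh$quantum_yield, 0.02)
  expect_equal(lib$fluorophores$carbostyril$quantum_yield, 0.97)
  np <- lib$fluorophores$nadh$lineshape
  expect_gte(np$wavelength_nm[which.max(np$value)], 450)
  expect_lte(np$wavelength_nm[which.max(np$value)], 460)
  cp <- lib$fluorophores$carbostyril$lineshape
  expect_equal(cp$wavelength_nm[which.max(cp$value)], 417, tolerance = 1)
  # unit areas
  tz <- function(s) sum(diff(s$wavelength_nm) *
                          (head(s$value, -1) + tail(s$value, -1)) / 2)
  expect_equal(tz(np), 1, tolerance = 1e-6)
  expect_equal(tz(cp), 1, tolerance = 1e-6)
})

test_that("lognormal lineshapes honour their peak and width parameters", {
  g <- seq(380, 600, by = 0.5)
  for (case in list(c(455, 100), c(417, 60))) {
    s <- lognormal_lineshape(g, case[1], case[2])
    expect_equal(g[which.max(s$value)], case[1], tolerance = 1)
    half <- max(s$value) / 2
    above <- range(g[s$value >= half])
    expect_equal(diff(above), case[2], tolerance = 2)
  }
})

test_that("Beer-Lambert absorption follows the recipe", {
  lib <- lib_cached()
  zero <- mua_from_recipe(phantom_recipe(hb_mg_per_ml = 0), lib)
  expect_true(all(zero$value == 0))
  # flat unit extinction at unit concentration gives ln(10)
  flat_lib <- lib
  flat_lib$extinction$hb <- spectrum(reflectance_grid(), rep(1, 401),
                                     "extinction")
  unit <- mua_from_recipe(phantom_recipe(hb_mg_per_ml = 1), flat_lib)
  expect_equal(unit$value, rep(log(10), 401), tolerance = 1e-12)
  # equal-absorber phantoms 3 and 5 share mua exactly
  expect_equal(mua_from_recipe(recipe_row(3), lib)$value,
               mua_from_recipe(recipe_row(5), lib)$value)
})

test_that("datasets are reproducible and ordered by composition", {
  lib <- lib_cached()
  d1 <- build_dataset(recipe_row(2), lib, seed = 5L, method = "scaling",
                      model = ref_model())
  d2 <- build_dataset(recipe_row(2), lib, seed = 5L, method = "scaling",
                      model = ref_model())
  expect_identical(d1$observed$reflectance$value, d2$observed$reflectance$value)
  expect_identical(d1$observed$bulk$value, d2$observed$bulk$value)
  # musp at 500 nm tracks the polystyrene concentration; phantom 3 is lowest
  musp500 <- vapply(1:5, function(i) {
    ds <- dataset_cached(i)
    ds$truth$optics$musp[ds$truth$optics$wavelength_nm == 500]
  }, numeric(1))
  expect_equal(which.min(musp500), 3L)
  expect_equal(order(musp500), order(validation_phantoms()$polystyrene_pct))
})

test_that("bulk band ratio rises across the NADH ladder and intensity falls with
          added absorber or scatterer", {
  ratios <- vapply(1:3, function(i) band_ratio(dataset_cached(i)$observed$bulk),
                   numeric(1))
  expect_true(all(diff(ratios) > 0))
  total <- function(i) {
    b <- dataset_cached(i)$observed$bulk
    sum(diff(b$wavelength_nm) * (head(b$value, -1) + tail(b$value, -1)) / 2)
  }
  expect_gt(total(2), total(5)) # more absorber dims the bulk signal
  expect_gt(total(2), total(4)) # more scatterer dims the bulk signal
})

test_that("dataset spectra tidy into a long table", {
  td <- tidy(dataset_cached(1))
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$signal),
                  c("reflectance_observed", "reflectance_truth",
                    "bulk_fluorescence", "intrinsic_fluorescence"))
})
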
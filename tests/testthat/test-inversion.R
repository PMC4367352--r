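test_that("albedo from coefficients obeys the stated limits", {
  props <- optical_properties(c(500, 600), mua_per_cm = c(0, 5),
                              mus_per_cm = c(10, 5), g = 0)
  cc <- albedo_from_coefficients(props)
  expect_equal(cc[1], 1 - 1e-12) # mua = 0 clamps just below 1
  expect_equal(cc[2], 0.5)       # mua = musp -> 1/2
  expect_error(albedo_from_coefficients(
    optical_properties(c(500, 600), 0, 0, 0)), "> 0")
})

test_that("albedo solves back from reflectance to 10 digits", {
  m <- ref_model()
  cc <- c(0.3, 0.7, 0.95, 0.999)
  r <- scaled_r_values(m, cc)
  back <- albedo_from_reflectance(m, r)
  expect_equal(back, cc, tolerance = 1e-10)
})

test_that("scaling identity and monotonicity in albedo hold", {
  m <- ref_model()
  # c = c_sim reproduces the reference r_total exactly
  expect_equal(scaled_r_values(m, m$c_sim), m$r_total, tolerance = 1e-12)
  # c below c_sim shrinks every term
  cc <- seq(0.05, m$c_sim, length.out = 40)
  r <- scaled_r_values(m, cc)
  expect_true(all(r[-length(r)] < r[-1]))
  expect_true(all(r <= m$r_total + 1e-12))
  # guards
  expect_error(scaled_reflectance(m, c(0.5, 1.5)), "0, 1")
  expect_error(scaled_reflectance(m, c(0.5, 0.9999)), "c_sim")
})

test_that("scaled reflectance matches direct Monte Carlo of the target", {
  m <- ref_model()
  for (cc in c(0.4, 0.8, 0.97)) {
    direct <- simulate_transport(
      c(mua = 1 - cc, mus = cc, g = 0),
      mc_config(seed = 400L + round(100 * cc), n_photons = 6e4))$r_total
    expect_equal(scaled_r_values(m, cc), direct, tolerance = 0.03)
  }
})

test_that("slab scaling model agrees with direct slab Monte Carlo", {
  sm <- slab_model_cached()
  cases <- list(c(c = 0.9, tau = 2.3), c(c = 0.98, tau = 7.7),
                c(c = 0.6, tau = 4.1))
  for (case in cases) {
    direct <- simulate_transport(
      c(mua = (1 - case["c"]), mus = case["c"], g = 0),
      mc_config(seed = 500L + round(10 * case["tau"]), n_photons = 6e4,
                slab_thickness_cm = case["tau"]))$r_total
    expect_equal(slab_r_values(sm, case["c"], case["tau"]), direct,
                 tolerance = 0.04, ignore_attr = TRUE)
  }
})

test_that("noise-free inverse crime recovers the physical basis parameters", {
  sm <- slab_model_cached()
  lib <- lib_cached()
  grid <- reflectance_grid(5)
  eps <- resample_spectrum(lib$extinction$hb, grid)
  theta <- c(C = 0.8, a = 7, b = 1.1)
  mua <- log(10) * eps$value * theta["C"]
  musp <- theta["a"] * (grid / 500)^(-theta["b"])
  meas <- slab_reflectance(sm, optical_properties(grid, mua, musp, 0), 0.2)
  fit <- invert_reflectance(meas, sm, extinction = eps, l_cm = 0.2, seed = 5)
  expect_true(fit$converged)
  expect_equal(unname(fit$par), unname(theta), tolerance = 0.01)
})

test_that("shape basis recovers concentrations exactly in the noise-free case", {
  sm <- slab_model_cached()
  lib <- lib_cached()
  grid <- reflectance_grid(5)
  tr <- recipe_optics(recipe_row(3), lib, grid)
  meas <- slab_reflectance(sm, tr, 0.2)
  beads <- suspension_optics(bead_suspension(1, 1), grid)
  fit <- invert_reflectance(
    meas, sm, extinction = lib$extinction$hb, basis = "shape",
    scatter_shape = spectrum(grid, beads$musp, kind = "coefficient"),
    l_cm = 0.2, seed = 9)
  expect_equal(fit$par[["C"]], 1.0, tolerance = 0.005)
  expect_equal(fit$extracted$musp, tr$musp, tolerance = 0.005)
})

test_that("albedo basis returns the identifiable pointwise albedo", {
  m <- ref_model()
  grid <- seq(400, 700, by = 50)
  cc_true <- seq(0.5, 0.95, length.out = length(grid))
  meas <- scaled_reflectance(m, cc_true, grid)
  fit <- invert_reflectance(meas, m, basis = "albedo")
  expect_equal(tidy(fit)$albedo, cc_true, tolerance = 1e-8)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("semi-infinite reflectance cannot fix the coefficient scale", {
  # the scale ray (kC, ka) leaves the semi-infinite forward map unchanged:
  # the identifiable content is the albedo spectrum
  m <- ref_model()
  lib <- lib_cached()
  grid <- reflectance_grid(10)
  eps <- resample_spectrum(lib$extinction$hb, grid)$value
  albedo_of <- function(k) {
    mua <- log(10) * eps * 0.5 * k
    musp <- k * 8 * (grid / 500)^(-1)
    musp / (musp + mua)
  }
  r1 <- scaled_r_values(m, albedo_of(1))
  r3 <- scaled_r_values(m, albedo_of(3))
  expect_equal(r1, r3, tolerance = 1e-12)
})

test_that("diffusion closed form behaves at its limits", {
  expect_lt(diffusion_reflectance(0.5), diffusion_reflectance(0.99))
  expect_gt(diffusion_reflectance(1 - 1e-9), 0.99)
  # internal reflection (mismatched) traps light inside, lowering the
  # escaping diffuse reflectance
  expect_lt(diffusion_reflectance(0.9, n_rel = 1.33),
            diffusion_reflectance(0.9))
})
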
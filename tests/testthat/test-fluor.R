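test_that("distortion and extraction are exact mutual inverses", {
  set.seed(42)
  for (k in 1:10) {
    ctx <- random_ctx()
    g <- ctx$emission_grid_nm
    f <- spectrum(g, runif(length(g), 0.01, 2), "fluorescence")
    bulk <- apply_distortion(f, ctx)
    back <- extract_intrinsic(bulk, ctx)
    expect_equal(back$value, f$value, tolerance = 1e-10)
  }
})

test_that("no-absorption limit reduces to a wavelength-independent scale", {
  g <- emission_grid(5)
  ctx <- fluor_context(g, R_x = 0.9, R_m = rep(0.9, length(g)),
                       R0_x = 0.9, R0_m = 0.9, mus_x_per_cm = 50,
                       g_x = 0.9, g_m = 0.9, l_cm = 1, S = 1)
  corr <- fluor_correction(ctx)
  expect_equal(corr, rep(corr[1], length(g)), tolerance = 1e-12)
  # hand algebra: eps terms with equal g, R = R0 everywhere
  eps <- exp(1 * (1 - 0.9)) - 1
  hand <- 50 * 1 * sqrt(0.9 * 0.9 * eps * eps) / ((0.9 / 0.9) * (1 + eps))
  expect_equal(corr[1], hand, tolerance = 1e-12)
})

test_that("normalized correction compensates absorption, never amplifies below 1", {
  set.seed(7)
  for (k in 1:10) {
    ctx <- random_ctx()
    ctx0 <- ctx
    ctx0$R_x <- ctx$R0_x
    ctx0$R_m <- rep(ctx$R0_m, length(ctx$R_m))
    ratio <- fluor_correction(ctx) / fluor_correction(ctx0)
    expect_true(all(ratio >= 1 - 1e-12))
  }
})

test_that("raising emission absorption dims the bulk signal pointwise", {
  g <- emission_grid(5)
  f <- spectrum(g, rep(1, length(g)), "fluorescence")
  R_m_hi <- rep(0.7, length(g))
  bulk_prev <- NULL
  for (scale in c(1, 0.8, 0.6, 0.4)) {
    ctx <- fluor_context(g, R_x = 0.7, R_m = R_m_hi * scale,
                         R0_x = 0.95, R0_m = 0.95, mus_x_per_cm = 30,
                         S = 1, l_cm = 1)
    bulk <- apply_distortion(f, ctx)$value
    if (!is.null(bulk_prev)) expect_true(all(bulk < bulk_prev))
    bulk_prev <- bulk
  }
})

test_that("degenerate contexts are rejected", {
  g <- emission_grid(10)
  expect_error(fluor_context(g, 0.5, 0.5, 0.9, 0.9, 50, S = 0), "S")
  expect_error(fluor_context(g, 0.5, 0.5, 0.9, 0.9, 50, g_x = 1), "g")
  expect_error(fluor_context(g, 0.95, 0.5, 0.9, 0.9, 50), "R0")
  expect_error(fluor_context(g, 0.5, 0.5, 0, 0.9, 50), "> 0")
})

test_that("zero-absorption reflectance ignores mua and balances a finite slab", {
  props1 <- optical_properties(seq(400, 500, by = 10), mua_per_cm = 5,
                               mus_per_cm = 40, g = 0.8)
  props2 <- optical_properties(seq(400, 500, by = 10), mua_per_cm = 0.1,
                               mus_per_cm = 40, g = 0.8)
  cfg <- mc_config(seed = 21L, n_photons = 5e3, slab_thickness_cm = 0.5,
                   n_inside = 1.33, n_outside = 1.33)
  r1 <- zero_absorption_reflectance(props1, cfg, every_nm = 50)
  r2 <- zero_absorption_reflectance(props2, cfg, every_nm = 50)
  expect_equal(r1$value, r2$value, tolerance = 1e-12) # mua overridden
  t0 <- attr(r1, "transmittance")
  expect_equal(r1$value + t0, rep(1, nrow(r1)), tolerance = 1e-6)
})

test_that("non-negative unmixing recovers synthetic mixtures", {
  lib <- lib_cached()
  basis <- list(nadh = lib$fluorophores$nadh$lineshape,
                carbostyril = lib$fluorophores$carbostyril$lineshape)
  g <- basis$nadh$wavelength_nm
  # single member
  one <- decompose_fluorophores(basis$carbostyril, basis)
  expect_equal(unname(one$weights), c(0, 1), tolerance = 1e-8)
  # weighted mixture to 6 digits
  mix <- spectrum(g, 0.3 * basis$nadh$value + 0.7 * basis$carbostyril$value,
                  "fluorescence")
  w <- decompose_fluorophores(mix, basis)
  expect_equal(unname(w$weights), c(0.3, 0.7), tolerance = 1e-6)
  # noisy input still yields non-negative weights
  set.seed(5)
  noisy <- spectrum(g, pmax(mix$value + rnorm(length(g), 0, 1e-3), 0),
                    "fluorescence")
  wn <- decompose_fluorophores(noisy, basis)
  expect_true(all(wn$weights >= 0))
  # collinear basis warns
  base2 <- list(a = basis$nadh,
                b = spectrum(g, basis$nadh$value * (1 + 1e-12), "fluorescence"))
  expect_warning(decompose_fluorophores(mix, base2), "collinear")
})
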
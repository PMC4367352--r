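test_that("conservative matched semi-infinite medium reflects everything", {
  cfg <- mc_config(seed = 1L, n_photons = 2e4, n_inside = 1.33,
                   n_outside = 1.33)
  res <- simulate_transport(c(mua = 0, mus = 10, g = 0.9), cfg)
  se <- sqrt(res$r_total * max(1 - res$r_total, 1e-12) / res$n_photons)
  expect_lte(abs(res$r_total - 1), max(3 * se, 1e-12))
  expect_equal(mc_weight_balance(res), 1, tolerance = 1e-12)
})

test_that("ballistic medium returns nothing", {
  cfg <- mc_config(seed = 2L, n_photons = 2e3, n_inside = 1.33,
                   n_outside = 1.33)
  res <- simulate_transport(c(mua = 1, mus = 0, g = 0), cfg)
  expect_equal(res$r_total, 0)
})

test_that("weight bookkeeping is exact across seeds", {
  for (seed in 1:8) {
    cfg <- mc_config(seed = seed, n_photons = 5e3)
    res <- simulate_transport(c(mua = 1, mus = 9, g = 0.8), cfg)
    expect_equal(mc_weight_balance(res), 1, tolerance = 1e-12)
    expect_true(all(res$n_reflect >= 0))
    # histogram sums to the diffuse reflectance exactly
    expect_equal(sum(res$n_reflect), res$r_total, tolerance = 1e-12)
  }
})

test_that("same seed reproduces the run bit for bit", {
  cfg <- mc_config(seed = 7L, n_photons = 5e3)
  a <- simulate_transport(c(mua = 0.5, mus = 20, g = 0.9), cfg)
  b <- simulate_transport(c(mua = 0.5, mus = 20, g = 0.9), cfg)
  expect_identical(a$r_total, b$r_total)
  expect_identical(a$n_reflect, b$n_reflect)
})

test_that("reflectance decreases monotonically with absorption", {
  mua_ladder <- c(0.05, 0.2, 0.8, 3, 10)
  r <- vapply(seq_along(mua_ladder), function(i) {
    cfg <- mc_config(seed = 100L + i, n_photons = 2e4)
    simulate_transport(c(mua = mua_ladder[i], mus = 10, g = 0), cfg)$r_total
  }, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("high-albedo reflectance agrees with diffusion theory within 5%", {
  cfg <- mc_config(seed = 3L, n_photons = 4e4, n_inside = 1, n_outside = 1)
  res <- simulate_transport(c(mua = 0.1, mus = 10, g = 0), cfg)
  expect_equal(res$r_total, diffusion_reflectance(10 / 10.1),
               tolerance = 0.05)
})

test_that("doubling photons shrinks the standard error", {
  r_small <- vapply(1:6, function(s)
    simulate_transport(c(mua = 1, mus = 9, g = 0),
                       mc_config(seed = 200L + s, n_photons = 2e3))$r_total,
    numeric(1))
  r_big <- vapply(1:6, function(s)
    simulate_transport(c(mua = 1, mus = 9, g = 0),
                       mc_config(seed = 300L + s, n_photons = 3.2e4))$r_total,
    numeric(1))
  # 16x photons -> ~4x smaller sd; allow generous slack for 6 replicates
  expect_lt(sd(r_big), sd(r_small))
})

test_that("finite slab conserves weight between faces when non-absorbing", {
  cfg <- mc_config(seed = 4L, n_photons = 1e4, slab_thickness_cm = 1,
                   n_inside = 1.33, n_outside = 1.33)
  res <- simulate_transport(c(mua = 0, mus = 20, g = 0.7), cfg)
  expect_equal(res$r_total + res$t_total, 1, tolerance = 1e-10)
  expect_gt(res$t_total, 0)
})

test_that("reference simulation is broadcast for constant c_sim and capped in tail", {
  ref <- ref_model()$reference
  expect_equal(sum(ref$n_reflect), ref$r_total, tolerance = 1e-12)
  # tail mass beyond the histogram cap is tiny
  expect_lt(ref$overflow, 1e-4 * ref$r_total)
  expect_error(simulate_reference(mc_config(seed = 1), c_sim = c(0.9, 0.95)),
               "non-constant")
  expect_error(simulate_reference(mc_config(seed = 1), c_sim = 1.2), "c_sim")
})

test_that("invalid configurations are rejected", {
  expect_error(mc_config(n_photons = 1e4), "seed")
  expect_error(mc_config(seed = 1, n_photons = 10), "n_photons")
  cfg <- mc_config(seed = 1L, n_photons = 1e3)
  expect_error(simulate_transport(c(mua = NA, mus = 1, g = 0), cfg), "finite")
  expect_error(simulate_transport(c(mua = 0, mus = 0, g = 0), cfg))
})
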
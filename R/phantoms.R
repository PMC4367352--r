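#' Chromophore and fluorophore library
#'
#' Bundled spectral building blocks for synthetic phantoms:
#'
#' * `hb`: a haemoglobin-like extinction spectrum in cm^-1 (mg/mL)^-1,
#'   modelled parametrically as a Soret Gaussian at 415 nm, Q-band Gaussians
#'   at 542 and 577 nm and a decaying baseline. It is a synthetic stand-in
#'   with the physiologically relevant features (Soret maximum in 400--430 nm,
#'   secondary structure at 520--580 nm), not a digitized literature spectrum;
#'   any tabulated extinction spectrum can be supplied instead.
#' * `nadh`: NADH-like fluorophore, log-normal emission lineshape peaking at
#'   455 nm (FWHM 100 nm), quantum yield 0.02.
#' * `carbostyril`: carbostyril-like fluorophore, log-normal lineshape peaking
#'   at 417 nm (FWHM 60 nm), quantum yield 0.97, with an optional right
#'   shoulder mimicking aggregation at high concentration.
#'
#' Lineshapes are normalized to unit area on the emission grid. Each
#' fluorophore also carries an `excitation_strength`: its relative absorption
#' per ug/mL at the 350 nm excitation. The 350 nm line sits on the NADH
#' absorption maximum but on the red edge of the carbostyril band, so the
#' NADH-like fluorophore is given a much larger excitation strength (10 vs 1);
#' the product `excitation_strength * quantum_yield` makes the two
#' fluorophores comparably bright per ug/mL, the regime in which the measured
#' 450 nm / 390 nm band ratio of phantom fluorescence responds strongly to
#' the NADH concentration.
#'
#' @param grid Wavelength grid for extinction spectra (nm).
#' @param em_grid Wavelength grid for emission lineshapes (nm).
#' @param carbostyril_shoulder Add a right shoulder to the carbostyril-like
#'   lineshape (default `FALSE`).
#' @return A list of class `chromophore_library` with elements `extinction`
#'   (named list of [spectrum()]s) and `fluorophores` (named list with
#'   `lineshape`, `peak_nm`, `quantum_yield`).
#' @export
chromophore_library <- function(grid = reflectance_grid(),
                                em_grid = emission_grid(),
                                carbostyril_shoulder = FALSE) {
  eps <- 7.0 * exp(-(grid - 415)^2 / (2 * 18^2)) +
    0.85 * exp(-(grid - 542)^2 / (2 * 12^2)) +
    0.95 * exp(-(grid - 577)^2 / (2 * 10^2)) +
    0.50 * exp(-(grid - 350) / 150)
  nadh_shape <- lognormal_lineshape(em_grid, peak_nm = 455, fwhm_nm = 100)
  carb <- lognormal_lineshape(em_grid, peak_nm = 417, fwhm_nm = 60)
  if (carbostyril_shoulder) {
    sh <- lognormal_lineshape(em_grid, peak_nm = 455, fwhm_nm = 55)
    v <- carb$value + 0.45 * sh$value
    carb <- spectrum(em_grid, v / trapz_int(em_grid, v),
                     kind = "fluorescence")
  }
  structure(list(
    extinction = list(hb = spectrum(grid, eps, kind = "extinction")),
    fluorophores = list(
      nadh = list(lineshape = nadh_shape, peak_nm = 455, quantum_yield = 0.02,
                  excitation_strength = 10),
      carbostyril = list(lineshape = carb, peak_nm = 417, quantum_yield = 0.97,
                         excitation_strength = 1))),
    class = "chromophore_library")
}

trapz_int <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Log-normal emission lineshape
#'
#' A log-normal peak parameterized by its mode and full width at half maximum,
#' normalized to unit area on the grid -- the standard skewed lineshape for
#' fluorophore emission bands.
#'
#' @param grid Wavelengths (nm).
#' @param peak_nm Mode of the peak (nm).
#' @param fwhm_nm Full width at half maximum (nm).
#' @return A fluorescence [spectrum()] with unit area.
#' @export
lognormal_lineshape <- function(grid, peak_nm, fwhm_nm) {
  # FWHM of a log-normal with log-sd sigma and mode lambda_p:
  # lambda_p * (exp(v) - exp(-v)), v = sqrt(2 sigma^2 log 2 - sigma^4)
  fw <- function(sigma) {
    v2 <- 2 * sigma^2 * log(2) - sigma^4
    if (v2 <= 0) return(Inf)
    peak_nm * (exp(sqrt(v2)) - exp(-sqrt(v2)))
  }
  sigma <- stats::uniroot(function(s) fw(s) - fwhm_nm,
                          lower = 1e-4, upper = 1, tol = 1e-10)$root
  mu <- log(peak_nm) + sigma^2
  y <- exp(-(log(grid) - mu)^2 / (2 * sigma^2)) / grid
  spectrum(grid, y / trapz_int(grid, y), kind = "fluorescence")
}

#' Absorption coefficient from a phantom recipe
#'
#' Beer--Lambert: `mua(lambda) = ln(10) * sum_i eps_i(lambda) * c_i`. For the
#' bundled library the only absorber is the haemoglobin-like chromophore;
#' fluorophores at ug/mL levels contribute negligible absorption and are not
#' included.
#'
#' @param recipe A one-row [phantom_recipe()].
#' @param lib A [chromophore_library()].
#' @return A coefficient [spectrum()] (cm^-1).
#' @export
mua_from_recipe <- function(recipe, lib = chromophore_library()) {
  stopifnot(inherits(recipe, "phantom_recipe"), nrow(recipe) == 1L,
            inherits(lib, "chromophore_library"))
  eps <- lib$extinction$hb
  spectrum(eps$wavelength_nm, log(10) * eps$value * recipe$hb_mg_per_ml,
           kind = "coefficient")
}

#' Ground-truth optical properties of a phantom recipe
#'
#' Combines the Beer--Lambert absorption of the absorber with the Mie
#' scattering of the microsphere suspension.
#'
#' @inheritParams mua_from_recipe
#' @param grid Wavelength grid (nm).
#' @return An [optical_properties()] tibble.
#' @export
recipe_optics <- function(recipe, lib = chromophore_library(),
                          grid = reflectance_grid()) {
  mua <- resample_spectrum(mua_from_recipe(recipe, lib), grid)$value
  beads <- suspension_optics(
    bead_suspension(recipe$bead_diameter_um, recipe$polystyrene_pct), grid)
  optical_properties(grid, mua_per_cm = mua, mus_per_cm = beads$mus, g = beads$g)
}

#' Ground-truth intrinsic fluorescence of a phantom recipe
#'
#' Brightness-weighted sum of the fluorophore lineshapes:
#' `f = sum_i c_i * excitation_strength_i * QY_i * lineshape_i`, in arbitrary
#' but internally consistent units (only relative comparisons across phantoms
#' are meaningful).
#'
#' @inheritParams mua_from_recipe
#' @return A fluorescence [spectrum()] on the library emission grid.
#' @export
intrinsic_from_recipe <- function(recipe, lib = chromophore_library()) {
  fl <- lib$fluorophores
  g <- fl$nadh$lineshape$wavelength_nm
  f <- recipe$nadh_ug_per_ml * fl$nadh$excitation_strength *
    fl$nadh$quantum_yield * fl$nadh$lineshape$value +
    recipe$carbostyril_ug_per_ml * fl$carbostyril$excitation_strength *
      fl$carbostyril$quantum_yield * fl$carbostyril$lineshape$value
  spectrum(g, f, kind = "fluorescence")
}

#' Build a complete synthetic phantom dataset
#'
#' Composes the forward chain for one recipe: Beer--Lambert absorption, Mie
#' scattering, Monte Carlo diffuse reflectance and photon-migration-distorted
#' bulk fluorescence, returning both the ground truth and the "observed"
#' spectra with multiplicative log-normal noise of coefficient of variation
#' `noise_cv`. Everything is reproducible from `(recipe, seed, noise_cv)` and
#' the stated simulation sizes; there is no hidden state.
#'
#' The observed reflectance is produced either by direct per-wavelength Monte
#' Carlo of the cuvette slab (thickness from the recipe) in the reduced
#' (similarity) representation on a decimated grid (`method = "mc_grid"`,
#' spline-interpolated back to 1 nm), or by semi-infinite albedo scaling of a
#' reference run (`method = "scaling"`, fast, noise-free before the
#' observation noise, and adequate for trend checks where the small
#' transmission loss through the back face is immaterial). The fluorescence
#' distortion context uses the semi-infinite geometry, for which the
#' zero-absorption reflectance equals `1 - specular` exactly.
#'
#' @inheritParams mua_from_recipe
#' @param noise_cv Multiplicative log-normal noise CV for observed spectra
#'   (default 0.01; benchtop acquisition normalizes lamp fluctuations away,
#'   leaving only small residual noise).
#' @param seed Integer seed controlling noise and all Monte Carlo sub-seeds.
#' @param method `"mc_grid"` or `"scaling"` (see Details).
#' @param refl_path_cm Path length of the reflectance sample cell in cm
#'   (default 0.2, a thin cell that keeps the optical thickness in the range
#'   where transmission losses anchor the absolute coefficient scale). The
#'   recipe's `thickness_cm` remains the fluorescence cuvette thickness.
#' @param model Optional pre-built [scaling_model()] to reuse across phantoms;
#'   built internally when `NULL`.
#' @param n_photons Photons per direct Monte Carlo wavelength.
#' @param every_nm Wavelength decimation of the direct Monte Carlo (nm).
#' @param cfg_ref Optional [mc_config()] for the internally built reference.
#' @return A list of class `phantom_dataset` with elements `recipe`, `truth`
#'   (`optics`, `intrinsic`), `observed` (`reflectance`, `bulk`), `ctx`
#'   (the [fluor_context()] used for the distortion), `model`, `noise_cv`,
#'   `seed`.
#' @export
build_dataset <- function(recipe, lib = chromophore_library(),
                          noise_cv = 0.01, seed = 1L,
                          method = c("mc_grid", "scaling"),
                          refl_path_cm = 0.2,
                          model = NULL, n_photons = 5e4, every_nm = 10,
                          cfg_ref = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(recipe, "phantom_recipe"), nrow(recipe) == 1L)
  grid <- reflectance_grid()
  egrid <- emission_grid()
  optics <- recipe_optics(recipe, lib, grid)
  if (all(optics$mus == 0) && method == "mc_grid")
    method <- "scaling" # nothing scatters; handled by the scaling limit
  if (is.null(model)) {
    cfg_ref <- cfg_ref %||% mc_config(seed = seed + 900L, n_photons = 2e5)
    model <- scaling_model(simulate_reference(cfg_ref, c_sim = 0.9995),
                           c_sim = 0.9995)
  }
  alb <- pmin(albedo_from_coefficients(optics), model$c_sim)
  if (method == "mc_grid") {
    idx <- unique(c(seq(1, length(grid), by = every_nm), length(grid)))
    rmc <- vapply(seq_along(idx), function(k) {
      i <- idx[k]
      cfg_i <- mc_config(seed = seed + 1000L + k, n_photons = n_photons,
                         slab_thickness_cm = refl_path_cm)
      simulate_transport(c(mua = optics$mua[i], mus = optics$musp[i], g = 0),
                         cfg_i)$r_total
    }, numeric(1))
    refl <- stats::spline(grid[idx], rmc, xout = grid, method = "fmm")$y
    refl <- pmin(pmax(refl, 0), 1)
  } else {
    refl <- pmin(scaled_r_values(model, alb), 1)
  }
  intrinsic <- intrinsic_from_recipe(recipe, lib)

  # distortion context from the truth optics (semi-infinite geometry)
  optics_em <- optical_properties(
    egrid,
    mua_per_cm = stats::approx(grid, optics$mua, xout = egrid)$y,
    mus_per_cm = stats::approx(grid, optics$mus, xout = egrid)$y,
    g = stats::approx(grid, optics$g, xout = egrid)$y)
  rsp <- ((model$reference$config$n_inside - model$reference$config$n_outside) /
            (model$reference$config$n_inside + model$reference$config$n_outside))^2
  r0 <- 1 - rsp
  x_nm <- 350
  i_x <- which.min(abs(grid - x_nm))
  alb_em <- pmin(albedo_from_coefficients(optics_em), model$c_sim)
  ctx <- fluor_context(
    emission_grid_nm = egrid,
    R_x = min(scaled_r_values(model, alb[i_x]), r0),
    R_m = pmin(scaled_r_values(model, alb_em), r0),
    R0_x = r0, R0_m = r0,
    mus_x_per_cm = max(optics$mus[i_x], 1e-9),
    g_x = optics$g[i_x], g_m = optics_em$g,
    l_cm = recipe$thickness_cm, S = 1, excitation_nm = x_nm)
  bulk <- apply_distortion(intrinsic, ctx)

  set.seed(seed)
  noisy <- function(v) {
    if (noise_cv <= 0) return(v)
    sdlog <- sqrt(log(1 + noise_cv^2))
    v * stats::rlnorm(length(v), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  obs_refl <- spectrum(grid, pmin(noisy(refl), 1), kind = "reflectance")
  obs_bulk <- spectrum(egrid, noisy(bulk$value), kind = "fluorescence")

  structure(list(recipe = recipe,
                 truth = list(optics = optics, intrinsic = intrinsic,
                              albedo = alb, reflectance = refl),
                 observed = list(reflectance = obs_refl, bulk = obs_bulk),
                 ctx = ctx, model = model, noise_cv = noise_cv, seed = seed,
                 method = method, refl_path_cm = refl_path_cm),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  r <- x$recipe
  cat(sprintf("<phantom_dataset> %s: Hb %.2f mg/mL, beads %.2f%%, NADH %.2f ug/mL, carbostyril %.2f ug/mL\n",
              r$label %||% "unnamed", r$hb_mg_per_ml, r$polystyrene_pct,
              r$nadh_ug_per_ml, r$carbostyril_ug_per_ml))
  cat(sprintf("  reflectance method = %s, noise_cv = %g, seed = %d\n",
              x$method, x$noise_cv, x$seed))
  invisible(x)
}

#' @export
tidy.phantom_dataset <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(signal = "reflectance_observed",
                   wavelength_nm = x$observed$reflectance$wavelength_nm,
                   value = x$observed$reflectance$value),
    tibble::tibble(signal = "reflectance_truth",
                   wavelength_nm = x$truth$optics$wavelength_nm,
                   value = x$truth$reflectance),
    tibble::tibble(signal = "bulk_fluorescence",
                   wavelength_nm = x$observed$bulk$wavelength_nm,
                   value = x$observed$bulk$value),
    tibble::tibble(signal = "intrinsic_fluorescence",
                   wavelength_nm = x$truth$intrinsic$wavelength_nm,
                   value = x$truth$intrinsic$value))
}
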
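#' Albedo-scaling model of diffuse reflectance
#'
#' Total diffuse reflectance of a semi-infinite homogeneous medium depends on
#' the optical coefficients only through the reduced single-scattering albedo
#' `c = musp / (musp + mua)` (in the similarity, `g = 0`, representation).
#' A single reference Monte Carlo run at albedo `c_sim` therefore predicts the
#' reflectance at any other albedo by reweighting the escaping-packet
#' histogram:
#'
#'   `R(c) = sum_j N_reflect(j) * (c / c_sim)^j`
#'
#' because with implicit capture a packet escaping after `j` interactions
#' carries weight proportional to `c^j` while its geometric path is
#' albedo-independent. The identity `R(c_sim) = r_total` holds exactly.
#'
#' @param reference An `mc_result` from [simulate_reference()].
#' @param c_sim The reference albedo used for that run.
#' @return A list of class `scaling_model` with the compressed histogram.
#' @export
scaling_model <- function(reference, c_sim = 0.9995) {
  stopifnot(inherits(reference, "mc_result"))
  if (c_sim <= 0 || c_sim >= 1) abort("c_sim must lie strictly in (0, 1)")
  h <- reference$n_reflect
  J <- length(h) - 1L
  keep <- which(h > 0)
  if (!length(keep)) abort("reference histogram is empty")
  # the overflow bin enters the sum with exponent J + 1; its mass is required
  # to be < 1e-4 of r_total so the approximation is immaterial for scaling
  # down in albedo, and the c = c_sim identity stays exact
  structure(list(j = keep, weight = h[keep],
                 overflow = h[J + 1L],
                 r_total = reference$r_total,
                 c_sim = c_sim,
                 reference = reference),
            class = "scaling_model")
}

#' @rdname scaling_model
#' @param model A `scaling_model`.
#' @param c Albedo values (one per wavelength), each in (0, 1) and not above
#'   `c_sim` (scaling up in albedo amplifies the histogram tail and its Monte
#'   Carlo noise; use a higher-albedo reference instead).
#' @param grid Optional wavelengths for the output spectrum; defaults to an
#'   index when omitted.
#' @return [scaled_reflectance()]: a reflectance [spectrum()] with
#'   `R(lambda) = sum_j N_reflect(j) (c(lambda)/c_sim)^j`.
#' @export
scaled_reflectance <- function(model, c, grid = NULL) {
  stopifnot(inherits(model, "scaling_model"))
  if (any(!is.finite(c)) || any(c <= 0) || any(c >= 1))
    abort("albedo values must lie strictly in (0, 1)")
  if (any(c > model$c_sim)) {
    abort(paste0("albedo exceeds the reference c_sim = ", model$c_sim,
                 "; scaling up in albedo is unstable - use a reference ",
                 "simulation with a higher c_sim"))
  }
  r <- scaled_r_values(model, c)
  if (is.null(grid)) grid <- seq_along(c)
  spectrum(grid, pmin(r, 1), kind = "reflectance")
}

#' @rdname scaling_model
#' @details `scaled_r_values()` evaluates the scaling sum and returns bare
#'   numeric reflectance values (no spectrum wrapper), in log space for
#'   numerical safety: `sum_j h_j * exp(j * log(c/c_sim))`.
#' @export
scaled_r_values <- function(model, c) {
  lu <- log(c) - log(model$c_sim)
  E <- exp(outer(lu, model$j)) # n_lambda x n_bins
  as.vector(E %*% model$weight)
}

#' Reduced single-scattering albedo from optical coefficients
#'
#' `c(lambda) = musp / (musp + mua)`, the variable through which total
#' reflectance of a semi-infinite medium depends on the coefficients. A zero
#' `mua` is clamped to `c = 1 - 1e-12`.
#'
#' @param props An [optical_properties()] tibble.
#' @return Numeric vector of albedos per wavelength.
#' @export
albedo_from_coefficients <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  tot <- props$musp + props$mua
  if (any(tot <= 0)) abort("mua + musp must be > 0 at every wavelength")
  pmin(props$musp / tot, 1 - 1e-12)
}

#' Pointwise albedo from measured reflectance
#'
#' Inverts the strictly increasing map `c -> R(c)` of a [scaling_model()] by
#' root bracketing, one wavelength at a time. This is the quantity a
#' single-geometry total-reflectance measurement identifies pointwise;
#' separating `mua` from `musp` additionally needs a spectral constraint
#' (see [invert_reflectance()]).
#'
#' @param model A `scaling_model`.
#' @param r Reflectance values, each in (0, r_total of the reference).
#' @return Albedo values in (0, c_sim\].
#' @export
albedo_from_reflectance <- function(model, r) {
  vapply(r, function(ri) {
    if (!is.finite(ri) || ri <= 0) abort("reflectance must be positive")
    if (ri >= model$r_total) return(model$c_sim)
    stats::uniroot(function(cc) scaled_r_values(model, cc) - ri,
                   lower = 1e-9, upper = model$c_sim, tol = 1e-12)$root
  }, numeric(1))
}

#' Extract absorption and reduced scattering coefficients from reflectance
#'
#' Least-squares fit of the albedo-scaling forward model to a measured
#' diffuse reflectance spectrum. Three parameterizations:
#'
#' * `"physical"` (default): `mua(lambda) = ln(10) * eps(lambda) * C`
#'   (Beer--Lambert, with `eps` the absorber extinction spectrum and the
#'   concentration `C` free) and `musp(lambda) = a * (lambda/500)^(-b)`
#'   (scattering power law with `a`, `b` free) -- three parameters. The power
#'   law is the generic tissue-like constraint; for scatterers whose spectral
#'   shape deviates from a power law (e.g. micron-sized spheres, whose Mie
#'   curve ripples by a few percent) the shape mismatch leaks into the weakly
#'   determined overall scale.
#' * `"shape"`: `musp(lambda) = a * S(lambda)` with a known scattering shape
#'   `S` (normalized internally to 1 at 500 nm, so `a` is `musp(500)`) --
#'   two parameters. This is the validation-phantom mode: the scatterer
#'   family is known (e.g. Mie shape of the bead suspension) and only
#'   concentrations are extracted.
#' * `"albedo"`: returns the pointwise albedo `c(lambda)` via
#'   [albedo_from_reflectance()] (no spectral constraint, and no separation
#'   of `mua` from `musp`).
#'
#' `C` and `a` are optimized on a log scale (they are positive and span
#' decades; log steps also keep Levenberg--Marquardt away from the degenerate
#' all-zero corner where the model saturates and gradients vanish), with
#' bounded Levenberg--Marquardt from `n_starts` seeded random initial points,
#' keeping the best fit.
#'
#' @param measured A reflectance [spectrum()] on the model grid.
#' @param model A [slab_scaling_model()] (recommended: the finite sample
#'   thickness is what makes `mua` and `musp` separately identifiable) or a
#'   semi-infinite [scaling_model()] (in which case only the albedo spectrum
#'   -- the ratio of the coefficients -- is identifiable and the returned
#'   absolute scale is arbitrary).
#' @param l_cm Sample thickness in cm (used with a slab model).
#' @param fit_bands Optional [band_set()]: evaluate the least-squares
#'   residuals only at the band centres. A spline reconstruction is an
#'   interpolant -- at the band centres it reproduces the measured values
#'   exactly, while between bands it adds correlated interpolation error that
#'   a plain least-squares fit would chase; restricting the residuals to the
#'   bands lets the spectral basis supply the between-band information.
#'   Extracted coefficient curves are always returned on the full grid.
#' @param extinction An extinction [spectrum()] `eps(lambda)` in
#'   cm^-1 (mg/mL)^-1, resampled internally onto the measured grid
#'   (required for the physical basis).
#' @param basis `"physical"`, `"shape"` or `"albedo"`.
#' @param scatter_shape A coefficient [spectrum()] giving the scattering
#'   spectral shape for `basis = "shape"` (any positive scale; normalized at
#'   500 nm internally).
#' @param seed Integer seed for the random multi-start.
#' @param n_starts Number of random initializations (default 10).
#' @param lower,upper Bounds for `(C, a, b)` in mg/mL, cm^-1 and
#'   dimensionless units; defaults `c(0, 0, 0)` and `c(5, 100, 4)` bracket
#'   tissue-like phantoms by a wide margin.
#' @return A list of class `reflectance_fit`: `extracted` (an
#'   [optical_properties()] tibble in the reduced representation, `g = 0`),
#'   `par` (named parameters for the physical basis), `residual_norm`,
#'   `n_iterations`, `converged`, `parameterization`, `fitted` (the modelled
#'   reflectance spectrum).
#' @export
invert_reflectance <- function(measured, model, extinction = NULL,
                               basis = c("physical", "shape", "albedo"),
                               scatter_shape = NULL,
                               l_cm = 1, fit_bands = NULL,
                               seed = 1L, n_starts = 10L,
                               lower = c(C = 0, a = 0, b = 0),
                               upper = c(C = 5, a = 100, b = 4)) {
  basis <- match.arg(basis)
  measured <- validate_spectrum(measured)
  if (!identical(spectrum_kind(measured), "reflectance"))
    abort("measured spectrum must be of kind 'reflectance'")
  slab <- inherits(model, "slab_scaling_model")
  if (!slab && !inherits(model, "scaling_model"))
    abort("model must be a scaling_model or slab_scaling_model")
  grid <- measured$wavelength_nm
  robs <- measured$value

  if (basis == "albedo") {
    if (slab) abort("the albedo basis needs a semi-infinite scaling_model")
    cc <- albedo_from_reflectance(model, robs)
    fit_r <- scaled_r_values(model, cc)
    out <- list(
      extracted = NULL, albedo = cc, par = NULL,
      residual_norm = sqrt(sum((fit_r - robs)^2)),
      n_iterations = length(grid), converged = TRUE,
      parameterization = "albedo",
      fitted = spectrum(grid, pmin(fit_r, 1), kind = "reflectance"),
      measured = measured)
    class(out) <- "reflectance_fit"
    return(out)
  }

  if (is.null(extinction)) abort("this basis needs an extinction spectrum")
  if (basis == "shape" && is.null(scatter_shape))
    abort("basis = 'shape' needs a scatter_shape spectrum")
  if (!is.null(fit_bands)) {
    fit_samples <- sample_bands(measured, fit_bands)
    wl_fit <- fit_samples$wavelength_nm
    r_fit <- fit_samples$value
  } else {
    wl_fit <- grid
    r_fit <- robs
  }
  eps_full <- resample_spectrum(extinction, grid)$value
  eps_fit <- resample_spectrum(extinction, wl_fit)$value
  if (basis == "shape") {
    sh <- resample_spectrum(scatter_shape, grid)
    s500 <- spectrum_at(sh, 500)
    if (s500 <= 0) abort("scatter_shape must be positive at 500 nm")
    shape_full <- sh$value / s500
    shape_fit <- resample_spectrum(sh, wl_fit)$value / s500
  }
  cmax <- model$c_sim * (1 - 1e-9)
  musp_of <- function(p, wl, shape) {
    if (basis == "shape") pmax(p[2] * shape, 1e-12)
    else pmax(p[2] * (wl / 500)^(-p[3]), 1e-12)
  }
  fwd_r <- function(p, wl, eps, shape) {
    mua <- log(10) * eps * p[1]
    musp <- musp_of(p, wl, shape)
    cc <- pmin(musp / (musp + mua), cmax)
    if (slab) slab_r_values(model, cc, (mua + musp) * l_cm)
    else scaled_r_values(model, cc)
  }
  npar <- if (basis == "shape") 2L else 3L
  # C and a live on a log scale inside the optimizer
  to_theta <- function(z) {
    th <- c(exp(z[1]), exp(z[2]))
    if (npar == 3L) th <- c(th, z[3])
    th
  }
  shp_fit <- if (basis == "shape") shape_fit else NULL
  residual_fn <- function(z) {
    fwd_r(to_theta(z), wl_fit, eps_fit, shp_fit) - r_fit
  }
  z_floor <- log(1e-6)
  z_lower <- c(max(log(lower[1]), z_floor, na.rm = TRUE),
               max(log(lower[2]), z_floor, na.rm = TRUE))
  z_upper <- c(log(upper[1]), log(upper[2]))
  if (npar == 3L) {
    z_lower <- c(z_lower, lower[3])
    z_upper <- c(z_upper, upper[3])
  }

  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i) {
    z <- c(runif(1, log(0.01), z_upper[1]), runif(1, log(0.1), z_upper[2]))
    if (npar == 3L) z <- c(z, runif(1, z_lower[3], z_upper[3]))
    z
  })
  ctrl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14,
                                     ptol = 1e-14, gtol = 0)
  best <- NULL
  for (z0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = z0, lower = z_lower, upper = z_upper,
                         fn = residual_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    rn <- sqrt(sum(res$fvec^2))
    if (is.null(best) || rn < best$rn)
      best <- list(rn = rn, par = to_theta(res$par), niter = res$niter,
                   converged = res$info %in% 1:4)
  }
  if (is.null(best)) abort("all optimization starts failed")
  p <- setNames(as.numeric(best$par),
                if (npar == 3L) c("C", "a", "b") else c("C", "a"))
  mua <- log(10) * eps_full * p[["C"]]
  musp <- if (basis == "shape") p[["a"]] * shape_full
          else p[["a"]] * (grid / 500)^(-p[["b"]])
  extracted <- optical_properties(grid, mua_per_cm = mua,
                                  mus_per_cm = musp, g = 0)
  fit_r <- fwd_r(p, grid, eps_full, if (basis == "shape") shape_full else NULL)
  out <- list(extracted = extracted, par = p,
              residual_norm = best$rn, n_iterations = best$niter,
              converged = best$converged, parameterization = basis,
              fitted = spectrum(grid, pmin(fit_r, 1), kind = "reflectance"),
              measured = measured)
  class(out) <- "reflectance_fit"
  out
}

#' @export
print.reflectance_fit <- function(x, ...) {
  cat(sprintf("<reflectance_fit> basis = %s, residual norm = %.3g, %s\n",
              x$parameterization, x$residual_norm,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$par))
    cat("  ", paste(sprintf("%s = %.4g", names(x$par), x$par),
                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.reflectance_fit <- function(x, ...) {
  if (identical(x$parameterization, "albedo")) {
    return(tibble::tibble(wavelength_nm = x$measured$wavelength_nm,
                          albedo = x$albedo))
  }
  tibble::as_tibble(x$extracted)
}

#' @export
glance.reflectance_fit <- function(x, ...) {
  tibble::tibble(parameterization = x$parameterization,
                 residual_norm = x$residual_norm,
                 n_iterations = x$n_iterations,
                 converged = x$converged,
                 C_mg_per_ml = if (!is.null(x$par)) x$par[["C"]] else NA_real_,
                 a_per_cm = if (!is.null(x$par)) x$par[["a"]] else NA_real_,
                 b = if (!is.null(x$par) && "b" %in% names(x$par))
                   x$par[["b"]] else NA_real_)
}

#' Diffusion-approximation reflectance of a semi-infinite medium
#'
#' Closed-form total diffuse reflectance under the diffusion approximation
#' with an extrapolated boundary, as a function of the reduced albedo
#' `a' = musp / (musp + mua)`:
#' `R = (a'/2) exp(-sqrt(3(1-a'))) (1 + exp(-(4/3) A sqrt(3(1-a'))))`,
#' where `A = (1 + r_d)/(1 - r_d)` accounts for internal reflection at the
#' surface (`A = 1` for matched boundaries). Accurate at high albedo; used as
#' an independent cross-check of the Monte Carlo engine, never as its
#' replacement.
#'
#' @param albedo Reduced albedo in (0, 1).
#' @param n_rel Relative refractive index inside/outside (1 = matched).
#' @return Diffuse reflectance fraction.
#' @export
diffusion_reflectance <- function(albedo, n_rel = 1) {
  stopifnot(all(albedo > 0 & albedo < 1))
  rd <- if (n_rel == 1) 0 else
    -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  A <- (1 + rd) / (1 - rd)
  s <- sqrt(3 * (1 - albedo))
  (albedo / 2) * exp(-s) * (1 + exp(-(4 / 3) * A * s))
}
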
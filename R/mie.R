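#' Mie efficiencies for a homogeneous sphere
#'
#' Computes the scattering efficiency `Qsca`, extinction efficiency `Qext`
#' and asymmetry parameter `g` (mean cosine of the scattering angle) from the
#' Lorenz--Mie partial-wave series. The series is truncated at
#' `nmax = ceil(x + 4.05 x^(1/3) + 2)` (the Wiscombe criterion); the
#' logarithmic derivative of the internal field is obtained by downward
#' recurrence for numerical stability, the Riccati--Bessel functions by upward
#' recurrence. For a real relative index the sphere does not absorb, so
#' `Qext == Qsca` to numerical precision.
#'
#' @param x Size parameter, `pi * diameter * n_medium / wavelength`, > 0.
#' @param m Relative refractive index `n_particle / n_medium`, > 0 (real).
#' @return A list with `qsca`, `qext`, `g`, `nmax`.
#' @examples
#' mie_efficiencies(x = 8.4, m = 1.2)$qsca
#' @export
mie_efficiencies <- function(x, m) {
  if (!is.finite(x) || x <= 0) abort("size parameter x must be > 0")
  if (!is.finite(m) || m <= 0) abort("relative index m must be > 0")
  nmax <- ceiling(x + 4.05 * x^(1 / 3) + 2)
  mx <- m * x
  # downward recurrence for the logarithmic derivative D_n(mx)
  nstart <- max(nmax, ceiling(abs(mx))) + 16L
  D <- numeric(nstart + 1L) # D[k] = D_{k-1}; D[nstart+1] = 0 seed
  for (k in nstart:1) {
    kn <- k / mx
    D[k] <- kn - 1 / (D[k + 1L] + kn)
  }
  D <- D[2:(nmax + 1L)] # D_1 .. D_nmax
  n <- seq_len(nmax)
  # Riccati-Bessel psi, chi by upward recurrence
  psi <- numeric(nmax); chi <- numeric(nmax)
  psi_m1 <- cos(x); psi_0 <- sin(x)
  chi_m1 <- -sin(x); chi_0 <- cos(x)
  pm2 <- psi_m1; pm1 <- psi_0; cm2 <- chi_m1; cm1 <- chi_0
  for (k in seq_len(nmax)) {
    psi[k] <- (2 * k - 1) / x * pm1 - pm2
    chi[k] <- (2 * k - 1) / x * cm1 - cm2
    pm2 <- pm1; pm1 <- psi[k]
    cm2 <- cm1; cm1 <- chi[k]
  }
  xi <- complex(real = psi, imaginary = -chi)
  psi_nm1 <- c(psi_0, psi[-nmax])
  xi_nm1 <- complex(real = psi_nm1, imaginary = -c(chi_0, chi[-nmax]))
  ta <- D / m + n / x
  tb <- D * m + n / x
  a <- (ta * psi - psi_nm1) / (ta * xi - xi_nm1)
  b <- (tb * psi - psi_nm1) / (tb * xi - xi_nm1)
  two_np1 <- 2 * n + 1
  qsca <- (2 / x^2) * sum(two_np1 * (Mod(a)^2 + Mod(b)^2))
  qext <- (2 / x^2) * sum(two_np1 * Re(a + b))
  gsum <- sum((n[-nmax] * (n[-nmax] + 2) / (n[-nmax] + 1)) *
                Re(a[-nmax] * Conj(a[-1]) + b[-nmax] * Conj(b[-1]))) +
    sum(two_np1 / (n * (n + 1)) * Re(a * Conj(b)))
  g <- (4 / x^2) * gsum / qsca
  list(qsca = qsca, qext = qext, g = g, nmax = nmax)
}

#' Refractive index dispersion of polystyrene and water
#'
#' Cauchy dispersion fits of the kind routinely used for polystyrene
#' microspheres (n ~ 1.59 at 589 nm) and water (n ~ 1.33), adequate over
#' 350--750 nm.
#'
#' @param wavelength_nm Wavelength(s) in nm.
#' @return Refractive index (same length as input).
#' @export
n_polystyrene <- function(wavelength_nm) {
  lu <- wavelength_nm / 1000
  1.5663 + 0.00785 / lu^2 + 0.000334 / lu^4
}

#' @rdname n_polystyrene
#' @export
n_water <- function(wavelength_nm) {
  1.3271 + 1901 / wavelength_nm^2
}

#' Microsphere suspension
#'
#' Describes a dilute suspension of non-absorbing spheres. The number density
#' per cm^3 is `(mass_fraction_pct/100) / (density * particle volume)`;
#' scatterers are treated as independent, which is adequate at the <= 0.5 w/v %
#' concentrations used for tissue phantoms.
#'
#' @param diameter_um Sphere diameter in um, > 0.
#' @param mass_fraction_pct Mass concentration, w/v % (g per 100 mL), >= 0.
#' @param n_particle Particle refractive index: a number or a function of
#'   wavelength in nm (default polystyrene dispersion).
#' @param n_medium Medium refractive index: a number or a function of
#'   wavelength in nm (default water dispersion).
#' @param particle_density_g_per_ml Particle density, default 1.05 (polystyrene).
#' @return A list of class `bead_suspension`.
#' @export
bead_suspension <- function(diameter_um = 1.0, mass_fraction_pct = 0.25,
                            n_particle = n_polystyrene, n_medium = n_water,
                            particle_density_g_per_ml = 1.05) {
  stopifnot(diameter_um > 0, mass_fraction_pct >= 0, particle_density_g_per_ml > 0)
  d_cm <- diameter_um * 1e-4
  vol_cm3 <- pi / 6 * d_cm^3
  number_density <- (mass_fraction_pct / 100) / (particle_density_g_per_ml * vol_cm3)
  structure(list(diameter_um = diameter_um,
                 mass_fraction_pct = mass_fraction_pct,
                 n_particle = n_particle, n_medium = n_medium,
                 particle_density_g_per_ml = particle_density_g_per_ml,
                 number_density_per_cm3 = number_density),
            class = "bead_suspension")
}

index_at <- function(nref, wavelength_nm) {
  if (is.function(nref)) nref(wavelength_nm) else rep_len(nref, length(wavelength_nm))
}

#' Scattering properties of a microsphere suspension
#'
#' Evaluates Mie theory per wavelength: `mus = number_density * Qsca * pi r^2`
#' with the size parameter computed from the wavelength in the medium
#' (`lambda / n_medium`); `g` from the asymmetry sum; `mua = 0` for
#' non-absorbing spheres. Doubling the mass fraction doubles `mus` exactly
#' (independent scatterers).
#'
#' @param suspension A [bead_suspension()].
#' @param grid Wavelengths in nm.
#' @return An [optical_properties()] tibble.
#' @export
suspension_optics <- function(suspension, grid = reflectance_grid()) {
  stopifnot(inherits(suspension, "bead_suspension"))
  np <- index_at(suspension$n_particle, grid)
  nm <- index_at(suspension$n_medium, grid)
  x <- pi * suspension$diameter_um * nm / (grid / 1000)
  m <- np / nm
  r_cm <- suspension$diameter_um * 1e-4 / 2
  geom <- pi * r_cm^2
  qs <- vapply(seq_along(grid), function(i) {
    eff <- mie_efficiencies(x[i], m[i])
    c(eff$qsca, eff$g)
  }, numeric(2))
  mus <- suspension$number_density_per_cm3 * qs[1, ] * geom
  optical_properties(grid, mua_per_cm = 0, mus_per_cm = mus, g = qs[2, ])
}
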
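#' Monte Carlo transport configuration
#'
#' Settings for photon-packet transport in a homogeneous slab. The default
#' geometry is a semi-infinite aqueous medium (`slab_thickness_cm = Inf`)
#' under a pencil beam at normal incidence, with a refractive-index mismatch
#' of 1.33 inside / 1.0 outside, approximating a thick liquid phantom under an
#' integrating sphere. The random seed is mandatory: there is no hidden
#' global state and two runs with the same seed give identical results.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_photons Number of photon packets, >= 1000.
#' @param slab_thickness_cm Slab thickness in cm, > 0, or `Inf` for a
#'   semi-infinite medium.
#' @param n_inside,n_outside Refractive indices of the medium and the
#'   surroundings. Set them equal for matched boundaries.
#' @param roulette_threshold Packet weight below which Russian roulette is
#'   played, in (0, 1).
#' @param roulette_survival Survival factor m (a packet survives roulette with
#'   probability 1/m and its weight is multiplied by m), integer >= 2.
#' @param hist_cap Largest interaction count binned individually; escaping
#'   weight with more interactions goes into an overflow bin.
#' @param max_steps Per-packet cap on interaction count; in a non-absorbing
#'   semi-infinite medium packets reaching the cap are closed analytically
#'   (they escape upward with probability 1), otherwise their weight is
#'   reported as `lost`.
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(seed, n_photons = 1e5, slab_thickness_cm = Inf,
                      n_inside = 1.33, n_outside = 1.0,
                      roulette_threshold = 1e-4, roulette_survival = 10L,
                      hist_cap = 1e4, max_steps = 1e6) {
  if (missing(seed)) abort("mc_config(): a seed is mandatory")
  stopifnot(n_photons >= 1e3, slab_thickness_cm > 0,
            roulette_threshold > 0, roulette_threshold < 1,
            roulette_survival >= 2, hist_cap >= 10, max_steps > 0)
  structure(list(seed = as.integer(seed), n_photons = as.integer(n_photons),
                 slab_thickness_cm = slab_thickness_cm,
                 n_inside = n_inside, n_outside = n_outside,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = as.integer(roulette_survival),
                 hist_cap = as.integer(hist_cap), max_steps = max_steps),
            class = "mc_config")
}

#' Simulate diffuse reflectance of a homogeneous slab
#'
#' Runs MCML-style photon-packet transport for a single set of optical
#' coefficients: exponential step sampling with `mu_t = mua + mus`, implicit
#' capture (a fraction `mua/mu_t` of the packet weight deposited per
#' interaction), Henyey--Greenstein scattering, Fresnel boundaries, Russian
#' roulette. Escaping weight through the top surface is accumulated into the
#' total diffuse reflectance `r_total` and binned by the packet's interaction
#' count, giving the histogram `n_reflect(j)` with
#' `sum_j n_reflect(j) == r_total` exactly.
#'
#' @param props Either a one-row [optical_properties()] tibble or a named
#'   numeric vector/list with `mua`, `mus`, `g`.
#' @param cfg An [mc_config()].
#' @return A list of class `mc_result`: `r_total`, `t_total`, `absorbed`,
#'   `specular`, `roulette_net`, `lost`, `n_reflect` (weight fractions by
#'   interaction count, last entry = overflow), `mean_interactions`, `seed`,
#'   `n_photons`, and the input coefficients.
#' @export
simulate_transport <- function(props, cfg) {
  stopifnot(inherits(cfg, "mc_config"))
  if (inherits(props, "optical_properties")) {
    if (nrow(props) != 1L)
      abort("pass a single-wavelength row of optical properties")
    mua <- props$mua; mus <- props$mus; g <- props$g
  } else {
    props <- as.list(props)
    mua <- props$mua; mus <- props$mus; g <- props$g
  }
  if (is.null(mua) || is.null(mus) || is.null(g) ||
      !is.finite(mua) || !is.finite(mus) || !is.finite(g))
    abort("props must provide finite mua, mus, g")
  set.seed(cfg$seed)
  raw <- .mc_run(mua, mus, g, cfg$n_inside, cfg$n_outside,
                 cfg$slab_thickness_cm, cfg$n_photons,
                 cfg$roulette_threshold, cfg$roulette_survival,
                 cfg$hist_cap, cfg$max_steps)
  structure(c(raw, list(seed = cfg$seed, mua = mua, mus = mus, g = g,
                        config = cfg)),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> r_total = %.5f, t = %.5f, absorbed = %.5f, specular = %.5f\n",
    x$r_total, x$t_total, x$absorbed, x$specular))
  cat(sprintf("  mean interactions of escaping packets: %.1f (n = %d, seed = %d)\n",
              x$mean_interactions, x$n_photons, x$seed))
  invisible(x)
}

#' @export
tidy.mc_result <- function(x, ...) {
  h <- x$n_reflect
  J <- length(h) - 1L
  tibble::tibble(interactions = c(seq_len(J), NA_integer_),
                 weight = h,
                 overflow = c(rep(FALSE, J), TRUE)) |>
    dplyr::filter(.data$weight > 0)
}

#' @export
glance.mc_result <- function(x, ...) {
  tibble::tibble(r_total = x$r_total, t_total = x$t_total,
                 absorbed = x$absorbed, specular = x$specular,
                 roulette_net = x$roulette_net, lost = x$lost,
                 mean_interactions = x$mean_interactions,
                 overflow = x$overflow, n_photons = x$n_photons,
                 seed = x$seed)
}

#' Weight bookkeeping of a Monte Carlo run
#'
#' `specular + reflected + transmitted + absorbed + roulette_net + lost`
#' equals 1 exactly (up to floating point): Russian roulette reshuffles weight
#' between packets but its net effect is tallied in `roulette_net`.
#'
#' @param result An `mc_result`.
#' @return The sum above (should be 1 to machine precision).
#' @export
mc_weight_balance <- function(result) {
  result$specular + result$r_total + result$t_total + result$absorbed +
    result$roulette_net + result$lost
}

#' Reference simulation for albedo scaling
#'
#' Runs the forward Monte Carlo for a reference phantom of reduced
#' single-scattering albedo `c_sim` in the similarity (reduced, `g = 0`)
#' representation: `mus = c_sim`, `mua = 1 - c_sim`, `mu_t = 1` (the absolute
#' scale is irrelevant in a semi-infinite medium). When `c_sim` is constant a
#' single run is broadcast across wavelengths.
#'
#' @param cfg An [mc_config()].
#' @param c_sim Reference albedo in (0, 1); a scalar or per-wavelength vector
#'   (all values must currently be equal; per-wavelength references are
#'   broadcast from the unique value).
#' @return An `mc_result` (single run) for scalar/constant `c_sim`.
#' @export
simulate_reference <- function(cfg, c_sim = 0.9995) {
  u <- unique(c_sim)
  if (length(u) != 1L)
    abort("non-constant c_sim is not supported; run simulate_transport per wavelength")
  if (u <= 0 || u >= 1) abort("c_sim must lie strictly in (0, 1)")
  simulate_transport(c(mua = 1 - u, mus = u, g = 0), cfg)
}
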
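#' Slab-aware albedo-scaling model
#'
#' Total reflectance of a *semi-infinite* medium depends on the optical
#' coefficients only through the albedo, so a single semi-infinite reference
#' cannot separate `mua` from `musp` (any common rescaling of both leaves the
#' reflectance unchanged). A real liquid phantom sits in a cuvette of known
#' thickness `l`, and the finite optical thickness `tau = (mua + musp) * l`
#' breaks that scale invariance: transmission losses through the back face
#' make the reflectance sensitive to the absolute coefficient scale.
#'
#' `slab_scaling_model()` runs one reference Monte Carlo simulation per node
#' of a logarithmic `tau` grid (each at reference albedo `c_sim`, reduced
#' `g = 0` representation, slab geometry). At fixed `tau` the albedo-scaling
#' identity `R(c) = sum_j N_reflect(j) (c/c_sim)^j` is exact, because packet
#' paths measured in mean free paths do not depend on the albedo; between
#' nodes the model interpolates with a C^1 (Catmull--Rom) cubic in `log(tau)`
#' so that least-squares fits see smooth derivatives.
#'
#' @param cfg An [mc_config()]; per-node seeds derive from `cfg$seed`.
#'   `slab_thickness_cm` is ignored (the node geometry is set by `tau`).
#' @param c_sim Reference albedo in (0, 1).
#' @param tau_grid Optical-thickness nodes (dimensionless), log-spaced by
#'   default from 0.3 to 60; beyond 60 a slab is indistinguishable from a
#'   semi-infinite medium at these albedos and `tau` is clamped.
#' @return A list of class `slab_scaling_model`.
#' @export
slab_scaling_model <- function(cfg, c_sim = 0.9995,
                               tau_grid = exp(seq(log(0.3), log(60),
                                                  length.out = 22))) {
  stopifnot(inherits(cfg, "mc_config"), c_sim > 0, c_sim < 1,
            all(tau_grid > 0), !is.unsorted(tau_grid))
  nodes <- lapply(seq_along(tau_grid), function(k) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k
    cfg_k$slab_thickness_cm <- tau_grid[k] # with mu_t = 1 per unit length
    res <- simulate_transport(c(mua = 1 - c_sim, mus = c_sim, g = 0), cfg_k)
    h <- res$n_reflect
    keep <- which(h > 0)
    list(j = keep, weight = h[keep], r_total = res$r_total)
  })
  structure(list(tau_grid = tau_grid, log_tau = log(tau_grid),
                 c_sim = c_sim, nodes = nodes, cfg = cfg),
            class = "slab_scaling_model")
}

#' @rdname slab_scaling_model
#' @param model A `slab_scaling_model`.
#' @param c Albedo values in (0, c_sim\].
#' @param tau Optical thickness values `(mua + musp) * l`, same length as `c`
#'   (clamped to the model's tau range).
#' @return `slab_r_values()`: bare numeric reflectance values, computed as the
#'   exact scaling sum at the four bracketing tau nodes blended by the cubic.
#' @export
slab_r_values <- function(model, c, tau) {
  stopifnot(inherits(model, "slab_scaling_model"), length(c) == length(tau))
  if (any(!is.finite(c)) || any(c <= 0) || any(c > model$c_sim))
    abort("albedo must lie in (0, c_sim]")
  nt <- length(model$tau_grid)
  lt <- log(pmin(pmax(tau, model$tau_grid[1]), model$tau_grid[nt]))
  k <- findInterval(lt, model$log_tau, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), nt - 1L)
  s <- (lt - model$log_tau[k]) / (model$log_tau[k + 1L] - model$log_tau[k])
  lu <- log(c) - log(model$c_sim)
  node_sum <- function(idx, lam_sel) {
    nd <- model$nodes[[idx]]
    as.vector(exp(outer(lu[lam_sel], nd$j)) %*% nd$weight)
  }
  out <- numeric(length(c))
  for (kk in unique(k)) {
    sel <- which(k == kk)
    i0 <- max(kk - 1L, 1L); i3 <- min(kk + 2L, nt)
    y0 <- node_sum(i0, sel); y1 <- node_sum(kk, sel)
    y2 <- node_sum(kk + 1L, sel); y3 <- node_sum(i3, sel)
    ss <- s[sel]
    out[sel] <- 0.5 * (2 * y1 + (-y0 + y2) * ss +
                         (2 * y0 - 5 * y1 + 4 * y2 - y3) * ss^2 +
                         (-y0 + 3 * y1 - 3 * y2 + y3) * ss^3)
  }
  out
}

#' Slab reflectance from optical coefficients
#'
#' Forward map from coefficient spectra to the diffuse reflectance of a slab
#' of thickness `l_cm`, via the slab-aware scaling model (reduced
#' representation: albedo `musp/(musp+mua)`, optical thickness
#' `(mua+musp) * l`).
#'
#' @param model A [slab_scaling_model()].
#' @param props An [optical_properties()] tibble.
#' @param l_cm Slab thickness in cm.
#' @return A reflectance [spectrum()] on the grid of `props`.
#' @export
slab_reflectance <- function(model, props, l_cm = 1) {
  stopifnot(inherits(props, "optical_properties"), l_cm > 0)
  cc <- pmin(albedo_from_coefficients(props), model$c_sim)
  tau <- (props$mua + props$musp) * l_cm
  r <- slab_r_values(model, cc, tau)
  spectrum(props$wavelength_nm, pmin(pmax(r, 0), 1), kind = "reflectance")
}
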
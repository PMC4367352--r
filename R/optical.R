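#' Optical properties of a homogeneous medium
#'
#' A per-wavelength table of the absorption coefficient `mua` (cm^-1), the
#' scattering coefficient `mus` (cm^-1) and the anisotropy factor `g` (mean
#' cosine of the single-scattering deflection, in (-1, 1)). The reduced
#' scattering coefficient `musp = mus * (1 - g)` is derived and stored as a
#' column so the table can be plotted and joined directly.
#'
#' @param wavelength_nm Strictly increasing wavelengths in nm.
#' @param mua_per_cm Absorption coefficient, cm^-1, >= 0 (recycled).
#' @param mus_per_cm Scattering coefficient, cm^-1, >= 0 (recycled).
#' @param g Anisotropy factor in (-1, 1) (recycled).
#' @return A tibble of class `optical_properties` with columns
#'   `wavelength_nm`, `mua`, `mus`, `g`, `musp`.
#' @export
optical_properties <- function(wavelength_nm, mua_per_cm, mus_per_cm, g) {
  n <- length(wavelength_nm)
  if (n < 1) abort("empty wavelength grid")
  if (n > 1 && any(diff(wavelength_nm) <= 0))
    abort("wavelengths must be strictly increasing")
  out <- tibble::tibble(
    wavelength_nm = as.numeric(wavelength_nm),
    mua = rep_len(as.numeric(mua_per_cm), n),
    mus = rep_len(as.numeric(mus_per_cm), n),
    g = rep_len(as.numeric(g), n)
  )
  if (any(out$mua < 0) || any(out$mus < 0)) abort("coefficients must be >= 0")
  if (any(out$g <= -1) || any(out$g >= 1)) abort("g must lie in (-1, 1)")
  if (!all(is.finite(out$mua)) || !all(is.finite(out$mus)) || !all(is.finite(out$g)))
    abort("non-finite optical properties")
  out$musp <- out$mus * (1 - out$g)
  class(out) <- c("optical_properties", class(out))
  out
}

#' Phantom recipes
#'
#' A recipe for a liquid homogeneous phantom: a haemoglobin-like absorber
#' (mg/mL), polystyrene microspheres as the scatterer (w/v %, bead diameter in
#' um), and two fluorophores -- an NADH-like low-quantum-yield fluorophore and
#' a carbostyril-like high-quantum-yield fluorophore (both ug/mL). `thickness_cm`
#' is the cuvette/sample thickness used by the fluorescence model.
#'
#' @param hb_mg_per_ml Absorber concentration, mg/mL, >= 0.
#' @param polystyrene_pct Microsphere mass concentration, w/v %, >= 0.
#' @param nadh_ug_per_ml NADH-like fluorophore concentration, ug/mL, >= 0.
#' @param carbostyril_ug_per_ml Carbostyril-like fluorophore concentration, ug/mL, >= 0.
#' @param bead_diameter_um Microsphere diameter in um (> 0), default 1.
#' @param thickness_cm Sample thickness in cm (> 0), default 1.
#' @param temperature_c Sample temperature in degrees Celsius.
#' @param label Optional name.
#' @return A one-row tibble of class `phantom_recipe`.
#' @export
phantom_recipe <- function(hb_mg_per_ml = 0, polystyrene_pct = 0,
                           nadh_ug_per_ml = 0, carbostyril_ug_per_ml = 0,
                           bead_diameter_um = 1.0, thickness_cm = 1.0,
                           temperature_c = 22, label = NA_character_) {
  stopifnot(hb_mg_per_ml >= 0, polystyrene_pct >= 0, nadh_ug_per_ml >= 0,
            carbostyril_ug_per_ml >= 0, bead_diameter_um > 0, thickness_cm > 0)
  out <- tibble::tibble(
    label = label,
    hb_mg_per_ml = hb_mg_per_ml,
    polystyrene_pct = polystyrene_pct,
    nadh_ug_per_ml = nadh_ug_per_ml,
    carbostyril_ug_per_ml = carbostyril_ug_per_ml,
    bead_diameter_um = bead_diameter_um,
    thickness_cm = thickness_cm,
    temperature_c = temperature_c
  )
  class(out) <- c("phantom_recipe", class(out))
  out
}

#' The five validation phantom recipes
#'
#' The standard five-phantom validation set: crossed ladders of absorber and
#' scatterer so that pairs share one property while the other differs
#' (phantoms 3 and 5 share the absorber concentration; 2 and 5 share the
#' scatterer concentration; 1 and 4 share the scatterer concentration), with
#' an NADH ladder rising across phantoms 1 to 3.
#'
#' @return A five-row `phantom_recipe` tibble.
#' @export
validation_phantoms <- function() {
  out <- dplyr::bind_rows(
    phantom_recipe(0.25, 0.50, 0.50, 1.50, label = "phantom1"),
    phantom_recipe(0.50, 0.25, 1.00, 1.00, label = "phantom2"),
    phantom_recipe(1.00, 0.15, 1.50, 0.50, label = "phantom3"),
    phantom_recipe(0.50, 0.50, 1.00, 1.00, label = "phantom4"),
    phantom_recipe(1.00, 0.25, 1.00, 1.00, label = "phantom5")
  )
  class(out) <- c("phantom_recipe", class(tibble::tibble()))
  out
}

#' Read and write phantom recipes as JSON
#'
#' @param path File path.
#' @return [read_recipe()]: a `phantom_recipe` tibble.
#' @export
read_recipe <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(phantom_recipe, as.list(x))
}

#' @rdname read_recipe
#' @param recipe A one-row `phantom_recipe`.
#' @export
write_recipe <- function(recipe, path) {
  jsonlite::write_json(as.list(recipe[1, ]), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
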
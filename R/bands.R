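#' Spectral band sets
#'
#' A band set is the list of centre wavelengths at which a miniaturized
#' detector samples a spectrum. Bands are ideal point samples (nearest grid
#' point) by default; [sample_bands()] offers an optional top-hat average for
#' filter realism. At least 4 bands are required so a cubic spline can
#' reconstruct the full spectrum.
#'
#' @param centers_nm Strictly increasing band centre wavelengths, >= 4 of them.
#' @param label Free-text label.
#' @return A tibble of class `band_set` with column `center_nm`.
#' @export
band_set <- function(centers_nm, label = "") {
  centers_nm <- as.numeric(centers_nm)
  if (length(centers_nm) < 4L) abort("need at least 4 bands (cubic spline minimum)")
  if (any(diff(centers_nm) <= 0)) abort("band centers must be strictly increasing")
  out <- tibble::tibble(center_nm = centers_nm)
  attr(out, "label") <- label
  class(out) <- c("band_set", class(out))
  out
}

#' @rdname band_set
#' @details `reflectance_bands()` is the default 16-band reflectance set:
#'   13 anchors evenly spread over 350--750 nm plus bands at 420, 540 and
#'   577 nm covering the haemoglobin Soret and Q features. It is a
#'   configurable stand-in: instruments define their own validated set, which
#'   can be passed anywhere a `band_set` is accepted.
#' @export
reflectance_bands <- function() {
  centers <- sort(unique(c(round(seq(350, 750, length.out = 13)), 420, 540, 577)))
  band_set(centers, label = "16-band reflectance (stand-in set)")
}

#' @rdname band_set
#' @details `fluorescence_bands()` is the 10-band emission set at 380, 400,
#'   420, 450, 480, 510, 540, 560, 580 and 600 nm.
#' @export
fluorescence_bands <- function() {
  band_set(c(380, 400, 420, 450, 480, 510, 540, 560, 580, 600),
           label = "10-band fluorescence")
}

#' Sample a spectrum at a set of bands
#'
#' @param s A [spectrum()].
#' @param bands A [band_set()]; centers must lie within the spectrum range.
#' @param fwhm_nm Optional top-hat full width for filter-style band averaging;
#'   `0` (default) takes the value at the nearest grid point.
#' @return A tibble with columns `wavelength_nm`, `value` (one row per band).
#' @export
sample_bands <- function(s, bands, fwhm_nm = 0) {
  s <- validate_spectrum(s)
  stopifnot(inherits(bands, "band_set"))
  ctr <- bands$center_nm
  rng <- range(s$wavelength_nm)
  if (any(ctr < rng[1] | ctr > rng[2]))
    abort("band center outside the spectrum range")
  if (fwhm_nm > 0) {
    val <- vapply(ctr, function(b) {
      inb <- s$wavelength_nm >= b - fwhm_nm / 2 & s$wavelength_nm <= b + fwhm_nm / 2
      mean(s$value[inb])
    }, numeric(1))
  } else {
    idx <- vapply(ctr, function(b) which.min(abs(s$wavelength_nm - b)), integer(1))
    val <- s$value[idx]
    ctr <- s$wavelength_nm[idx]
  }
  tibble::tibble(wavelength_nm = ctr, value = val)
}

#' Reconstruct a full spectrum from sparse band samples
#'
#' Cubic-spline interpolation of the band samples onto a dense grid. The
#' default `"fmm"` end condition fits cubics through the boundary points and
#' reproduces cubic polynomials exactly; `"natural"` (zero second derivative
#' at the ends) is available. Negative reconstructed values are clamped to 0,
#' with the number of clamped points recorded in the `n_clamped` attribute.
#'
#' @param samples A tibble/data frame with columns `wavelength_nm`, `value`
#'   (>= 4 rows, strictly increasing, no duplicates).
#' @param grid Target wavelength grid.
#' @param kind Spectrum kind of the result.
#' @param method Spline end condition, `"fmm"` or `"natural"`.
#' @return A [spectrum()] on `grid`.
#' @export
reconstruct_spectrum <- function(samples, grid,
                                 kind = c("reflectance", "fluorescence",
                                          "extinction", "coefficient"),
                                 method = c("fmm", "natural")) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  w <- samples$wavelength_nm
  v <- samples$value
  if (length(w) < 4L) abort("need at least 4 samples for a cubic spline")
  if (anyDuplicated(w)) abort("duplicate sample wavelengths")
  if (any(diff(w) < 0)) { o <- order(w); w <- w[o]; v <- v[o] }
  sp <- stats::spline(w, v, xout = grid, method = method)
  y <- sp$y
  n_clamped <- sum(y < 0)
  if (n_clamped > 0) y[y < 0] <- 0
  if (kind == "reflectance") y <- pmin(y, 1)
  out <- spectrum(grid, y, kind = kind)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Fluorescence band ratio
#'
#' Ratio of the spectrum value at `band_a_nm` to the value at `band_b_nm`
#' (default 450 nm / 390 nm), the summary used to track the NADH-like
#' contribution in bulk fluorescence spectra.
#'
#' @param s A [spectrum()].
#' @param band_a_nm,band_b_nm Numerator and denominator wavelengths (nm).
#' @return A non-negative ratio.
#' @export
band_ratio <- function(s, band_a_nm = 450, band_b_nm = 390) {
  s <- validate_spectrum(s)
  va <- spectrum_at(s, band_a_nm)
  vb <- spectrum_at(s, band_b_nm)
  if (vb == 0) abort("band ratio denominator is zero")
  va / vb
}
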
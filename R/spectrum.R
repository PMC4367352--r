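#' Spectra as tibbles
#'
#' A spectrum is a tibble with columns `wavelength_nm` (strictly increasing,
#' in nanometres) and `value`, plus a `kind` attribute recording what the
#' values are. Reflectance spectra are dimensionless fractions in \[0, 1\];
#' fluorescence spectra are intensities in arbitrary (but internally
#' consistent) units; extinction spectra are in cm^-1 per concentration unit;
#' coefficient spectra (e.g. an absorption coefficient) are in cm^-1.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param value Numeric vector of non-negative values, same length.
#' @param kind One of `"reflectance"`, `"fluorescence"`, `"extinction"`,
#'   `"coefficient"`.
#' @return A tibble of class `spectrum` with columns `wavelength_nm`, `value`.
#' @examples
#' s <- spectrum(c(400, 500), c(0, 1), kind = "reflectance")
#' resample_spectrum(s, 450)$value # 0.5
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("reflectance", "fluorescence", "extinction",
                              "coefficient")) {
  kind <- match.arg(kind)
  out <- tibble::tibble(wavelength_nm = as.numeric(wavelength_nm),
                        value = as.numeric(value))
  attr(out, "kind") <- kind
  class(out) <- c("spectrum", class(out))
  validate_spectrum(out)
}

#' @export
#' @rdname spectrum
#' @param s A spectrum.
validate_spectrum <- function(s) {
  w <- s$wavelength_nm
  v <- s$value
  if (length(w) < 2L) abort("a spectrum needs at least 2 points")
  if (length(w) != length(v)) abort("wavelength and value lengths differ")
  if (anyNA(w) || anyNA(v) || !all(is.finite(w)) || !all(is.finite(v)))
    abort("spectrum contains non-finite entries")
  if (any(diff(w) <= 0)) abort("wavelengths must be strictly increasing")
  bad <- which(v < 0)
  if (length(bad))
    abort(sprintf("negative value at wavelength %g nm (row %d)", w[bad[1]], bad[1]))
  if (identical(spectrum_kind(s), "reflectance") && any(v > 1)) {
    bad <- which(v > 1)[1]
    abort(sprintf("reflectance value %g > 1 at %g nm (row %d)", v[bad], w[bad], bad))
  }
  s
}

#' @export
#' @rdname spectrum
spectrum_kind <- function(s) attr(s, "kind") %||% "coefficient"

#' Canonical wavelength grids
#'
#' The package works on a 350--750 nm grid at 1 nm steps for reflectance and
#' a 380--600 nm grid at 1 nm for fluorescence emission, matching the ranges
#' over which benchtop instruments record these signals for aqueous phantoms.
#'
#' @param step_nm Grid step in nm (default 1).
#' @return Numeric vector of wavelengths.
#' @export
reflectance_grid <- function(step_nm = 1) seq(350, 750, by = step_nm)

#' @rdname reflectance_grid
#' @export
emission_grid <- function(step_nm = 1) seq(380, 600, by = step_nm)

#' Read and write two-column spectra
#'
#' Reads a delimited text file with two columns (wavelength in nm, value).
#' The delimiter is auto-detected among comma, tab and semicolon; a header
#' line is optional. Rows are sorted by wavelength; duplicate wavelengths are
#' averaged with a warning. Validation errors name the offending line.
#'
#' @param path File path.
#' @param kind Spectrum kind (see [spectrum()]).
#' @return A [spectrum()] tibble.
#' @export
read_spectrum <- function(path, kind = c("reflectance", "fluorescence",
                                         "extinction", "coefficient")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("'%s' is empty", path))
  first <- lines[[1]]
  delim_counts <- vapply(c(",", "\t", ";"),
                         function(d) lengths(regmatches(first, gregexpr(d, first, fixed = TRUE))),
                         integer(1))
  delim <- c(",", "\t", ";")[which.max(delim_counts)]
  if (max(delim_counts) == 0L) delim <- ","
  parse_row <- function(line, i) {
    parts <- trimws(strsplit(line, delim, fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) < 2L)
      abort(sprintf("line %d of '%s' does not have two columns", i, path))
    suppressWarnings(as.numeric(parts[1:2]))
  }
  start <- 1L
  head_vals <- suppressWarnings(as.numeric(trimws(strsplit(first, delim, fixed = TRUE)[[1]][1:2])))
  if (anyNA(head_vals)) start <- 2L # header line
  if (start > length(lines)) abort(sprintf("'%s' has a header but no data", path))
  rows <- lapply(seq(start, length(lines)), function(i) {
    vals <- parse_row(lines[[i]], i)
    if (anyNA(vals))
      abort(sprintf("malformed row at line %d of '%s'", i, path))
    vals
  })
  m <- do.call(rbind, rows)
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  if (anyDuplicated(m[, 1])) {
    warn("duplicate wavelengths averaged")
    agg <- tapply(m[, 2], m[, 1], mean)
    m <- cbind(as.numeric(names(agg)), as.numeric(agg))
  }
  spectrum(m[, 1], m[, 2], kind = kind)
}

#' @rdname read_spectrum
#' @param s A spectrum to write.
#' @param delim Output delimiter (default comma).
#' @export
write_spectrum <- function(s, path, delim = ",") {
  s <- validate_spectrum(s)
  header <- paste("wavelength_nm", "value", sep = delim)
  body <- paste(formatC(s$wavelength_nm, digits = 15, format = "g"),
                formatC(s$value, digits = 15, format = "g"), sep = delim)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; extrapolation outside the source range is an error.
#'
#' @param s A [spectrum()].
#' @param grid Target wavelengths in nm, strictly increasing.
#' @return A [spectrum()] on `grid`, same kind.
#' @export
resample_spectrum <- function(s, grid) {
  s <- validate_spectrum(s)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) abort("target grid must be strictly increasing")
  if (min(grid) < min(s$wavelength_nm) || max(grid) > max(s$wavelength_nm))
    abort("resample grid extends beyond the spectrum range (extrapolation refused)")
  v <- stats::approx(s$wavelength_nm, s$value, xout = grid, method = "linear")$y
  out <- tibble::tibble(wavelength_nm = grid, value = v)
  attr(out, "kind") <- spectrum_kind(s)
  class(out) <- c("spectrum", class(tibble::tibble()))
  out
}

# value lookup at one or more wavelengths (linear interpolation, range-checked)
spectrum_at <- function(s, wavelength_nm) {
  if (min(wavelength_nm) < min(s$wavelength_nm) ||
      max(wavelength_nm) > max(s$wavelength_nm))
    abort("wavelength outside spectrum range")
  stats::approx(s$wavelength_nm, s$value, xout = wavelength_nm)$y
}
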
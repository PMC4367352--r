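#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types: spectra,
#' optical-property tables, reflectance fits (measured vs fitted overlay),
#' phantom datasets (all four signals) and chain results (extracted vs
#' expected coefficients).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name phantomspec-autoplot
NULL

#' @rdname phantomspec-autoplot
#' @export
autoplot.spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength_nm, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = spectrum_kind(object)) +
    ggplot2::theme_minimal()
}

#' @rdname phantomspec-autoplot
#' @export
autoplot.optical_properties <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("mua", "musp"),
                              names_to = "coefficient", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~coefficient, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(mua = "absorption (1/cm)",
                            musp = "reduced scattering (1/cm)"))) +
    ggplot2::labs(x = "wavelength (nm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname phantomspec-autoplot
#' @export
autoplot.reflectance_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(wavelength_nm = object$measured$wavelength_nm,
                   value = object$measured$value, curve = "measured"),
    tibble::tibble(wavelength_nm = object$fitted$wavelength_nm,
                   value = object$fitted$value, curve = "fitted"))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "diffuse reflectance",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname phantomspec-autoplot
#' @export
autoplot.phantom_dataset <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, scales = "free_y") +
    ggplot2::labs(x = "wavelength (nm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname phantomspec-autoplot
#' @export
autoplot.chain_result <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(object$per_phantom, function(p) {
    tibble::tibble(label = p$recipe$label,
                   wavelength_nm = p$fit$extracted$wavelength_nm,
                   mua_extracted = p$fit$extracted$mua,
                   mua_expected = p$dataset$truth$optics$mua,
                   musp_extracted = p$fit$extracted$musp,
                   musp_expected = p$dataset$truth$optics$musp)
  }))
  long <- dplyr::bind_rows(
    tibble::tibble(label = df$label, expected = df$mua_expected,
                   extracted = df$mua_extracted, coefficient = "mua"),
    tibble::tibble(label = df$label, expected = df$musp_expected,
                   extracted = df$musp_extracted, coefficient = "musp"))
  ggplot2::ggplot(long, ggplot2::aes(.data$expected, .data$extracted,
                                     colour = .data$label)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~coefficient, scales = "free") +
    ggplot2::labs(x = "expected (1/cm)", y = "extracted (1/cm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
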
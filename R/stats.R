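#' Partial correlation with a t-based test
#'
#' First-order partial correlation by the residual construction: `x` and `y`
#' are each regressed on the control covariates, and the Pearson correlation
#' of the residuals is reported with a two-sided p-value from the t transform
#' `t = r sqrt(df / (1 - r^2))`, `df = n - k - 2` for `k` controls. Used to
#' check whether sample temperature has any association with spectroscopic
#' signal intensity once wavelength and composition are controlled for.
#'
#' @param data A data frame.
#' @param x,y Column names (strings) of the two variables to correlate.
#' @param controls Character vector of control covariate column names.
#' @return A one-row tibble with `r`, `df`, `statistic`, `p_value`, `n`.
#' @export
partial_correlation <- function(data, x, y, controls = character()) {
  stopifnot(is.data.frame(data), x %in% names(data), y %in% names(data),
            all(controls %in% names(data)))
  n <- nrow(data)
  k <- length(controls)
  if (n < k + 3) abort("need at least 3 more records than control covariates")
  cols <- c(x, y, controls)
  if (any(vapply(cols, function(cl) sd(data[[cl]]) == 0, logical(1))))
    abort("constant column among the variables or controls")
  rx <- if (k) residuals(lm(stats::reformulate(controls, response = x), data = data))
        else data[[x]] - mean(data[[x]])
  ry <- if (k) residuals(lm(stats::reformulate(controls, response = y), data = data))
        else data[[y]] - mean(data[[y]])
  r <- cor(rx, ry)
  df <- n - k - 2
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df)
  tibble::tibble(r = r, df = df, statistic = tval, p_value = p, n = n)
}

#' Synthetic temperature-study table
#'
#' Simulates the record layout of a temperature study: spectroscopic intensity
#' measured across wavelengths and phantom compositions at several
#' temperatures. Under the default `temperature_effect = 0` the intensity is
#' independent of temperature by construction (a null table for calibrating
#' [partial_correlation()]); a nonzero effect adds a linear temperature slope.
#' The intensity surface is linear in the control covariates: the residual
#' construction behind a partial correlation only has its nominal null
#' distribution when the control model is correctly specified, so the
#' calibration table is built to satisfy that premise.
#'
#' @param n_wavelengths Wavelengths per phantom/temperature cell.
#' @param temperatures Temperatures (deg C), default the 22--42 range.
#' @param concentrations Absorber concentration levels (mg/mL).
#' @param temperature_effect Linear intensity change per deg C.
#' @param noise_sd Additive noise standard deviation.
#' @param seed Integer seed.
#' @return A tibble with columns `intensity`, `temperature`, `wavelength`,
#'   `concentration`.
#' @export
synth_temperature_table <- function(n_wavelengths = 40,
                                    temperatures = c(22, 37, 40, 42),
                                    concentrations = c(0.25, 0.5, 1.0),
                                    temperature_effect = 0,
                                    noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  g <- tidyr::expand_grid(
    temperature = temperatures,
    concentration = concentrations,
    wavelength = seq(400, 700, length.out = n_wavelengths))
  base <- 0.3 + 0.0008 * (g$wavelength - 350) - 0.15 * g$concentration
  g$intensity <- base + temperature_effect * (g$temperature - 22) +
    rnorm(nrow(g), sd = noise_sd)
  g
}
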
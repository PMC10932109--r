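#' Instrumental resolution specification
#'
#' Describes the wavelength band of a velocity-selector SANS instrument.
#' The fractional spread is treated as a FWHM-like quantity, as quoted for
#' mechanical velocity selectors (e.g. "6 Angstrom +/- 10%").
#'
#' @param wavelength Neutron wavelength lambda0 in Angstrom (> 0).
#' @param wavelength_spread Fractional FWHM spread dlambda/lambda in
#'   `[0, 1)`.
#' @return An object of class `resolution_spec`.
#' @export
resolution_spec <- function(wavelength = 6, wavelength_spread = 0.10) {
  stopifnot_scalar(wavelength, "wavelength")
  if (!is.numeric(wavelength_spread) || length(wavelength_spread) != 1L ||
      wavelength_spread < 0 || wavelength_spread >= 1)
    stop("'wavelength_spread' must lie in [0, 1)", call. = FALSE)
  structure(list(wavelength = wavelength,
                 wavelength_spread = wavelength_spread),
            class = "resolution_spec")
}

#' @export
print.resolution_spec <- function(x, ...) {
  cat(sprintf("Resolution: lambda = %g A, dlambda/lambda = %g%% (FWHM)\n",
              x$wavelength, 100 * x$wavelength_spread))
  invisible(x)
}

#' Smear a model curve through the instrumental resolution
#'
#' Each intensity is replaced by a Gaussian-kernel average over Q with
#' relative width sigma_Q / Q = (dlambda/lambda) / 2.355, i.e. the FWHM
#' wavelength band converted to a Gaussian standard deviation. The kernel
#' is truncated at +/- 3 sigma and renormalized over the available grid, so
#' a constant curve is reproduced exactly. Intended for noise-free model
#' curves; uncertainties on the input are dropped.
#'
#' @param model_curve A noise-free [scattering_curve()].
#' @param res A [resolution_spec()].
#' @return A smeared [scattering_curve()] on the same Q grid. With zero
#'   wavelength spread the input is returned unchanged.
#' @export
smear_resolution <- function(model_curve, res = resolution_spec()) {
  stopifnot(inherits(model_curve, "scattering_curve"),
            inherits(res, "resolution_spec"))
  if (res$wavelength_spread == 0) return(model_curve)
  q <- model_curve$q
  i <- model_curve$intensity
  sig_q <- q * res$wavelength_spread / 2.355
  out <- vapply(seq_along(q), function(k) {
    w <- stats::dnorm(q, q[k], sig_q[k])
    w[abs(q - q[k]) > 3 * sig_q[k]] <- 0
    sum(w * i) / sum(w)
  }, numeric(1))
  scattering_curve(q, out, label = model_curve$label)
}
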
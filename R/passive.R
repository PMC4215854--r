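#' Passive membrane properties
#'
#' Bundles the passive electrical parameters of a model cell: axial
#' resistivity, specific membrane capacitance and resistance, leak reversal
#' potential, and a (typically tiny) potassium leak density.
#'
#' @param ra Axial resistivity (ohm cm).
#' @param cm Specific membrane capacitance (uF/cm^2).
#' @param rm Specific membrane resistance (ohm cm^2).
#' @param el Leak reversal potential (mV), must lie in -120..0.
#' @param gkl Potassium leak conductance density (S/cm^2), non-negative.
#'
#' @return An object of class `olm_passive`.
#' @export
#' @examples
#' p <- passive_properties(ra = 300, cm = 0.96857, rm = 59156,
#'                         el = -73.588, gkl = 9.9005e-10)
#' membrane_time_constant(p)  # ~57 ms
passive_properties <- function(ra, cm, rm, el, gkl = 0) {
  stopifnot(is.numeric(ra), is.numeric(cm), is.numeric(rm), is.numeric(el),
            is.numeric(gkl))
  if (ra <= 0 || cm <= 0 || rm <= 0)
    stop("ra, cm and rm must be strictly positive")
  if (gkl < 0) stop("gkl must be non-negative")
  if (el < -120 || el > 0) stop("el must lie within [-120, 0] mV")
  structure(list(ra = ra, cm = cm, rm = rm, el = el, gkl = gkl),
            class = "olm_passive")
}

#' Fitted passive property sets for the two reference O-LM morphologies
#'
#' The two passive parameter sets fitted against O-LM seal-test recordings,
#' used throughout the model database construction.
#'
#' @param morph Which morphology's passive set to return (1 or 2).
#' @return An [passive_properties()] object.
#' @export
olm_passive_defaults <- function(morph = 1) {
  morph <- match.arg(as.character(morph), c("1", "2"))
  if (morph == "1")
    passive_properties(ra = 300, cm = 0.96857, rm = 59156,
                       el = -73.588, gkl = 9.9005e-10)
  else
    passive_properties(ra = 300, cm = 0.9, rm = 39038,
                       el = -73.8424, gkl = 1.0015e-9)
}

#' Membrane time constant Rm * Cm
#'
#' @param passive An `olm_passive` object.
#' @return Time constant in ms.
#' @export
membrane_time_constant <- function(passive) {
  stopifnot(inherits(passive, "olm_passive"))
  # ohm cm^2 * uF/cm^2 = 1e-6 s = 1e-3 ms
  passive$rm * passive$cm * 1e-3
}

#' @export
print.olm_passive <- function(x, ...) {
  cat("Passive properties: Ra", x$ra, "ohm cm, Cm", x$cm, "uF/cm2, Rm",
      x$rm, "ohm cm2, EL", x$el, "mV, gKL", x$gkl, "S/cm2\n")
  invisible(x)
}
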
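# Unit discipline: all internal lengths are nm, energies kcal/mol, times ps
# (rates are converted to s^-1 and permeabilities to cm/s only at reporting
# boundaries).  These constants are the only sanctioned conversion factors.

#' Physical constants and unit conversions
#'
#' Returns the fixed unit system used throughout the package: the Boltzmann
#' constant in kcal/(mol K), the conversion from millimolar concentration to
#' molecules per cubic nanometre, and the conversion from nm/s to cm/s.
#'
#' @return A named list with elements `kB` (kcal mol^-1 K^-1),
#'   `mM_to_per_nm3` (molecules nm^-3 per mM) and `nm_per_s_to_cm_per_s`.
#' @examples
#' unit_constants()$kB * 310  # thermal energy at 310 K, kcal/mol
#' @export
unit_constants <- function() {
  list(
    kB = 1.987204e-3,
    mM_to_per_nm3 = 6.0221e-4,
    nm_per_s_to_cm_per_s = 1e-7
  )
}

.kB <- 1.987204e-3
.mM_to_per_nm3 <- 6.0221e-4
.nm_per_s_to_cm_per_s <- 1e-7

#' Convert temperatures to kelvin
#'
#' Helper used at input boundaries so that configuration files may quote
#' temperatures in degrees Celsius; everything internal is kelvin.
#'
#' @param x numeric temperature(s).
#' @param unit `"K"` (default) or `"C"`.
#' @return Temperatures in kelvin.
#' @export
as_kelvin <- function(x, unit = c("K", "C")) {
  unit <- match.arg(unit)
  out <- if (unit == "C") x + 273.15 else x
  if (any(out <= 0)) stop("temperature must be positive (in kelvin)")
  out
}

# trapezoid rule; x must be sorted increasing
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
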
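#' Physical constants used throughout
#'
#' Gas constant and Boltzmann constant (SI, CODATA exact values).
#' @keywords internal
#' @name constants
NULL

.R_GAS <- 8.31446261815324  # J / (mol K)
.K_B <- 1.380649e-23        # J / K

#' Solvent specification
#'
#' Bundles the solvent molar volume and the absolute temperature that set the
#' pressure scale \eqn{RT/V_1} of the mixing pressure and the \eqn{k_B T}
#' factor of scattering amplitudes.
#'
#' @param V1 molar volume of the solvent (m^3/mol). Default is water at 25 C,
#'   `1.805e-5` m^3/mol.
#' @param temperature absolute temperature (K). Default 298.15 K.
#' @return An object of class `solvent_spec` with fields `V1`, `T`, `R`, `kB`.
#' @examples
#' sv <- solvent_spec()
#' pressure_scale(sv)  # RT/V1 in Pa, about 1.37e8 for water at 25 C
#' @export
solvent_spec <- function(V1 = 1.805e-5, temperature = 298.15) {
  stopifnot(is.numeric(V1), length(V1) == 1L, is.finite(V1),
            is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature))
  if (V1 <= 0) stop("solvent molar volume V1 must be positive", call. = FALSE)
  if (temperature <= 0) stop("absolute temperature must be positive", call. = FALSE)
  structure(
    list(V1 = V1, T = temperature, R = .R_GAS, kB = .K_B),
    class = "solvent_spec"
  )
}

#' @export
print.solvent_spec <- function(x, ...) {
  cat(sprintf("<solvent_spec> V1 = %.4g m^3/mol, T = %.2f K, RT/V1 = %.4g Pa\n",
              x$V1, x$T, pressure_scale(x)))
  invisible(x)
}

#' Osmotic pressure scale RT/V1
#'
#' @param solvent a [solvent_spec()].
#' @return `RT/V1` in Pa.
#' @export
pressure_scale <- function(solvent) {
  stopifnot(inherits(solvent, "solvent_spec"))
  solvent$R * solvent$T / solvent$V1
}

#' Convert mM to mol/m^3 and kPa to Pa
#'
#' Interface helpers: the package works in SI units internally (Pa, mol/m^3,
#' K); bench units are millimolar and kilopascal. 1 mM = 1 mol/m^3, so the
#' concentration conversion is the identity kept for self-documenting code.
#' @param x numeric vector.
#' @return numeric vector in SI units.
#' @export
mM_to_molm3 <- function(x) x * 1.0

#' @rdname mM_to_molm3
#' @export
kPa_to_Pa <- function(x) x * 1000

.check_phi <- function(phi, allow_zero = FALSE) {
  if (!is.numeric(phi) || any(!is.finite(phi))) {
    stop("polymer volume fraction phi must be finite numeric", call. = FALSE)
  }
  lo_ok <- if (allow_zero) all(phi >= 0) else all(phi > 0)
  if (!lo_ok || any(phi >= 1)) {
    stop("polymer volume fraction phi must lie in (0, 1)", call. = FALSE)
  }
  invisible(phi)
}
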
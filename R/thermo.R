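#' Thermodynamic conditions
#'
#' Bundles the temperature and gas constant used throughout the package.
#' Defaults reproduce the conventional 298.15 K reference state with the
#' gas constant in kcal/(mol K), the unit system of the reaction free
#' energies and segment interaction energies used here.
#'
#' @param T temperature in kelvin. Must be strictly positive.
#' @param R gas constant in kcal/(mol K).
#' @return An object of class `thermo_conditions` with elements `T`, `R`
#'   and the derived product `RT` (kcal/mol).
#' @examples
#' cond <- thermo_conditions()
#' cond$RT
#' @export
thermo_conditions <- function(T = 298.15, R = 1.98720425e-3) {
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T),
            is.numeric(R), length(R) == 1L, is.finite(R), R > 0)
  if (T <= 0) stop("temperature must be positive (kelvin)")
  structure(list(T = T, R = R, RT = R * T), class = "thermo_conditions")
}

#' @export
print.thermo_conditions <- function(x, ...) {
  cat(sprintf("Thermodynamic conditions: T = %.2f K, R = %.8g kcal/(mol K), RT = %.5f kcal/mol\n",
              x$T, x$R, x$RT))
  invisible(x)
}

#' Equilibrium constant from a reaction free energy
#'
#' Converts a standard Gibbs free energy of reaction into the
#' dimensionless equilibrium constant, K = exp(-dG / RT).
#'
#' @param dG standard reaction free energy in kcal/mol (finite numeric).
#' @param cond a [thermo_conditions()] object.
#' @return Strictly positive dimensionless equilibrium constant(s).
#' @seealso [gibbs_from_K()] for the exact inverse.
#' @examples
#' equilibrium_constant(0)            # 1
#' equilibrium_constant(-7.11)        # ~1.6e5 at 298.15 K
#' @export
equilibrium_constant <- function(dG, cond = thermo_conditions()) {
  stopifnot(is.numeric(dG), inherits(cond, "thermo_conditions"))
  if (any(!is.finite(dG))) stop("dG must be finite (kcal/mol)")
  exp(-dG / cond$RT)
}

#' Reaction free energy from an equilibrium constant
#'
#' The inverse of [equilibrium_constant()]: dG = -RT ln K.
#'
#' @param K dimensionless equilibrium constant, strictly positive.
#' @param cond a [thermo_conditions()] object.
#' @return Reaction free energy in kcal/mol.
#' @examples
#' gibbs_from_K(1.62e5)  # -7.11 kcal/mol at 298.15 K
#' @export
gibbs_from_K <- function(K, cond = thermo_conditions()) {
  stopifnot(is.numeric(K), inherits(cond, "thermo_conditions"))
  if (any(!is.finite(K)) || any(K <= 0)) stop("K must be finite and > 0")
  -cond$RT * log(K)
}
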
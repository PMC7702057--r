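#' Boltzmann constant in electron-volts per Kelvin
#'
#' The value 8.62e-5 eV K^-1 conventional in metabolic scaling work (not the
#' longer CODATA expansion), fixed so that activation-energy estimates are
#' reproducible against the ecological literature.
#' @export
boltzmann_k <- 8.62e-5

#' Standardized inverse Boltzmann temperature
#'
#' Converts temperature in degrees Celsius to the standardized inverse
#' Boltzmann scale `x = 1/(k T_ref) - 1/(k T)` (units eV^-1), centred on a
#' reference temperature (default 15 degrees C) so that `x(T_ref) = 0` and the
#' slope of a log-transformed rate against `x` is directly an apparent
#' activation energy in eV, with positive slope meaning the rate increases
#' with temperature.
#'
#' @param temp_C temperature(s), degrees Celsius; must exceed -273.15.
#' @param T_ref_C reference temperature, degrees Celsius (default 15).
#' @return numeric vector of standardized temperatures (eV^-1).
#' @seealso [unstandardize_temperature()] for the inverse transform.
#' @examples
#' standardize_temperature(15)   # 0 by construction
#' standardize_temperature(16)   # about 0.139 eV^-1
#' @export
standardize_temperature <- function(temp_C, T_ref_C = 15) {
  if (any(temp_C <= -273.15)) stop("temperature below absolute zero")
  T_K <- temp_C + 273.15
  T_ref_K <- T_ref_C + 273.15
  1 / (boltzmann_k * T_ref_K) - 1 / (boltzmann_k * T_K)
}

#' @rdname standardize_temperature
#' @param x standardized temperature(s), eV^-1.
#' @export
unstandardize_temperature <- function(x, T_ref_C = 15) {
  T_ref_K <- T_ref_C + 273.15
  inv <- 1 / (boltzmann_k * T_ref_K) - x
  if (any(inv <= 0)) stop("standardized temperature out of physical range")
  1 / (boltzmann_k * inv) - 273.15
}
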
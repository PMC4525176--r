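# Physical constants and unit conversions used throughout the package.
# Internally everything is SI with angles in radians; user-facing values keep
# the field's customary units (Debye, deg^2/s, cm^2/s, Angstrom).

.k_B <- 1.380649e-23        # Boltzmann constant, J/K (exact, SI 2019)
.debye_si <- 3.33564e-30    # 1 Debye in C m
.deg2rad <- pi / 180

#' @keywords internal
debye_to_si <- function(mu_debye) mu_debye * .debye_si

#' @keywords internal
deg2_to_rad2 <- function(x) x * .deg2rad^2

#' @keywords internal
rad2_to_deg2 <- function(x) x / .deg2rad^2

stop_invalid <- function(...) {
  stop(structure(
    class = c("propellr_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(name, " must be a single finite positive number")
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_invalid(name, " must be a single finite non-negative number")
  }
  invisible(x)
}
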
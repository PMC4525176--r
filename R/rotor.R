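#' Chiral rotor: one enantiomer's physical parameters
#'
#' Bundles the molecular parameters that control propeller propulsion of a
#' dipolar chiral molecule: the permanent dipole moment, the rotational
#' diffusion coefficient about the propeller axis \eqn{I_1}, the hydrodynamic
#' coupling length \eqn{L_{rev}} (signed axial displacement per full revolution
#' about \eqn{I_1}), and the translational diffusion coefficient.
#'
#' `mirror()` returns the opposite enantiomer: handedness flips and
#' \eqn{L_{rev}} changes sign; all achiral parameters are unchanged.
#'
#' @param name molecule label.
#' @param handedness `"S"` or `"R"` absolute configuration.
#' @param dipole_debye permanent dipole moment, Debye (>= 0).
#' @param l_rev_angstrom signed displacement per 360 degree revolution about
#'   the propeller axis, Angstrom. Zero means an achiral (non-propelling)
#'   rotation axis.
#' @param d_r_deg2_s rotational diffusion coefficient about the propeller
#'   axis, deg^2/s (> 0).
#' @param d_trans_cm2_s translational diffusion coefficient, cm^2/s (> 0).
#' @return An object of class `chiral_rotor`.
#' @examples
#' mol <- chiral_rotor("molecule I", "S", 5.3, 1.22, 3.98814e12, 8.3e-6)
#' mirror(mol)
#' @export
chiral_rotor <- function(name, handedness = c("S", "R"), dipole_debye,
                         l_rev_angstrom, d_r_deg2_s, d_trans_cm2_s) {
  handedness <- match.arg(handedness)
  check_nonneg(dipole_debye, "dipole_debye")
  if (!is.numeric(l_rev_angstrom) || length(l_rev_angstrom) != 1L ||
      !is.finite(l_rev_angstrom)) {
    stop_invalid("l_rev_angstrom must be a single finite number")
  }
  check_positive(d_r_deg2_s, "d_r_deg2_s")
  check_positive(d_trans_cm2_s, "d_trans_cm2_s")
  structure(
    list(name = as.character(name)[1L], handedness = handedness,
         dipole_debye = dipole_debye, l_rev_angstrom = l_rev_angstrom,
         d_r_deg2_s = d_r_deg2_s, d_trans_cm2_s = d_trans_cm2_s),
    class = "chiral_rotor"
  )
}

#' @rdname chiral_rotor
#' @param rotor a `chiral_rotor`.
#' @export
mirror <- function(rotor) {
  stopifnot(inherits(rotor, "chiral_rotor"))
  rotor$handedness <- if (rotor$handedness == "S") "R" else "S"
  rotor$l_rev_angstrom <- -rotor$l_rev_angstrom
  rotor
}

#' @export
print.chiral_rotor <- function(x, ...) {
  cat("Chiral rotor:", x$name, sprintf("(%s enantiomer)\n", x$handedness))
  cat(sprintf("  dipole moment        %g Debye\n", x$dipole_debye))
  cat(sprintf("  L_rev                %+g Angstrom / revolution\n",
              x$l_rev_angstrom))
  cat(sprintf("  D_r (about I1)       %g deg^2/s\n", x$d_r_deg2_s))
  cat(sprintf("  D_trans              %g cm^2/s\n", x$d_trans_cm2_s))
  invisible(x)
}

#' Rotating-field protocol
#'
#' The rotating electric field (REF) and bath conditions a rotor is exposed
#' to. The field has fixed magnitude `e_v_m` and rotates at frequency `nu_hz`
#' in the plane perpendicular to the propulsion (flow) axis. The rotation
#' sense is defined looking along the flow direction, from injection toward
#' collection.
#'
#' @param e_v_m electric field magnitude, V/m (>= 0).
#' @param nu_hz field rotation frequency, Hz (>= 0).
#' @param sense `"CW"` or `"CCW"`, viewed along the flow axis from injection
#'   toward collection.
#' @param temperature_k bath temperature, K (> 0). Default 293 K.
#' @param eta_pa_s solvent dynamic viscosity, N s/m^2 (> 0). Default is
#'   benzene, 0.0065.
#' @return An object of class `field_protocol`.
#' @examples
#' field_protocol(6e5, 9e5, "CW")
#' @export
field_protocol <- function(e_v_m, nu_hz, sense = c("CW", "CCW"),
                           temperature_k = 293, eta_pa_s = 0.0065) {
  sense <- match.arg(sense)
  check_nonneg(e_v_m, "e_v_m")
  check_nonneg(nu_hz, "nu_hz")
  check_positive(temperature_k, "temperature_k")
  check_positive(eta_pa_s, "eta_pa_s")
  structure(
    list(e_v_m = e_v_m, nu_hz = nu_hz, sense = sense,
         temperature_k = temperature_k, eta_pa_s = eta_pa_s),
    class = "field_protocol"
  )
}

#' @export
print.field_protocol <- function(x, ...) {
  cat("Rotating electric field protocol\n")
  cat(sprintf("  |E|          %g V/m\n", x$e_v_m))
  cat(sprintf("  nu           %g Hz (%s)\n", x$nu_hz, x$sense))
  cat(sprintf("  T            %g K\n", x$temperature_k))
  cat(sprintf("  eta          %g N s/m^2\n", x$eta_pa_s))
  invisible(x)
}

# Signed rotation sense: +1 when the field's angular-velocity vector points
# along the flow axis (CW viewed along the flow direction), -1 otherwise.
sense_sign <- function(field) if (field$sense == "CW") 1 else -1

#' Read and write rotor / field JSON configurations
#'
#' Plain JSON files with the keys `dipole_debye`, `l_rev_angstrom`,
#' `d_r_deg2_s`, `d_trans_cm2_s`, `handedness` (and optional `name`) for a
#' rotor, and `e_v_m`, `nu_hz`, `sense`, `temperature_k`, `eta_pa_s` for a
#' field protocol.
#'
#' @param path file path.
#' @return `read_rotor_json()` a `chiral_rotor`; `read_field_json()` a
#'   `field_protocol`; the writers return `path` invisibly.
#' @export
read_rotor_json <- function(path) {
  if (!file.exists(path)) stop_invalid("rotor config not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("dipole_debye", "l_rev_angstrom", "d_r_deg2_s", "d_trans_cm2_s",
              "handedness")
  missing <- setdiff(needed, names(j))
  if (length(missing)) {
    stop_invalid("rotor config ", path, " lacks keys: ",
                 paste(missing, collapse = ", "))
  }
  chiral_rotor(name = if (is.null(j$name)) basename(path) else j$name,
               handedness = j$handedness,
               dipole_debye = j$dipole_debye,
               l_rev_angstrom = j$l_rev_angstrom,
               d_r_deg2_s = j$d_r_deg2_s,
               d_trans_cm2_s = j$d_trans_cm2_s)
}

#' @rdname read_rotor_json
#' @param rotor a `chiral_rotor`.
#' @export
write_rotor_json <- function(rotor, path) {
  stopifnot(inherits(rotor, "chiral_rotor"))
  jsonlite::write_json(unclass(rotor), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname read_rotor_json
#' @export
read_field_json <- function(path) {
  if (!file.exists(path)) stop_invalid("field config not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("e_v_m", "nu_hz", "sense", "temperature_k", "eta_pa_s")
  missing <- setdiff(needed, names(j))
  if (length(missing)) {
    stop_invalid("field config ", path, " lacks keys: ",
                 paste(missing, collapse = ", "))
  }
  field_protocol(e_v_m = j$e_v_m, nu_hz = j$nu_hz, sense = j$sense,
                 temperature_k = j$temperature_k, eta_pa_s = j$eta_pa_s)
}

#' @rdname read_rotor_json
#' @param field a `field_protocol`.
#' @export
write_field_json <- function(field, path) {
  stopifnot(inherits(field, "field_protocol"))
  jsonlite::write_json(unclass(field), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
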
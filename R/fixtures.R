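#' Built-in molecule and field parameter sets
#'
#' The two binaphthyl study molecules and the experimental rotating-field
#' protocol, with the published parameters: molecule I (dipole 5.3 D,
#' L_rev 1.22 Angstrom/rev, D = 8.3e-6 cm^2/s) and molecule II (10.9 D,
#' 0.18 Angstrom/rev -- the mean magnitude of the S/R coupling slopes --
#' D = 1.4e-5 cm^2/s, D_r = 8.2e12 deg^2/s). Molecule I's rotational
#' diffusion coefficient is not published as a number; the value
#' 3.98814e12 deg^2/s is back-solved from its escape frequency of
#' 0.507 MHz at the experimental field and is flagged as inferred in the
#' JSON fixture.
#'
#' @param which `"molecule_I"` or `"molecule_II"`.
#' @return A [chiral_rotor()] (or [field_protocol()] for
#'   `reference_field()`).
#' @examples
#' propeller_predict(reference_rotor("molecule_I"), reference_field())
#' @export
reference_rotor <- function(which = c("molecule_I", "molecule_II")) {
  which <- match.arg(which)
  if (which == "molecule_I") {
    chiral_rotor("molecule I", "S", dipole_debye = 5.3,
                 l_rev_angstrom = 1.22, d_r_deg2_s = 3.98814e12,
                 d_trans_cm2_s = 8.3e-6)
  } else {
    chiral_rotor("molecule II", "S", dipole_debye = 10.9,
                 l_rev_angstrom = 0.18, d_r_deg2_s = 8.2e12,
                 d_trans_cm2_s = 1.4e-5)
  }
}

#' @rdname reference_rotor
#' @export
reference_field <- function() {
  field_protocol(e_v_m = 6e5, nu_hz = 9e5, sense = "CW",
                 temperature_k = 293, eta_pa_s = 0.0065)
}

#' Write the bundled fixture files
#'
#' Writes `molecule_I.json`, `molecule_II.json`, `field.json`, a linear
#' CD/absorbance calibration table, a short synthetic rotor trajectory and a
#' synthetic chromatogram into `out_dir`. All content is generated by the
#' package itself (the CSVs carry a fixed seed), so the files are
#' reproducible byte for byte.
#'
#' @param out_dir writable output directory (created if absent).
#' @return Character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_invalid("cannot create fixture directory ", out_dir)
  }
  paths <- character(0)
  wjson <- function(x, file) {
    p <- file.path(out_dir, file)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p
  }
  m1 <- unclass(reference_rotor("molecule_I"))
  m1$d_r_note <- paste("inferred: back-solved from the 0.507 MHz escape",
                       "frequency at 6e5 V/m, 293 K (not directly published)")
  paths <- c(paths, wjson(m1, "molecule_I.json"))
  paths <- c(paths, wjson(unclass(reference_rotor("molecule_II")),
                          "molecule_II.json"))
  paths <- c(paths, wjson(unclass(reference_field()), "field.json"))

  calib <- data.frame(ee_pct = seq(-100, 100, by = 25),
                      ratio = seq(-1, 1, by = 0.25))
  p <- file.path(out_dir, "calibration_synthetic.csv")
  utils::write.csv(calib, p, row.names = FALSE)
  paths <- c(paths, p)

  # short synthetic free-diffusion trajectory (seed fixed for byte identity)
  cfg <- simulation_config(reference_rotor("molecule_I"), field = NULL,
                           dt = 2e-15, n_steps = 2000, record_every = 20,
                           seed = 42L)
  p <- file.path(out_dir, "trajectory_synthetic.csv")
  write_trajectory_csv(simulate_rotor(cfg), p)
  paths <- c(paths, p)

  # synthetic chromatogram of a partially separated racemic slug
  prof <- gaussian_pair_profile(v = 45e-9, d_cm2_s = 1.4e-5,
                                t_s = 21 * 3600, x0_cm = 5,
                                grid_cm = seq(0, 10, by = 0.05))
  p <- file.path(out_dir, "chromatogram_synthetic.csv")
  write_chromatogram_csv(profile_to_chromatogram(prof), p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Path to a bundled fixture file
#'
#' @param file fixture file name, e.g. `"molecule_I.json"`; empty to list
#'   the fixture directory.
#' @return Full path within the installed package.
#' @export
propellr_fixture <- function(file = "") {
  system.file("extdata", file, package = "propellr", mustWork = file != "")
}
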
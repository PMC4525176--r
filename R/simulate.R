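#' Configuration for the rotational Brownian dynamics simulator
#'
#' Validates and bundles everything [simulate_rotor()] needs. The step size
#' must satisfy the small-rotation condition `dt * D_r <= 0.01 rad^2`, the
#' regime in which the sequential-axis rotation update is accurate.
#'
#' @param rotor a [chiral_rotor()].
#' @param field a [field_protocol()] or `NULL` for field-free diffusion.
#' @param dt time step, s (> 0).
#' @param n_steps number of steps (>= 1).
#' @param record_every record every this many steps (>= 1).
#' @param seed integer seed; the trajectory is bit-reproducible given the
#'   full configuration and seed.
#' @param waveform `"ideal_circular"` (uniformly rotating field) or
#'   `"four_phase_square"` (90-degree stepping field emulating the four-pole
#'   electrode drive).
#' @param rotational_noise,translational_noise logical switches for the two
#'   thermal noise channels; both `TRUE` for physical runs. Turning
#'   rotational noise off gives the deterministic driven rotor, used to
#'   cross-check [effective_frequency_ode()].
#' @param d_r_axes optional length-3 override of the rotational diffusion
#'   coefficient per body axis, deg^2/s; by default the single scalar
#'   `rotor$d_r_deg2_s` applies to all three axes.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(rotor, field = NULL, dt, n_steps,
                              record_every = 1L, seed = 1L,
                              waveform = c("ideal_circular",
                                           "four_phase_square"),
                              rotational_noise = TRUE,
                              translational_noise = TRUE,
                              d_r_axes = NULL) {
  stopifnot(inherits(rotor, "chiral_rotor"))
  if (!is.null(field)) stopifnot(inherits(field, "field_protocol"))
  waveform <- match.arg(waveform)
  check_positive(dt, "dt")
  if (n_steps < 1) stop_invalid("n_steps must be >= 1")
  if (record_every < 1 || n_steps %% record_every != 0) {
    stop_invalid("record_every must be >= 1 and divide n_steps")
  }
  if (is.null(d_r_axes)) d_r_axes <- rep(rotor$d_r_deg2_s, 3L)
  if (length(d_r_axes) != 3L || any(d_r_axes <= 0)) {
    stop_invalid("d_r_axes must be three positive values (deg^2/s)")
  }
  if (rotational_noise && max(deg2_to_rad2(d_r_axes)) * dt > 0.01) {
    # small-rotation regime for the stochastic update; with noise off the
    # kernel's per-step |dtheta| <= 0.5 rad guard covers the torque term
    stop_invalid("dt * D_r exceeds 0.01 rad^2 per step; reduce dt ",
                 "below ", signif(0.01 / max(deg2_to_rad2(d_r_axes)), 3), " s")
  }
  structure(
    list(rotor = rotor, field = field, dt = dt, n_steps = as.integer(n_steps),
         record_every = as.integer(record_every), seed = as.integer(seed),
         waveform = waveform, rotational_noise = rotational_noise,
         translational_noise = translational_noise, d_r_axes = d_r_axes),
    class = "simulation_config"
  )
}

#' Instantaneous field vector of the rotating-field protocol
#'
#' The lab-frame field at time `t`. The flow (propulsion) axis is lab
#' \eqn{x}; the field rotates in the \eqn{yz} plane. For the `"CW"` sense the
#' angular-velocity vector points along \eqn{+x} (right-hand rule), for
#' `"CCW"` along \eqn{-x}. The `"four_phase_square"` waveform holds the
#' field magnitude constant while the direction steps through exactly four
#' orientations per period, the idealisation of the four-pole square-wave
#' drive.
#'
#' @param t time, s (>= 0), vectorised.
#' @param field a [field_protocol()].
#' @param waveform `"ideal_circular"` or `"four_phase_square"`.
#' @return A length(t) x 3 matrix of field vectors, V/m.
#' @export
field_at <- function(t, field, waveform = c("ideal_circular",
                                            "four_phase_square")) {
  stopifnot(inherits(field, "field_protocol"))
  waveform <- match.arg(waveform)
  if (any(t < 0)) stop_invalid("t must be >= 0")
  omega <- sense_sign(field) * 2 * pi * field$nu_hz
  if (waveform == "ideal_circular") {
    phase <- omega * t
  } else {
    frac <- (field$nu_hz * t) %% 1
    phase <- sign(omega) * floor(frac * 4) * (pi / 2)
  }
  cbind(x = rep(0, length(t)),
        y = field$e_v_m * cos(phase),
        z = field$e_v_m * sin(phase))
}

#' Simulate a rotor trajectory
#'
#' Runs the overdamped rotational Brownian dynamics defined by a
#' [simulation_config()]: per step the body frame is rotated about each body
#' axis by a deterministic torque increment plus Gaussian rotational noise,
#' and the centre of mass advances along the instantaneous propeller axis
#' \eqn{I_1} by \eqn{(L_{rev}/2\pi)\,\Delta\theta_1} plus isotropic
#' translational noise. The dipole lies along body axis \eqn{I_2}, so the
#' field torque never acts about the dipole axis itself.
#'
#' @param config a [simulation_config()].
#' @return An object of class `rotor_trajectory`: list with `times` (s),
#'   `frames` (n x 9 matrix of body-axis triads, columns `e11..e33`, row
#'   layout I1 then I2 then I3 in lab coordinates), `cum_angle_deg` (n x 3,
#'   unwrapped rotation about each body axis), `com_angstrom` (n x 3 lab
#'   centre-of-mass), and the `config` as an attribute.
#' @examples
#' mol <- chiral_rotor("demo", "S", 5.3, 1.22, 4e12, 8.3e-6)
#' cfg <- simulation_config(mol, dt = 5e-15, n_steps = 1000, seed = 7)
#' traj <- simulate_rotor(cfg)
#' @export
simulate_rotor <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rotor <- config$rotor
  has_field <- !is.null(config$field) && config$field$e_v_m > 0
  if (has_field) {
    xi <- rotational_friction(rotor$d_r_deg2_s,
                              config$field$temperature_k)
    omega <- sense_sign(config$field) * 2 * pi * config$field$nu_hz
    e_mag <- config$field$e_v_m
  } else {
    xi <- 1
    omega <- 0
    e_mag <- 0
  }
  set.seed(config$seed)
  raw <- bd_simulate_cpp(
    n_steps = config$n_steps, dt = config$dt,
    d_r_rad2_s = deg2_to_rad2(config$d_r_axes),
    l_rev_angstrom = rotor$l_rev_angstrom,
    d_trans_ang2_s = rotor$d_trans_cm2_s * 1e16,  # cm^2/s -> Angstrom^2/s
    rotational_noise = config$rotational_noise,
    translational_noise = config$translational_noise,
    has_field = has_field,
    mu_si = debye_to_si(rotor$dipole_debye),
    e_mag = e_mag, omega_signed = omega, xi = xi,
    waveform = if (config$waveform == "ideal_circular") 0L else 1L,
    record_every = config$record_every
  )
  colnames(raw$frames) <- c("e11", "e12", "e13", "e21", "e22", "e23",
                            "e31", "e32", "e33")
  colnames(raw$cum_angle_deg) <- c("ang1_deg", "ang2_deg", "ang3_deg")
  colnames(raw$com_angstrom) <- c("x_A", "y_A", "z_A")
  structure(
    list(times = raw$times, frames = raw$frames,
         cum_angle_deg = raw$cum_angle_deg, com_angstrom = raw$com_angstrom),
    config = config, class = "rotor_trajectory"
  )
}

#' @export
print.rotor_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("Rotor trajectory:", n, "records over",
      format(x$times[n], digits = 4), "s\n")
  cat(sprintf("  net rotation about I1  %.4g revolutions\n",
              (x$cum_angle_deg[n, 1] - x$cum_angle_deg[1, 1]) / 360))
  cat(sprintf("  net COM displacement   (%.3g, %.3g, %.3g) Angstrom\n",
              x$com_angstrom[n, 1], x$com_angstrom[n, 2],
              x$com_angstrom[n, 3]))
  invisible(x)
}

#' @export
plot.rotor_trajectory <- function(x, axis = 1, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(x$times, x$cum_angle_deg[, axis], type = "l",
                 xlab = "time (s)",
                 ylab = sprintf("rotation about I%d (deg)", axis), ...)
  graphics::plot(x$cum_angle_deg[, axis], x$com_angstrom[, axis],
                 pch = ".", xlab = sprintf("angle about I%d (deg)", axis),
                 ylab = "lab displacement (Angstrom)", ...)
  invisible(x)
}

#' Trajectory CSV input/output
#'
#' Fixed column layout `t_s, e11..e33, ang1_deg..ang3_deg, x_A, y_A, z_A`:
#' time, the body-axis triad (row-major, I1 then I2 then I3, lab
#' coordinates), unwrapped cumulative rotation about each body axis in
#' degrees, and the centre of mass in Angstrom.
#'
#' @param traj a `rotor_trajectory`.
#' @param path output/input file path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` a `rotor_trajectory` (without the generating
#'   config).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "rotor_trajectory"))
  df <- data.frame(t_s = traj$times, traj$frames, traj$cum_angle_deg,
                   traj$com_angstrom, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  needed <- c("t_s", "e11", "e12", "e13", "e21", "e22", "e23", "e31", "e32",
              "e33", "ang1_deg", "ang2_deg", "ang3_deg", "x_A", "y_A", "z_A")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_invalid("trajectory CSV lacks columns: ",
                 paste(missing, collapse = ", "))
  }
  structure(
    list(times = df$t_s,
         frames = as.matrix(df[, needed[2:10]]),
         cum_angle_deg = as.matrix(df[, needed[11:13]]),
         com_angstrom = as.matrix(df[, needed[14:16]])),
    class = "rotor_trajectory"
  )
}
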
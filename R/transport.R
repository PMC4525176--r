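#' Enantiomeric excess versus exposure time (drifting-Gaussian model)
#'
#' For two overlapping Gaussian concentration profiles with opposite drift
#' velocities \eqn{\pm v} and common diffusion coefficient \eqn{D}, split
#' into two halves at the centre of the combined profile, the excess in each
#' half is \deqn{ee(t) = v \sqrt{t / (\pi D)},} the small-drift limit of the
#' exact centre-split result \eqn{erf(v\sqrt{t/4D})}. The value is capped at
#' 1 since the formula is a low-enrichment approximation.
#'
#' @param v drift (propulsion) speed, m/s; the sign is ignored.
#' @param d_cm2_s translational diffusion coefficient, cm^2/s (> 0).
#' @param t_s exposure time, s (>= 0), vectorised.
#' @return ee as a fraction in \eqn{[0, 1]}.
#' @examples
#' ee_vs_time(25e-9, 8.3e-6, 45 * 3600)   # ~0.20 (molecule I, 45 h)
#' @export
ee_vs_time <- function(v, d_cm2_s, t_s) {
  check_positive(d_cm2_s, "d_cm2_s")
  if (any(t_s < 0)) stop_invalid("t_s must be >= 0")
  v_cm <- abs(v) * 100
  pmin(v_cm * sqrt(t_s / (pi * d_cm2_s)), 1)
}

#' Concentration profile container
#'
#' A 1-D spatial profile of the two enantiomer concentrations in the
#' separation capillary.
#'
#' @param grid_cm uniform, strictly increasing positions, cm.
#' @param c_S,c_R non-negative concentration arrays (arbitrary units).
#' @param active_region length-2 interval (cm) where the rotating field (and
#'   hence the drift) acts; defaults to the whole grid.
#' @return An object of class `concentration_profile`.
#' @export
concentration_profile <- function(grid_cm, c_S, c_R,
                                  active_region = range(grid_cm)) {
  stopifnot(length(grid_cm) == length(c_S), length(c_S) == length(c_R))
  dx <- diff(grid_cm)
  if (any(dx <= 0) || diff(range(dx)) > 1e-9 * mean(dx)) {
    stop_invalid("grid_cm must be uniform and strictly increasing")
  }
  if (any(c_S < -1e-12) || any(c_R < -1e-12)) {
    stop_invalid("concentrations must be non-negative")
  }
  structure(
    list(grid_cm = grid_cm, c_S = pmax(c_S, 0), c_R = pmax(c_R, 0),
         active_region = sort(active_region)),
    class = "concentration_profile"
  )
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration profile: %d points on [%.3g, %.3g] cm\n",
              length(x$grid_cm), min(x$grid_cm), max(x$grid_cm)))
  tot <- trapz(x$grid_cm, x$c_S) + trapz(x$grid_cm, x$c_R)
  sep <- trapz(x$grid_cm, x$c_S) - trapz(x$grid_cm, x$c_R)
  cat(sprintf("  total mass %.4g, overall ee %.3g%%\n", tot,
              if (tot > 0) 100 * sep / tot else 0))
  invisible(x)
}

#' @export
plot.concentration_profile <- function(x, ...) {
  graphics::matplot(x$grid_cm, cbind(x$c_S, x$c_R), type = "l",
                    lty = 1, col = c("blue", "red"),
                    xlab = "position (cm)", ylab = "concentration (a.u.)",
                    ...)
  graphics::legend("topright", c("S", "R"), col = c("blue", "red"), lty = 1,
                   bty = "n")
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Drifting Gaussian enantiomer pair
#'
#' The analytic solution of free drift-diffusion from a point release at
#' `x0`: S drifts toward larger x at `+v`, R at `-v`, both spreading with
#' variance \eqn{2Dt}. Each species is normalised to unit mass on the
#' (sufficiently wide) grid.
#'
#' @param v drift speed of the S enantiomer toward larger x, m/s (signed).
#' @param d_cm2_s diffusion coefficient, cm^2/s.
#' @param t_s elapsed time, s (> 0).
#' @param x0_cm release position, cm.
#' @param grid_cm uniform spatial grid, cm.
#' @return A [concentration_profile()].
#' @export
gaussian_pair_profile <- function(v, d_cm2_s, t_s, x0_cm, grid_cm) {
  check_positive(d_cm2_s, "d_cm2_s")
  check_positive(t_s, "t_s")
  v_cm <- v * 100
  sigma <- sqrt(2 * d_cm2_s * t_s)
  c_S <- stats::dnorm(grid_cm, mean = x0_cm + v_cm * t_s, sd = sigma)
  c_R <- stats::dnorm(grid_cm, mean = x0_cm - v_cm * t_s, sd = sigma)
  concentration_profile(grid_cm, c_S, c_R)
}

#' Enantiomeric excess of the two sides of a cut profile
#'
#' Integrated ee, in percent and signed toward S, of the leading
#' (x > cut) and trailing (x < cut) portions of a profile:
#' \eqn{ee = (\int c_S - \int c_R) / (\int c_S + \int c_R)}. For a symmetric
#' drifted pair the two sides carry opposite signs.
#'
#' @param profile a [concentration_profile()].
#' @param cut_cm cut position inside the grid; defaults to the centre of
#'   mass of the combined profile.
#' @return List with `ee_leading_pct` and `ee_trailing_pct`.
#' @export
split_ee <- function(profile, cut_cm = NULL) {
  stopifnot(inherits(profile, "concentration_profile"))
  g <- profile$grid_cm
  tot <- profile$c_S + profile$c_R
  if (is.null(cut_cm)) {
    cut_cm <- trapz(g, g * tot) / trapz(g, tot)
  }
  if (cut_cm <= min(g) || cut_cm >= max(g)) {
    stop_invalid("cut position lies outside the grid")
  }
  side_ee <- function(mask) {
    s <- trapz_masked(g, profile$c_S, mask)
    r <- trapz_masked(g, profile$c_R, mask)
    if (s + r <= 0) stop_invalid("empty side: ee undefined")
    100 * (s - r) / (s + r)
  }
  list(ee_leading_pct = side_ee(g >= cut_cm),
       ee_trailing_pct = side_ee(g <= cut_cm))
}

trapz_masked <- function(x, y, mask) {
  if (sum(mask) < 2) return(0)
  trapz(x[mask], y[mask])
}

#' Evolve a profile in the bounded separation chamber
#'
#' Explicit conservative finite-difference drift-diffusion on a closed
#' (reflecting) domain. The drift \eqn{\pm v} (S toward larger x, R toward
#' smaller x) acts only inside `active_region` -- material that diffuses out
#' of the electrode-covered region is no longer driven -- while diffusion
#' acts everywhere. Fluxes are assembled in flux form with first-order
#' upwinding of the advection, so total mass of each species is conserved to
#' rounding.
#'
#' @param profile a [concentration_profile()].
#' @param v drift speed, m/s (S toward larger x).
#' @param d_cm2_s diffusion coefficient, cm^2/s.
#' @param dt_s time step, s; must satisfy \eqn{D\,dt/\Delta x^2 \le 0.4}.
#' @param n_steps number of steps.
#' @return The evolved [concentration_profile()].
#' @export
evolve_bounded <- function(profile, v, d_cm2_s, dt_s, n_steps) {
  stopifnot(inherits(profile, "concentration_profile"))
  check_positive(d_cm2_s, "d_cm2_s")
  check_positive(dt_s, "dt_s")
  g <- profile$grid_cm
  dx <- g[2] - g[1]
  if (d_cm2_s * dt_s / dx^2 > 0.4) {
    stop_invalid("CFL violation: D dt/dx^2 = ",
                 signif(d_cm2_s * dt_s / dx^2, 3), " > 0.4")
  }
  v_cm <- v * 100
  if (abs(v_cm) * dt_s / dx > 0.9) {
    stop_invalid("advection Courant number exceeds 0.9; reduce dt")
  }
  # drift is defined on cell interfaces, on only where both cells are active
  mid <- (g[-1] + g[-length(g)]) / 2
  act <- mid >= profile$active_region[1] & mid <= profile$active_region[2]
  step_species <- function(conc, v_sp) {
    # interface fluxes: advective (upwind) + diffusive
    n <- length(conc)
    vi <- ifelse(act, v_sp, 0)
    up <- ifelse(vi > 0, conc[-n], conc[-1])
    flux <- vi * up - d_cm2_s * (conc[-1] - conc[-n]) / dx
    conc + dt_s / dx * (c(0, flux) - c(flux, 0))
  }
  c_S <- profile$c_S
  c_R <- profile$c_R
  for (i in seq_len(n_steps)) {
    c_S <- step_species(c_S, v_cm)
    c_R <- step_species(c_R, -v_cm)
    if (min(c_S, c_R) < -1e-8 * max(c_S, c_R, 1)) {
      stop("finite-difference instability: negative concentrations; ",
           "reduce dt")
    }
  }
  concentration_profile(g, pmax(c_S, 0), pmax(c_R, 0),
                        profile$active_region)
}

#' Steady-state exponential profile in a closed chamber
#'
#' In a closed container of length `L` the balance of drift and diffusion
#' gives the zero-flux steady state
#' \deqn{C(x) = C_{ave}\frac{vL/D\; e^{vx/D}}{e^{vL/D}-1}, \quad x\in[0,L],}
#' whose spatial mean is \eqn{C_{ave}}. The opposite enantiomer gets the
#' mirrored profile \eqn{C(L-x)}. As \eqn{v \to 0} the profile tends to the
#' uniform distribution.
#'
#' @param v drift speed of the S enantiomer, m/s (may be 0).
#' @param d_cm2_s diffusion coefficient, cm^2/s.
#' @param l_cm chamber length, cm (> 0).
#' @param c_ave average concentration (a.u.).
#' @param n_points grid resolution.
#' @return A [concentration_profile()] on \eqn{[0, L]} with `c_S` the
#'   profile above and `c_R` its mirror.
#' @export
steady_state_profile <- function(v, d_cm2_s, l_cm, c_ave = 1,
                                 n_points = 501) {
  check_positive(d_cm2_s, "d_cm2_s")
  check_positive(l_cm, "l_cm")
  x <- seq(0, l_cm, length.out = n_points)
  v_cm <- v * 100
  if (v_cm == 0) {
    c_S <- rep(c_ave, n_points)
  } else {
    a <- v_cm * l_cm / d_cm2_s
    # C = C_ave * a * exp(v x / D) / (exp(a) - 1); expm1 keeps small-a exact
    c_S <- c_ave * a * exp(v_cm * x / d_cm2_s) / expm1(a)
  }
  concentration_profile(x, c_S, rev(c_S))
}

#' Characteristic drift-diffusion length
#'
#' \eqn{D/|v|}: the length scale over which propulsion wins against
#' diffusion. Smaller values mean stronger separation.
#'
#' @param d_cm2_s diffusion coefficient, cm^2/s.
#' @param v drift speed, m/s.
#' @return Length in cm; `Inf` for `v = 0`.
#' @examples
#' characteristic_length(8.3e-6, 25e-9)  # ~3.3 cm
#' @export
characteristic_length <- function(d_cm2_s, v) {
  check_positive(d_cm2_s, "d_cm2_s")
  if (v == 0) return(Inf)
  d_cm2_s / abs(v * 100)
}

#' Enrichment level from enantiomeric excess
#'
#' The fraction of the majority enantiomer: `(100 + |ee|) / 2` percent.
#'
#' @param ee_pct ee in percent, in \eqn{[-100, 100]}.
#' @return Enrichment level in percent.
#' @examples
#' enrichment_from_ee(61)  # 80.5
#' @export
enrichment_from_ee <- function(ee_pct) {
  if (any(!is.finite(ee_pct)) || any(abs(ee_pct) > 100)) {
    stop_invalid("ee must lie in [-100, 100] percent")
  }
  (100 + abs(ee_pct)) / 2
}

#' Fit the propulsion velocity to measured ee(t) data
#'
#' Least-squares fit of the square-root law \eqn{ee = v\sqrt{t/(\pi D)}} to
#' enantiomeric-excess measurements at known diffusion coefficient: a linear
#' regression of ee on \eqn{\sqrt{t/(\pi D)}} through the origin.
#'
#' @param t_s exposure times, s.
#' @param ee observed ee fractions (0-1 scale).
#' @param d_cm2_s independently measured diffusion coefficient, cm^2/s.
#' @return Object of class `ee_fit` with `v_m_s`, `stderr_m_s` and the
#'   underlying `lm` fit; has `coef`, `predict` and `print` methods.
#' @export
fit_propulsion_velocity <- function(t_s, ee, d_cm2_s) {
  check_positive(d_cm2_s, "d_cm2_s")
  stopifnot(length(t_s) == length(ee), length(t_s) >= 3)
  s <- sqrt(t_s / (pi * d_cm2_s))          # cm^-1 * ... units: s^.5 cm^-1 s^-.5
  fit <- stats::lm(ee ~ s - 1)
  v_cm <- stats::coef(fit)[["s"]]
  se_cm <- summary(fit)$coefficients["s", "Std. Error"]
  structure(
    list(v_m_s = v_cm / 100, stderr_m_s = se_cm / 100,
         d_cm2_s = d_cm2_s, fit = fit),
    class = "ee_fit"
  )
}

#' @export
coef.ee_fit <- function(object, ...) c(v_m_s = object$v_m_s)

#' @export
predict.ee_fit <- function(object, t_s, ...) {
  ee_vs_time(object$v_m_s, object$d_cm2_s, t_s)
}

#' @export
print.ee_fit <- function(x, ...) {
  cat(sprintf("Propulsion velocity from ee(t): %.3g +/- %.2g nm/s\n",
              x$v_m_s * 1e9, x$stderr_m_s * 1e9))
  invisible(x)
}

#' Profile CSV input/output
#'
#' Columns `x_cm, c_S, c_R`.
#'
#' @param profile a [concentration_profile()].
#' @param path file path.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "concentration_profile"))
  utils::write.csv(
    data.frame(x_cm = profile$grid_cm, c_S = profile$c_S,
               c_R = profile$c_R),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x_cm", "c_S", "c_R") %in% names(df))) {
    stop_invalid("profile CSV needs columns x_cm, c_S, c_R")
  }
  concentration_profile(df$x_cm, df$c_S, df$c_R)
}
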
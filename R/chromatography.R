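#' Chromatogram container
#'
#' Simultaneous absorbance and circular-dichroism (CD) elution traces from
#' the in-line detector.
#'
#' @param time_s strictly increasing elution times, s.
#' @param absorbance baseline-subtracted absorbance, a.u. (>= 0).
#' @param cd signed CD signal, a.u.
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(time_s, absorbance, cd) {
  stopifnot(length(time_s) == length(absorbance),
            length(absorbance) == length(cd))
  if (any(diff(time_s) <= 0)) {
    stop_invalid("time_s must be strictly increasing")
  }
  if (any(absorbance < -1e-12)) {
    stop_invalid("absorbance must be non-negative after baseline subtraction")
  }
  structure(list(time_s = time_s, absorbance = pmax(absorbance, 0), cd = cd),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram: %d points, %.4g-%.4g s\n",
              length(x$time_s), min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, ...) {
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(x$time_s, x$absorbance, type = "l",
                 xlab = "elution time (s)", ylab = "absorbance (a.u.)", ...)
  graphics::plot(x$time_s, x$cd, type = "l", col = "purple",
                 xlab = "elution time (s)", ylab = "CD (a.u.)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Map a spatial concentration profile to an elution chromatogram
#'
#' The capillary content is pumped past a fixed detector: a slice at
#' position x (cm) elutes at \eqn{t = (x_{det} - x)/u} with linear velocity
#' \eqn{u} = flow rate / cross-section, so the leading edge (largest x,
#' closest to the detector/collection end) elutes first. Absorbance is
#' proportional to total concentration, the CD signal to the concentration
#' difference scaled by `cd_per_ee`.
#'
#' @param profile a [concentration_profile()].
#' @param flow_rate_ul_min volumetric flow rate, microlitre/min (> 0).
#' @param capillary_id_um capillary inner diameter, micrometre.
#' @param detector_position_cm detector position; must be at or beyond the
#'   far end of the profile grid.
#' @param cd_per_ee CD signal per unit ee fraction at unit concentration.
#' @return A [chromatogram()].
#' @export
profile_to_chromatogram <- function(profile, flow_rate_ul_min = 0.050,
                                    capillary_id_um = 75,
                                    detector_position_cm = NULL,
                                    cd_per_ee = 1) {
  stopifnot(inherits(profile, "concentration_profile"))
  check_positive(flow_rate_ul_min, "flow_rate_ul_min")
  check_positive(capillary_id_um, "capillary_id_um")
  g <- profile$grid_cm
  if (is.null(detector_position_cm)) detector_position_cm <- max(g)
  if (detector_position_cm < max(g)) {
    stop_invalid("detector lies behind part of the profile")
  }
  q_cm3_s <- flow_rate_ul_min * 1e-3 / 60          # ul/min -> cm^3/s
  area_cm2 <- pi * (capillary_id_um * 1e-4 / 2)^2
  u <- q_cm3_s / area_cm2                          # linear velocity, cm/s
  t <- (detector_position_cm - g) / u              # decreasing in x
  ord <- order(t)
  chromatogram(time_s = t[ord],
               absorbance = (profile$c_S + profile$c_R)[ord],
               cd = cd_per_ee * (profile$c_S - profile$c_R)[ord])
}

#' Full width at half maximum of a single chromatographic peak
#'
#' Width of the absorbance peak at half its maximum, with linear
#' interpolation between sampling points. Requires one dominant peak:
#' exactly two half-maximum crossings.
#'
#' @param chrom a [chromatogram()].
#' @return FWHM in seconds.
#' @export
fwhm <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  y <- chrom$absorbance
  t <- chrom$time_s
  half <- max(y) / 2
  above <- y >= half
  if (!any(above)) stop_invalid("no half-maximum crossing found")
  runs <- rle(above)
  if (sum(runs$values) != 1) {
    stop_invalid("absorbance trace is not a single dominant peak (",
                 sum(runs$values), " regions above half maximum)")
  }
  i1 <- which(above)[1]
  i2 <- max(which(above))
  cross <- function(i_lo, i_hi) {
    # linear interpolation of the crossing between samples i_lo and i_hi
    t[i_lo] + (half - y[i_lo]) * (t[i_hi] - t[i_lo]) / (y[i_hi] - y[i_lo])
  }
  t_left <- if (i1 == 1) t[1] else cross(i1 - 1, i1)
  t_right <- if (i2 == length(y)) t[i2] else cross(i2 + 1, i2)
  t_right - t_left
}

#' Diffusion coefficient from diffusive peak spreading
#'
#' For a Gaussian peak undergoing one-dimensional diffusion,
#' \eqn{FWHM^2 = FWHM_0^2 + 16\ln 2\, D\, t}. A linear regression of the
#' squared spatial FWHM against the waiting time gives
#' \eqn{D = slope / (16 \ln 2)}, with a free intercept for the injection
#' width.
#'
#' @param t_s waiting times, s (>= 3 values).
#' @param fwhm_cm peak full widths at half maximum, in cm (convert elution
#'   FWHM to length with the flow velocity first).
#' @return List with `d_cm2_s`, `stderr` and the `fit`.
#' @export
estimate_D_from_spreading <- function(t_s, fwhm_cm) {
  stopifnot(length(t_s) == length(fwhm_cm))
  if (length(t_s) < 3) stop_invalid("need at least 3 (t, FWHM) pairs")
  w2 <- fwhm_cm^2
  fit <- stats::lm(w2 ~ t_s)
  slope <- stats::coef(fit)[["t_s"]]
  # a constant series gives a slope at rounding level: report D = 0
  if (slope < 0 &&
      abs(slope) * diff(range(t_s)) < 1e-9 * max(w2, 1e-300)) {
    slope <- 0
  }
  if (slope < 0) stop_invalid("negative FWHM^2 slope: no diffusive spreading")
  # summary.lm warns on an exactly collinear (noise-free) series
  se <- suppressWarnings(summary(fit)$coefficients["t_s", "Std. Error"])
  k <- 16 * log(2)
  list(d_cm2_s = slope / k, stderr = se / k, fit = fit)
}

#' CD/absorbance calibration curve
#'
#' Linear map between the concentration-independent ratio of integrated CD
#' to integrated absorbance and the enantiomeric excess, fitted from
#' standards of known ee. The default (synthetic-detector) calibration is
#' the identity line `ee_pct = 100 * ratio`, which is exact when the CD
#' channel is generated with `cd_per_ee = 1`.
#'
#' @param ee_pct known ee values, percent.
#' @param ratio measured CD/absorbance ratios.
#' @return Object of class `calibration_curve` with the fitted slope and
#'   intercept (ratio as a function of ee).
#' @export
calibration_curve <- function(ee_pct, ratio) {
  stopifnot(length(ee_pct) == length(ratio), length(ee_pct) >= 2)
  fit <- stats::lm(ratio ~ ee_pct)
  slope <- stats::coef(fit)[["ee_pct"]]
  if (slope == 0 || !is.finite(slope)) {
    stop_invalid("calibration map is not strictly monotone")
  }
  structure(list(slope = slope,
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 fit = fit),
            class = "calibration_curve")
}

#' @rdname calibration_curve
#' @export
default_calibration <- function() {
  calibration_curve(ee_pct = c(-100, 0, 100), ratio = c(-1, 0, 1))
}

#' @rdname calibration_curve
#' @param path CSV with columns `ee_pct, ratio`.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("ee_pct", "ratio") %in% names(df))) {
    stop_invalid("calibration CSV needs columns ee_pct, ratio")
  }
  calibration_curve(df$ee_pct, df$ratio)
}

#' Enantiomeric excess from the CD/absorbance ratio
#'
#' The ratio of integrated CD to integrated absorbance over a time window is
#' concentration independent; the calibration curve converts it to ee in
#' percent.
#'
#' @param chrom a [chromatogram()].
#' @param calibration a [calibration_curve()]; default identity.
#' @param window length-2 time window, s; default the whole record.
#' @return ee in percent (signed toward S for the built-in conventions).
#' @export
ee_from_cd <- function(chrom, calibration = default_calibration(),
                       window = range(chrom$time_s)) {
  stopifnot(inherits(chrom, "chromatogram"),
            inherits(calibration, "calibration_curve"))
  mask <- chrom$time_s >= window[1] & chrom$time_s <= window[2]
  if (sum(mask) < 2) stop_invalid("window contains fewer than 2 samples")
  a <- trapz(chrom$time_s[mask], chrom$absorbance[mask])
  if (a <= 1e-300 * max(chrom$absorbance, 1)) {
    stop_invalid("absorbance integral is ~0: ee undefined")
  }
  ratio <- trapz(chrom$time_s[mask], chrom$cd[mask]) / a
  (ratio - calibration$intercept) / calibration$slope
}

#' Split a chromatogram into leading and trailing fractions
#'
#' Partition at a cut time; by default the absorbance centre of mass,
#' corresponding to splitting the sample slug into two halves at the centre
#' of the absorption profile. The leading fraction is the earlier-eluting
#' part.
#'
#' @param chrom a [chromatogram()].
#' @param cut_time_s cut position, s, inside the record; `NULL` for the
#'   absorbance centre of mass.
#' @param method `"com"` (centre of mass, default) or `"peak"` (absorbance
#'   maximum), used when `cut_time_s` is `NULL`.
#' @return List with `leading` and `trailing` chromatograms and `cut_time_s`.
#' @export
split_fractions <- function(chrom, cut_time_s = NULL,
                            method = c("com", "peak")) {
  stopifnot(inherits(chrom, "chromatogram"))
  method <- match.arg(method)
  t <- chrom$time_s
  if (is.null(cut_time_s)) {
    cut_time_s <- if (method == "com") {
      trapz(t, t * chrom$absorbance) / trapz(t, chrom$absorbance)
    } else {
      t[which.max(chrom$absorbance)]
    }
  }
  if (cut_time_s <= min(t) || cut_time_s >= max(t)) {
    stop_invalid("cut time lies outside the record")
  }
  # insert an interpolated sample at the cut so the two fractions tile the
  # record exactly and integrated signal is conserved
  a_cut <- stats::approx(t, chrom$absorbance, cut_time_s)$y
  c_cut <- stats::approx(t, chrom$cd, cut_time_s)$y
  lead <- t < cut_time_s
  trail <- t > cut_time_s
  list(
    leading = chromatogram(c(t[lead], cut_time_s),
                           c(chrom$absorbance[lead], a_cut),
                           c(chrom$cd[lead], c_cut)),
    trailing = chromatogram(c(cut_time_s, t[trail]),
                            c(a_cut, chrom$absorbance[trail]),
                            c(c_cut, chrom$cd[trail])),
    cut_time_s = cut_time_s
  )
}

#' Chromatogram CSV input/output
#'
#' Columns `t_s, abs_au, cd_au`.
#'
#' @param chrom a [chromatogram()].
#' @param path file path.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  utils::write.csv(
    data.frame(t_s = chrom$time_s, abs_au = chrom$absorbance,
               cd_au = chrom$cd),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram_csv
#' @export
read_chromatogram_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "abs_au", "cd_au") %in% names(df))) {
    stop_invalid("chromatogram CSV needs columns t_s, abs_au, cd_au")
  }
  chromatogram(df$t_s, df$abs_au, df$cd_au)
}
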
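# Hand-built trajectory: uniform rotation about the propeller axis (lab x)
# at `rate_hz`, with COM advancing l_rev per revolution along x. Used as an
# analytic oracle for the estimators, independent of the BD kernel.
constant_rate_trajectory <- function(rate_hz, dt, n, l_rev = 0) {
  t <- (0:(n - 1)) * dt
  ang <- 2 * pi * rate_hz * t
  frames <- cbind(e11 = rep(1, n), e12 = 0, e13 = 0,
                  e21 = 0, e22 = cos(ang), e23 = sin(ang),
                  e31 = 0, e32 = -sin(ang), e33 = cos(ang))
  cum <- cbind(ang1_deg = rate_hz * t * 360, ang2_deg = 0, ang3_deg = 0)
  com <- cbind(x_A = l_rev * rate_hz * t, y_A = 0, z_A = 0)
  structure(list(times = t, frames = frames, cum_angle_deg = cum,
                 com_angstrom = com),
            class = "rotor_trajectory")
}
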
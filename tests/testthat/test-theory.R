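test_that("field coupling matches hand unit conversion and handles edge cases", {
  expect_equal(field_coupling(mol1, ref_field), X_MOL1, tolerance = 1e-4)
  expect_equal(field_coupling(mol2, ref_field), X_MOL2, tolerance = 1e-4)
  m0 <- chiral_rotor("apolar", "S", 0, 1, 1e12, 1e-5)
  expect_identical(field_coupling(m0, ref_field), 0)
  # coupling is invariant under mirroring
  expect_identical(field_coupling(mirror(mol1), ref_field),
                   field_coupling(mol1, ref_field))
  expect_error(field_protocol(6e5, 9e5, "CW", temperature_k = -1),
               class = "propellr_invalid_parameter")
})

test_that("mirror is an involution that only flips handedness and L_rev", {
  m <- mirror(mol1)
  expect_identical(m$handedness, "R")
  expect_identical(m$l_rev_angstrom, -mol1$l_rev_angstrom)
  expect_identical(m$d_r_deg2_s, mol1$d_r_deg2_s)
  expect_identical(mirror(m), mol1)
})

test_that("Boltzmann angular density is normalised, peaked forward", {
  # zero coupling: uniform density over the sphere
  expect_equal(angular_density(c(0, 1, pi), 0), rep(1 / (4 * pi), 3))
  for (x in c(0.001, 1, 10)) {
    total <- integrate(function(a) angular_density(a, x) * 2 * pi * sin(a),
                       0, pi, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
    # forward/backward density ratio follows the closed form e^(2x)
    expect_equal(angular_density(0, x) / angular_density(pi, x), exp(2 * x),
                 tolerance = 1e-10)
  }
})

test_that("responding fraction: limits, small-x expansion, monotonicity", {
  expect_identical(responding_fraction(0), 0)
  expect_equal(responding_fraction(X_MOL1), 2.61985e-3, tolerance = 1e-4)
  expect_equal(responding_fraction(10), 1 - 20 / (exp(20) - 1),
               tolerance = 1e-12)
  xs <- c(1e-4, 1e-3, 1e-2)
  expect_equal(responding_fraction(xs), xs - xs^2 / 3, tolerance = 1e-4)
  # strictly increasing until it saturates at 1 in double precision
  grid <- 10^seq(-4, 1, length.out = 40)
  expect_true(all(diff(responding_fraction(grid)) > 0))
  expect_true(responding_fraction(500) <= 1)
  expect_error(responding_fraction(-0.1),
               class = "propellr_invalid_parameter")
  # alternative min/max-ratio baseline, retained for comparison
  expect_equal(responding_fraction(X_MOL1, mode = "exponential"),
               1 - exp(-2 * X_MOL1), tolerance = 1e-10)
})

test_that("rotational friction from the Einstein relation", {
  # hand computation: kT / (8.2e12 * (pi/180)^2) at 293 K
  expect_equal(rotational_friction(8.2e12, 293), 1.61951e-30,
               tolerance = 1e-4)
  expect_equal(rotational_friction(4.1e12, 293),
               2 * rotational_friction(8.2e12, 293))
  # deg^2/s input and the equivalent rad^2/s value agree
  d_rad <- 8.2e12 * (pi / 180)^2
  expect_equal(rotational_friction(8.2e12, 293),
               1.380649e-23 * 293 / d_rad)
  expect_error(rotational_friction(-1, 293),
               class = "propellr_invalid_parameter")
})

test_that("Stokes-Einstein rotational diffusion for the 6 Angstrom sphere", {
  d_r <- stokes_einstein_rotational(6, 0.0065, 293)
  expect_equal(d_r, 3e12, tolerance = 0.02)
  expect_equal(stokes_einstein_rotational(12, 0.0065, 293), d_r / 8,
               tolerance = 1e-10)
  expect_equal(stokes_einstein_rotational(6, 0.0065, 586), 2 * d_r,
               tolerance = 1e-10)
  expect_error(stokes_einstein_rotational(0, 0.0065, 293),
               class = "propellr_invalid_parameter")
})

test_that("escape frequency reproduces both molecules and vanishes at E=0", {
  expect_equal(escape_frequency(mol2, ref_field), 2.1e6, tolerance = 0.03)
  # molecule I carries the back-solved D_r, so its escape frequency is the
  # published 0.507 MHz by construction
  expect_equal(escape_frequency(mol1, ref_field), 0.507e6, tolerance = 1e-4)
  off <- field_protocol(0, 9e5, "CW")
  expect_identical(escape_frequency(mol2, off), 0)
})

test_that("effective frequency: slip branch, locked branch, asymptote", {
  expect_equal(effective_frequency(9e5, 0.507e6), 156.4e3, tolerance = 1e-3)
  expect_identical(effective_frequency(9e5, 2.1e6), 9e5)   # locked
  # continuity at the transition
  eps <- 1e-9
  expect_equal(effective_frequency(1e6 * (1 + eps), 1e6),
               effective_frequency(1e6, 1e6), tolerance = 1e-4)
  # far asymptote nu_esc^2 / (2 nu)
  expect_equal(effective_frequency(100 * 5e5, 5e5) / 5e5, 1 / 200,
               tolerance = 1e-4)
  # maximum of nu_eff(nu) sits at nu = nu_esc and decays beyond
  nu_grid <- seq(0.1e6, 5e6, by = 0.05e6)
  ne <- effective_frequency(nu_grid, 1e6)
  expect_equal(nu_grid[which.max(ne)], 1e6)
  expect_true(all(diff(ne[nu_grid >= 1e6]) < 0))
  expect_error(effective_frequency(-1, 1), class = "propellr_invalid_parameter")
})

test_that("driven-rotor ODE integration matches the closed form within 1%", {
  nu_esc <- 0.507e6
  for (ratio in c(0.5, 0.99, 1.01, 2, 10, 100)) {
    nu <- ratio * nu_esc
    expect_equal(effective_frequency_ode(nu, nu_esc, n_cycles = 1000),
                 effective_frequency(nu, nu_esc),
                 tolerance = 0.01)
  }
})

test_that("driven-rotor ODE degenerate regimes", {
  # locked: constant phase lag, rotates with the field
  expect_equal(effective_frequency_ode(9e5, 2.1e6, n_cycles = 300), 9e5,
               tolerance = 1e-3)
  expect_identical(effective_frequency_ode(9e5, 0), 0)
  expect_identical(effective_frequency_ode(0, 1e6), 0)
  expect_error(effective_frequency_ode(9e5, 5e5, n_cycles = 5),
               class = "propellr_invalid_parameter")
})

test_that("angular correction factor: exact limits and small-x expansion", {
  expect_identical(angular_correction(0), 0.5)
  expect_equal(angular_correction(1e4), 2 / pi, tolerance = 1e-3)
  for (x in c(1e-3, 5e-3, 1e-2)) {
    expect_equal(angular_correction(x), 0.5 * (1 + x^2 / 48),
                 tolerance = 2e-9)
  }
  # monotone non-decreasing in the coupling
  vals <- vapply(c(0, 0.1, 1, 5, 20, 100), angular_correction, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0.5 & vals <= 2 / pi + 1e-9))
})

test_that("propulsion velocity reproduces the 25 and ~45 nm/s chain", {
  v1 <- propulsion_velocity(mol1, ref_field)
  expect_equal(v1 * 1e9, 25, tolerance = 0.01)
  v2 <- propulsion_velocity(mol2, ref_field)
  expect_equal(v2 * 1e9, 45, tolerance = 0.05)
  # zero field -> no drift
  expect_identical(propulsion_velocity(mol1, field_protocol(0, 9e5, "CW")), 0)
})

test_that("propulsion velocity symmetries: mirror, sense, scalar invariants", {
  v1 <- propulsion_velocity(mol1, ref_field)
  expect_identical(propulsion_velocity(mirror(mol1), ref_field), -v1)
  ccw <- field_protocol(ref_field$e_v_m, ref_field$nu_hz, "CCW")
  expect_identical(propulsion_velocity(mol1, ccw), -v1)
  # the scalar factors never see the handedness
  pS <- propeller_predict(mol1, ref_field)
  pR <- propeller_predict(mirror(mol1), ref_field)
  expect_identical(pS$responding_fraction, pR$responding_fraction)
  expect_identical(pS$nu_eff_hz, pR$nu_eff_hz)
  expect_identical(pS$a_cor, pR$a_cor)
  expect_identical(pS$velocity_m_s, -pR$velocity_m_s)
})

test_that("below the escape frequency v is linear in E to first order", {
  # halving E halves nu_esc but the drive stays locked, so v tracks F ~ x
  f1 <- field_protocol(3e5, 1e5, "CW")
  f2 <- field_protocol(6e5, 1e5, "CW")
  v1 <- propulsion_velocity(mol2, f1)
  v2 <- propulsion_velocity(mol2, f2)
  expect_equal(v2 / v1, 2, tolerance = 0.01)
})
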
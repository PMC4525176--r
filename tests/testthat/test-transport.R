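trapz_ <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

test_that("ee kinetics reproduce the published drift-diffusion predictions", {
  # molecule I: 25 nm/s, D = 8.3e-6 cm^2/s, 45 h
  expect_equal(100 * ee_vs_time(25e-9, 8.3e-6, 45 * 3600), 19.705,
               tolerance = 1e-4)
  # molecule II: 45 nm/s, D = 1.4e-5 cm^2/s, 46 h
  expect_equal(100 * ee_vs_time(45e-9, 1.4e-5, 46 * 3600), 27.612,
               tolerance = 1e-4)
  expect_identical(ee_vs_time(25e-9, 8.3e-6, 0), 0)
  # the formula is capped at full enrichment
  expect_identical(ee_vs_time(1e-3, 1e-6, 1e6), 1)
})

test_that("ee grows exactly as sqrt(t)", {
  t <- 10^seq(2, 6, length.out = 30)
  ee <- ee_vs_time(45e-9, 1.4e-5, t)
  slope <- coef(lm(log(ee) ~ log(t)))[[2]]
  expect_equal(slope, 0.5, tolerance = 1e-6)
})

test_that("gaussian pair profile: symmetry and the centre-split oracle", {
  g <- seq(-5, 15, by = 0.01)
  v <- 45e-9
  prof <- gaussian_pair_profile(v, 1.4e-5, 21 * 3600, 5, g)
  # mirror symmetry about the release point
  i <- which(g == 7)
  j <- which(g == 3)
  expect_equal(prof$c_S[i], prof$c_R[j], tolerance = 1e-12)
  # t -> 0: coincident peaks, no excess anywhere
  p0 <- gaussian_pair_profile(v, 1.4e-5, 1e-3, 5, g)
  s0 <- split_ee(p0, 5)
  expect_equal(s0$ee_leading_pct, 0, tolerance = 1e-9)
  # the numerical centre split equals the exact erf result ...
  for (hours in c(2, 10, 21, 40)) {
    t_s <- hours * 3600
    p <- gaussian_pair_profile(v, 1.4e-5, t_s, 5, g)
    se <- split_ee(p, 5)
    z <- (v * 100 / 2) * sqrt(t_s / 1.4e-5)
    ee_erf <- 100 * (2 * pnorm(z * sqrt(2)) - 1)
    expect_equal(se$ee_leading_pct, ee_erf, tolerance = 1e-4)
    expect_equal(se$ee_trailing_pct, -se$ee_leading_pct, tolerance = 1e-9)
    # ... and the small-drift sqrt(t) law tracks it within 1% up to
    # ee ~ 0.2 (the approximation degrades quadratically in ee)
    ee_lin <- 100 * ee_vs_time(v, 1.4e-5, t_s)
    expect_equal(se$ee_leading_pct, ee_lin,
                 tolerance = if (ee_lin <= 20) 0.01 else 0.02)
  }
})

test_that("off-centre cuts toward the edge are more enriched", {
  g <- seq(-5, 15, by = 0.01)
  prof <- gaussian_pair_profile(45e-9, 1.4e-5, 45 * 3600, 5, g)
  centre <- split_ee(prof, 5)$ee_leading_pct
  for (cut in c(6, 7, 8)) {
    expect_gt(split_ee(prof, cut)$ee_leading_pct, centre)
  }
  # zero drift: both sides racemic, no 0/0 failure
  p0 <- gaussian_pair_profile(0, 1.4e-5, 3600, 5, g)
  s0 <- split_ee(p0, 5)
  expect_equal(abs(s0$ee_leading_pct) + abs(s0$ee_trailing_pct), 0,
               tolerance = 1e-9)
  expect_error(split_ee(prof, 99), class = "propellr_invalid_parameter")
})

test_that("bounded solver conserves mass and reproduces free evolution", {
  g <- seq(-5, 15, by = 0.02)
  d <- 1.4e-5
  p0 <- gaussian_pair_profile(45e-9, d, 3600, 5, g)
  dt <- 0.3 * 0.02^2 / d
  n <- ceiling(4 * 3600 / dt)
  pe <- evolve_bounded(p0, 45e-9, d, 4 * 3600 / n, n)
  m0 <- trapz_(g, p0$c_S)
  me <- trapz_(g, pe$c_S)
  expect_equal(me, m0, tolerance = 1e-6)
  # short-time, wide active region: matches the analytic Gaussian pair
  pa <- gaussian_pair_profile(45e-9, d, 5 * 3600, 5, g)
  expect_lt(max(abs(pe$c_S - pa$c_S)) / max(pa$c_S), 0.01)
  expect_lt(max(abs(pe$c_R - pa$c_R)) / max(pa$c_R), 0.01)
  expect_error(evolve_bounded(p0, 45e-9, d, 1e3, 10),
               class = "propellr_invalid_parameter")  # CFL violation
})

test_that("pure diffusion in the solver grows the variance by 2 D t", {
  g <- seq(0, 10, by = 0.02)
  d <- 1.4e-5
  p0 <- gaussian_pair_profile(0, d, 3600, 5, g)
  t_add <- 3 * 3600
  dt <- 0.3 * 0.02^2 / d
  n <- ceiling(t_add / dt)
  pe <- evolve_bounded(p0, 0, d, t_add / n, n)
  varx <- function(c) {
    mu <- trapz_(g, g * c) / trapz_(g, c)
    trapz_(g, (g - mu)^2 * c) / trapz_(g, c)
  }
  expect_equal(varx(pe$c_S) - varx(p0$c_S), 2 * d * t_add, tolerance = 0.01)
})

test_that("finite active region caps the attainable ee", {
  # drift confined to [0, 10] cm; far beyond the characteristic time the
  # bounded ee must fall below the unbounded sqrt(t) law
  g <- seq(-5, 15, by = 0.05)
  d <- 1.4e-5
  v <- 45e-9 * 20               # exaggerated drift to reach the walls fast
  p0 <- gaussian_pair_profile(v, d, 600, 5, g)
  p0$active_region <- c(0, 10)
  t_add <- 100 * 3600
  dt <- 0.35 * 0.05^2 / d
  n <- ceiling(t_add / dt)
  pe <- evolve_bounded(p0, v, d, t_add / n, n)
  ee_bounded <- abs(split_ee(pe)$ee_leading_pct) / 100
  ee_unbounded <- ee_vs_time(v, d, t_add + 600)
  expect_lt(ee_bounded, ee_unbounded)
})

test_that("steady-state profile: normalisation, zero flux, v -> 0 limit", {
  v <- 25e-9
  d <- 8.3e-6
  ss <- steady_state_profile(v, d, 10, c_ave = 2, n_points = 2001)
  g <- ss$grid_cm
  expect_equal(trapz_(g, ss$c_S) / 10, 2, tolerance = 1e-5)
  # zero-flux condition v C - D dC/dx = 0 at interior points
  v_cm <- v * 100
  dcdx <- diff(ss$c_S) / diff(g)
  cmid <- (ss$c_S[-1] + ss$c_S[-length(g)]) / 2
  expect_lt(max(abs(v_cm * cmid - d * dcdx)) / max(v_cm * cmid), 1e-4)
  # R enantiomer is the spatial mirror
  expect_equal(ss$c_R, rev(ss$c_S))
  # vanishing drift: uniform distribution
  ss0 <- steady_state_profile(0, d, 10, c_ave = 2)
  expect_equal(ss0$c_S, rep(2, length(ss0$c_S)))
  # tiny drift tends continuously to uniform
  ss1 <- steady_state_profile(1e-15, d, 10, c_ave = 2)
  expect_equal(ss1$c_S, rep(2, length(ss1$c_S)), tolerance = 1e-6)
})

test_that("characteristic length D/v matches the published scale", {
  expect_equal(characteristic_length(8.3e-6, 25e-9), 3.32, tolerance = 1e-3)
  expect_equal(characteristic_length(8.3e-6, 50e-9),
               characteristic_length(8.3e-6, 25e-9) / 2)
  expect_identical(characteristic_length(8.3e-6, 0), Inf)
})

test_that("ee to enrichment-level conversion", {
  expect_identical(enrichment_from_ee(61), 80.5)
  expect_identical(enrichment_from_ee(0), 50)
  expect_identical(enrichment_from_ee(100), 100)
  expect_identical(enrichment_from_ee(-61), 80.5)
  expect_error(enrichment_from_ee(150), class = "propellr_invalid_parameter")
})

test_that("propulsion velocity is recovered from noisy ee(t) data", {
  set.seed(7)
  t_s <- seq(1, 60, length.out = 15) * 3600
  truth <- 50e-9
  ee <- ee_vs_time(truth, 1.4e-5, t_s) * (1 + rnorm(15, 0, 0.05))
  fit <- fit_propulsion_velocity(t_s, ee, 1.4e-5)
  expect_equal(fit$v_m_s, truth, tolerance = 0.1)
  expect_equal(unname(coef(fit)["v_m_s"]), fit$v_m_s)
  expect_equal(predict(fit, t_s[3]),
               ee_vs_time(fit$v_m_s, 1.4e-5, t_s[3]))
})

test_that("profile CSV round-trips", {
  g <- seq(0, 10, by = 0.1)
  prof <- gaussian_pair_profile(45e-9, 1.4e-5, 3600, 5, g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- read_profile_csv(path)
  expect_equal(back$c_S, prof$c_S, tolerance = 1e-12)
  expect_equal(back$grid_cm, prof$grid_cm)
})
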
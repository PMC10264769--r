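test_that("saturated mass: default, exact-line extrapolation, plateau", {
  # strictly linear mass vs psi from the first point
  psis <- seq(-0.2, -2.4, length.out = 8)
  masses <- 2 + 0.3 * psis          # slope 0.3 g/MPa, intercept 2 g
  cu <- pv_curve(masses, psis, dry_mass = 1)
  expect_equal(saturated_mass(cu)$sat_mass, max(masses))
  sm <- saturated_mass(cu, correct = TRUE)
  expect_equal(sm$sat_mass, masses[1] + 0.3 * abs(psis[1]))
  expect_equal(sm$sat_mass, 2)
  # synthetic curve with known saturated mass 2.000 g and a 2-point plateau
  set.seed(9)
  errs <- replicate(20, {
    cu <- simulate_pv_curve(swc_true = 1.0, noise_sd = 0.005,
                            plateau_points = 2)
    saturated_mass(cu, correct = TRUE)$sat_mass
  })
  expect_true(all(abs(errs - 2) / 2 < 0.01))
})

test_that("saturated water content", {
  psis <- seq(-0.3, -2.5, length.out = 6)
  cu <- pv_curve(seq(2, 1.4, length.out = 6), psis, dry_mass = 1)
  expect_equal(swc(cu, sat_mass = 2), 1.0)
  cu2 <- pv_curve(seq(1.5, 1.1, length.out = 6), psis, dry_mass = 0.5)
  expect_equal(swc(cu2, sat_mass = 1.5), 2.0)
  expect_error(swc(cu, sat_mass = 0.9), "exceed")
  # recovery on simulated curves
  set.seed(14)
  rel <- replicate(200, {
    cu <- simulate_pv_curve(swc_true = 1.5, noise_sd = 0.02)
    abs(swc(cu) - 1.5) / 1.5
  })
  expect_true(all(rel < 0.02))
})

test_that("purely osmotic curve: -1/psi linear throughout", {
  rs <- seq(0.99, 0.5, length.out = 10)
  psis <- -1.5 / rs
  masses <- 1 + 1.5 * rs
  f <- fit_pv(pv_curve(masses, psis, dry_mass = 1), sat_mass = 2.5)
  expect_true(f$no_turgor)
  expect_equal(f$tlp_index, 1L)
  expect_equal(f$psi_sft, -1.5, tolerance = 1e-9)
})

test_that("capacitance is exact for a linear pre-breakpoint generator", {
  # pre-TLP: water content (mol/kg) = 60 + 20 * psi; post-TLP: -1/psi
  # exactly linear in deficit (the pre segment is a hyperbola there, so the
  # breakpoint is identifiable)
  dry <- 1
  psi_pre <- c(-0.3, -0.6, -0.9, -1.2)
  wc_pre <- 60 + 20 * psi_pre                       # mol/kg
  mass_pre <- dry + wc_pre * 18.015 * dry / 1000
  sat <- mass_pre[1]
  d_last <- sat - mass_pre[4]
  y_last <- -1 / psi_pre[4]
  # continue with a line in (deficit, -1/psi) dropping clear of the last
  # pre point so no pre observation lies on it
  b <- -0.9
  d_post <- d_last + c(0.05, 0.1, 0.15, 0.2)
  y_post <- (y_last - 0.05) + b * (d_post - d_last)
  stopifnot(all(y_post > 0))
  cu <- pv_curve(c(mass_pre, sat - d_post),
                 c(psi_pre, -1 / y_post), dry_mass = dry)
  f <- fit_pv(cu, sat_mass = sat)
  expect_equal(f$tlp_index, 5L)
  expect_equal(f$c_t, 20, tolerance = 1e-9)
})

test_that("noiseless simulated curves are recovered near-exactly", {
  cu <- simulate_pv_curve(psi_sft = -1.5, swc_true = 1.5,
                          apoplastic_frac = 0.2, noise_sd = 0)
  tru <- attr(cu, "truth")
  f <- fit_pv(cu)
  expect_equal(f$psi_sft, tru$psi_sft, tolerance = 0.02)
  expect_lt(abs(f$psi_tlp - tru$psi_tlp), 0.1)
  expect_lte(f$psi_tlp, f$psi_sft)
})

test_that("turgor loss point never above osmotic potential at full turgor", {
  set.seed(31)
  for (i in 1:40) {
    cu <- simulate_pv_curve(psi_sft = runif(1, -3, -0.8),
                            swc_true = runif(1, 0.5, 4),
                            apoplastic_frac = runif(1, 0, 0.4),
                            noise_sd = 0.02)
    f <- fit_pv(cu)
    expect_lte(f$psi_tlp, f$psi_sft)
    expect_gt(f$c_t, 0)
  }
})

test_that("breakpoint equals exhaustive brute-force search", {
  set.seed(55)
  for (i in 1:30) {
    cu <- simulate_pv_curve(psi_sft = runif(1, -2.5, -1),
                            swc_true = runif(1, 1, 3),
                            apoplastic_frac = runif(1, 0, 0.3),
                            noise_sd = 0.02)
    f <- fit_pv(cu)
    sat <- max(cu$masses)
    k_oracle <- brute_force_breakpoint(sat - cu$masses, -1 / cu$psis)
    if (!f$no_turgor) expect_identical(f$tlp_index, k_oracle)
  }
})

test_that("capacitance basis follows the dry mass", {
  # same water dynamics, dry mass in g vs 'kg-like' rescaling of the basis:
  # C_T is per kg dry mass, so halving dry mass doubles C_T
  cu1 <- simulate_pv_curve(noise_sd = 0, dry_mass = 1)
  cu2 <- simulate_pv_curve(noise_sd = 0, dry_mass = 0.5)
  f1 <- fit_pv(cu1); f2 <- fit_pv(cu2)
  expect_equal(f1$psi_sft, f2$psi_sft, tolerance = 1e-9)
  expect_equal(f1$swc, f2$swc, tolerance = 1e-9)
  expect_equal(f1$c_t, f2$c_t, tolerance = 1e-9)
})

test_that("degenerate inputs fail loudly", {
  psis <- seq(-0.3, -2.5, length.out = 5)
  expect_error(pv_curve(seq(2, 1.5, length.out = 5), psis, 1), "at least 6")
  expect_error(pv_curve(seq(1.4, 2, length.out = 6),
                        seq(-0.3, -2.5, length.out = 6), 1),
               "non-increasing")
  expect_error(pv_curve(seq(2, 1.5, length.out = 6),
                        seq(0.3, -2, length.out = 6), 1), "< 0")
  # post-segment line extrapolating to a non-positive -1/psi intercept
  d <- seq(0.2, 0.9, length.out = 8)
  y <- -0.05 + 0.5 * d
  stopifnot(all(y > 0))
  cu <- pv_curve(2 - d, -1 / y, dry_mass = 1)
  expect_error(fit_pv(cu, sat_mass = 2), "fit failed")
})
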
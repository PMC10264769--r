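test_that("hydraulically weighted diameter is the fourth-power mean", {
  expect_equal(hydraulic_diameter(c(10, 10, 10)), 10)
  expect_equal(hydraulic_diameter(17.3), 17.3)
  # frozen from an independent evaluation of ((10^4 + 20^4)/2)^0.25
  expect_equal(hydraulic_diameter(c(10, 20)), 17.074764851741445,
               tolerance = 1e-6)
  # power-mean inequality: D_h >= arithmetic mean, any input
  set.seed(1)
  for (i in 1:25) {
    d <- runif(sample(2:40, 1), 2, 80)
    expect_gte(hydraulic_diameter(d), mean(d))
  }
  expect_error(vessel_section(numeric(), image_area = 1), "at least one")
  expect_error(hydraulic_diameter(c(10, -1)), "> 0")
})

test_that("vessel frequency divides count by image area", {
  vs <- vessel_section(rep(20, 50), image_area = 0.5)
  expect_equal(vessel_frequency(vs), 100)
  # 20x field of view
  expect_equal(vessel_frequency(vessel_section(rep(15, 13), image_area = 0.22)),
               13 / 0.22)
  expect_error(vessel_section(rep(10, 3), image_area = 0), "positive")
})

test_that("theoretical conductivity follows Hagen-Poiseuille scaling", {
  # frozen prefactor pi*rho/(128*eta) from independent evaluation
  k <- physical_constants()
  expect_equal(pi * k$rho / (128 * k$eta), 2.4450612734011127e10,
               tolerance = 1e-6)
  expect_equal(theoretical_conductivity(100, 20), 0.3912098037441782,
               tolerance = 1e-6)
  expect_equal(theoretical_conductivity(0, 20), 0)
  # quartic law and linearity in VF
  expect_equal(theoretical_conductivity(100, 40),
               16 * theoretical_conductivity(100, 20))
  expect_equal(theoretical_conductivity(200, 20),
               2 * theoretical_conductivity(100, 20))
  expect_error(theoretical_conductivity(100, -5), "> 0")
})

test_that("module K_th equals brute-force per-vessel summation", {
  set.seed(42)
  for (i in 1:10) {
    d <- runif(sample(5:60, 1), 5, 70)      # um
    area <- runif(1, 0.1, 4)                # mm^2
    vs <- vessel_section(d, image_area = area)
    k_mod <- theoretical_conductivity(vessel_frequency(vs),
                                      hydraulic_diameter(vs))
    # direct Hagen-Poiseuille sum over vessels: (pi rho / 128 eta) sum d^4 / A
    k_brute <- (pi * 998.2 / (128 * 1.002e-9)) *
      sum((d * 1e-6)^4) / (area * 1e-6)
    expect_equal(k_mod, k_brute, tolerance = 1e-9)
  }
})

test_that("pit summaries: ratios, pooled density, mode switch", {
  p <- pit_morphology(d_pml = c(4, 6), d_pms = c(4, 6),
                      d_pal = c(2, 3), d_pas = c(2, 3),
                      a_pit = c(12, 25), a_pa = c(3, 6),
                      pit_counts = data.frame(n_pits = c(10, 5),
                                              wall_area = c(200, 100)))
  s <- pit_summary(p)
  expect_equal(s$r_pa, 1)       # circular apertures
  expect_equal(s$r_pit, 1)
  expect_equal(s$d_p, 15 / 300) # pooled, not mean of per-wall densities
  one <- pit_morphology(4, 2, 4, 2, 10, 4)
  expect_equal(pit_summary(one)$r_pa, 2)
  expect_true(is.na(pit_summary(one)$d_p))
  # per-pit vs ratio-of-means modes differ when shapes vary
  p2 <- pit_morphology(d_pml = c(8, 3), d_pms = c(2, 3),
                       d_pal = c(4, 1.5), d_pas = c(1, 1.5),
                       a_pit = c(12, 7), a_pa = c(3, 1.7))
  expect_equal(pit_summary(p2)$r_pit, mean(c(4, 1)))
  expect_equal(pit_summary(p2, ratio_mode = "of_means")$r_pit, 11 / 5)
  expect_error(pit_morphology(4, 0, 4, 2, 10, 4), "> 0")
  expect_error(pit_morphology(4, 2, 4, 2, 3, 4), "exceed")
})

test_that("pit ratios are scale-invariant, areas scale quadratically", {
  p <- pit_morphology(d_pml = c(5, 7), d_pms = c(4, 5),
                      d_pal = c(3, 2), d_pas = c(1, 2),
                      a_pit = c(15, 27), a_pa = c(2, 3),
                      pit_counts = data.frame(n_pits = 8, wall_area = 160))
  f <- 2.5
  ps <- pit_morphology(d_pml = f * c(5, 7), d_pms = f * c(4, 5),
                       d_pal = f * c(3, 2), d_pas = f * c(1, 2),
                       a_pit = f^2 * c(15, 27), a_pa = f^2 * c(2, 3),
                       pit_counts = data.frame(n_pits = 8,
                                               wall_area = f^2 * 160))
  s <- pit_summary(p); ss <- pit_summary(ps)
  expect_equal(ss$r_pa, s$r_pa)
  expect_equal(ss$r_pit, s$r_pit)
  expect_equal(ss$a_pit, f^2 * s$a_pit)
  expect_equal(ss$d_p, s$d_p / f^2)
})

test_that("packing position is the wall coverage fraction", {
  expect_equal(packing_position(10, 0.1), 1.0)
  expect_equal(packing_position(13.29, 0.045), 0.59805, tolerance = 1e-6)
  expect_equal(packing_position(174.74, 0.004), 0.69896, tolerance = 1e-6)
  expect_error(packing_position(-1, 0.1), "positive")
})

test_that("stomatal counting keeps top/left border, drops bottom/right", {
  # 1 mm^2 field (1000 x 1000 um): 50 interior, 4 on top/left, 3 on
  # bottom/right borders
  set.seed(3)
  interior <- cbind(runif(50, 50, 950), runif(50, 50, 950))
  topleft <- rbind(c(0.5, 500), c(0.5, 700), c(300, 999.5), c(600, 999.5))
  botright <- rbind(c(999.5, 400), c(200, 0.5), c(999.5, 0.5))
  fld <- stomatal_field(rbind(interior, topleft, botright),
                        stomatal_areas = rep(450, 5),
                        field_width = 1000, field_height = 1000)
  st <- stomatal_traits(fld, border_tol = 1)
  expect_equal(st$d_s, 54)
  expect_equal(st$s_s, 450)
  # empty field
  e <- stomatal_traits(stomatal_field(matrix(numeric(), ncol = 2),
                                      field_width = 1000,
                                      field_height = 1000))
  expect_equal(e$d_s, 0)
  expect_true(is.na(e$s_s) && !e$s_s_defined)
  # away from all borders the rule is irrelevant
  fld2 <- stomatal_field(interior, field_width = 1000, field_height = 1000)
  expect_equal(stomatal_traits(fld2, border_tol = 5)$n, nrow(interior))
})

test_that("equivalent diameter preserves lumen area", {
  expect_equal(equivalent_diameter(9, 4), 6)
  d <- equivalent_diameter(20, 10)
  expect_equal(pi * (d / 2)^2, pi * 10 * 5)  # ellipse area pi*a*b
  expect_error(equivalent_diameter(4, 9), ">=")
})
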
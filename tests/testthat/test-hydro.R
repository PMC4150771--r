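test_that("water density and viscosity reproduce standard table values", {
  # CRC/Kell reference points: 4, 20, 25 degC
  expect_equal(water_density(277.15), 1.0000, tolerance = 1e-3)
  expect_equal(water_density(293.15), 0.99823, tolerance = 1e-3)
  expect_equal(water_density(298.15), 0.99705, tolerance = 1e-3)
  expect_equal(water_viscosity(277.15), 1.567, tolerance = 1e-3)
  expect_equal(water_viscosity(293.15), 1.002, tolerance = 1e-3)
  expect_equal(water_viscosity(298.15), 0.8905, tolerance = 1e-3)
  expect_error(water_properties(273.14), "range")
  expect_error(water_properties(373.16), "range")
})

test_that("s20,w conversion reproduces the unfolded-DNA table rows", {
  te <- te_4C()
  expect_equal(correct_s20w(0.79, te, 0.54), 1.24, tolerance = 0.01 / 1.24)
  expect_equal(correct_s20w(0.77, te, 0.54), 1.20, tolerance = 0.012 / 1.20)
  # identity when the experimental state is the reference state
  w20 <- water_20C()
  expect_equal(correct_s20w(1.7, w20, 0.54), 1.7, tolerance = 1e-12)
  # linear in s_exp
  f1 <- correct_s20w(1, te, 0.54)
  expect_equal(correct_s20w(c(0.5, 2, 7), te, 0.54), c(0.5, 2, 7) * f1)
  # correction factor matches the closed form eta ratio x buoyancy ratio
  fac <- (water_viscosity(277.15) / water_viscosity(293.15)) *
    (1 - 0.54 * water_density(293.15)) / (1 - 0.54 * water_density(277.15))
  expect_equal(f1, fac, tolerance = 0.005)
  # flotation guard
  buoyant <- solution_conditions(277.15, density = 1.3)
  expect_error(correct_s20w(1, buoyant, 0.8), "floats")
})

test_that("frictional ratios from sequence masses match the table", {
  expect_equal(frictional_ratio(6966.8, 0.54, 1.24), 1.98,
               tolerance = 0.03 / 1.98)
  expect_equal(frictional_ratio(6980.7, 0.54, 1.20), 2.05,
               tolerance = 0.03 / 2.05)
  # sphere: s chosen as the anhydrous-sphere value gives f/f0 = 1
  M <- 8000; vbar <- 0.6
  rho0 <- water_density(293.15); eta0 <- water_viscosity(293.15) / 100
  r0 <- (3 * M * vbar / (4 * pi * 6.02214076e23))^(1 / 3)
  s_sphere <- M * (1 - vbar * rho0) / (6.02214076e23 * 6 * pi * eta0 * r0) / 1e-13
  expect_equal(frictional_ratio(M, vbar, s_sphere), 1, tolerance = 1e-10)
  # faster than a sphere is non-physical: warn but return
  expect_warning(v <- frictional_ratio(M, vbar, 1.05 * s_sphere), "non-physical")
  expect_lt(v, 1)
  # for fixed M and vbar, f/f0 is proportional to 1/s
  s <- c(0.5, 1, 2, 4)
  ff <- suppressWarnings(frictional_ratio(7000, 0.54, s))
  expect_equal(ff * s, rep(ff[1] * s[1], 4), tolerance = 1e-12)
})

test_that("Perrin prolate factor matches its closed form and is monotone", {
  expect_identical(perrin_prolate_factor(1), 1)
  expect_equal(perrin_prolate_factor(2), 1.044, tolerance = 1e-3)
  expect_equal(perrin_prolate_factor(10), 1.543, tolerance = 1e-3)
  expect_error(perrin_prolate_factor(0.9), "prolate")
  p <- seq(1, 30, by = 0.25)
  expect_true(all(diff(perrin_prolate_factor(p)) > 0))
})

test_that("Perrin inversion reproduces the table axial ratios and round-trips", {
  r1 <- axial_ratio_from_ff0(1.98, vbar = 0.54, hydration = 0.59)
  r2 <- axial_ratio_from_ff0(2.05, vbar = 0.54, hydration = 0.59)
  expect_equal(r1$axial_ratio, 10.1, tolerance = 0.2 / 10.1)
  expect_equal(r2$axial_ratio, 11.1, tolerance = 0.2 / 11.1)
  # hydration-only f/f0 is the sphere limit, flagged not failed
  hf <- hydration_factor(0.54, 0.59)
  sph <- axial_ratio_from_ff0(hf, 0.54, 0.59)
  expect_identical(sph$axial_ratio, 1)
  expect_true(sph$at_sphere_limit)
  below <- axial_ratio_from_ff0(0.9 * hf, 0.54, 0.59)
  expect_true(below$at_sphere_limit)
  # round trip to 4 significant figures across the prolate range
  for (p in c(1.05, 2, 5, 10, 30)) {
    target <- perrin_prolate_factor(p) * hf
    back <- axial_ratio_from_ff0(target, 0.54, 0.59)$axial_ratio
    expect_equal(back, p, tolerance = 1e-4)
  }
})

test_that("hydro_summary chains conversion, friction and shape", {
  tab <- hydro_summary(6966.8, 0.54, 0.79, te_4C())
  expect_equal(tab$s20w, 1.24, tolerance = 0.01)
  expect_equal(tab$axial_ratio, 10.1, tolerance = 0.35)
})

test_that("solution_conditions validates its inputs", {
  expect_error(solution_conditions(250), "range")
  expect_error(solution_conditions(300, density = -1), "positive")
  w <- solution_conditions(277.15)
  expect_equal(w$density, water_density(277.15))
})
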
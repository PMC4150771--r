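test_that("multiphase model has its boundary values and a checked point", {
  expect_identical(multiphase_model(0, c(0.4, 0.2), c(1e-3, 1e-5)), 0)
  expect_equal(multiphase_model(1e9, c(0.4, 0.2), c(1e-3, 1e-5)), 0.6,
               tolerance = 1e-6)
  # independently computed: 0.45(1-e^-1.8) + 0.18(1-e^-0.06)
  expect_equal(multiphase_model(600, c(0.45, 0.18), c(3e-3, 1e-4)),
               0.3861, tolerance = 1e-4 / 0.3861)
})

test_that("noiseless biphasic data are recovered exactly", {
  tr <- repair_truth("G1-KCl", seed = 1, noise_sd = 0)
  fit <- fit_repair(gen_repair_course(tr), 2)
  expect_equal(fit$amplitudes, tr$amplitudes, tolerance = 1e-6)
  expect_equal(fit$rates, tr$rates, tolerance = 1e-6)
  expect_identical(fit$n_phases, 2L)
  # prediction is non-decreasing and bounded by the summed amplitudes
  tt <- seq(0, 5e4, length.out = 200)
  f <- multiphase_model(tt, fit$amplitudes, fit$rates)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f <= sum(fit$amplitudes) + 1e-12))
})

test_that("phase ordering is enforced and near-ties are merged", {
  tr <- repair_truth("G1-KCl", seed = 1, noise_sd = 0)
  fit <- fit_repair(gen_repair_course(tr), 2)
  expect_true(all(diff(fit$rates) < 0))
  # force a tie: single-exponential truth fit with two phases often lands
  # both rates together; merged result collapses to one phase
  tc1 <- gen_repair_course(repair_truth("G1-TEA", seed = 2, noise_sd = 0))
  f2 <- fit_repair(tc1, 2, start = list(A = c(0.5, 0.45), k = c(1.6e-3, 1.6e-3)))
  expect_lte(f2$n_phases, 2L)
  if (f2$n_phases == 1L)
    expect_equal(f2$amplitudes, 0.95, tolerance = 1e-4)
})

test_that("a spurious second phase is statistically rejected", {
  hits <- vapply(1:20, function(s) {
    tc <- gen_repair_course(repair_truth("G1-TEA", seed = s))
    f2 <- fit_repair(tc, 2)
    # either merged away or amplitude within 2 SE of zero
    f2$n_phases == 1L ||
      min(f2$amplitudes) <= 2 * f2$se_amplitudes[which.min(f2$amplitudes)]
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("phase-count selection finds the generating model", {
  # noiseless: exactly two
  sel0 <- select_phase_count(gen_repair_course(
    repair_truth("G1-KCl", seed = 1, noise_sd = 0)))
  expect_identical(sel0$n_phases, 2L)
  expect_true(is.data.frame(sel0$selection))
  # noisy two-phase truth: selects 2 in most replicates
  np <- vapply(1:30, function(s)
    select_phase_count(gen_repair_course(
      repair_truth("G1-KCl", seed = s)))$n_phases, integer(1))
  expect_gte(sum(np == 2), 27)
  # one-phase truth: selects 1
  np1 <- vapply(1:30, function(s)
    select_phase_count(gen_repair_course(
      repair_truth("G1-TEA", seed = s)))$n_phases, integer(1))
  expect_gte(sum(np1 == 1), 27)
})

test_that("rate recovery degrades monotonically with noise", {
  rmse_k1 <- vapply(c(0.01, 0.02, 0.05), function(sig) {
    k1 <- vapply(1:40, function(s) {
      tc <- gen_repair_course(repair_truth("G1-KCl", seed = s,
                                           noise_sd = sig))
      fit_repair(tc, 2)$rates[1]
    }, numeric(1))
    sqrt(mean((k1 - 1.5e-3)^2))
  }, numeric(1))
  expect_true(all(diff(rmse_k1) > 0))
})

test_that("rate scaling converts to moles per second", {
  r <- scale_rate(1e-3, 0.25e-6, 4e-4)
  expect_equal(r$value, 1.0e-13)
  expect_identical(r$units, "mol/s")
  expect_equal(scale_rate(1e-3, 0.25e-6, 8e-4)$value, 2e-13)   # linear in V
  expect_equal(scale_rate(0, 0.25e-6, 4e-4)$value, 0)
  novol <- scale_rate(1e-3, 0.25e-6)
  expect_identical(novol$units, "mol/L/s")
  expect_equal(novol$value, 2.5e-10)
})

test_that("tetrad classification matches the quadruplex geometry", {
  tel <- get_fixture("22wt")$sequence
  # outer-tetrad set: first/last G of a tract
  for (pos in c(2, 4, 8, 10))
    expect_identical(classify_tetrad(tel, pos)$tetrad_class, "outer")
  # inner-tetrad set: middle G of a tract
  for (pos in c(3, 9, 21))
    expect_identical(classify_tetrad(tel, pos)$tetrad_class, "inner")
  g5 <- classify_tetrad(tel, 9)
  expect_identical(g5$tract_index, 2L)
  expect_identical(g5$within_tract, "middle")
  expect_error(classify_tetrad(tel, 1), "not a guanine")      # adenine
  expect_error(classify_tetrad("AGGGTTAGGG", 2), "four G-tracts")
})

test_that("the fixture panel maps labels to the published tetrad classes", {
  outer <- c("G1", "G3", "G4", "G6")
  inner <- c("G2", "G5", "G11")
  for (nm in outer) {
    fx <- get_fixture(nm)
    expect_identical(classify_tetrad(fx$sequence, fx$methyl_position)$tetrad_class,
                     "outer")
  }
  for (nm in inner) {
    fx <- get_fixture(nm)
    expect_identical(classify_tetrad(fx$sequence, fx$methyl_position)$tetrad_class,
                     "inner")
  }
})
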
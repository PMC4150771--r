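test_that("reduced molecular weight follows its defining formula", {
  # own closed-form oracle: M (1 - vbar rho) omega^2 / (2 R T), CGS
  omega <- 2 * pi * 25000 / 60
  expect_equal(reduced_molecular_weight(21519, 0.744, 1.000, 25000, 277.15),
               21519 * (1 - 0.744) * omega^2 / (2 * 8.314462618e7 * 277.15),
               tolerance = 1e-12)
  expect_equal(reduced_molecular_weight(21519, 0.744, 1.000, 25000, 277.15),
               0.8193, tolerance = 1e-3)
  expect_identical(reduced_molecular_weight(21519, 0.744, 1, 0, 277.15), 0)
  expect_equal(reduced_molecular_weight(21519, 0.8, 1.25, 20000, 277.15), 0)
})

test_that("complex vbar is the mass-weighted average", {
  expect_equal(complex_vbar(0, 21519, 0.744, 6966.8, 0.54), 0.54)
  expect_equal(complex_vbar(3, 21519, 0.7, 6966.8, 0.7), 0.7)
  expect_equal(complex_vbar(2, 21519, 0.744, 6966.8, 0.54), 0.7156,
               tolerance = 5e-4 / 0.7156)
})

test_that("two-species profile has the expected limits and guards", {
  r <- seq(6.95, 7.15, length.out = 51)   # grid contains r0 exactly
  base <- list(alpha_P = 0.3, alpha_PnD = 0, zeta = 0, r0 = 7.05,
               sigma_P = 1.5, sigma_PnD = 3)
  a <- eq2_profile(r, base)
  expect_equal(eq2_profile(7.05, base), 0.3)
  expect_true(all(diff(a) > 0))
  flat <- modifyList(base, list(alpha_P = 0, zeta = 0.12))
  expect_equal(eq2_profile(r, flat), rep(0.12, 51))
  blow <- modifyList(base, list(sigma_P = 1e4))
  expect_error(eq2_profile(r, blow), "clip")
})

test_that("generated scans conserve the loading signal over the column", {
  tr <- eq_truth("KCl", seed = 1, noise_sd = 0)
  scans <- gen_equilibrium_scans(tr)
  # sector-weighted mean signal must equal the loading for every speed
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    dil <- if (grepl("dil1", sc$channel_id)) 1 else 0.5
    load <- (tr$A_protein + tr$A_complex) * dil
    mean_sig <- 2 * pracma::trapz(sc$radius, sc$absorbance * sc$radius) /
      (max(sc$radius)^2 - min(sc$radius)^2)
    expect_equal(mean_sig, load, tolerance = 1e-3)   # trapezoid-rule error
  }
})

test_that("global fit recovers stoichiometry exactly without noise", {
  for (scen in c("KCl", "K-free")) {
    tr <- eq_truth(scen, seed = 1, noise_sd = 0)
    fit <- fit_global_stoichiometry(gen_equilibrium_scans(tr), agt_spec(),
                                    g5x_spec(), water_properties(277.15))
    expect_equal(fit$n, tr$n, tolerance = 1e-4 / tr$n)
    # published fit criterion: small, randomly distributed residuals
    for (i in seq_len(nrow(fit$per_scan))) {
      sc <- gen_equilibrium_scans(tr)[[i]]
      res <- sc$absorbance - eq_fit_curve(fit, i, sc$radius)
      expect_lt(max(abs(res)), 1e-6)
    }
  }
})

test_that("noisy-scan residuals of a correct fit pass a runs test", {
  tr <- eq_truth("KCl", seed = 42)
  scans <- gen_equilibrium_scans(tr)
  fit <- fit_global_stoichiometry(scans, agt_spec(), g5x_spec(),
                                  water_properties(277.15))
  # trim margins like the fitter does, then test the sign sequence
  sc <- scans[[1]]
  keep <- sc$radius >= min(sc$radius) + 0.005 &
    sc$radius <= max(sc$radius) - 0.005
  res <- sc$absorbance[keep] - eq_fit_curve(fit, 1, sc$radius[keep])
  expect_gt(runs_test(res)$p_value, 0.01)
})

test_that("stoichiometry recovery from noisy replicates stays in band", {
  ns <- vapply(1:20, function(s) recover_n("KCl", s), numeric(1))
  expect_true(all(abs(ns - 2) < 0.1))
  ns4 <- vapply(101:115, function(s) recover_n("K-free", s), numeric(1))
  expect_true(all(abs(ns4 - 4) < 0.2))
})

test_that("sharing n across scans can only raise the total RSS", {
  tr <- eq_truth("KCl", seed = 9)
  scans <- gen_equilibrium_scans(tr)
  P <- agt_spec(); D <- g5x_spec(); W <- water_properties(277.15)
  glob <- fit_global_stoichiometry(scans, P, D, W)
  indep <- sum(vapply(scans, function(sc)
    fit_global_stoichiometry(list(sc), P, D, W)$rss, numeric(1)))
  expect_gte(glob$rss, indep - 1e-10)
  # the gap is small when one true n generated all scans
  expect_lt((glob$rss - indep) / glob$rss, 0.2)
})

test_that("higher rotor speed steepens the equilibrium profile", {
  r <- seq(6.95, 7.15, length.out = 80)
  curv_at_base <- function(rpm) {
    sg <- reduced_molecular_weight(50000, 0.71, 1.0, rpm, 277.15)
    a <- eq2_profile(r, list(alpha_P = 0, alpha_PnD = 0.1, zeta = 0,
                             r0 = 7.05, sigma_P = 0, sigma_PnD = sg))
    d2 <- diff(diff(a))
    d2[length(d2)]
  }
  cs <- vapply(c(15000, 20000, 25000, 30000), curv_at_base, numeric(1))
  expect_true(all(diff(cs) > 0))
})

test_that("equilibrium attainment check compares scan pairs", {
  tr <- eq_truth("KCl", seed = 3, noise_sd = 0.002)
  a <- gen_equilibrium_scans(tr)[[1]]
  tr2 <- eq_truth("KCl", seed = 4, noise_sd = 0.002)
  b <- gen_equilibrium_scans(tr2)[[1]]
  chk <- equilibrium_attained(a, b)
  expect_true(chk$at_equilibrium)       # same underlying profile
  shifted <- scan_table(b$radius, b$absorbance + 0.05, b$rotor_speed)
  expect_false(equilibrium_attained(a, shifted)$at_equilibrium)
})
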
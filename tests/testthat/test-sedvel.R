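test_that("no transport occurs without a field or sedimentation", {
  g <- cell_geometry()
  sims <- lamm_solve(0, 1e-12, g, 40000, times = c(600, 1200), c0 = 0.4,
                     n_r = 200)
  for (sc in sims)
    expect_lt(max(abs(sc$absorbance - 0.4)), 1e-6)
})

test_that("sector-weighted mass is conserved through a full run", {
  W <- water_properties(277.15)
  D <- diffusion_from_s(2.0, 1.36, 0.54, W)
  sims <- lamm_solve(2.0, D, cell_geometry(), 40000,
                     times = seq(3600, 36000, by = 3600), c0 = 0.5)
  m <- vapply(sims, sector_mass, numeric(1))
  expect_lt(max(abs(m / m[1] - 1)), 1e-3)
})

test_that("boundary midpoint follows the analytic sedimentation law", {
  W <- water_properties(277.15)
  D <- diffusion_from_s(2.0, 1.36, 0.54, W)
  times <- seq(3600, 18000, by = 3600)    # before back-diffusion dominates
  sims <- lamm_solve(2.0, D, cell_geometry(), 40000, times, c0 = 0.5)
  omega2 <- (2 * pi * 40000 / 60)^2
  for (j in seq_along(times)) {
    sc <- sims[[j]]
    # midpoint of the moving boundary: where c crosses half the plateau
    plateau <- stats::quantile(sc$absorbance, 0.6)
    rb_obs <- sc$radius[which.min(abs(sc$absorbance - plateau / 2))]
    rb_pred <- 5.9 * exp(2e-13 * omega2 * times[j])
    expect_equal(rb_obs, rb_pred, tolerance = 0.01)
  }
})

test_that("halving the radial step changes profiles by well under 0.2% RMS", {
  W <- water_properties(277.15)
  D <- diffusion_from_s(2.0, 1.36, 0.54, W)
  t_out <- c(7200, 14400)
  # default resolution against a grid with the radial step halved
  coarse <- lamm_solve(2.0, D, cell_geometry(), 40000, t_out, c0 = 0.5,
                       n_r = 400)
  fine <- lamm_solve(2.0, D, cell_geometry(), 40000, t_out, c0 = 0.5,
                     n_r = 799)
  for (j in seq_along(t_out)) {
    yc <- coarse[[j]]$absorbance
    yf <- approx(fine[[j]]$radius, fine[[j]]$absorbance,
                 coarse[[j]]$radius)$y
    rms <- sqrt(mean((yc - yf)^2)) / 0.5
    expect_lt(rms, 0.002)
  }
})

test_that("the D(s) scaling law has the Stokes-Einstein sphere limit", {
  W <- water_20C()
  s <- 1.8
  M <- mass_from_s(s, 1, 0.6, W)
  r0 <- (3 * M * 0.6 / (4 * pi * 6.02214076e23))^(1 / 3)
  D_stokes <- 1.380649e-16 * W$temperature /
    (6 * pi * (W$viscosity / 100) * r0)
  expect_equal(diffusion_from_s(s, 1, 0.6, W), D_stokes, tolerance = 1e-10)
  # and the implied mass closes the Svedberg relation s = M(1-vbar rho)D/(RT)
  expect_equal(s * 1e-13,
               M * (1 - 0.6 * W$density) * D_stokes /
                 (8.314462618e7 * W$temperature),
               tolerance = 1e-10)
})

test_that("s to mass mapping is strictly increasing", {
  W <- water_properties(277.15)
  M <- mass_from_s(seq(0.5, 5, by = 0.25), 1.36, 0.54, W)
  expect_true(all(diff(M) > 0))
})

test_that("c(S) inversion recovers a single species", {
  W <- water_properties(277.15)
  tr <- vel_truth(seed = 2)
  scans <- gen_velocity_scans(tr)
  dist <- cs_invert(scans, s_grid = seq(0.6, 4, by = 0.1), f_over_f0 = 1.36,
                    vbar = 0.54, buffer = W, n_r = 300)
  mode_s <- dist$s_grid[which.max(dist$c)]
  expect_lte(abs(mode_s - 2.0), 0.1 + 1e-9)      # within one grid step
  expect_equal(weight_average_s(dist), 2.0, tolerance = 0.02)
  expect_equal(dist$total_signal, tr$c0, tolerance = 0.05)
  # c(M): mean mass within 10% of the generating species' mass
  cm <- cs_to_cm(dist, 0.54, W)
  expect_equal(cm$M_mean, mass_from_s(2.0, 1.36, 0.54, W), tolerance = 0.1)
})

test_that("c(S) inversion separates two species with equal signal", {
  W <- water_properties(277.15)
  g <- cell_geometry()
  times <- seq(3600, 36000, by = 3600)
  a <- lamm_solve(1.4, diffusion_from_s(1.4, 1.36, 0.54, W), g, 40000,
                  times, c0 = 0.25, n_r = 300)
  b <- lamm_solve(2.8, diffusion_from_s(2.8, 1.36, 0.54, W), g, 40000,
                  times, c0 = 0.25, n_r = 300)
  set.seed(7)
  scans <- lapply(seq_along(times), function(j) {
    scan_table(a[[j]]$radius,
               a[[j]]$absorbance + b[[j]]$absorbance +
                 rnorm(300, 0, 0.005),
               40000, 277.15, time = times[j])
  })
  sgrid <- seq(0.6, 4, by = 0.1)
  dist <- cs_invert(scans, sgrid, 1.36, 0.54, W, n_r = 300)
  # integrated weight on each side of the midpoint between the species
  cut <- 2.1
  w_lo <- pracma::trapz(sgrid[sgrid <= cut], dist$c[sgrid <= cut])
  w_hi <- pracma::trapz(sgrid[sgrid > cut], dist$c[sgrid > cut])
  expect_equal(w_lo / (w_lo + w_hi), 0.5, tolerance = 0.1)
  # a mode near each generating s
  lo_mode <- sgrid[sgrid <= cut][which.max(dist$c[sgrid <= cut])]
  hi_mode <- sgrid[sgrid > cut][which.max(dist$c[sgrid > cut])]
  expect_lte(abs(lo_mode - 1.4), 0.2 + 1e-9)
  expect_lte(abs(hi_mode - 2.8), 0.2 + 1e-9)
})

test_that("heavier regularization flattens the distribution monotonically", {
  W <- water_properties(277.15)
  tr <- vel_truth(seed = 5)
  scans <- gen_velocity_scans(tr)
  sgrid <- seq(1, 3, by = 0.2)
  flat <- vapply(c(1e-4, 1e-2, 1, 100), function(w) {
    d <- cs_invert(scans, sgrid, 1.36, 0.54, W, reg_weight = w, n_r = 200)
    max(d$c) / max(min(d$c), 1e-12)
  }, numeric(1))
  expect_true(all(diff(flat) <= 1e-6))
})

test_that("weight-average s behaves on constructed distributions", {
  delta <- structure(list(s_grid = seq(1, 3, 0.1),
                          c = ifelse(seq(1, 3, 0.1) == 2, 1, 0)),
                     class = "s_distribution")
  expect_equal(weight_average_s(delta), 2.0)
  bim <- structure(list(s_grid = seq(0.5, 3.5, 0.1),
                        c = dnorm(seq(0.5, 3.5, 0.1), 1, 0.1) +
                          dnorm(seq(0.5, 3.5, 0.1), 3, 0.1)),
                   class = "s_distribution")
  expect_equal(weight_average_s(bim), 2.0, tolerance = 1e-6)
  empty <- structure(list(s_grid = 1:5, c = rep(0, 5)),
                     class = "s_distribution")
  expect_error(weight_average_s(empty), "undefined|empty")
})
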
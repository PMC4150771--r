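#' Radial absorbance scan
#'
#' One sedimentation scan: absorbance versus radius at a given rotor speed
#' and temperature. Used both for equilibrium profiles and for velocity
#' boundary scans (where `time` records the elapsed run time).
#'
#' @param radius Radial positions (cm), strictly increasing, length >= 20.
#' @param absorbance Absorbance (AU), same length as `radius`.
#' @param rotor_speed Rotor speed (rpm), > 0.
#' @param temperature Absolute temperature (K).
#' @param channel_id Free-text channel identifier.
#' @param time Optional elapsed time (s) for velocity scans.
#' @return An object of class `scan_table`.
#' @export
scan_table <- function(radius, absorbance, rotor_speed, temperature = 277.15,
                       channel_id = "A", time = NA_real_) {
  stopifnot(length(radius) == length(absorbance), length(radius) >= 20,
            all(diff(radius) > 0), rotor_speed > 0, temperature > 0)
  structure(list(radius = as.numeric(radius),
                 absorbance = as.numeric(absorbance),
                 rotor_speed = rotor_speed, temperature = temperature,
                 channel_id = channel_id, time = time),
            class = "scan_table")
}

#' @export
print.scan_table <- function(x, ...) {
  cat(sprintf("<scan_table> %s: %d points, r in [%.3f, %.3f] cm, %g rpm, %.2f K%s\n",
              x$channel_id, length(x$radius), min(x$radius), max(x$radius),
              x$rotor_speed, x$temperature,
              if (is.finite(x$time)) sprintf(", t = %g s", x$time) else ""))
  invisible(x)
}

#' Species specification for equilibrium modelling
#'
#' @param molar_mass Molar mass (g/mol).
#' @param vbar Partial specific volume (ml/g).
#' @param extinction Optional signal scale factor; never used in fitting
#'   (amplitudes are free parameters), carried for bookkeeping only.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(molar_mass, vbar, extinction = NA_real_) {
  stopifnot(molar_mass > 0, vbar >= 0.4, vbar <= 1.0)
  structure(list(molar_mass = molar_mass, vbar = vbar, extinction = extinction),
            class = "species_spec")
}

#' Reduced molecular weight sigma
#'
#' sigma = M (1 - vbar * rho) omega^2 / (2 R T) with omega = 2 pi rpm / 60,
#' evaluated in CGS units (R = 8.3145e7 erg/mol/K) so that
#' exp[sigma (r^2 - r0^2)] is dimensionless for r in cm. sigma is the
#' exponential curvature parameter of an equilibrium radial profile.
#'
#' @param molar_mass Molar mass (g/mol).
#' @param vbar Partial specific volume (ml/g).
#' @param density Solvent density (g/ml).
#' @param rotor_speed Rotor speed (rpm); 0 gives sigma = 0 (no field).
#' @param temperature Absolute temperature (K).
#' @return sigma in 1/cm^2.
#' @examples
#' reduced_molecular_weight(21519, 0.744, 1.000, 25000, 277.15)  # ~0.819
#' @export
reduced_molecular_weight <- function(molar_mass, vbar, density, rotor_speed,
                                     temperature) {
  stopifnot(molar_mass > 0, vbar > 0, density > 0, rotor_speed >= 0,
            temperature > 0)
  omega <- 2 * pi * rotor_speed / 60
  molar_mass * (1 - vbar * density) * omega^2 / (2 * .const$R_cgs * temperature)
}

#' Partial specific volume of an n:1 protein-DNA complex
#'
#' Mass-weighted average of the component vbars:
#' (n M_P vbar_P + M_D vbar_D) / (n M_P + M_D).
#'
#' @param n Number of protein molecules bound per DNA (>= 0; may be
#'   non-integer during fitting).
#' @param M_P,vbar_P Protein molar mass (g/mol) and vbar (ml/g).
#' @param M_D,vbar_D DNA molar mass (g/mol) and vbar (ml/g).
#' @return vbar of the complex (ml/g).
#' @examples
#' complex_vbar(2, 21519, 0.744, 6966.8, 0.54)  # ~0.7156
#' @export
complex_vbar <- function(n, M_P, vbar_P, M_D, vbar_D) {
  stopifnot(n >= 0, M_P > 0, M_D > 0)
  (n * M_P * vbar_P + M_D * vbar_D) / (n * M_P + M_D)
}

# Exponent clip bound for eq2_profile: exp(700) is near double overflow
.EQ2_EXP_CLIP <- 500

#' Two-species equilibrium absorbance profile
#'
#' A(r) = alpha_P exp[sigma_P (r^2 - r0^2)]
#'      + alpha_PnD exp[sigma_PnD (r^2 - r0^2)] + zeta.
#' The two exponentials are the free protein and the saturated protein-DNA
#' complex; zeta is a radially constant baseline.
#'
#' @param radius Radial positions (cm).
#' @param pars List with `alpha_P`, `alpha_PnD`, `zeta`, `r0`, `sigma_P`,
#'   `sigma_PnD` (see [reduced_molecular_weight()]).
#' @return Absorbance (AU) at each radius.
#' @export
eq2_profile <- function(radius, pars) {
  need <- c("alpha_P", "alpha_PnD", "zeta", "r0", "sigma_P", "sigma_PnD")
  stopifnot(all(need %in% names(pars)))
  x <- radius^2 - pars$r0^2
  e1 <- pars$sigma_P * x
  e2 <- pars$sigma_PnD * x
  if (max(abs(e1), abs(e2)) > .EQ2_EXP_CLIP)
    stop("exponent exceeds clip bound: parameters outside model range")
  pars$alpha_P * exp(e1) + pars$alpha_PnD * exp(e2) + pars$zeta
}

# Per-scan linear solve at fixed n: A(r) = aP e1 + aPnD e2 + zeta.
# Returns coefficients and RSS. Amplitudes are clamped at zero via a
# reduced solve if the unconstrained optimum is negative.
.eq_linear_fit <- function(scan, sigma_P, sigma_PnD, r0) {
  x <- scan$radius^2 - r0^2
  X <- cbind(exp(sigma_P * x), exp(sigma_PnD * x), 1)
  y <- scan$absorbance
  b <- tryCatch(qr.solve(X, y), error = function(e) rep(NA_real_, 3))
  if (anyNA(b)) return(list(coef = c(0, 0, mean(y)), rss = sum((y - mean(y))^2)))
  if (b[1] < 0 || b[2] < 0) {
    # enforce non-negative amplitudes: try each amplitude dropped
    best <- NULL
    for (drop in 1:2) {
      keep <- setdiff(1:2, drop)
      Xr <- X[, c(keep, 3), drop = FALSE]
      br <- qr.solve(Xr, y)
      if (br[1] >= 0) {
        bb <- numeric(3); bb[keep] <- br[1]; bb[3] <- br[2]
        r <- sum((y - Xr %*% br)^2)
        if (is.null(best) || r < best$rss) best <- list(coef = bb, rss = r)
      }
    }
    if (!is.null(best)) return(best)
    return(list(coef = c(0, 0, mean(y)), rss = sum((y - mean(y))^2)))
  }
  list(coef = b, rss = sum((y - X %*% b)^2))
}

# Global RSS profiled over the per-scan linear parameters at fixed n
.eq_profile_rss <- function(n, scans, protein, dna, buffer, r0s) {
  vC <- complex_vbar(n, protein$molar_mass, protein$vbar,
                     dna$molar_mass, dna$vbar)
  MC <- n * protein$molar_mass + dna$molar_mass
  tot <- 0
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    sP <- reduced_molecular_weight(protein$molar_mass, protein$vbar,
                                   buffer$density, sc$rotor_speed,
                                   sc$temperature)
    sC <- reduced_molecular_weight(MC, vC, buffer$density, sc$rotor_speed,
                                   sc$temperature)
    tot <- tot + .eq_linear_fit(sc, sP, sC, r0s[i])$rss
  }
  tot
}

#' Global sedimentation-equilibrium stoichiometry fit
#'
#' Fits the two-species model (free protein P + saturated complex PnD,
#' see [eq2_profile()]) simultaneously to multiple scans (rotor speeds and
#' loading dilutions), with per-scan amplitudes and baseline but a single
#' shared stoichiometry n. n determines the complex mass n*M_P + M_D and,
#' through [complex_vbar()], its buoyancy, hence the curvature of the
#' second exponential in every scan.
#'
#' The fit uses variable projection: at fixed n the model is linear in the
#' per-scan parameters, which are solved exactly (with amplitudes clamped
#' non-negative); the profiled RSS(n) is scanned on a grid over (0, 12] and
#' the best bracket refined with Brent's method, which handles a multimodal
#' n-surface without depending on a starting guess. The standard error of n
#' comes from the curvature of the profiled RSS at the optimum.
#'
#' @param scans List of [scan_table] objects (>= 2 recommended: several
#'   speeds and/or dilutions).
#' @param protein,dna [species_spec] objects (protein: M = 21519 g/mol for
#'   AGT, vbar = 0.744 ml/g; DNA per its sequence mass, vbar = 0.54 ml/g
#'   for quadruplex DNA).
#' @param buffer A [solution_conditions] object.
#' @param n_init Optional starting guess; included in the search grid.
#' @param trim Radial margin (cm) excluded at each scan's extremes
#'   (meniscus/base artefacts); default 0.005.
#' @param n_max Upper bound of the stoichiometry search (default 12).
#' @return An object of class `eq_fit`: `n`, `se_n`, `rss`, `per_scan`
#'   (data.frame of per-scan alpha_P, alpha_PnD, zeta, r0, sigma_P,
#'   sigma_PnD), `vbar_complex`, `mass_complex`, and the inputs needed to
#'   reproduce model curves.
#' @export
fit_global_stoichiometry <- function(scans, protein, dna, buffer,
                                     n_init = NULL, trim = 0.005, n_max = 12) {
  stopifnot(length(scans) >= 1, inherits(protein, "species_spec"),
            inherits(dna, "species_spec"),
            inherits(buffer, "solution_conditions"))
  scans <- lapply(scans, function(sc) {
    keep <- sc$radius >= min(sc$radius) + trim & sc$radius <= max(sc$radius) - trim
    if (sum(keep) < 20) stop("fewer than 20 points after trimming scan window")
    sc$radius <- sc$radius[keep]; sc$absorbance <- sc$absorbance[keep]
    sc
  })
  r0s <- vapply(scans, function(sc) mean(range(sc$radius)), numeric(1))

  grid <- sort(unique(c(seq(0.25, n_max, by = 0.25), n_init)))
  rssg <- vapply(grid, .eq_profile_rss, numeric(1),
                 scans = scans, protein = protein, dna = dna,
                 buffer = buffer, r0s = r0s)
  i <- which.min(rssg)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(.eq_profile_rss, c(lo, hi), scans = scans, protein = protein,
                  dna = dna, buffer = buffer, r0s = r0s, tol = 1e-8)
  n_hat <- opt$minimum; rss <- opt$objective

  # per-scan linear parameters at the optimum
  vC <- complex_vbar(n_hat, protein$molar_mass, protein$vbar,
                     dna$molar_mass, dna$vbar)
  MC <- n_hat * protein$molar_mass + dna$molar_mass
  per <- lapply(seq_along(scans), function(i) {
    sc <- scans[[i]]
    sP <- reduced_molecular_weight(protein$molar_mass, protein$vbar,
                                   buffer$density, sc$rotor_speed, sc$temperature)
    sC <- reduced_molecular_weight(MC, vC, buffer$density, sc$rotor_speed,
                                   sc$temperature)
    co <- .eq_linear_fit(sc, sP, sC, r0s[i])$coef
    data.frame(channel_id = sc$channel_id, rotor_speed = sc$rotor_speed,
               alpha_P = co[1], alpha_PnD = co[2], zeta = co[3],
               r0 = r0s[i], sigma_P = sP, sigma_PnD = sC)
  })
  per <- do.call(rbind, per)

  npt <- sum(vapply(scans, function(s) length(s$radius), integer(1)))
  npar <- 3L * length(scans) + 1L
  dof <- npt - npar
  s2 <- rss / max(dof, 1)
  # curvature of profiled RSS: var(n) = 2 s^2 / d2RSS/dn2
  h <- max(1e-3, 1e-3 * n_hat)
  d2 <- (.eq_profile_rss(n_hat + h, scans, protein, dna, buffer, r0s) -
           2 * rss +
           .eq_profile_rss(max(n_hat - h, 1e-6), scans, protein, dna, buffer, r0s)) / h^2
  se_n <- if (is.finite(d2) && d2 > 0) sqrt(2 * s2 / d2) else NA_real_

  structure(list(n = n_hat, se_n = se_n, rss = rss, dof = dof,
                 per_scan = per, vbar_complex = vC, mass_complex = MC,
                 protein = protein, dna = dna, buffer = buffer),
            class = "eq_fit")
}

#' @export
print.eq_fit <- function(x, ...) {
  cat(sprintf("<eq_fit> stoichiometry n = %.3f +/- %.3f (RSS %.4g, %d scans)\n",
              x$n, x$se_n, x$rss, nrow(x$per_scan)))
  invisible(x)
}

#' Model curve for one fitted scan
#'
#' @param fit An `eq_fit` from [fit_global_stoichiometry()].
#' @param scan_index Row of `fit$per_scan` to evaluate.
#' @param radius Radii (cm) at which to evaluate the model.
#' @return Absorbance (AU).
#' @export
eq_fit_curve <- function(fit, scan_index, radius) {
  p <- fit$per_scan[scan_index, ]
  eq2_profile(radius, list(alpha_P = p$alpha_P, alpha_PnD = p$alpha_PnD,
                           zeta = p$zeta, r0 = p$r0, sigma_P = p$sigma_P,
                           sigma_PnD = p$sigma_PnD))
}

#' Wald-Wolfowitz runs test on fit residuals
#'
#' The published criterion for an acceptable equilibrium fit is small,
#' randomly distributed residuals; this tests the sign sequence of the
#' residuals for non-randomness.
#'
#' @param residuals Numeric residual vector.
#' @return List with `n_runs`, `expected`, `z`, `p_value` (two-sided,
#'   normal approximation).
#' @export
runs_test <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0)
    return(list(n_runs = 1, expected = NA_real_, z = NA_real_, p_value = 0))
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v  <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  z <- (runs - mu) / sqrt(v)
  list(n_runs = runs, expected = mu, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Check attainment of sedimentation equilibrium
#'
#' Equilibrium is accepted when successive scans (nominally 6 h apart)
#' superimpose; this compares two scans by RMS difference on the common
#' radial grid.
#'
#' @param scan_a,scan_b Two [scan_table] objects at the same speed.
#' @param threshold RMS difference (AU) below which the pair counts as
#'   superimposed (default 0.01).
#' @return List with `rms` and logical `at_equilibrium`.
#' @export
equilibrium_attained <- function(scan_a, scan_b, threshold = 0.01) {
  lo <- max(min(scan_a$radius), min(scan_b$radius))
  hi <- min(max(scan_a$radius), max(scan_b$radius))
  if (hi <= lo) stop("scans do not overlap radially")
  r <- seq(lo, hi, length.out = 200)
  a <- approx(scan_a$radius, scan_a$absorbance, r)$y
  b <- approx(scan_b$radius, scan_b$absorbance, r)$y
  rms <- sqrt(mean((a - b)^2))
  list(rms = rms, at_equilibrium = rms < threshold)
}
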
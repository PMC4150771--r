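#' Solution (buffer) physical conditions
#'
#' Container for the temperature, density and viscosity of an experimental
#' buffer. These set the buoyancy term (1 - vbar * rho) and the viscous drag
#' used when standardizing sedimentation coefficients to 20 degC water.
#' Omitted density/viscosity default to pure water at the given temperature,
#' which is the appropriate treatment for dilute buffers such as TE
#' (10 mM Tris, 1 mM EDTA).
#'
#' @param temperature Absolute temperature (K); must lie in [270, 380].
#' @param density Solvent density (g/ml); default: pure water at
#'   `temperature`.
#' @param viscosity Solvent viscosity (cP); default: pure water at
#'   `temperature`.
#' @param label Free-text buffer label (e.g. `"TE"`, `"TE+75mM KCl"`).
#' @return An object of class `solution_conditions` with fields
#'   `temperature`, `density`, `viscosity`, `label`.
#' @examples
#' solution_conditions(277.15, label = "TE")   # TE treated as water at 4 degC
#' @export
solution_conditions <- function(temperature, density = NULL, viscosity = NULL,
                                label = "water") {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (temperature < 270 || temperature > 380)
    stop("temperature out of supported range [270, 380] K")
  if (is.null(density))   density   <- water_density(temperature)
  if (is.null(viscosity)) viscosity <- water_viscosity(temperature)
  if (density <= 0)   stop("density must be positive")
  if (viscosity <= 0) stop("viscosity must be positive")
  structure(list(temperature = temperature, density = density,
                 viscosity = viscosity, label = label),
            class = "solution_conditions")
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf("<solution_conditions> %s: T = %.2f K, rho = %.5f g/ml, eta = %.4f cP\n",
              x$label, x$temperature, x$density, x$viscosity))
  invisible(x)
}

#' Density of pure water
#'
#' Kell's (1975) polynomial for the density of air-free water at 1 atm,
#' valid 0-100 degC. Returns 0.998203 g/ml at 20 degC.
#'
#' @param temperature Absolute temperature (K), in [273.15, 373.15].
#' @return Density in g/ml.
#' @export
water_density <- function(temperature) {
  .check_water_T(temperature)
  t <- temperature - 273.15
  (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 - 46.170461e-6 * t^3 +
     105.56302e-9 * t^4 - 280.54253e-12 * t^5) / (1 + 16.879850e-3 * t) / 1000
}

#' Viscosity of pure water
#'
#' Standard CRC correlations: Hardy-Cottington form for 0-20 degC,
#' log10(eta) = 1301/(998.333 + 8.1855(t-20) + 0.00585(t-20)^2) - 3.30233
#' (eta in poise), and the (20-t)/(t+96) form above 20 degC anchored at
#' eta(20 degC) = 1.002 cP. The two branches agree at 20 degC.
#'
#' @param temperature Absolute temperature (K), in [273.15, 373.15].
#' @return Dynamic viscosity in cP.
#' @export
water_viscosity <- function(temperature) {
  .check_water_T(temperature)
  t <- temperature - 273.15
  ifelse(
    t <= 20,
    100 * 10^(1301 / (998.333 + 8.1855 * (t - 20) + 0.00585 * (t - 20)^2) - 3.30233),
    1.002 * 10^((20 - t) / (t + 96) * (1.2364 - 1.37e-3 * (20 - t) + 5.7e-6 * (20 - t)^2))
  )
}

.check_water_T <- function(temperature) {
  if (any(temperature < 273.15 | temperature > 373.15))
    stop("temperature outside liquid-water range [273.15, 373.15] K")
  invisible(TRUE)
}

#' Pure-water reference conditions
#'
#' Convenience constructor bundling [water_density()] and
#' [water_viscosity()] into a [solution_conditions] object.
#'
#' @inheritParams water_density
#' @return A `solution_conditions` object labelled `"water"`.
#' @examples
#' water_properties(293.15)  # the 20 degC standardization reference
#' @export
water_properties <- function(temperature) {
  .check_water_T(temperature)
  solution_conditions(temperature,
                      density = water_density(temperature),
                      viscosity = water_viscosity(temperature),
                      label = "water")
}

#' Standardize a sedimentation coefficient to 20 degC water (s20,w)
#'
#' Converts an observed sedimentation coefficient s(T,B) to the s20,w scale:
#' s20w = s * (1 - vbar*rho_20w)/(1 - vbar*rho_TB) * eta_TB/eta_20w.
#' This removes the buffer- and temperature-dependence of buoyancy and drag
#' so that coefficients measured under different conditions are comparable.
#'
#' @param s_exp Observed sedimentation coefficient (Svedberg). May be a
#'   vector; the correction is linear in `s_exp`.
#' @param buffer A [solution_conditions] object for the experimental state.
#' @param vbar Partial specific volume of the species (ml/g); 0.54 for
#'   G-quadruplex DNA, 0.55 for single-stranded DNA.
#' @return Standardized coefficient(s) in Svedberg.
#' @examples
#' te4 <- solution_conditions(277.15, label = "TE")   # TE ~ water at 4 degC
#' correct_s20w(0.79, te4, vbar = 0.54)               # ~1.24 S
#' @export
correct_s20w <- function(s_exp, buffer, vbar) {
  stopifnot(inherits(buffer, "solution_conditions"), vbar > 0)
  rho20 <- water_density(293.15)
  eta20 <- water_viscosity(293.15)
  b_ref <- 1 - vbar * rho20
  b_exp <- 1 - vbar * buffer$density
  if (b_ref <= 0 || b_exp <= 0)
    stop("buoyancy term (1 - vbar*rho) is non-positive: species floats")
  s_exp * (b_ref / b_exp) * (buffer$viscosity / eta20)
}

#' Frictional ratio f/f0 from mass, vbar and s20,w
#'
#' Translational friction from the Svedberg relation,
#' f = M (1 - vbar*rho0) / (N_A * s), relative to the Stokes friction
#' f0 = 6 pi eta0 R0 of the anhydrous sphere of equal mass and vbar,
#' R0 = (3 M vbar / (4 pi N_A))^(1/3). All quantities in 20 degC water.
#'
#' @param molar_mass Molar mass (g/mol).
#' @param vbar Partial specific volume (ml/g).
#' @param s20w Sedimentation coefficient standardized to 20 degC water (S).
#' @return The dimensionless frictional ratio. Values slightly below 1 can
#'   arise from noisy s; a warning is emitted and the value returned.
#' @examples
#' frictional_ratio(6966.8, 0.54, 1.24)  # ~1.99 (22-mer quadruplex, unfolded)
#' @export
frictional_ratio <- function(molar_mass, vbar, s20w) {
  stopifnot(molar_mass > 0, vbar > 0, s20w > 0)
  rho0 <- water_density(293.15)
  eta0 <- water_viscosity(293.15) / 100       # cP -> poise (g/cm/s)
  if (1 - vbar * rho0 <= 0) stop("species floats in 20 degC water")
  s_sec <- s20w * .const$svedberg
  f  <- molar_mass * (1 - vbar * rho0) / (.const$N_A * s_sec)
  r0 <- (3 * molar_mass * vbar / (4 * pi * .const$N_A))^(1 / 3)
  f0 <- 6 * pi * eta0 * r0
  out <- f / f0
  if (any(out < 1))
    warning("f/f0 < 1 (non-physical); returning value unchanged")
  out
}

#' Perrin shape factor for a prolate ellipsoid of revolution
#'
#' P(p) = p^(-1/3) * sqrt(p^2 - 1) / log(p + sqrt(p^2 - 1)) for axial ratio
#' p = a/b > 1, with the sphere limit P(1) = 1. P increases monotonically
#' with p, so the relation can be inverted uniquely.
#'
#' @param axial_ratio Prolate axial ratio a/b, >= 1. Vectorized.
#' @return The shape contribution to the frictional ratio (>= 1).
#' @examples
#' perrin_prolate_factor(c(1, 2, 10))  # 1, 1.044, 1.543
#' @export
perrin_prolate_factor <- function(axial_ratio) {
  if (any(axial_ratio < 1)) stop("axial_ratio must be >= 1 (prolate branch)")
  p <- axial_ratio
  out <- rep(1, length(p))
  gt <- p > 1 + 1e-12
  q <- p[gt]
  out[gt] <- q^(-1 / 3) * sqrt(q^2 - 1) / log(q + sqrt(q^2 - 1))
  out
}

#' Hydration contribution to the frictional ratio
#'
#' ((vbar + delta / rho0) / vbar)^(1/3): the swelling of the equivalent
#' sphere by delta grams of water per gram of macromolecule, with rho0 the
#' density of 20 degC water.
#'
#' @param vbar Partial specific volume (ml/g).
#' @param hydration Hydration delta (g water / g macromolecule).
#' @return Dimensionless factor >= 1.
#' @export
hydration_factor <- function(vbar, hydration) {
  stopifnot(vbar > 0, hydration >= 0)
  ((vbar + hydration / water_density(293.15)) / vbar)^(1 / 3)
}

#' Invert the Perrin relation: axial ratio from f/f0
#'
#' Decomposes the frictional ratio as f/f0 = P(p) * hydration_factor and
#' solves P(p) = (f/f0) / hydration_factor for the unique prolate axial
#' ratio p >= 1 by bracketing + uniroot to |P(p) - target| < 1e-8. If the
#' implied shape factor is below 1 (hydration alone over-explains f/f0) the
#' sphere is reported with `at_sphere_limit = TRUE` instead of failing.
#'
#' @param f_over_f0 Measured frictional ratio.
#' @param vbar Partial specific volume (ml/g).
#' @param hydration Hydration (g/g); 0.59 is the package default for these
#'   DNAs (see the methods vignette).
#' @return A list of class `shape_result`: `axial_ratio`, `shape_factor`,
#'   `hydration_used`, `at_sphere_limit`.
#' @examples
#' axial_ratio_from_ff0(1.98, vbar = 0.54, hydration = 0.59)  # a/b ~ 10.1
#' @export
axial_ratio_from_ff0 <- function(f_over_f0, vbar, hydration = 0.59) {
  stopifnot(f_over_f0 > 0)
  hf <- hydration_factor(vbar, hydration)
  target <- f_over_f0 / hf
  if (target <= 1) {
    res <- list(axial_ratio = 1, shape_factor = 1, hydration_used = hydration,
                at_sphere_limit = TRUE)
    class(res) <- "shape_result"
    return(res)
  }
  hi <- 2
  while (perrin_prolate_factor(hi) < target && hi < 1e6) hi <- hi * 2
  p <- uniroot(function(p) perrin_prolate_factor(p) - target,
               lower = 1, upper = hi, tol = 1e-10)$root
  stopifnot(abs(perrin_prolate_factor(p) - target) < 1e-8)
  res <- list(axial_ratio = p, shape_factor = target,
              hydration_used = hydration, at_sphere_limit = FALSE)
  class(res) <- "shape_result"
  res
}

#' @export
print.shape_result <- function(x, ...) {
  cat(sprintf("<shape_result> a/b = %.3f (P = %.4f, hydration %.2f g/g%s)\n",
              x$axial_ratio, x$shape_factor, x$hydration_used,
              if (x$at_sphere_limit) ", at sphere limit" else ""))
  invisible(x)
}

#' Hydrodynamic summary for one species
#'
#' Runs the full standardization chain for one species: s20,w conversion,
#' frictional ratio from the sequence mass, and Perrin prolate axial ratio.
#'
#' @param molar_mass Molar mass (g/mol).
#' @param vbar Partial specific volume (ml/g).
#' @param s_exp Observed sedimentation coefficient (S).
#' @param buffer A [solution_conditions] for the experimental state.
#' @param hydration Hydration (g/g) used in the shape inversion.
#' @return A one-row `data.frame` with columns `s_exp`, `s20w`, `f_over_f0`,
#'   `axial_ratio`.
#' @export
hydro_summary <- function(molar_mass, vbar, s_exp, buffer, hydration = 0.59) {
  s20 <- correct_s20w(s_exp, buffer, vbar)
  ff0 <- frictional_ratio(molar_mass, vbar, s20)
  shp <- axial_ratio_from_ff0(ff0, vbar, hydration)
  data.frame(s_exp = s_exp, s20w = s20, f_over_f0 = ff0,
             axial_ratio = shp$axial_ratio)
}
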
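#' Sector cell geometry
#'
#' Standard double-sector centerpiece geometry for a velocity run.
#'
#' @param meniscus Meniscus radius (cm).
#' @param base Cell base radius (cm); must exceed `meniscus`.
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(meniscus = 5.9, base = 7.2) {
  stopifnot(meniscus > 0, base > meniscus)
  structure(list(meniscus = meniscus, base = base, sector = TRUE),
            class = "cell_geometry")
}

#' Molar mass implied by (s, f/f0, vbar)
#'
#' Under the single-frictional-ratio scaling used by c(S) analysis, a
#' species with sedimentation coefficient s, frictional ratio f/f0 and
#' partial specific volume vbar has a unique molar mass, obtained by
#' eliminating the Stokes radius between the Svedberg relation
#' s = M(1 - vbar rho)/(N_A f) and f = (f/f0) 6 pi eta R0 with
#' R0 = (3 M vbar / 4 pi N_A)^(1/3). M is strictly increasing in s.
#'
#' @param s Sedimentation coefficient (S). Vectorized.
#' @param f_over_f0 Common frictional ratio (>= 1).
#' @param vbar Partial specific volume (ml/g).
#' @param conditions A [solution_conditions] giving rho and eta.
#' @return Molar mass (g/mol).
#' @export
mass_from_s <- function(s, f_over_f0, vbar, conditions) {
  stopifnot(all(s > 0), f_over_f0 >= 1, inherits(conditions, "solution_conditions"))
  eta <- conditions$viscosity / 100                      # poise
  rho <- conditions$density
  if (1 - vbar * rho <= 0) stop("species floats under these conditions")
  s_sec <- s * .const$svedberg
  k <- s_sec * .const$N_A * f_over_f0 * 6 * pi * eta *
    (3 * vbar / (4 * pi * .const$N_A))^(1 / 3) / (1 - vbar * rho)
  k^(3 / 2)
}

#' Diffusion coefficient implied by (s, f/f0, vbar)
#'
#' D = k_B T / f with the friction f of the [mass_from_s()] species. In the
#' sphere limit f/f0 = 1 this reduces to the Stokes-Einstein coefficient of
#' the anhydrous sphere.
#'
#' @inheritParams mass_from_s
#' @return Diffusion coefficient (cm^2/s).
#' @export
diffusion_from_s <- function(s, f_over_f0, vbar, conditions) {
  M <- mass_from_s(s, f_over_f0, vbar, conditions)
  eta <- conditions$viscosity / 100
  r0 <- (3 * M * vbar / (4 * pi * .const$N_A))^(1 / 3)
  f <- f_over_f0 * 6 * pi * eta * r0
  .const$k_B_cgs * conditions$temperature / f
}

# Tridiagonal transport operator for the Lamm equation in a sector cell:
# dc/dt = -(1/r) d/dr [ r (s w^2 r c - D dc/dr) ], no-flux at both ends.
# Node-centered finite volume: faces halfway between nodes, end cells of
# half width, hybrid central/upwind advection, diffusion centered. The
# trapezoidal sector integral of c(r) r dr is then an exact invariant of
# the semi-discrete system (and of Crank-Nicolson stepping).
.lamm_operator <- function(r, dr, s_sec, D, omega2) {
  n <- length(r)
  A <- matrix(0, n, n)
  w <- c(dr / 2, rep(dr, n - 2), dr / 2)     # cell widths
  rf <- (r[-n] + r[-1]) / 2                  # interior face radii
  adv <- s_sec * omega2 * rf^2               # advective flux coefficient
  dif <- D * rf / dr                         # diffusive flux coef (times dc)
  # hybrid advection: second-order central where the cell Peclet number
  # permits (u dr / D <= 2, no spurious oscillation), first-order upwind
  # where the front would otherwise wiggle
  pe <- ifelse(dif > 0, adv / dif, Inf)
  for (i in seq_len(n - 1)) {
    if (pe[i] <= 2) {
      # F = adv*(c_i + c_{i+1})/2 - dif*(c_{i+1} - c_i)
      cl <- adv[i] / 2 + dif[i]; cr <- adv[i] / 2 - dif[i]
    } else {
      # F = adv*c_i - dif*(c_{i+1} - c_i)
      cl <- adv[i] + dif[i]; cr <- -dif[i]
    }
    A[i, i]         <- A[i, i]         - cl / (r[i] * w[i])
    A[i, i + 1]     <- A[i, i + 1]     - cr / (r[i] * w[i])
    A[i + 1, i]     <- A[i + 1, i]     + cl / (r[i + 1] * w[i + 1])
    A[i + 1, i + 1] <- A[i + 1, i + 1] + cr / (r[i + 1] * w[i + 1])
  }
  A
}

#' Finite-volume Lamm-equation solver
#'
#' Simulates sedimentation-velocity concentration profiles c(r, t) for a
#' single ideal species in a sector-shaped cell, solving
#' dc/dt = -(1/r) d/dr [ r (s omega^2 r c - D dc/dr) ] with no-flux
#' boundaries at meniscus and base. The scheme is a conservative
#' finite-volume discretization (hybrid central/upwind advection switched
#' on the cell Peclet number, centered diffusion) advanced by
#' Crank-Nicolson; sector-weighted mass is conserved to
#' machine precision by construction. The time step is capped at half the
#' advective CFL step and sub-stepped automatically, never left unstable.
#'
#' @param s Sedimentation coefficient (S), >= 0.
#' @param D Diffusion coefficient (cm^2/s), > 0.
#' @param geometry A [cell_geometry].
#' @param rotor_speed Rotor speed (rpm).
#' @param times Output times (s), increasing, first >= 0.
#' @param c0 Initial (uniform) loading signal (AU).
#' @param n_r Number of radial grid points (default 400, >= 200 advised).
#' @param temperature Temperature (K) recorded in the output scans.
#' @return List of [scan_table] objects, one per output time.
#' @export
lamm_solve <- function(s, D, geometry, rotor_speed, times, c0 = 1,
                       n_r = 400, temperature = 277.15) {
  stopifnot(s >= 0, D > 0, inherits(geometry, "cell_geometry"),
            rotor_speed > 0, all(diff(times) > 0), times[1] >= 0, n_r >= 50)
  r <- seq(geometry$meniscus, geometry$base, length.out = n_r)
  dr <- r[2] - r[1]
  omega2 <- (2 * pi * rotor_speed / 60)^2
  s_sec <- s * .const$svedberg
  A <- .lamm_operator(r, dr, s_sec, D, omega2)

  u_max <- s_sec * omega2 * geometry$base
  dt_max <- if (u_max > 0) 0.5 * dr / u_max else Inf

  conc <- rep(c0, n_r)
  eye <- diag(n_r)
  prop_cache <- list()
  propagator <- function(dt) {
    key <- sprintf("%.8e", dt)
    if (is.null(prop_cache[[key]]))
      prop_cache[[key]] <<- solve(eye - (dt / 2) * A, eye + (dt / 2) * A)
    prop_cache[[key]]
  }

  out <- vector("list", length(times))
  t_now <- 0
  for (j in seq_along(times)) {
    span <- times[j] - t_now
    if (span > 0) {
      nst <- max(1L, ceiling(span / dt_max))
      P <- propagator(span / nst)
      for (k in seq_len(nst)) conc <- P %*% conc
      conc <- as.numeric(conc)
      t_now <- times[j]
    }
    out[[j]] <- scan_table(r, conc, rotor_speed, temperature,
                           channel_id = "sim", time = times[j])
  }
  out
}

#' Sector-weighted total signal of a scan
#'
#' Integral of c(r) r dr (trapezoidal), proportional to the total amount of
#' material in a sector cell; conserved by [lamm_solve()].
#'
#' @param scan A [scan_table].
#' @return The sector-weighted integral.
#' @export
sector_mass <- function(scan) {
  pracma::trapz(scan$radius, scan$absorbance * scan$radius)
}

#' Tikhonov-regularized c(S) inversion of velocity scans
#'
#' Expresses the observed boundary scans as a non-negative superposition of
#' single-species Lamm solutions on a grid of sedimentation coefficients,
#' each with the diffusion coefficient implied by a common frictional ratio
#' ([diffusion_from_s()]). The coefficients are found by non-negative least
#' squares with a second-difference (smoothness) penalty; the penalty
#' weight can be fixed or chosen by an L-curve corner heuristic.
#'
#' @param scans List of [scan_table] velocity scans with `time` set; at
#'   least 5 spanning visible boundary movement.
#' @param s_grid Grid of sedimentation coefficients (S), increasing.
#' @param f_over_f0 Common frictional ratio used for D(s).
#' @param vbar Partial specific volume (ml/g).
#' @param buffer A [solution_conditions] for the run.
#' @param reg_weight Tikhonov weight; `NULL` (default) selects it by the
#'   L-curve heuristic over a log-spaced candidate set.
#' @param geometry Cell geometry; default spans the scans' radial range.
#' @param n_r Radial grid for the forward models (default 400).
#' @return An object of class `s_distribution`: `s_grid`, `c` (signal per
#'   Svedberg, >= 0), `f_over_f0`, `reg_weight`, `total_signal`
#'   (= integral of c ds), and `empty` flag.
#' @export
cs_invert <- function(scans, s_grid, f_over_f0, vbar, buffer,
                      reg_weight = NULL, geometry = NULL, n_r = 400) {
  stopifnot(length(scans) >= 5, all(diff(s_grid) > 0), all(s_grid > 0))
  times <- vapply(scans, `[[`, numeric(1), "time")
  stopifnot(all(is.finite(times)))
  ord <- order(times)
  scans <- scans[ord]; times <- times[ord]
  rpm <- scans[[1]]$rotor_speed
  if (is.null(geometry)) {
    rng <- range(unlist(lapply(scans, `[[`, "radius")))
    geometry <- cell_geometry(rng[1], rng[2])
  }

  # basis: unit-loading forward solutions, interpolated onto each scan grid
  y <- unlist(lapply(scans, `[[`, "absorbance"))
  B <- matrix(0, length(y), length(s_grid))
  for (k in seq_along(s_grid)) {
    Dk <- diffusion_from_s(s_grid[k], f_over_f0, vbar, buffer)
    sim <- lamm_solve(s_grid[k], Dk, geometry, rpm, times, c0 = 1, n_r = n_r,
                      temperature = buffer$temperature)
    col <- unlist(lapply(seq_along(scans), function(j)
      approx(sim[[j]]$radius, sim[[j]]$absorbance, scans[[j]]$radius,
             rule = 2)$y))
    B[, k] <- col
  }

  K <- length(s_grid)
  L <- matrix(0, max(K - 2, 1), K)
  if (K >= 3) for (i in seq_len(K - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  scale0 <- sqrt(sum(B^2) / sum(L^2))

  solve_w <- function(w) {
    Aw <- rbind(B, sqrt(w) * scale0 * L)
    bw <- c(y, rep(0, nrow(L)))
    pracma::lsqnonneg(Aw, bw)$x
  }

  if (is.null(reg_weight)) {
    cand <- 10^seq(-8, 0, by = 1)
    res <- sapply(cand, function(w) {
      x <- solve_w(w)
      c(sqrt(sum((B %*% x - y)^2)), sqrt(sum((L %*% x)^2)))
    })
    lr <- log10(pmax(res[1, ], 1e-300)); ls <- log10(pmax(res[2, ], 1e-300))
    # discrete curvature of the (log residual, log seminorm) curve
    curv <- rep(-Inf, length(cand))
    for (i in 2:(length(cand) - 1)) {
      v1 <- c(lr[i] - lr[i - 1], ls[i] - ls[i - 1])
      v2 <- c(lr[i + 1] - lr[i], ls[i + 1] - ls[i])
      cross <- v1[1] * v2[2] - v1[2] * v2[1]
      nn <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
      if (nn > 0) curv[i] <- cross / nn
    }
    reg_weight <- cand[which.max(curv)]
  }
  x <- solve_w(reg_weight)

  ds <- mean(diff(s_grid))
  cdist <- x / ds                       # signal per Svedberg
  total <- pracma::trapz(s_grid, cdist)
  structure(list(s_grid = s_grid, c = cdist, f_over_f0 = f_over_f0,
                 reg_weight = reg_weight, total_signal = total,
                 empty = all(x <= 0)),
            class = "s_distribution")
}

#' @export
print.s_distribution <- function(x, ...) {
  if (x$empty) {
    cat("<s_distribution> empty (all-zero solution)\n")
  } else {
    cat(sprintf("<s_distribution> %d grid points in [%.2f, %.2f] S, sw = %.3f S, total %.3f\n",
                length(x$s_grid), min(x$s_grid), max(x$s_grid),
                weight_average_s(x), x$total_signal))
  }
  invisible(x)
}

#' Weight-average sedimentation coefficient of a c(S) distribution
#'
#' integral(s c ds) / integral(c ds).
#'
#' @param dist An `s_distribution` from [cs_invert()], or any list with
#'   `s_grid` and `c`.
#' @return Weight-average s (S).
#' @export
weight_average_s <- function(dist) {
  tot <- pracma::trapz(dist$s_grid, dist$c)
  if (tot <= 0) stop("empty distribution: weight-average s undefined")
  pracma::trapz(dist$s_grid, dist$s_grid * dist$c) / tot
}

#' Map a c(S) distribution to molar mass, c(M)
#'
#' Applies [mass_from_s()] to the grid; the mapping is strictly increasing
#' so the distribution transforms monotonically.
#'
#' @inheritParams weight_average_s
#' @param vbar Partial specific volume (ml/g).
#' @param conditions A [solution_conditions].
#' @return List with `M_grid` (g/mol), `c` (per-Svedberg weights carried
#'   over), and `M_mean` (signal-weighted mean mass).
#' @export
cs_to_cm <- function(dist, vbar, conditions) {
  M <- mass_from_s(dist$s_grid, dist$f_over_f0, vbar, conditions)
  tot <- pracma::trapz(dist$s_grid, dist$c)
  if (tot <= 0) stop("empty distribution")
  Mmean <- pracma::trapz(dist$s_grid, M * dist$c) / tot
  list(M_grid = M, c = dist$c, M_mean = Mmean)
}
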
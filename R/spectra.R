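#' CD spectrum
#'
#' @param wavelength Wavelengths (nm), increasing.
#' @param ellipticity CD signal (arbitrary units), same length.
#' @param temperature Temperature (K).
#' @param sample_label Free-text sample label.
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelength, ellipticity, temperature = 283.15,
                        sample_label = "") {
  stopifnot(length(wavelength) == length(ellipticity),
            all(diff(wavelength) > 0))
  structure(list(wavelength = as.numeric(wavelength),
                 ellipticity = as.numeric(ellipticity),
                 temperature = temperature, sample_label = sample_label),
            class = "cd_spectrum")
}

#' Thermal melting curve (CD at 295 nm)
#'
#' @param temperature Temperatures (K), increasing.
#' @param signal CD signal at 295 nm, same length.
#' @param label Sample label.
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, signal, label = "") {
  stopifnot(length(temperature) == length(signal),
            all(diff(temperature) > 0))
  structure(list(temperature = as.numeric(temperature),
                 signal = as.numeric(signal), label = label),
            class = "melt_curve")
}

#' Protein-subtracted difference spectrum
#'
#' Subtracts a reference spectrum (typically free protein) from a mixture
#' spectrum after linear interpolation of the reference onto the mixture's
#' wavelength grid; wavelengths outside the overlap are dropped. The
#' result isolates the nucleic-acid CD contribution of a protein/DNA
#' mixture.
#'
#' @param mix Mixture [cd_spectrum].
#' @param reference Reference [cd_spectrum] to subtract.
#' @return A [cd_spectrum] on the overlapping part of `mix`'s grid.
#' @export
difference_spectrum <- function(mix, reference) {
  stopifnot(inherits(mix, "cd_spectrum"), inherits(reference, "cd_spectrum"))
  lo <- max(min(mix$wavelength), min(reference$wavelength))
  hi <- min(max(mix$wavelength), max(reference$wavelength))
  keep <- mix$wavelength >= lo & mix$wavelength <= hi
  if (!any(keep)) stop("spectra do not overlap in wavelength")
  wl <- mix$wavelength[keep]
  ref <- approx(reference$wavelength, reference$ellipticity, wl)$y
  cd_spectrum(wl, mix$ellipticity[keep] - ref, mix$temperature,
              sample_label = paste0(mix$sample_label, " - ",
                                    reference$sample_label))
}

#' Heuristic G-quadruplex topology call from a CD spectrum
#'
#' Antiparallel quadruplexes show a CD maximum near 295 nm with a minimum
#' near 235 nm; parallel quadruplexes show a maximum near 260 nm. The
#' spectrum is classified by the location of its global maximum (and, for
#' the antiparallel call, the presence of a negative band in the trough
#' window); anything else is indeterminate.
#'
#' @param spec A [cd_spectrum] covering at least 230-310 nm.
#' @param max_window_anti Window (nm) for the antiparallel maximum
#'   (default c(285, 305)).
#' @param min_window_anti Window for the antiparallel minimum
#'   (default c(230, 245)).
#' @param max_window_par Window for the parallel maximum
#'   (default c(255, 270)).
#' @return One of `"antiparallel"`, `"parallel"`, `"indeterminate"`.
#' @export
classify_topology <- function(spec, max_window_anti = c(285, 305),
                              min_window_anti = c(230, 245),
                              max_window_par = c(255, 270)) {
  stopifnot(inherits(spec, "cd_spectrum"))
  wl <- spec$wavelength; y <- spec$ellipticity
  if (min(wl) > 230 || max(wl) < 310)
    stop("spectrum must cover 230-310 nm")
  if (diff(range(y)) <= .Machine$double.eps * 100) return("indeterminate")
  wmax <- wl[which.max(y)]
  in_win <- function(w, win) w >= win[1] & w <= win[2]
  trough <- y[in_win(wl, min_window_anti)]
  if (in_win(wmax, max_window_anti) && length(trough) && min(trough) < 0)
    return("antiparallel")
  if (in_win(wmax, max_window_par)) return("parallel")
  "indeterminate"
}

#' Two-state van 't Hoff folded fraction
#'
#' theta(T) = 1 / (1 + exp[(dH/R) (1/Tm - 1/T)]): 1 well below Tm,
#' 0 well above, exactly 0.5 at Tm.
#'
#' @param temperature Temperatures (K).
#' @param Tm Midpoint temperature (K).
#' @param dH Van 't Hoff enthalpy of unfolding (J/mol), > 0.
#' @return Folded fraction in (0, 1).
#' @export
folded_fraction <- function(temperature, Tm, dH) {
  1 / (1 + exp(dH / .const$R_si * (1 / Tm - 1 / temperature)))
}

#' Two-state melting model with linear baselines
#'
#' signal(T) = folded_baseline(T) * theta(T)
#'           + unfolded_baseline(T) * (1 - theta(T)).
#'
#' @param temperature Temperatures (K).
#' @param Tm,dH See [folded_fraction()].
#' @param bf Folded baseline `c(intercept, slope)` (signal, signal/K).
#' @param bu Unfolded baseline `c(intercept, slope)`.
#' @return Model signal.
#' @export
melt_model <- function(temperature, Tm, dH, bf, bu) {
  th <- folded_fraction(temperature, Tm, dH)
  (bf[1] + bf[2] * temperature) * th +
    (bu[1] + bu[2] * temperature) * (1 - th)
}

#' Fit a two-state melting transition
#'
#' Least-squares fit of [melt_model()] (van 't Hoff two-state unfolding
#' with linear folded/unfolded baselines) to a CD melting curve. Tm is
#' initialized at the temperature of steepest signal change and dH from a
#' coarse grid; a no-transition error is raised when the signal is
#' monotone within noise (no interior inflection separating two
#' baselines).
#'
#' @param curve A [melt_curve] spanning both baselines (>= 10 points on
#'   each side of the transition recommended).
#' @return An object of class `melt_fit`: `Tm` (K), `se_Tm`, `dH_vH`
#'   (J/mol), `folded_baseline`, `unfolded_baseline`, `rss`, `label`.
#' @export
fit_melting <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  Tv <- curve$temperature; y <- curve$signal
  n <- length(Tv)
  if (n < 25) stop("melting curve too short to bracket both baselines")

  # crude transition locator: steepest descent of a lightly smoothed
  # signal, searched away from the (unsmoothable) edges
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  dy <- diff(ys) / diff(Tv)
  interior <- 3:(n - 3)
  i0 <- interior[which.min(dy[interior])]
  amp <- abs(mean(y[seq_len(5)]) - mean(y[n - 0:4]))
  noise <- sd(diff(y)) / sqrt(2)
  if (amp < 4 * noise)
    stop("no transition detected: signal monotone within noise")
  Tm0 <- Tv[i0]

  nb <- max(5L, floor(n / 5))
  bf0 <- coef(lm(y[seq_len(nb)] ~ Tv[seq_len(nb)]))
  bu0 <- coef(lm(y[n - seq_len(nb) + 1] ~ Tv[n - seq_len(nb) + 1]))

  resid_fun <- function(par) {
    melt_model(Tv, par[1], exp(par[2]), par[3:4], par[5:6]) - y
  }
  best <- NULL
  for (dH0 in c(1e5, 2e5, 4e5)) {
    par0 <- unname(c(Tm0, log(dH0), bf0, bu0))
    ft <- suppressWarnings(
      minpack.lm::nls.lm(par0, fn = resid_fun,
                         lower = c(min(Tv), log(1e3), rep(-Inf, 4)),
                         upper = c(max(Tv), log(1e8), rep(Inf, 4)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, maxfev = 4000,
                           ftol = 1e-14, ptol = 1e-14)))
    if (is.null(best) || ft$deviance < best$deviance) best <- ft
  }
  par <- best$par
  rss <- best$deviance

  # a genuine transition beats a straight line decisively; a monotone
  # drift does not, however well the sigmoid shadows it
  rss_line <- sum(stats::resid(lm(y ~ Tv))^2)
  if (rss_line < 2 * rss)
    stop("no transition detected: signal monotone within noise")

  resid_nat <- function(q) melt_model(Tv, q[1], q[2], q[3:4], q[5:6]) - y
  se <- .ls_covariance(c(par[1], exp(par[2]), par[3:6]), resid_nat, rss, n)

  structure(list(Tm = par[1], se_Tm = se[1], dH_vH = exp(par[2]),
                 folded_baseline = par[3:4], unfolded_baseline = par[5:6],
                 rss = rss, label = curve$label,
                 fitted = melt_model(Tv, par[1], exp(par[2]), par[3:4],
                                     par[5:6])),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> %s: Tm = %.2f +/- %.2f K, dH_vH = %.0f kJ/mol\n",
              x$label, x$Tm, x$se_Tm, x$dH_vH / 1000))
  invisible(x)
}

#' Rank samples by thermal stability
#'
#' Orders melt fits by descending Tm. Pairs whose Tm difference is smaller
#' than their combined standard error are flagged as ties.
#'
#' @param fits List of `melt_fit` objects.
#' @return A data.frame with columns `label`, `Tm`, `se_Tm`,
#'   `tie_with_next` (logical), ordered most to least stable.
#' @export
rank_stability <- function(fits) {
  stopifnot(length(fits) >= 1)
  df <- data.frame(label = vapply(fits, `[[`, character(1), "label"),
                   Tm = vapply(fits, `[[`, numeric(1), "Tm"),
                   se_Tm = vapply(fits, `[[`, numeric(1), "se_Tm"))
  df <- df[order(-df$Tm), ]
  rownames(df) <- NULL
  n <- nrow(df)
  df$tie_with_next <- FALSE
  if (n > 1) {
    dT <- -diff(df$Tm)
    comb <- sqrt(df$se_Tm[-n]^2 + df$se_Tm[-1]^2)
    df$tie_with_next[-n] <- is.finite(comb) & dT < comb
  }
  df
}
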
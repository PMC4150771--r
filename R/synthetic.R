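# Oligonucleotide fixture set: human-telomere 22-mers with single 6mG
# substitutions (G1..G6, G11 numbered 5'->3' along the G residues of the
# tracts), unlabeled variants (x suffix), a 25-mer 3'-extended G11, a
# scrambled single-stranded 26-mer, and the NarI-site 24-mer duplex pair.
# Masses are the synthesis-report values (Da); "fl" marks a 5'
# 6-carboxyfluorescein label.
.fixtures <- local({
  tel22 <- "AGGGTTAGGGTTAGGGTTAGGG"
  tel25 <- "AGGGTTAGGGTTAGGGTTAGGGTTA"
  df <- data.frame(
    name = c("22wt", "22wtx", "G1", "G2", "G3", "G4", "G5", "G5x", "G6",
             "G11", "25-mer G11", "26-mer", "24-mer NarI",
             "24-mer NarI complement"),
    sequence = c(tel22, tel22, tel22, tel22, tel22, tel22, tel22, tel22,
                 tel22, tel22, tel25,
                 "AGTCAGTCAGTCAGTCAGTCAGTCAG",
                 "GGGTCATTTGGCGCCTTTCGATCC",
                 "GGATCGAAAGGCGCCAAATGACCC"),
    methyl_position = c(NA, NA, 2, 3, 4, 8, 9, 9, 10, 21, 21, NA, 11, NA),
    fluorophore = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                    TRUE, TRUE, TRUE, FALSE, FALSE),
    molar_mass = c(7565.3, 6966.8, 7579.2, 7579.2, 7579.2, 7579.2, 7579.2,
                   6980.7, 7579.2, 7579.2, 8500.9, 8532.7, 7326.8, 7380.2),
    stringsAsFactors = FALSE
  )
  df
})

#' Sequence fixture lookup
#'
#' Returns the oligonucleotide fixture (sequence, molar mass, 6mG position,
#' fluorophore flag) for one of the study's DNAs: the telomeric 22-mer
#' (22wt), its unlabeled form (22wtx), the single-6mG variants G1-G6 and
#' G11 (and unlabeled G5x), the 3'-extended 25-mer G11, a single-stranded
#' 26-mer, and the NarI-assay 24-mer duplex strands.
#'
#' @param name Fixture name (see above), or nothing to list all names.
#' @return A list of class `sequence_fixture` with fields `name`,
#'   `sequence`, `methyl_position` (NA if unmethylated), `fluorophore`,
#'   `molar_mass`; or, with no argument, the character vector of names.
#' @examples
#' get_fixture("G5")$methyl_position   # 9: middle G of tract 2
#' @export
get_fixture <- function(name) {
  if (missing(name)) return(.fixtures$name)
  i <- match(name, .fixtures$name)
  if (is.na(i)) stop(sprintf("unknown fixture '%s'", name))
  out <- as.list(.fixtures[i, ])
  class(out) <- "sequence_fixture"
  out
}

#' Truth record for a synthetic dataset
#'
#' Bundles a scenario identifier, the generating parameters, the noise
#' level and the seed. Regeneration from the same record is bit-identical;
#' every generator attaches its record to the data it emits so fitting
#' modules can be scored against the truth.
#'
#' @param .scenario_id Text identifier (dotted formal so that scenario
#'   parameters passed through `...` can never partially match it).
#' @param .seed Integer RNG seed.
#' @param ... Scenario parameters, stored as-is.
#' @param .noise_sd Noise standard deviation (units of the generated
#'   signal).
#' @return An object of class `truth_record` with fields `scenario_id`,
#'   `seed`, `noise_sd` and the `...` parameters.
#' @export
truth_record <- function(.scenario_id, .seed, ..., .noise_sd = 0) {
  structure(c(list(scenario_id = .scenario_id, seed = as.integer(.seed),
                   noise_sd = .noise_sd), list(...)),
            class = "truth_record")
}

#' Default sedimentation-equilibrium scenarios
#'
#' The two study designs: `"KCl"` (folded quadruplex; truth n = 2;
#' 25 000 and 35 000 rpm) and `"K-free"` (unfolded DNA; truth n = 4;
#' 12 000, 16 000 and 20 000 rpm), each at two loading dilutions, 4 degC,
#' G5x-mass DNA with AGT in molar excess.
#'
#' @param scenario `"KCl"` or `"K-free"`.
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise (AU), default 0.005.
#' @return A [truth_record] consumed by [gen_equilibrium_scans()].
#' @export
eq_truth <- function(scenario = c("KCl", "K-free"), seed = 1,
                     noise_sd = 0.005) {
  scenario <- match.arg(scenario)
  spec <- if (scenario == "KCl") {
    list(n = 2, speeds = c(25000, 35000))
  } else {
    list(n = 4, speeds = c(12000, 16000, 20000))
  }
  truth_record(paste0("eq-", scenario), seed, .noise_sd = noise_sd,
               n = spec$n, speeds = spec$speeds, dilutions = c(1, 0.5),
               A_protein = 0.45, A_complex = 0.30,
               M_P = 21519, vbar_P = 0.744,
               M_D = get_fixture("G5x")$molar_mass, vbar_D = 0.54,
               temperature = 277.15, meniscus = 6.95, base = 7.15,
               n_points = 120)
}

# mass-conserving amplitude at r0 for loading signal A0 in [rm, rb]
.eq_alpha_from_loading <- function(A0, sigma, rm, rb, r0) {
  span <- (rb^2 - rm^2) / 2
  if (abs(sigma) < 1e-12) return(A0)
  integral <- (exp(sigma * (rb^2 - r0^2)) - exp(sigma * (rm^2 - r0^2))) /
    (2 * sigma)
  A0 * span / integral
}

#' Generate synthetic sedimentation-equilibrium scans
#'
#' Produces noiseless two-species equilibrium profiles (free protein +
#' saturated complex, [eq2_profile()]) at the scenario's speeds and
#' dilutions, with amplitudes set by conservation of the loading signal
#' over the solution column, plus Gaussian noise. The truth record is
#' attached as attribute `"truth"`.
#'
#' @param truth A [truth_record] from [eq_truth()] (or hand-built with the
#'   same fields).
#' @param buffer Optional [solution_conditions]; default water at the
#'   scenario temperature.
#' @return List of [scan_table] objects (speeds x dilutions).
#' @export
gen_equilibrium_scans <- function(truth, buffer = NULL) {
  stopifnot(inherits(truth, "truth_record"))
  if (is.null(buffer)) buffer <- water_properties(truth$temperature)
  set.seed(truth$seed)
  vC <- complex_vbar(truth$n, truth$M_P, truth$vbar_P, truth$M_D,
                     truth$vbar_D)
  MC <- truth$n * truth$M_P + truth$M_D
  r <- seq(truth$meniscus, truth$base, length.out = truth$n_points)
  r0 <- mean(range(r))
  scans <- list()
  for (speed in truth$speeds) {
    sP <- reduced_molecular_weight(truth$M_P, truth$vbar_P, buffer$density,
                                   speed, truth$temperature)
    sC <- reduced_molecular_weight(MC, vC, buffer$density, speed,
                                   truth$temperature)
    for (dil in truth$dilutions) {
      aP <- .eq_alpha_from_loading(truth$A_protein * dil, sP,
                                   truth$meniscus, truth$base, r0)
      aC <- .eq_alpha_from_loading(truth$A_complex * dil, sC,
                                   truth$meniscus, truth$base, r0)
      a <- eq2_profile(r, list(alpha_P = aP, alpha_PnD = aC, zeta = 0,
                               r0 = r0, sigma_P = sP, sigma_PnD = sC))
      if (truth$noise_sd > 0)
        a <- a + rnorm(length(a), 0, truth$noise_sd)
      scans[[length(scans) + 1L]] <-
        scan_table(r, a, speed, truth$temperature,
                   channel_id = sprintf("%grpm-dil%.2g", speed, dil))
    }
  }
  attr(scans, "truth") <- truth
  scans
}

#' Default repair-kinetics scenarios
#'
#' Amplitude/rate structures emulating the study's headline panels:
#' \describe{
#'   \item{G1-KCl}{biphasic, plateau 0.63 (A = 0.45/0.18), fast rate
#'     1.5e-3 /s, slow rate 30-fold lower.}
#'   \item{G5-KCl}{biphasic, plateau 0.39 (A = 0.24/0.15).}
#'   \item{G1-TEA, G5-TEA}{single-phase (slow phase suppressed in the
#'     unfolded state), plateaus 0.95 / 0.94.}
#'   \item{NarI}{duplex assay: fast/slow absolute rates k[DNA]V of
#'     0.31e-13 and 0.23e-14 mol/s at 0.037 uM DNA.}
#' }
#' Fast rates are chosen so k1 * [DNA] * V falls in the 0.7-1.7e-13 mol/s
#' band at the assay concentration (0.25 uM DNA, 4e-4 L); slow rates sit
#' in the upper part of the 0.015-0.11e-13 mol/s band, where the slow
#' phase is resolvable within the sampling window (as the published
#' two-phase fits require), giving fast/slow ratios of 13.6 (G1) and
#' 15 (G5), inside the 11-60-fold band.
#'
#' @param scenario One of `"G1-KCl"`, `"G5-KCl"`, `"G1-TEA"`, `"G5-TEA"`,
#'   `"NarI"`.
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise (mole fraction), default 0.02.
#' @return A [truth_record] consumed by [gen_repair_course()].
#' @export
repair_truth <- function(scenario = c("G1-KCl", "G5-KCl", "G1-TEA",
                                      "G5-TEA", "NarI"),
                         seed = 1, noise_sd = 0.02) {
  scenario <- match.arg(scenario)
  # gel lanes of the standard sampling design plus the long-incubation
  # (8.8 h) extent measurement that anchors the reaction plateau
  tel_times <- c(30, 60, 300, 600, 1200, 1800, 2700, 3600, 5400, 7200,
                 10800, 31680)
  nari_times <- c(15, 30, 45, 60, 120, 180, 270, 360)
  p <- switch(scenario,
    "G1-KCl" = list(A = c(0.45, 0.18), k = c(1.5e-3, 1.1e-4),
                    times = tel_times, dna_conc = 0.25e-6,
                    dna = "G1", buf = "KCl", assay = "gel-mobility"),
    "G5-KCl" = list(A = c(0.24, 0.15), k = c(1.2e-3, 8e-5),
                    times = tel_times, dna_conc = 0.25e-6,
                    dna = "G5", buf = "KCl", assay = "gel-mobility"),
    "G1-TEA" = list(A = 0.95, k = 1.6e-3,
                    times = tel_times, dna_conc = 0.25e-6,
                    dna = "G1", buf = "TEA", assay = "gel-mobility"),
    "G5-TEA" = list(A = 0.94, k = 1.4e-3,
                    times = tel_times, dna_conc = 0.25e-6,
                    dna = "G5", buf = "TEA", assay = "gel-mobility"),
    "NarI"   = list(A = c(0.80, 0.15), k = c(2.095e-3, 1.554e-4),
                    times = nari_times, dna_conc = 0.037e-6,
                    dna = "24-mer NarI", buf = "KAc", assay = "NarI")
  )
  truth_record(paste0("repair-", scenario), seed, .noise_sd = noise_sd,
               amplitudes = p$A, rates = p$k, times = p$times,
               trials = 2, dna_conc = p$dna_conc, reaction_volume = 4e-4,
               dna_label = p$dna, buffer_label = p$buf, assay = p$assay)
}

#' Generate a synthetic repair time course
#'
#' [multiphase_model()] values at the scenario's sampling grid plus
#' Gaussian noise, clipped to [0, 1]. A scenario with `trials > 1` emits
#' the pooled course of that many parallel trials (the replicate whose
#' combined data are fitted, mirroring the duplex-assay practice of
#' fitting two parallel reactions jointly); successive trials are offset
#' by 1 s to reflect aliquot-timing differences. Truth record attached as
#' attribute `"truth"`.
#'
#' @param truth A [truth_record] from [repair_truth()].
#' @return A [time_course].
#' @export
gen_repair_course <- function(truth) {
  stopifnot(inherits(truth, "truth_record"))
  set.seed(truth$seed)
  ntrial <- if (is.null(truth$trials)) 1L else truth$trials
  tt <- NULL; ff <- NULL
  for (j in seq_len(ntrial)) {
    tj <- truth$times + (j - 1)
    f <- multiphase_model(tj, truth$amplitudes, truth$rates)
    if (truth$noise_sd > 0)
      f <- pmin(pmax(f + rnorm(length(f), 0, truth$noise_sd), 0), 1)
    tt <- c(tt, tj)
    ff <- c(ff, f)
  }
  ord <- order(tt)
  tc <- time_course(tt[ord], ff[ord], dna_label = truth$dna_label,
                    buffer_label = truth$buffer_label,
                    dna_conc = truth$dna_conc,
                    reaction_volume = truth$reaction_volume,
                    assay = truth$assay)
  attr(tc, "truth") <- truth
  tc
}

#' Default sedimentation-velocity scenario
#'
#' A single ideal species emulating a folded quadruplex boundary: the
#' velocity-run conditions are 40 000 rpm at 4 degC, scans every hour for
#' 10 h, default s = 2.0 S with f/f0 = 1.36 and vbar = 0.54.
#'
#' @param s Sedimentation coefficient (S).
#' @param f_over_f0 Frictional ratio setting D through
#'   [diffusion_from_s()].
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise (AU), default 0.005.
#' @return A [truth_record] consumed by [gen_velocity_scans()].
#' @export
vel_truth <- function(s = 2.0, f_over_f0 = 1.36, seed = 1,
                      noise_sd = 0.005) {
  truth_record("vel-single-species", seed, .noise_sd = noise_sd,
               s = s, f_over_f0 = f_over_f0, vbar = 0.54,
               rotor_speed = 40000, temperature = 277.15,
               times = seq(3600, 36000, by = 3600), c0 = 0.5,
               meniscus = 5.9, base = 7.2, n_points_out = 200)
}

#' Generate synthetic sedimentation-velocity scans
#'
#' Runs [lamm_solve()] for the scenario species and adds Gaussian noise on
#' a down-sampled radial grid. Truth record attached as attribute
#' `"truth"`.
#'
#' @param truth A [truth_record] from [vel_truth()].
#' @param buffer Optional [solution_conditions]; default water at the
#'   scenario temperature.
#' @return List of [scan_table] objects, one per scan time.
#' @export
gen_velocity_scans <- function(truth, buffer = NULL) {
  stopifnot(inherits(truth, "truth_record"))
  if (is.null(buffer)) buffer <- water_properties(truth$temperature)
  set.seed(truth$seed)
  D <- diffusion_from_s(truth$s, truth$f_over_f0, truth$vbar, buffer)
  geom <- cell_geometry(truth$meniscus, truth$base)
  sims <- lamm_solve(truth$s, D, geom, truth$rotor_speed, truth$times,
                     c0 = truth$c0, temperature = truth$temperature)
  out <- lapply(sims, function(sc) {
    idx <- round(seq(1, length(sc$radius), length.out = truth$n_points_out))
    a <- sc$absorbance[idx]
    if (truth$noise_sd > 0) a <- a + rnorm(length(a), 0, truth$noise_sd)
    scan_table(sc$radius[idx], a, sc$rotor_speed, sc$temperature,
               channel_id = "syn", time = sc$time)
  })
  attr(out, "truth") <- truth
  out
}

#' Default thermal-melting panel
#'
#' Tm values spanning 337 K (22wt, most stable) down to 313 K (G5), in the
#' stability order 22wt > G1 > G6 > G4 > G3 > G11 > G2 > G5; outer-tetrad
#' adducts (G1, G3, G4, G6) all rank above inner-tetrad adducts
#' (G2, G5, G11).
#'
#' @return Named numeric vector of Tm (K).
#' @export
melt_panel_tm <- function() {
  c("22wt" = 337, "G1" = 333.5, "G6" = 330.5, "G4" = 327.5,
    "G3" = 324.5, "G11" = 321, "G2" = 317, "G5" = 313)
}

#' Melting scenario for one DNA
#'
#' @param label Sample label.
#' @param Tm Midpoint (K).
#' @param dH Van 't Hoff enthalpy (J/mol), default 2e5.
#' @param seed RNG seed.
#' @param noise_frac Noise as a fraction of the transition amplitude,
#'   default 0.01.
#' @return A [truth_record] consumed by [gen_melt_curve()].
#' @export
melt_truth <- function(label, Tm, dH = 2e5, seed = 1, noise_frac = 0.01) {
  truth_record(paste0("melt-", label), seed, .noise_sd = noise_frac,
               label = label, Tm = Tm, dH = dH,
               folded_baseline = c(1.6, -0.002),
               unfolded_baseline = c(0.35, -0.0005),
               T_grid = seq(273, 363, by = 0.5))
}

#' Generate a synthetic CD melting curve
#'
#' Two-state [melt_model()] on the scenario's 0.5 K temperature grid plus
#' Gaussian noise scaled to the transition amplitude. Truth record
#' attached as attribute `"truth"`.
#'
#' @param truth A [truth_record] from [melt_truth()].
#' @return A [melt_curve].
#' @export
gen_melt_curve <- function(truth) {
  stopifnot(inherits(truth, "truth_record"))
  set.seed(truth$seed)
  Tg <- truth$T_grid
  y <- melt_model(Tg, truth$Tm, truth$dH, truth$folded_baseline,
                  truth$unfolded_baseline)
  amp <- abs((truth$folded_baseline[1] + truth$folded_baseline[2] * truth$Tm) -
               (truth$unfolded_baseline[1] + truth$unfolded_baseline[2] * truth$Tm))
  if (truth$noise_sd > 0)
    y <- y + rnorm(length(y), 0, truth$noise_sd * amp)
  mc <- melt_curve(Tg, y, label = truth$label)
  attr(mc, "truth") <- truth
  mc
}

#' Generate a synthetic CD spectrum
#'
#' Gaussian-band cartoon of a quadruplex CD spectrum: an antiparallel fold
#' gets a positive band at 295 nm and a negative band at 235 nm; a
#' parallel fold a positive band at 260 nm; `"none"` gives a weak
#' featureless spectrum. Used for topology-classification and
#' difference-spectrum demonstrations.
#'
#' @param topology `"antiparallel"`, `"parallel"` or `"none"`.
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise (signal units), default 0.02.
#' @param label Sample label.
#' @return A [cd_spectrum] on a 220-320 nm grid.
#' @export
gen_cd_spectrum <- function(topology = c("antiparallel", "parallel", "none"),
                            seed = 1, noise_sd = 0.02, label = topology) {
  topology <- match.arg(topology)
  set.seed(seed)
  wl <- seq(220, 320, by = 1)
  band <- function(center, width, height) height * exp(-((wl - center) / width)^2)
  y <- switch(topology,
              antiparallel = band(295, 10, 3) + band(235, 8, -2),
              parallel = band(260, 12, 4) + band(240, 8, -0.8),
              none = rep(0.05, length(wl)))
  if (noise_sd > 0) y <- y + rnorm(length(wl), 0, noise_sd)
  cd_spectrum(wl, y, sample_label = label[1])
}
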
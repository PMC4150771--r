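#!/usr/bin/env Rscript
# Repair kinetics of 6mG adducts: biphasic fits with F-test phase-count
# selection across the study scenarios. Folded quadruplexes (KCl) repair
# in two phases with position-dependent extents (outer > inner tetrad);
# unfolded DNAs (TEA) lose the slow phase and repair almost completely;
# the duplex NarI substrate serves as the double-stranded comparison.

library(quadrepair)
dir.create("results", showWarnings = FALSE)
seed <- 1L
n_rep <- 20L

scenarios <- c("G1-KCl", "G5-KCl", "G1-TEA", "G5-TEA", "NarI")

rows <- lapply(seq_along(scenarios), function(j) {
  scen <- scenarios[j]
  fits <- lapply(seq_len(n_rep), function(i) {
    tr <- repair_truth(scen, seed = seed * 1000L + 40L * j + i)
    select_phase_count(gen_repair_course(tr))
  })
  tr <- repair_truth(scen, seed = 1)
  fx <- get_fixture(tr$dna_label)
  tclass <- if (tr$assay == "NarI") "duplex" else
    classify_tetrad(fx$sequence, fx$methyl_position)$tetrad_class
  np <- vapply(fits, `[[`, integer(1), "n_phases")
  k1 <- vapply(fits, function(f) f$rates[1], numeric(1))
  k2 <- vapply(fits, function(f)
    if (f$n_phases >= 2) f$rates[2] else NA_real_, numeric(1))
  pl <- vapply(fits, function(f) sum(f$amplitudes), numeric(1))
  data.frame(scenario = scen, tetrad_class = tclass,
             modal_phases = as.integer(names(which.max(table(np)))),
             plateau_med = median(pl),
             plateau_true = sum(tr$amplitudes),
             k1_med = median(k1),
             k1_dna_V_e13 = scale_rate(median(k1), tr$dna_conc,
                                       tr$reaction_volume)$value * 1e13,
             ratio_med = median(k1 / k2, na.rm = TRUE),
             replicates = n_rep)
})
tab <- do.call(rbind, rows)

print(tab, digits = 3)
message(sprintf(
  "Extents: G1 %.0f%% vs G5 %.0f%% in K+ (outer > inner); ~%.0f%% in TEA. Fast rates %.1f-%.1f e-13 mol/s.",
  100 * tab$plateau_med[1], 100 * tab$plateau_med[2],
  100 * mean(tab$plateau_med[3:4]),
  min(tab$k1_dna_V_e13[1:2]), max(tab$k1_dna_V_e13[1:2])))

write.csv(format(tab, digits = 8), "results/04_repair_kinetics.csv",
          row.names = FALSE)
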
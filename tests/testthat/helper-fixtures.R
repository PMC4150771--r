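# shared shortcuts for the suite

te_4C <- function() solution_conditions(277.15, label = "TE")
water_20C <- function() water_properties(293.15)

agt_spec <- function() species_spec(21519, 0.744)
g5x_spec <- function() species_spec(6980.7, 0.54)

# run one stoichiometry-recovery replicate for a given scenario/seed
recover_n <- function(scenario, seed) {
  tr <- eq_truth(scenario, seed = seed)
  fit_global_stoichiometry(gen_equilibrium_scans(tr), agt_spec(), g5x_spec(),
                           water_properties(tr$temperature))$n
}
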
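#!/usr/bin/env Rscript
# Stage 4: restrained Monte Carlo ensemble.
#
# Runs the coarse-grained Metropolis sampler on the dimer with hinge
# moves, scoring each conformation by the clash penalty plus the
# inverse-Boltzmann EPR term built from a DEER-inverted distance
# distribution, and checks that the sampled intermonomer distance
# statistics reproduce the underlying truth.

suppressPackageStartupMessages(library(hingeflex))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args)) args[1] else 1)
dir.create("results", showWarnings = FALSE)

model <- make_two_domain_dimer(synthetic_spec(seed = seed))
conf <- conformation(model$chains, model$sites)
g <- default_r_grid()

rows <- list()
inter_pairs <- list(c("A.GF86", "B.GF86"), c("A.J58", "B.J58"))
tgrid <- deer_time_grid(85, periods = 3, dt = 0.05)
for (flex in c(5, 20)) {
  te <- simulate_truth_ensemble(model, flexibility = flex,
                                n_conformers = 300, seed = seed + 7,
                                pairs = inter_pairs)
  truth <- te$distributions[[1]]
  # one DEER measurement per intermonomer pair; all restraints used
  rs <- lapply(seq_along(inter_pairs), function(q) {
    tr <- simulate_trace(te$distributions[[q]], 0.3, 0.05, sigma = 0.005,
                         seed = seed + 11 + q, t_grid = tgrid)
    tk <- tikhonov_invert(background_correct(tr), alpha = 10)
    epr_restraint(model$sites[[inter_pairs[[q]][1]]],
                  model$sites[[inter_pairs[[q]][2]]], tk$p)
  })
  ens <- run_mc(conf, move_set(backbone = model$hinge_bonds,
                               labels = FALSE, delta_deg = 30),
                rs, energy_params(),
                mc_config(n_trials = 20000, seed = seed + 13))
  d_mc <- ens$distance_trace[-(1:5000), 1]
  rows[[length(rows) + 1]] <- data.frame(
    hinge_flex_deg = flex,
    truth_mean = round(dist_mean(truth), 2),
    mc_mean = round(mean(d_mc), 2),
    abs_error = round(abs(mean(d_mc) - dist_mean(truth)), 2),
    acceptance = round(ens$acceptance / ens$n_trials, 3))
  if (flex == 20) {
    write_ensemble_pdb(ens, "results/04_ensemble_flex20.pdb",
                       max_models = 25)
    write.table(ens$energy_trace[seq(1, 20000, by = 20), ],
                "results/04_energy_trace_flex20.tsv", sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/04_recovery.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab, row.names = FALSE)
cat("Restrained hinge sampling recovers the truth intermonomer mean",
    "within", max(tab$abs_error), "Angstrom.\n")
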
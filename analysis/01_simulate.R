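#!/usr/bin/env Rscript
# Stage 1: generate the synthetic inputs for the whole analysis.
#
# The generators emulate the statistical structure of the molecular
# dynamics data behind the thrombin-inhibitor heat-capacity study: four
# energy/temperature scans (holoprotein, apoprotein, ligand in water,
# pure water) with perfectly linear mean energies and AR(1)-correlated
# frames; an ITC-style enthalpy-vs-temperature series from the
# mandatory-coupling equilibrium model; and two-state end-to-end distance
# trajectories of the free ligand.

suppressMessages(library(bindcp))
seed <- 1L
dir.create("results", showWarnings = FALSE)

# Energy scans with the derivative structure of the inhibitor-2 system
# (no hirugen): slopes in kcal/mol/K, five temperatures 283-303 K.
spec <- scan_spec(n_frames = 2000L, noise_sd = 1, ar1 = 0.9)
scan <- gen_energy_scan(spec, seed = seed)
for (sys in names(scan$traces))
  write_energy_table(scan$traces[[sys]],
                     file.path("results", paste0("energies_", sys, ".tsv")))
cat(sprintf("energy scans written; implied true delta_Cp = %.3f kcal/mol/K\n",
            scan$true_delta_cp))

# ITC series from the ligand-3 equilibrium fit, 0.1 kcal/mol noise.
lig3 <- equilibrium_params(17.86, 0.0601, 3.69)
itc <- gen_itc_series(lig3, temperatures = seq(283, 313, by = 5),
                      noise_sd = 0.1, seed = seed)
write_itc_table(itc, "results/itc_series.tsv")
cat(sprintf("ITC series written: %d points, %.0f-%.0f K\n",
            nrow(itc), min(itc$temperature), max(itc$temperature)))

# Two-state ligand trajectories at three temperatures (average fitted
# equilibrium across ligands), saved as distance/energy tables.
avg <- equilibrium_params(17.57, 0.0582, 0)
spec2 <- two_state_spec(equilibrium = avg, n_frames = 10000L)
for (tt in c(283, 298, 313)) {
  tr <- gen_two_state_trajectory(spec2, temperature = tt, seed = seed)
  utils::write.table(
    data.frame(distance_A = tr$distances,
               intra_kcal_per_mol = tr$intra_energy,
               solvent_kcal_per_mol = tr$solvent_energy),
    file.path("results", sprintf("two_state_%dK.tsv", tt)),
    sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("trajectory at %d K: generating extended fraction %.3f\n",
              tt, tr$p_extended))
}
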
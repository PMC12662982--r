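#!/usr/bin/env Rscript
# Stage 1 -- build the synthetic study.
#
# Constructs a flexible toy molecule (a stereogenic carbon with four
# distinct substituents, two of them rotatable chains), a three-conformer
# ensemble of the true configuration, and its inverted-stereocenter decoy;
# simulates one-bond C-H RDCs, 13C Delta-Delta-RCSAs, shielding tensors and
# 1H/13C chemical shifts from a known alignment tensor and known conformer
# populations (0.5/0.3/0.2) at realistic noise (RDC 0.5 Hz, RCSA 2 ppb,
# 13C 0.2 ppm, 1H 0.02 ppm); writes the full on-disk bundle that the later
# stages consume, plus a ground-truth sidecar.

suppressPackageStartupMessages(library(anisofit))

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ens <- make_toy_ensemble(3, 23, seed = 3)
decoy <- make_decoy_configuration(ens, "C1")
pops <- c(c1 = 0.5, c2 = 0.3, c3 = 0.2)
truth <- make_true_tensor(axial_magnitude = 5e-4, rhombicity = 0.3,
                          orientation_seed = 7)

sim <- simulate_dataset(ens, truth, pops, seed = seed)
decoy_sh <- generate_shieldings(decoy, seed = seed + 1000L)
# the decoy's computed shifts differ from the truth's by systematic
# per-atom offsets, as diastereomeric predictions do
decoy_computed <- perturb_computed_shifts(sim$computed, sim$shifts,
                                          seed = seed + 2000L)

write_xyz_ensemble(ens, file.path(out, "truth.xyz"))
write_xyz_ensemble(decoy, file.path(out, "decoy.xyz"))
write_table(sim$rdc, file.path(out, "rdc.csv"))
write_table(sim$rcsa, file.path(out, "rcsa.csv"))
write_table(sim$shieldings, file.path(out, "truth_shieldings.csv"))
write_table(decoy_sh, file.path(out, "decoy_shieldings.csv"))
write_table(energies_for_populations(pops), file.path(out, "truth_energies.csv"))
write_table(energies_for_populations(pops), file.path(out, "decoy_energies.csv"))
# shift tables: shared experimental column, configuration-specific computed
write_table(cbind(sim$shifts, as.data.frame(sim$computed)),
            file.path(out, "truth_shifts.csv"))
write_table(cbind(sim$shifts, as.data.frame(decoy_computed)),
            file.path(out, "decoy_shifts.csv"))

jsonlite::write_json(
  list(seed = seed,
       true_tensor_svec = as.numeric(attr(truth, "svec")),
       true_populations = as.list(pops),
       noise = sim$truth$noise,
       decoy = "stereocenter C1 inverted (H + methyl branch reflected)"),
  file.path(out, "truth_sidecar.json"), auto_unbox = TRUE, digits = NA)

cat("Simulated study written to", out, "\n")
cat(sprintf("  %d conformers, %d atoms (%d C)\n", n_conformers(ens),
            length(ensemble_labels(ens)),
            sum(ensemble_elements(ens) == "C")))
cat(sprintf("  %d RDCs, %d ddRCSAs, %d shifts per configuration\n",
            nrow(sim$rdc), nrow(sim$rcsa), nrow(sim$shifts)))
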
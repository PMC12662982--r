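#!/usr/bin/env Rscript
# Stage 3 -- single-tensor fits and diastereomer discrimination.
#
# Fits one alignment tensor per configuration and data block: RDC-only,
# Delta-Delta-RCSA per reference scheme (the external solvent reference and
# two internal carbon references, mirroring the multi-reference layout of
# RCSA studies), and the simultaneous RDC+RCSA fit. The verdict ranks the
# configurations by combined Q factor. Writes the Q-factor table and the
# machine-readable discrimination report.

suppressPackageStartupMessages(library(anisofit))

dat <- "results/data"
out <- "results"
references <- c("EXTERNAL", "C2", "C5")

rdc <- read_table(file.path(dat, "rdc.csv"), "rdc")
rcsa <- read_table(file.path(dat, "rcsa.csv"), "rcsa")

configs <- lapply(c(truth = "truth", decoy = "decoy"), function(cfg) {
  ens <- read_xyz_ensemble(file.path(dat, paste0(cfg, ".xyz")), cfg)
  pops <- boltzmann_weights(
    read_table(file.path(dat, paste0(cfg, "_energies.csv")), "energy"),
    kind = "G_THERMAL", temperature = 298.15)
  sel <- select_by_population(ens, pops, cutoff = 0.05)
  list(ensemble = sel$ensemble, populations = sel$populations,
       shieldings = read_table(file.path(dat, paste0(cfg, "_shieldings.csv")),
                               "shielding"))
})

report <- discriminate(configs, rdc = rdc, rcsa = rcsa,
                       references = references)
write_report(report, file.path(out, "discrimination_report.json"))

qtab <- do.call(rbind, lapply(names(report$configurations), function(lab) {
  fits <- report$configurations[[lab]]$fits
  do.call(rbind, lapply(names(fits), function(block) {
    f <- fits[[block]]
    data.frame(configuration = lab, block = block,
               q_rdc = f$q_rdc, q_rcsa = f$q_rcsa,
               q_combined = f$q_combined,
               condition_number = f$condition_number)
  }))
}))
write_table(qtab, file.path(out, "q_factors.csv"))

print(report)
cat("\nQ factors by block:\n")
print(qtab, row.names = FALSE, digits = 3)
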
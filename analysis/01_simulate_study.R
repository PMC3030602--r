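#!/usr/bin/env Rscript
# Stage 1: generate the desk-scale synthetic study (two-channel miRNA
# probe signals at three time points, probe-level mRNA ratios, two
# target-prediction tables, pathway gene sets) and write the raw inputs
# that the later stages read back through the data-model layer.

suppressPackageStartupMessages(library(mirpath))

seed <- 20260101L
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- simulate_study(cfg)

for (tp in TIMEPOINTS) {
  write_tsv(sim$probe_signals[[tp]],
            file.path(out, sprintf("probe_signals_%s.tsv", tp)),
            provenance = list(stage = "simulate", seed = seed,
                              timepoint = tp))
  write_tsv(sim$mrna_ratios[[tp]],
            file.path(out, sprintf("mrna_ratios_%s.tsv", tp)),
            provenance = list(stage = "simulate", seed = seed,
                              timepoint = tp))
}
for (db in names(sim$predictions)) {
  write_tsv(sim$predictions[[db]],
            file.path(out, sprintf("predictions_%s.tsv", db)),
            provenance = list(stage = "simulate", seed = seed, db = db))
}
write_gmt(sim$pathways, file.path(out, "pathways.gmt"))
write_universe_sidecar(sim$universe, file.path(out, "universe.json"),
                       extra = list(seed = seed,
                                    planted_pathway =
                                      sim$truth$planted_pathways))
saveRDS(sim$truth, file.path(out, "truth.rds"))

cat("simulated study written to", out, "\n")
cat(sprintf("  universe: %d miRNAs, %d genes, %d pathways\n",
            length(sim$universe$mirna_ids),
            length(sim$universe$gene_ids), length(sim$pathways)))
cat(sprintf("  planted enriched pathway: %s\n",
            sim$truth$planted_pathways))
cat(sprintf("  planted modulated miRNAs per time point: %d\n",
            nrow(sim$truth$modulated_mirnas$ST)))
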
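#!/usr/bin/env Rscript
# Stage 4: inverse-correlation pairing. Crosses the modulated miRNA and
# gene sets (0.6 log-ratio rule) with each prediction database at the
# p < 0.05 cutoff, and intersects consecutive time points to find pairs
# inversely regulated twice.

suppressPackageStartupMessages(library(mirpath))

indir <- "results/simdata"
out <- "results"
meas <- read.delim(file.path(out, "mirna_measurements.tsv"),
                   comment.char = "#")

mirna_sets <- list(); gene_sets <- list()
for (tp in TIMEPOINTS) {
  mirna_sets[[tp]] <- call_modulated_mirnas(meas[meas$timepoint == tp, ])
  ratios <- read.delim(file.path(indir,
                                 sprintf("mrna_ratios_%s.tsv", tp)),
                       comment.char = "#")
  gene_sets[[tp]] <- call_modulated_genes(ratios, timepoint = tp)
}

all_pairs <- list()
for (db in SOURCE_DBS) {
  pred <- read_target_predictions(
    file.path(indir, sprintf("predictions_%s.tsv", db)), db)
  for (tp in TIMEPOINTS) {
    p <- inverse_pairs(mirna_sets[[tp]], gene_sets[[tp]], pred)
    all_pairs[[paste(db, tp)]] <- p
    cat(sprintf("%s %s: %d inverse pairs (%d predictions in)\n",
                db, tp, nrow(p), nrow(pred)))
  }
}
pairs_tsv <- do.call(rbind, all_pairs)
write_tsv(pairs_tsv, file.path(out, "inverse_pairs.tsv"),
          provenance = list(stage = "pairing", target_p_max = 0.05))

rec_st_it <- recurrent_pairs(all_pairs[["microcosm ST"]],
                             all_pairs[["microcosm IT"]])
rec_it_lt <- recurrent_pairs(all_pairs[["microcosm IT"]],
                             all_pairs[["microcosm LT"]])
cat(sprintf("pairs recurring ST+IT: %d; IT+LT: %d (microcosm)\n",
            nrow(rec_st_it), nrow(rec_it_lt)))
if (nrow(rec_st_it)) {
  write_tsv(rec_st_it, file.path(out, "recurrent_pairs_st_it.tsv"),
            provenance = list(stage = "pairing"))
}
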
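# End-to-end orchestration: simulate (or load), normalize, call
# differential sets, pair, enrich, summarize. Every output file carries a
# provenance header and the whole run is a pure function of the
# configuration and seed.

#' Pipeline run configuration
#'
#' @param sim_config A [simulation_config()] describing the input data
#'   (the pipeline currently runs from simulated inputs; individual
#'   stages accept externally read tables directly).
#' @param fc_min miRNA fold-change calling threshold (default 1.5).
#' @param p_max miRNA p-value calling threshold (default 0.01).
#' @param log_thr mRNA log2-ratio threshold for the pairing-rule gene
#'   set (default 0.6).
#' @param target_p_max Prediction p-value cutoff for pairing (default
#'   0.05).
#' @param combined_p_threshold Pathway selection threshold (default
#'   0.05).
#' @param n_trials Permutation trials (default 1000).
#' @param seed Master seed for every random stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim_config = simulation_config(),
                       fc_min = 1.5, p_max = 0.01, log_thr = 0.6,
                       target_p_max = 0.05, combined_p_threshold = 0.05,
                       n_trials = 1000, seed = 1L) {
  stopifnot(fc_min >= 1, p_max >= 0, p_max <= 1, log_thr >= 0,
            target_p_max >= 0, target_p_max <= 1)
  structure(list(sim_config = sim_config, fc_min = fc_min, p_max = p_max,
                 log_thr = log_thr, target_p_max = target_p_max,
                 combined_p_threshold = combined_p_threshold,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Stages in order: simulate inputs, normalize miRNA probe signals and
#' summarize fold inductions, call modulated miRNA and gene sets, build
#' inverse pairs per time point and database, run the pathway analysis,
#' and summarize time-point overlap. If `out_dir` is given, all result
#' tables are written as provenance-stamped TSV/JSON files.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return List with `measurements`, `mirna_sets`, `gene_sets_standard`,
#'   `gene_sets_both_pools`, `pairs`, `enrichment`, `overlap`, `counts`
#'   (rows in/out at each filter), and `config`.
#' @export
run_all <- function(cfg = run_config(), out_dir = NULL) {
  sim_cfg <- cfg$sim_config
  sim_cfg$seed <- cfg$seed
  data <- simulate_study(sim_cfg)
  counts <- list()

  measurements <- list()
  mirna_sets <- list()
  gene_sets_standard <- list()
  gene_sets_both <- list()
  for (tp in TIMEPOINTS) {
    ratios <- normalize_probe_signals(data$probe_signals[[tp]])
    meas <- summarize_mirna_measurements(ratios, tp)
    check_universe_membership(meas, data$universe)
    measurements[[tp]] <- meas
    mirna_sets[[tp]] <- call_modulated_mirnas(meas, fc_min = cfg$fc_min,
                                              p_max = cfg$p_max)
    gene_sets_standard[[tp]] <-
      call_modulated_genes(data$mrna_ratios[[tp]], log_thr = cfg$log_thr,
                           timepoint = tp)
    gene_sets_both[[tp]] <-
      call_modulated_genes_both_pools(data$mrna_ratios[[tp]],
                                      fc_min = cfg$fc_min, timepoint = tp)
    counts[[paste0("mirnas_measured_", tp)]] <- nrow(meas)
    counts[[paste0("mirnas_modulated_", tp)]] <-
      nrow(mirna_sets[[tp]]$members)
    counts[[paste0("genes_modulated_standard_", tp)]] <-
      nrow(gene_sets_standard[[tp]]$members)
    counts[[paste0("genes_modulated_both_pools_", tp)]] <-
      nrow(gene_sets_both[[tp]]$members)
  }

  pairs <- list()
  for (db in names(data$predictions)) {
    for (tp in TIMEPOINTS) {
      key <- paste(db, tp, sep = "_")
      pairs[[key]] <- inverse_pairs(mirna_sets[[tp]],
                                    gene_sets_standard[[tp]],
                                    data$predictions[[db]],
                                    p_max = cfg$target_p_max)
      counts[[paste0("pairs_", key)]] <- nrow(pairs[[key]])
    }
  }

  enrichment <- run_pathway_analysis(
    data$pathways, mirna_sets, gene_sets_both, data$predictions,
    data$universe,
    cfg = permutation_config(n_trials = cfg$n_trials, seed = cfg$seed),
    p_threshold = cfg$combined_p_threshold)
  counts$pathways_selected <- nrow(enrichment$selected)

  overlap <- list()
  for (db in names(data$predictions)) {
    sel <- enrichment$selected[enrichment$selected$source_db == db, ,
                               drop = FALSE]
    overlap[[db]] <- overlap_summary(
      lapply(setNames(TIMEPOINTS, TIMEPOINTS), function(tp) {
        sel$pathway_id[sel$timepoint == tp]
      }))
  }

  result <- list(measurements = measurements, mirna_sets = mirna_sets,
                 gene_sets_standard = gene_sets_standard,
                 gene_sets_both_pools = gene_sets_both,
                 pairs = pairs, enrichment = enrichment,
                 overlap = overlap, counts = counts, config = cfg,
                 truth = data$truth)
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

#' Write pipeline outputs to a directory
#'
#' @param result Result list from [run_all()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  prov <- list(package = "mirpath",
               version = as.character(utils::packageVersion("mirpath")),
               seed = cfg$seed,
               fc_min = cfg$fc_min, p_max = cfg$p_max,
               log_thr = cfg$log_thr, target_p_max = cfg$target_p_max,
               combined_p_threshold = cfg$combined_p_threshold,
               n_trials = cfg$n_trials)
  meas <- do.call(rbind, result$measurements)
  write_tsv(meas, file.path(out_dir, "mirna_measurements.tsv"), prov)
  sets <- do.call(rbind, lapply(result$mirna_sets, function(s) {
    cbind(s$members, timepoint = s$timepoint, rule_tag = s$rule_tag,
          stringsAsFactors = FALSE)
  }))
  write_tsv(sets, file.path(out_dir, "modulated_mirnas.tsv"), prov)
  gsets <- do.call(rbind, lapply(
    c(result$gene_sets_standard, result$gene_sets_both_pools),
    function(s) cbind(s$members, timepoint = s$timepoint,
                      rule_tag = s$rule_tag, stringsAsFactors = FALSE)))
  write_tsv(gsets, file.path(out_dir, "modulated_genes.tsv"), prov)
  all_pairs <- do.call(rbind, result$pairs)
  write_tsv(all_pairs, file.path(out_dir, "inverse_pairs.tsv"), prov)
  write_tsv(result$enrichment$results,
            file.path(out_dir, "enrichment_results.tsv"), prov)
  write_tsv(result$enrichment$selected,
            file.path(out_dir, "enrichment_selected.tsv"), prov)
  jsonlite::write_json(
    list(provenance = prov, overlap = result$overlap,
         counts = result$counts),
    file.path(out_dir, "run_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
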
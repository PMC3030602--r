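# Seeded generator for every input the pipeline consumes, with the
# statistical structure the analysis assumes: a lognormal two-channel
# intensity model with probe-level Gaussian noise on the log2 scale,
# probe-level mRNA ratios with multi-probe genes, sparse miRNA->gene
# prediction tables with per-prediction p-values, and pathway gene sets
# with optional planted enrichment.

#' Simulation configuration
#'
#' The `"desk"` preset shrinks the emulated universes (200 miRNAs, 2000
#' genes, 30 pathways) for routine testing; the `"full"` preset matches
#' the nominal design scale (566-miRNA chip, 20461-gene array, 117
#' pathways). Any field can be overridden by name.
#'
#' @param preset `"desk"` or `"full"`.
#' @param ... Named overrides of individual fields.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(preset = c("desk", "full"), ..., seed = 1L) {
  preset <- match.arg(preset)
  cfg <- list(
    n_mirnas = 200L,
    n_genes = 2000L,
    n_pathways = 30L,
    pathway_size_range = c(20L, 60L),
    n_modulated_mirnas = 10L,    # per direction, per time point
    n_modulated_genes = 190L,    # per time point (both directions)
    planted_pathway_count = 1L,
    planted_gene_fraction = 0.35, # modulated fraction of a planted pathway
    n_planted_pairs = 10L,       # guaranteed inverse pairs per time point
    target_density = 0.02,       # background edge probability per db
    target_enrichment = 6,       # edge-density factor inside planted sets
    probe_noise_sd = 0.1,        # log2 probe noise, both platforms
    probes_per_mirna = 8L,
    n_replicates = 2L,
    probes_per_gene_range = c(1L, 3L),
    mirna_fi_range = c(1.5, 6),  # planted |fold induction| range
    gene_fc_range = c(1.6, 4),   # planted mRNA fold-change range
    channel_bias = 0.25,         # constant log2 dye offset on cy3
    background_range = c(20, 60),
    seed = as.integer(seed))
  if (preset == "full") {
    cfg$n_mirnas <- 566L
    cfg$n_genes <- 20461L
    cfg$n_pathways <- 117L
    cfg$n_modulated_genes <- 1955L
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  cfg$seed <- as.integer(seed)
  stopifnot(cfg$n_mirnas > 0, cfg$n_genes > 0, cfg$n_pathways > 0,
            cfg$target_density > 0, cfg$target_density < 1,
            cfg$target_enrichment >= 1)
  if (2L * cfg$n_modulated_mirnas > cfg$n_mirnas ||
      cfg$n_modulated_genes > cfg$n_genes) {
    stop("planted counts exceed the universe")
  }
  structure(cfg, class = "simulation_config")
}

.sim_ids <- function(prefix, n) {
  sprintf("%s%04d", prefix, seq_len(n))
}

# Sparse background prediction table: per miRNA a binomial number of
# target genes at the background density; p-values uniform on (0, 0.05]
# mimicking a database that only stores predictions below its own cutoff.
.sim_predictions <- function(mirna_ids, gene_ids, density, source_db) {
  k <- stats::rbinom(length(mirna_ids), length(gene_ids), density)
  rows <- lapply(seq_along(mirna_ids), function(i) {
    if (k[i] == 0L) return(NULL)
    data.frame(mirna_id = mirna_ids[i],
               gene_id = sample(gene_ids, k[i]),
               p_value = runif(k[i], 1e-6, 0.05),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mirna_id = character(), gene_id = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  }
  out$source_db <- source_db
  out
}

.add_edges <- function(pred, mirnas, genes, prob, p_range, source_db) {
  if (!length(mirnas) || !length(genes)) return(pred)
  grid <- expand.grid(mirna_id = mirnas, gene_id = genes,
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < prob
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(pred)
  grid$p_value <- runif(nrow(grid), p_range[1], p_range[2])
  grid$source_db <- source_db
  rbind(pred, grid)
}

#' Simulate a complete profiling study
#'
#' Generates, for the three time points, the raw two-channel miRNA probe
#' signals, the probe-level mRNA log ratios, two target-prediction tables,
#' a pathway GMT-style list and the measurement universe. Planted
#' modulated miRNAs receive log2 shifts of +/- log2(FI) with FI drawn in
#' `mirna_fi_range`; planted inverse pairs get guaranteed prediction edges
#' with p < 0.01; planted pathways receive enriched edge density from
#' modulated miRNAs and a raised share of modulated member genes. All
#' output is fully determined by `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List with `probe_signals`, `mrna_ratios` (per-time-point
#'   lists), `predictions` (per-database list), `pathways`, `universe`,
#'   and `truth` (the planted configuration).
#' @export
simulate_study <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  mirna_ids <- .sim_ids("mmu-miR-sim-", cfg$n_mirnas)
  gene_ids <- .sim_ids("GENE", cfg$n_genes)
  universe <- make_universe(mirna_ids, gene_ids)

  # pathways: sizes uniform in range, members drawn from the universe
  sizes <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                  cfg$n_pathways, replace = TRUE)
  pathways <- lapply(sizes, function(s) sample(gene_ids, s))
  names(pathways) <- .sim_ids("WPSIM", cfg$n_pathways)
  attr(pathways, "description") <-
    setNames(paste("synthetic pathway", seq_len(cfg$n_pathways)),
             names(pathways))
  planted_pathways <- head(names(pathways), cfg$planted_pathway_count)

  truth <- list(planted_pathways = planted_pathways,
                modulated_mirnas = list(), modulated_genes = list(),
                planted_pairs = list())
  probe_signals <- list()
  mrna_ratios <- list()
  mod_mirnas_union <- character()

  log2_range <- log2(cfg$mirna_fi_range)
  for (tp in TIMEPOINTS) {
    # --- planted modulated miRNAs -------------------------------------
    n_mod <- cfg$n_modulated_mirnas
    chosen <- if (n_mod > 0) sample(mirna_ids, 2L * n_mod) else character()
    up <- head(chosen, n_mod)
    down <- utils::tail(chosen, n_mod)
    fi <- 2^runif(length(chosen), log2_range[1], log2_range[2])
    delta <- setNames(rep(0, cfg$n_mirnas), mirna_ids)
    if (length(chosen)) {
      delta[up] <- log2(fi[seq_along(up)])
      delta[down] <- -log2(fi[length(up) + seq_along(down)])
    }
    truth$modulated_mirnas[[tp]] <- data.frame(
      mirna_id = chosen,
      direction = rep(c("up", "down"), c(length(up), length(down))),
      fold_induction = 2^delta[chosen],
      stringsAsFactors = FALSE)
    mod_mirnas_union <- union(mod_mirnas_union, chosen)

    # --- two-channel probe signals ------------------------------------
    baseline <- runif(cfg$n_mirnas, 6, 12)
    grid <- expand.grid(probe_index = seq_len(cfg$probes_per_mirna),
                        replicate = seq_len(cfg$n_replicates),
                        channel = c("cy3_ova", "cy5_pbs"),
                        mirna_idx = seq_len(cfg$n_mirnas),
                        stringsAsFactors = FALSE)
    probe_eff <- rnorm(cfg$n_mirnas * cfg$probes_per_mirna, 0, 0.3)
    eff_idx <- (grid$mirna_idx - 1L) * cfg$probes_per_mirna +
      grid$probe_index
    log2_signal <- baseline[grid$mirna_idx] + probe_eff[eff_idx] +
      ifelse(grid$channel == "cy3_ova",
             delta[grid$mirna_idx] + cfg$channel_bias, 0) +
      rnorm(nrow(grid), 0, cfg$probe_noise_sd)
    background <- runif(nrow(grid), cfg$background_range[1],
                        cfg$background_range[2])
    probe_signals[[tp]] <- data.frame(
      mirna_id = mirna_ids[grid$mirna_idx],
      probe_index = grid$probe_index,
      replicate = grid$replicate,
      channel = grid$channel,
      raw = 2^log2_signal + background,
      background = background,
      stringsAsFactors = FALSE)

    # --- planted modulated genes and probe-level mRNA ratios ----------
    n_mod_g <- cfg$n_modulated_genes
    planted_members <- unlist(pathways[planted_pathways], use.names = FALSE)
    n_from_planted <- min(round(cfg$planted_gene_fraction *
                                  length(planted_members)), n_mod_g)
    mod_genes <- unique(c(
      if (n_from_planted > 0) sample(planted_members, n_from_planted),
      sample(setdiff(gene_ids, planted_members),
             max(n_mod_g - n_from_planted, 0L))))
    g_dir <- sample(rep(c(1, -1), length.out = length(mod_genes)))
    g_eff <- setNames(rep(0, cfg$n_genes), gene_ids)
    g_eff[mod_genes] <- g_dir * runif(length(mod_genes),
                                      log2(cfg$gene_fc_range[1]),
                                      log2(cfg$gene_fc_range[2]))
    truth$modulated_genes[[tp]] <- data.frame(
      gene_id = mod_genes,
      direction = ifelse(g_dir > 0, "up", "down"),
      log2_fc = g_eff[mod_genes],
      stringsAsFactors = FALSE)
    n_probes <- sample(seq(cfg$probes_per_gene_range[1],
                           cfg$probes_per_gene_range[2]),
                       cfg$n_genes, replace = TRUE)
    gene_rep <- rep(seq_len(cfg$n_genes), n_probes)
    n_rows <- length(gene_rep)
    mrna_ratios[[tp]] <- data.frame(
      gene_id = gene_ids[gene_rep],
      probe_id = sprintf("%s_probe%d_%s", gene_ids[gene_rep],
                         sequence(n_probes), tp),
      log_ratio_pool1 = g_eff[gene_rep] +
        rnorm(n_rows, 0, cfg$probe_noise_sd),
      log_ratio_pool2 = g_eff[gene_rep] +
        rnorm(n_rows, 0, cfg$probe_noise_sd),
      stringsAsFactors = FALSE)

    # --- guaranteed inverse pairs (recorded; edges added below) -------
    if (cfg$n_planted_pairs > 0 && length(chosen) && length(mod_genes)) {
      g_up <- mod_genes[g_dir > 0]
      g_down <- mod_genes[g_dir < 0]
      n_half <- ceiling(cfg$n_planted_pairs / 2)
      pairs <- rbind(
        data.frame(mirna_id = sample(up, min(n_half, length(up)),
                                     replace = TRUE),
                   gene_id = sample(g_down, min(n_half, length(g_down))),
                   stringsAsFactors = FALSE),
        data.frame(mirna_id = sample(down, min(n_half, length(down)),
                                     replace = TRUE),
                   gene_id = sample(g_up, min(n_half, length(g_up))),
                   stringsAsFactors = FALSE))
      pairs <- pairs[!duplicated(paste(pairs$mirna_id, pairs$gene_id)), ,
                     drop = FALSE]
      truth$planted_pairs[[tp]] <- pairs
    } else {
      truth$planted_pairs[[tp]] <- data.frame(mirna_id = character(),
                                              gene_id = character(),
                                              stringsAsFactors = FALSE)
    }
  }

  # --- prediction databases (static across time points) ---------------
  predictions <- list()
  for (db in SOURCE_DBS) {
    pred <- .sim_predictions(mirna_ids, gene_ids, cfg$target_density, db)
    for (pw in planted_pathways) {
      pred <- .add_edges(pred, mod_mirnas_union, pathways[[pw]],
                         prob = min(1, cfg$target_density *
                                      cfg$target_enrichment),
                         p_range = c(1e-4, 0.01), source_db = db)
    }
    if (db == "microcosm") {
      for (tp in TIMEPOINTS) {
        pp <- truth$planted_pairs[[tp]]
        if (nrow(pp)) {
          pp$p_value <- runif(nrow(pp), 1e-4, 0.01)
          pp$source_db <- db
          pred <- rbind(pred, pp)
        }
      }
    }
    predictions[[db]] <- dedup_predictions(pred)
  }

  list(probe_signals = probe_signals, mrna_ratios = mrna_ratios,
       predictions = predictions, pathways = pathways,
       universe = universe, truth = truth, config = cfg)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Emulates the validation design: a panel of assays measured at the
#' three time points in treated (OVA) and control (PBS) groups of mice,
#' normalized to a flat reference assay. The treated-group target Ct is
#' shifted by `-log2(FC)` so that the 2^-ddCt computation recovers the
#' planted fold change exactly at zero noise.
#'
#' @param planted_fc Data frame with columns `assay_id`, `timepoint`,
#'   `fc` (planted OVA/PBS fold change per assay and time point).
#' @param n_mice Mice per group (default 6).
#' @param noise_sd Gaussian replicate noise on Ct, in cycles (default 0).
#' @param baseline_ct Target-assay baseline Ct (default 25).
#' @param reference_ct Reference-assay Ct (default 20).
#' @param reference_id Reference assay name (default `"U6"`).
#' @param seed Integer seed.
#' @return List with `ct_table` (long format, see [delta_ct_table()]) and
#'   `truth` (the planted fold changes).
#' @export
simulate_ct <- function(planted_fc, n_mice = 6, noise_sd = 0,
                        baseline_ct = 25, reference_ct = 20,
                        reference_id = "U6", seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(planted_fc))) {
    a <- planted_fc$assay_id[i]
    tp <- planted_fc$timepoint[i]
    fc <- planted_fc$fc[i]
    for (grp in c("PBS", "OVA")) {
      shift <- if (grp == "OVA") -log2(fc) else 0
      for (mouse in seq_len(n_mice)) {
        sid <- sprintf("%s_%s_m%d", grp, tp, mouse)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = grp, timepoint = tp,
          assay_id = c(a, reference_id),
          is_reference = c(FALSE, TRUE),
          ct = c(baseline_ct + shift + rnorm(1, 0, noise_sd),
                 reference_ct + rnorm(1, 0, noise_sd)),
          stringsAsFactors = FALSE)
      }
    }
  }
  ct_table <- do.call(rbind, rows)
  # one reference row per (sample, assay pairing) duplicates the reference
  # within a sample when several assays share it; collapse to one row
  key <- paste(ct_table$sample_id, ct_table$assay_id, ct_table$ct)
  ct_table <- ct_table[!duplicated(key), , drop = FALSE]
  rownames(ct_table) <- NULL
  list(ct_table = ct_table, truth = planted_fc)
}
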
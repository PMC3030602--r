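# Pathway enrichment combining a permutation-based miRNA-target statistic
# with a hypergeometric mRNA statistic via Stouffer's method.
#
# For each pathway the observed statistic is the number of (miRNA, gene)
# pairs such that the miRNA is modulated, the gene belongs to the pathway
# and is a predicted target of the miRNA. Its null distribution is
# estimated by redrawing the modulated miRNA set uniformly at random
# (same size, without replacement) from the chip universe.

#' Permutation configuration
#'
#' @param n_trials Number of random redraws of the modulated miRNA set
#'   (default 1000).
#' @param seed Master integer seed; per-(timepoint, database) streams are
#'   derived from it by stable label hashing.
#' @return List of class `permutation_config`.
#' @export
permutation_config <- function(n_trials = 1000, seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  structure(list(n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "permutation_config")
}

#' Derive a stream seed from a master seed and a label
#'
#' Deterministic polynomial hash of the label folded into the master seed,
#' kept below 2^31 so it is a valid R integer seed. Used to give every
#' (timepoint, database) combination its own reproducible permutation
#' stream.
#'
#' @param master Integer master seed.
#' @param label Character scalar.
#' @return Integer seed.
#' @export
label_seed <- function(master, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 1000003
  as.integer((as.numeric(master) %% 1000000) * 1009 + h) %% .Machine$integer.max
}

#' Count modulated-miRNA target pairs in a pathway
#'
#' Each qualifying (miRNA, gene) pair counts exactly once: the miRNA is in
#' the modulated set, the gene is a pathway member, and the prediction
#' table links the two.
#'
#' @param pathway_genes Character vector of pathway gene symbols.
#' @param modulated_mirna_ids Character vector of modulated miRNA ids.
#' @param predictions De-duplicated prediction data frame (`mirna_id`,
#'   `gene_id`).
#' @return Non-negative integer count.
#' @export
count_target_pairs <- function(pathway_genes, modulated_mirna_ids,
                               predictions) {
  sum(predictions$mirna_id %in% modulated_mirna_ids &
        predictions$gene_id %in% pathway_genes)
}

# Per-miRNA target counts inside each pathway: a |universe| x |pathways|
# integer matrix M with M[m, p] = number of predicted targets of miRNA m
# that belong to pathway p. Observed and permuted pair counts are column
# sums over the rows of a (sampled) modulated set.
.pair_count_matrix <- function(pathways, universe_mirnas, predictions) {
  mat <- matrix(0L, nrow = length(universe_mirnas),
                ncol = length(pathways),
                dimnames = list(universe_mirnas, names(pathways)))
  pred <- predictions[predictions$mirna_id %in% universe_mirnas, ,
                      drop = FALSE]
  for (p in names(pathways)) {
    hits <- pred[pred$gene_id %in% pathways[[p]], , drop = FALSE]
    if (nrow(hits)) {
      tab <- table(hits$mirna_id)
      mat[names(tab), p] <- as.integer(tab)
    }
  }
  mat
}

#' Permutation p-value for pathway miRNA-target enrichment
#'
#' Estimates, over `cfg$n_trials` uniform redraws of the modulated miRNA
#' set (same size, without replacement, from the chip universe), the
#' proportion of trials whose pair count is as high as (>=) the observed
#' one. The raw proportion is reported; an exact zero is clamped to
#' `1 / (2 * n_trials)` downstream, before the normal-score transform.
#'
#' @param pathway_genes Character vector of pathway gene symbols.
#' @param modulated_mirna_ids Modulated miRNA ids (subset of the universe).
#' @param universe_mirnas Chip universe of miRNA ids.
#' @param predictions De-duplicated prediction data frame.
#' @param cfg A [permutation_config()].
#' @return List with `p_mirna` and `observed_pairs`.
#' @export
permutation_pvalue <- function(pathway_genes, modulated_mirna_ids,
                               universe_mirnas, predictions,
                               cfg = permutation_config()) {
  if (!all(modulated_mirna_ids %in% universe_mirnas)) {
    stop("modulated miRNAs are not all members of the universe")
  }
  pw <- list(pw = pathway_genes)
  mat <- .pair_count_matrix(pw, universe_mirnas, predictions)
  observed <- sum(mat[modulated_mirna_ids, 1L])
  m <- length(modulated_mirna_ids)
  set.seed(cfg$seed)
  counts <- vapply(seq_len(cfg$n_trials), function(i) {
    sum(mat[sample.int(nrow(mat), m), 1L])
  }, numeric(1))
  list(p_mirna = sum(counts >= observed) / cfg$n_trials,
       observed_pairs = observed)
}

#' Hypergeometric p-value for pathway mRNA enrichment
#'
#' Upper-tail probability P(X >= k) of the overlap between the modulated
#' gene set and the pathway, with the chip gene content as the reference
#' population. Pathway genes outside the universe are discarded before
#' computation.
#'
#' @param pathway_genes Character vector of pathway gene symbols.
#' @param modulated_gene_ids Modulated gene symbols (subset of universe).
#' @param gene_universe Chip gene universe.
#' @return Probability in [0, 1].
#' @export
hypergeom_pvalue <- function(pathway_genes, modulated_gene_ids,
                             gene_universe) {
  pw <- intersect(pathway_genes, gene_universe)
  mod <- intersect(modulated_gene_ids, gene_universe)
  if (!length(pw)) {
    warning("pathway has no genes in the universe: p set to 1")
    return(1)
  }
  k <- length(intersect(pw, mod))
  phyper(k - 1, m = length(mod),
         n = length(gene_universe) - length(mod),
         k = length(pw), lower.tail = FALSE)
}

#' Combine two p-values by Stouffer's method
#'
#' Equal-weight inverse-normal combination:
#' `z_i = qnorm(1 - p_i)`, `p = 1 - pnorm((z_1 + z_2) / sqrt(2))`.
#' Symmetric in its arguments and monotone in each.
#'
#' @param p_mirna,p_mrna Probabilities in [0, 1] (vectorized).
#' @return Combined probability.
#' @export
stouffer_combine <- function(p_mirna, p_mrna) {
  for (p in list(p_mirna, p_mrna)) {
    if (any(!is.finite(p) | p < 0 | p > 1)) {
      stop("p-values must lie in [0, 1]")
    }
  }
  z <- qnorm(1 - p_mirna) + qnorm(1 - p_mrna)
  1 - pnorm(z / sqrt(2))
}

#' Run the full pathway analysis
#'
#' For every (time point, database) combination: observed pair counts per
#' pathway, permutation p-values from a shared set of null draws (each
#' trial redraws one modulated set and scores all pathways against it),
#' hypergeometric mRNA p-values, Stouffer combination, and selection at
#' `p_threshold`. A Benjamini-Hochberg column is included for reference
#' but takes no part in selection.
#'
#' @param pathways Named list of gene sets (see [read_gmt()]).
#' @param mirna_sets List of `modulated_set` objects (kind `"mirna"`), one
#'   per time point.
#' @param gene_sets List of `modulated_set` objects (kind `"mrna"`,
#'   both-pools rule), one per time point, same order.
#' @param predictions_by_db Named list of de-duplicated prediction data
#'   frames, one per database.
#' @param universe A `mirpath_universe`.
#' @param cfg A [permutation_config()].
#' @param p_threshold Combined p-value selection threshold (default 0.05,
#'   strict).
#' @return List with `results` (full table: one row per pathway, time
#'   point and database) and `selected` (the subset with
#'   `p_combined < p_threshold`).
#' @export
run_pathway_analysis <- function(pathways, mirna_sets, gene_sets,
                                 predictions_by_db, universe,
                                 cfg = permutation_config(),
                                 p_threshold = 0.05) {
  tps_mirna <- vapply(mirna_sets, function(s) s$timepoint, character(1))
  tps_gene <- vapply(gene_sets, function(s) s$timepoint, character(1))
  if (!identical(tps_mirna, tps_gene)) {
    stop("mirna_sets and gene_sets time points differ")
  }
  clamp <- 1 / (2 * cfg$n_trials)
  res <- list()
  for (db in names(predictions_by_db)) {
    pred <- predictions_by_db[[db]]
    mat <- .pair_count_matrix(pathways, universe$mirna_ids, pred)
    for (i in seq_along(mirna_sets)) {
      tp <- unname(tps_mirna[i])
      mod_mirnas <- set_members(mirna_sets[[i]])
      if (!all(mod_mirnas %in% universe$mirna_ids)) {
        stop("modulated miRNAs outside the chip universe at ", tp)
      }
      mod_genes <- set_members(gene_sets[[i]])
      observed <- if (length(mod_mirnas)) {
        unname(colSums(mat[mod_mirnas, , drop = FALSE]))
      } else {
        numeric(ncol(mat))
      }
      m <- length(mod_mirnas)
      exceed <- numeric(ncol(mat))
      set.seed(label_seed(cfg$seed, paste(tp, db, sep = ":")))
      for (trial in seq_len(cfg$n_trials)) {
        trial_counts <- if (m) {
          colSums(mat[sample.int(nrow(mat), m), , drop = FALSE])
        } else {
          numeric(ncol(mat))
        }
        exceed <- exceed + (trial_counts >= observed)
      }
      p_mirna <- exceed / cfg$n_trials
      p_mrna <- unname(vapply(pathways, hypergeom_pvalue, numeric(1),
                              modulated_gene_ids = mod_genes,
                              gene_universe = universe$gene_ids))
      p_combined <- stouffer_combine(pmax(p_mirna, clamp), p_mrna)
      res[[paste(tp, db)]] <- data.frame(
        pathway_id = names(pathways),
        timepoint = tp,
        source_db = db,
        observed_pairs = as.integer(observed),
        p_mirna = p_mirna,
        p_mrna = p_mrna,
        p_combined = p_combined,
        p_combined_bh = p.adjust(p_combined, method = "BH"),
        n_trials = cfg$n_trials,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  list(results = results,
       selected = results[results$p_combined < p_threshold, ,
                          drop = FALSE])
}

#' Time-point overlap of selected pathways
#'
#' Partitions the union of the per-time-point selections by the number of
#' time points at which each pathway was selected.
#'
#' @param selected_by_tp Named list of three character vectors of pathway
#'   ids (one per time point).
#' @return List with `exactly_1`, `exactly_2`, `exactly_3` counts and
#'   `all_three` (the ids selected at every time point).
#' @export
overlap_summary <- function(selected_by_tp) {
  if (length(selected_by_tp) != 3) stop("expected three selection sets")
  ids <- unique(unlist(selected_by_tp))
  n_tp <- vapply(ids, function(id) {
    sum(vapply(selected_by_tp, function(s) id %in% s, logical(1)))
  }, integer(1))
  list(exactly_1 = sum(n_tp == 1L),
       exactly_2 = sum(n_tp == 2L),
       exactly_3 = sum(n_tp == 3L),
       all_three = sort(ids[n_tp == 3L]))
}
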
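# Inverse-correlation pairing of modulated miRNAs and mRNAs against a
# target-prediction table. A pair is reported when the miRNA and the gene
# change in opposite directions at the same time point and the prediction
# database supports the interaction below the p-value cutoff.

#' Inversely correlated miRNA-mRNA pairs at one time point
#'
#' Crosses the modulated miRNA and gene sets with the target predictions:
#' a pair is emitted iff the (miRNA, gene) interaction is predicted with
#' p-value strictly below `p_max` and the two directions oppose (miRNA up
#' with gene down, or the reverse).
#'
#' @param mirna_set `modulated_set` of kind `"mirna"`.
#' @param gene_set `modulated_set` of kind `"mrna"` (the log-ratio rule
#'   set is the intended input).
#' @param predictions De-duplicated prediction data frame (`mirna_id`,
#'   `gene_id`, `p_value`, `source_db`).
#' @param p_max Prediction p-value cutoff (default 0.05, strict).
#' @return Data frame sorted by (mirna_id, gene_id): `mirna_id`,
#'   `gene_id`, `timepoint`, `mirna_direction`, `gene_direction`,
#'   `mirna_fi`, `gene_fi`, `prediction_p`, `source_db`.
#' @export
inverse_pairs <- function(mirna_set, gene_set, predictions,
                          p_max = 0.05) {
  if (mirna_set$timepoint != gene_set$timepoint) {
    stop("time-point mismatch: ", mirna_set$timepoint, " vs ",
         gene_set$timepoint)
  }
  mm <- mirna_set$members
  gm <- gene_set$members
  pred <- predictions[predictions$p_value < p_max, , drop = FALSE]
  mi <- match(pred$mirna_id, mm$id)
  gi <- match(pred$gene_id, gm$id)
  keep <- !is.na(mi) & !is.na(gi) &
    mm$direction[mi] != gm$direction[gi]
  out <- data.frame(mirna_id = pred$mirna_id[keep],
                    gene_id = pred$gene_id[keep],
                    timepoint = rep(mirna_set$timepoint, sum(keep)),
                    mirna_direction = mm$direction[mi[keep]],
                    gene_direction = gm$direction[gi[keep]],
                    mirna_fi = mm$fold_induction[mi[keep]],
                    gene_fi = gm$fold_induction[gi[keep]],
                    prediction_p = pred$p_value[keep],
                    source_db = pred$source_db[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairs recurring at two time points
#'
#' Intersects two pair tables on (mirna_id, gene_id), keeping the
#' per-time-point directions - which may flip between time points.
#'
#' @param pairs_a,pairs_b Pair tables from [inverse_pairs()] at two
#'   different time points.
#' @return Data frame with one row per recurring pair: identifiers,
#'   prediction p-value (minimum of the two, normally identical), and
#'   suffixed direction/fold-induction columns for each time point.
#' @export
recurrent_pairs <- function(pairs_a, pairs_b) {
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs_a) || !nrow(pairs_b)) return(empty)
  tp_a <- unique(pairs_a$timepoint)
  tp_b <- unique(pairs_b$timepoint)
  key_a <- paste(pairs_a$mirna_id, pairs_a$gene_id, sep = "\r")
  key_b <- paste(pairs_b$mirna_id, pairs_b$gene_id, sep = "\r")
  common <- intersect(key_a, key_b)
  if (!length(common)) return(empty)
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  out <- data.frame(
    mirna_id = pairs_a$mirna_id[ia],
    gene_id = pairs_a$gene_id[ia],
    prediction_p = pmin(pairs_a$prediction_p[ia],
                        pairs_b$prediction_p[ib]),
    source_db = pairs_a$source_db[ia],
    stringsAsFactors = FALSE)
  out[[paste0("mirna_direction_", tolower(tp_a))]] <-
    pairs_a$mirna_direction[ia]
  out[[paste0("mirna_direction_", tolower(tp_b))]] <-
    pairs_b$mirna_direction[ib]
  out[[paste0("mirna_fi_", tolower(tp_a))]] <- pairs_a$mirna_fi[ia]
  out[[paste0("mirna_fi_", tolower(tp_b))]] <- pairs_b$mirna_fi[ib]
  out[[paste0("gene_fi_", tolower(tp_a))]] <- pairs_a$gene_fi[ia]
  out[[paste0("gene_fi_", tolower(tp_b))]] <- pairs_b$gene_fi[ib]
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
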
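# Bench-assay arithmetic used for validation: qPCR relative
# quantification (2^-ddCt), microarray/qPCR concordance, and luciferase
# reporter knockdown ratios.

#' Reference-normalized delta-Ct
#'
#' dCt = mean(target Ct) - mean over reference assays of their mean Ct.
#' mRNA assays use two housekeeping genes (B2m, Hprt1); miRNA assays use
#' the single U6 small nuclear RNA. References are aggregated by the
#' arithmetic mean of their per-assay mean Cts.
#'
#' @param target_cts Numeric vector of target Ct values (cycles) for one
#'   sample.
#' @param reference_cts List of numeric vectors, one per reference assay
#'   in the same sample (at least one).
#' @return delta-Ct in cycles.
#' @export
delta_ct <- function(target_cts, reference_cts) {
  if (!length(reference_cts)) stop("missing reference assay")
  if (!is.list(reference_cts)) reference_cts <- list(reference_cts)
  ref_means <- vapply(reference_cts, mean, numeric(1))
  mean(target_cts) - mean(ref_means)
}

#' Fold change by the 2^-ddCt method
#'
#' ddCt = mean(dCt treated) - mean(dCt control); the fold change is
#' 2^-ddCt, so a treated Ct two cycles below control gives fold change 4.
#'
#' @param dct_treated Numeric vector of per-sample delta-Ct values in the
#'   treated (OVA) group.
#' @param dct_control Numeric vector of delta-Ct values in the control
#'   (PBS) group.
#' @return Positive fold change.
#' @export
fold_change_ddct <- function(dct_treated, dct_control) {
  if (!length(dct_treated) || !length(dct_control)) {
    stop("both groups must be non-empty")
  }
  2^-(mean(dct_treated) - mean(dct_control))
}

#' Per-sample delta-Ct table
#'
#' Computes the reference-normalized delta-Ct for every non-reference
#' assay in every sample of a long-format Ct table.
#'
#' @param ct_table Data frame with columns `sample_id`, `group`,
#'   `timepoint`, `assay_id`, `is_reference` (logical), `ct`.
#' @return Data frame with `sample_id`, `group`, `timepoint`, `assay_id`,
#'   `delta_ct`.
#' @export
delta_ct_table <- function(ct_table) {
  required <- c("sample_id", "group", "timepoint", "assay_id",
                "is_reference", "ct")
  missing <- setdiff(required, names(ct_table))
  if (length(missing)) {
    stop("Ct table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(ct_table$ct <= 0 | ct_table$ct >= 45)) {
    stop("Ct values must lie in (0, 45)")
  }
  out <- list()
  for (s in unique(ct_table$sample_id)) {
    sub <- ct_table[ct_table$sample_id == s, , drop = FALSE]
    refs <- sub[sub$is_reference, , drop = FALSE]
    if (!nrow(refs)) stop("sample '", s, "' has no reference assay")
    ref_list <- split(refs$ct, refs$assay_id)
    targets <- sub[!sub$is_reference, , drop = FALSE]
    for (a in unique(targets$assay_id)) {
      rows <- targets[targets$assay_id == a, , drop = FALSE]
      out[[paste(s, a)]] <- data.frame(
        sample_id = s, group = rows$group[1],
        timepoint = rows$timepoint[1], assay_id = a,
        delta_ct = delta_ct(rows$ct, ref_list),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' qPCR fold changes per assay and time point
#'
#' Applies [fold_change_ddct()] to the OVA vs PBS groups for every
#' (assay, time point) combination of a delta-Ct table.
#'
#' @param dct Data frame as returned by [delta_ct_table()].
#' @return Data frame with `assay_id`, `timepoint`, `fc_qpcr`.
#' @export
qpcr_fold_changes <- function(dct) {
  combos <- unique(dct[, c("assay_id", "timepoint")])
  combos$fc_qpcr <- vapply(seq_len(nrow(combos)), function(i) {
    sub <- dct[dct$assay_id == combos$assay_id[i] &
                 dct$timepoint == combos$timepoint[i], , drop = FALSE]
    fold_change_ddct(sub$delta_ct[sub$group == "OVA"],
                     sub$delta_ct[sub$group == "PBS"])
  }, numeric(1))
  rownames(combos) <- NULL
  combos
}

#' Microarray vs qPCR concordance
#'
#' A (microarray, qPCR) fold-change pair is concordant when both
#' platforms report the same direction of change - the sign of the log
#' fold change agrees. With `band > 1`, fold changes inside the no-change
#' band `(1/band, band)` on both platforms also count as concordant
#' (both platforms call "no change"); the default `band = 1` is the pure
#' direction rule. The reported percentage is rounded to an integer.
#'
#' @param fc_pairs Data frame with columns `fc_microarray`, `fc_qpcr`
#'   (both positive), plus any identifier columns which are passed
#'   through.
#' @param band No-change band half-width as a fold change (default 1).
#' @return List with `pairs` (input plus logical `concordant`) and
#'   `percent_concordant` (integer).
#' @export
platform_concordance <- function(fc_pairs, band = 1) {
  if (any(fc_pairs$fc_microarray <= 0 | fc_pairs$fc_qpcr <= 0)) {
    stop("fold changes must be positive")
  }
  la <- log(fc_pairs$fc_microarray)
  lq <- log(fc_pairs$fc_qpcr)
  same_sign <- sign(la) == sign(lq)
  in_band <- abs(la) < log(band) & abs(lq) < log(band)
  fc_pairs$concordant <- same_sign | in_band
  list(pairs = fc_pairs,
       percent_concordant =
         round(100 * sum(fc_pairs$concordant) / nrow(fc_pairs)))
}

#' Luciferase reporter knockdown
#'
#' Luciferase activities are first normalized by the protein amount of
#' the corresponding lysate, then the miRNA condition is expressed
#' relative to the non-functional-control condition set at 100.
#'
#' @param activity_with_mirna,activity_with_control Raw luciferase
#'   activities (positive).
#' @param protein_with,protein_control Protein amounts used for
#'   normalization (positive).
#' @return Normalized activity as percent of control.
#' @export
reporter_knockdown <- function(activity_with_mirna, activity_with_control,
                               protein_with = 1, protein_control = 1) {
  vals <- c(activity_with_mirna, activity_with_control, protein_with,
            protein_control)
  if (any(vals <= 0)) stop("activities and protein amounts must be positive")
  100 * (activity_with_mirna / protein_with) /
    (activity_with_control / protein_control)
}
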
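# Differential (modulated) miRNA and mRNA set construction.
#
# Two definitions of "modulated gene" coexist and are tagged explicitly:
# the +/-0.6 log2-ratio rule (tag "standard") feeds inverse-correlation
# pairing; the 1.5-fold-in-both-pools rule (tag "both_pools") feeds the
# pathway analysis. Both apply the same multi-probe consistency rule.

#' Construct a modulated set
#'
#' @param timepoint Time-point label.
#' @param up,down Data frames with columns `id`, `fold_induction` (and
#'   optionally `p_value`) for up- and down-regulated members.
#' @param kind `"mirna"` or `"mrna"`.
#' @param rule_tag `"standard"` or `"both_pools"`.
#' @return An object of class `modulated_set` holding the membership table.
#' @export
modulated_set <- function(timepoint, up, down, kind = c("mirna", "mrna"),
                          rule_tag = c("standard", "both_pools")) {
  kind <- match.arg(kind)
  rule_tag <- match.arg(rule_tag)
  if (length(intersect(up$id, down$id))) {
    stop("up and down sets overlap")
  }
  members <- rbind(
    if (nrow(up)) cbind(up, direction = "up", stringsAsFactors = FALSE),
    if (nrow(down)) cbind(down, direction = "down",
                          stringsAsFactors = FALSE))
  if (is.null(members)) {
    members <- data.frame(id = character(), fold_induction = numeric(),
                          direction = character(),
                          stringsAsFactors = FALSE)
  }
  structure(list(timepoint = as.character(as_timepoint(timepoint)),
                 members = members[order(members$id), , drop = FALSE],
                 kind = kind, rule_tag = rule_tag),
            class = "modulated_set")
}

#' @export
print.modulated_set <- function(x, ...) {
  cat(sprintf("modulated %s set (%s rule) at %s: %d up, %d down\n",
              x$kind, x$rule_tag, x$timepoint,
              sum(x$members$direction == "up"),
              sum(x$members$direction == "down")))
  invisible(x)
}

#' Members of a modulated set
#'
#' @param set A `modulated_set`.
#' @param direction `"up"`, `"down"`, or `"both"` (default).
#' @return Character vector of member ids.
#' @export
set_members <- function(set, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  m <- set$members
  if (direction != "both") m <- m[m$direction == direction, , drop = FALSE]
  m$id
}

#' Call modulated miRNAs
#'
#' A miRNA is called up-regulated when its fold induction is at least
#' `fc_min` and its t-test p-value is below `p_max`; down-regulated when
#' the fold induction is at most `1/fc_min` under the same p-value rule.
#' The fold threshold is inclusive, the p threshold strict.
#'
#' @param measurements Data frame with `mirna_id`, `timepoint`,
#'   `fold_induction`, `p_value`; all rows must share one time point.
#' @param fc_min Fold-change threshold (default 1.5).
#' @param p_max p-value threshold (default 0.01).
#' @return A `modulated_set` of kind `"mirna"`.
#' @export
call_modulated_mirnas <- function(measurements, fc_min = 1.5,
                                  p_max = 0.01) {
  tp <- unique(as.character(measurements$timepoint))
  if (length(tp) != 1) {
    stop("measurements mix time points: ", paste(tp, collapse = ", "))
  }
  sig <- measurements$p_value < p_max
  up <- measurements[sig & measurements$fold_induction >= fc_min, ,
                     drop = FALSE]
  down <- measurements[sig & measurements$fold_induction <= 1 / fc_min, ,
                       drop = FALSE]
  pick <- function(df) data.frame(id = df$mirna_id,
                                  fold_induction = df$fold_induction,
                                  p_value = df$p_value,
                                  stringsAsFactors = FALSE)
  modulated_set(tp, pick(up), pick(down), kind = "mirna",
                rule_tag = "standard")
}

# Per-gene direction call under the multi-probe consistency rule:
# all probe values must share one sign and at least one must exceed `thr`
# in magnitude. Returns "up", "down" or NA.
.consistent_direction <- function(values, thr) {
  if (!length(values)) stop("gene with zero probes")
  s <- sign(values)
  if (all(s > 0) && any(values > thr)) return("up")
  if (all(s < 0) && any(values < -thr)) return("down")
  NA_character_
}

#' Call modulated genes (log-ratio rule)
#'
#' Per probe, the mean log2 ratio over the two treated pools is taken. A
#' single-probe gene is up if that mean exceeds `log_thr`, down if below
#' `-log_thr`. A multi-probe gene is included only if the direction of
#' change is consistent between all probes and at least one probe
#' satisfies the threshold. `log_thr = 0.6` corresponds to a 1.52-fold
#' change.
#'
#' @param probe_ratios Data frame with `gene_id`, `probe_id`,
#'   `log_ratio_pool1`, `log_ratio_pool2` for one time point.
#' @param log_thr Log2-ratio threshold (default 0.6, strict).
#' @param timepoint Time-point label attached to the result.
#' @return A `modulated_set` of kind `"mrna"`, rule tag `"standard"`.
#' @export
call_modulated_genes <- function(probe_ratios, log_thr = 0.6,
                                 timepoint = "ST") {
  probe_mean <- (probe_ratios$log_ratio_pool1 +
                 probe_ratios$log_ratio_pool2) / 2
  by_gene <- split(probe_mean, probe_ratios$gene_id)
  dirs <- vapply(by_gene, .consistent_direction, character(1),
                 thr = log_thr)
  fi <- vapply(by_gene, function(v) 2^mean(v), numeric(1))
  ids <- names(by_gene)
  up <- data.frame(id = ids[!is.na(dirs) & dirs == "up"],
                   stringsAsFactors = FALSE)
  down <- data.frame(id = ids[!is.na(dirs) & dirs == "down"],
                     stringsAsFactors = FALSE)
  up$fold_induction <- fi[up$id]
  down$fold_induction <- fi[down$id]
  modulated_set(timepoint, up, down, kind = "mrna",
                rule_tag = "standard")
}

#' Call modulated genes (both-pools fold rule)
#'
#' The pathway analysis uses a stricter definition: a gene is modulated
#' when its magnitude of change exceeds `fc_min`-fold in the same
#' direction in both treated pools. Probes are aggregated per pool by the
#' same consistency rule as [call_modulated_genes()] (all probes one sign,
#' at least one past the threshold).
#'
#' @param probe_ratios Data frame as in [call_modulated_genes()].
#' @param fc_min Fold threshold applied per pool (default 1.5; the log2
#'   threshold is `log2(fc_min)`, strict).
#' @param timepoint Time-point label attached to the result.
#' @return A `modulated_set` of kind `"mrna"`, rule tag `"both_pools"`.
#' @export
call_modulated_genes_both_pools <- function(probe_ratios, fc_min = 1.5,
                                            timepoint = "ST") {
  thr <- log2(fc_min)
  by_gene1 <- split(probe_ratios$log_ratio_pool1, probe_ratios$gene_id)
  by_gene2 <- split(probe_ratios$log_ratio_pool2, probe_ratios$gene_id)
  d1 <- vapply(by_gene1, .consistent_direction, character(1), thr = thr)
  d2 <- vapply(by_gene2, .consistent_direction, character(1), thr = thr)
  agree <- !is.na(d1) & !is.na(d2) & d1 == d2
  ids <- names(by_gene1)
  fi <- vapply(seq_along(ids), function(i) {
    2^mean(c(by_gene1[[i]], by_gene2[[i]]))
  }, numeric(1))
  names(fi) <- ids
  up <- data.frame(id = ids[agree & d1 == "up"], stringsAsFactors = FALSE)
  down <- data.frame(id = ids[agree & d1 == "down"],
                     stringsAsFactors = FALSE)
  up$fold_induction <- fi[up$id]
  down$fold_induction <- fi[down$id]
  modulated_set(timepoint, up, down, kind = "mrna",
                rule_tag = "both_pools")
}

#' miRNAs modulated at multiple time points
#'
#' @param sets List of three `modulated_set` objects (ST, IT, LT order is
#'   taken from their `timepoint` fields).
#' @param k Minimum number of time points at which a miRNA must be
#'   modulated (in either direction).
#' @return Data frame with one row per recurrent miRNA: `mirna_id`,
#'   `n_timepoints`, and per-time-point `<tp>_fi` / `<tp>_direction`
#'   columns (NA where not modulated).
#' @export
recurrent_mirnas <- function(sets, k = 2) {
  tps <- vapply(sets, function(s) s$timepoint, character(1))
  if (anyDuplicated(tps)) stop("duplicate time points in input sets")
  all_ids <- sort(unique(unlist(lapply(sets, set_members))))
  if (!length(all_ids)) {
    out <- data.frame(mirna_id = character(), n_timepoints = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(mirna_id = all_ids, stringsAsFactors = FALSE)
  n_tp <- integer(length(all_ids))
  for (i in seq_along(sets)) {
    m <- sets[[i]]$members
    idx <- match(all_ids, m$id)
    out[[paste0(tolower(tps[i]), "_fi")]] <- m$fold_induction[idx]
    out[[paste0(tolower(tps[i]), "_direction")]] <- m$direction[idx]
    n_tp <- n_tp + !is.na(idx)
  }
  out$n_timepoints <- n_tp
  out <- out[out$n_timepoints >= k, , drop = FALSE]
  rownames(out) <- NULL
  out
}
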
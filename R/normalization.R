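# Raw two-channel probe signals -> per-miRNA fold inductions and p-values.
#
# The chip design hybridizes the treated (OVA) and control (PBS) RNA pools
# on the same array in two channels, in a duplicate experiment. Analysis
# follows the conventional two-color path: background subtraction, log2,
# cyclic loess normalization across channel/replicate columns, per-probe
# log ratios, then a one-sample t-test of the log ratios against zero.

#' Background-correct raw intensities
#'
#' Corrected intensity is `max(raw - background, floor)`. A strictly
#' positive floor absorbs negative corrections so the subsequent log2
#' transform stays finite.
#'
#' @param raw Numeric vector of raw intensities (non-negative).
#' @param background Numeric vector of local background estimates.
#' @param floor Positive lower bound applied after subtraction (default 1).
#' @return Numeric vector of corrected intensities, order preserved.
#' @export
subtract_background <- function(raw, background, floor = 1) {
  if (floor <= 0) stop("floor must be positive")
  if (length(raw) != length(background)) {
    stop("raw and background lengths differ")
  }
  pmax(raw - background, floor)
}

#' Cyclic loess normalization of a log2 signal matrix
#'
#' For every pair of columns a loess curve is fitted in (A, M) rotated
#' coordinates - A the column mean, M the difference - and subtracted
#' symmetrically from the two columns; the procedure cycles over all pairs
#' for a fixed number of iterations. This removes intensity-dependent
#' inter-channel bias while leaving each row's grand mean unchanged.
#'
#' The fit is delegated to [limma::normalizeCyclicLoess()] with
#' `method = "pairs"`.
#'
#' @param mat Numeric matrix, probes in rows, arrays/channels in columns
#'   (at least 2), log2 scale, finite entries.
#' @param span Loess span (default 0.4).
#' @param iterations Number of cycles over all column pairs (default 3).
#' @return Normalized matrix, same dimensions and column order.
#' @export
cyclic_loess_normalize <- function(mat, span = 0.4, iterations = 3) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("cyclic loess needs at least 2 columns")
  if (any(!is.finite(mat))) stop("non-finite entries in signal matrix")
  out <- limma::normalizeCyclicLoess(mat, span = span,
                                     iterations = iterations,
                                     method = "pairs")
  dimnames(out) <- dimnames(mat)
  out
}

#' Fold induction and t-test p-value from log2 ratios
#'
#' Summarizes the per-probe-per-replicate log2 (treated/control) ratios of
#' one miRNA: fold induction is `2^mean(log2 ratio)` and the p-value is a
#' two-sided one-sample t-test of the log ratios against zero.
#'
#' Degenerate inputs follow fixed conventions: zero variance with zero mean
#' gives p = 1; zero variance with nonzero mean gives p = 0 with a warning
#' (the evidence is formally infinite, which only arises in noise-free
#' synthetic data).
#'
#' @param log_ratios Numeric vector of log2 ratios, length >= 2.
#' @return List with `fold_induction`, `p_value`, `n`.
#' @export
fold_and_pvalue <- function(log_ratios) {
  log_ratios <- as.numeric(log_ratios)
  if (length(log_ratios) < 2) {
    stop("need at least 2 log-ratio observations for a t-test")
  }
  m <- mean(log_ratios)
  if (sd(log_ratios) == 0) {
    if (m == 0) {
      p <- 1
    } else {
      warning("zero-variance log ratios with nonzero mean: p set to 0")
      p <- 0
    }
  } else {
    p <- t.test(log_ratios, mu = 0)$p.value
  }
  list(fold_induction = 2^m, p_value = p, n = length(log_ratios))
}

# Pivot a long probe-signal table into a probes x (replicate, channel)
# log2 matrix. Rows are (mirna_id, probe_index); column order is fixed.
.signal_matrix <- function(signals, floor = 1) {
  required <- c("mirna_id", "probe_index", "replicate", "channel",
                "raw", "background")
  missing <- setdiff(required, names(signals))
  if (length(missing)) {
    stop("probe-signal table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!all(signals$channel %in% c("cy3_ova", "cy5_pbs"))) {
    stop("channel must be 'cy3_ova' or 'cy5_pbs'")
  }
  corrected <- subtract_background(signals$raw, signals$background, floor)
  row_key <- paste(signals$mirna_id, signals$probe_index, sep = "\r")
  col_key <- paste0("r", signals$replicate, "_", signals$channel)
  rows <- unique(row_key)
  cols <- sort(unique(col_key))
  mat <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
                dimnames = list(rows, cols))
  mat[cbind(match(row_key, rows), match(col_key, cols))] <- log2(corrected)
  if (any(is.na(mat))) {
    stop("incomplete probe design: some (probe, replicate, channel) ",
         "combinations are missing")
  }
  attr(mat, "mirna_id") <- signals$mirna_id[match(rows, row_key)]
  mat
}

#' Normalize probe signals into per-probe log2 ratios
#'
#' Runs the full pre-processing chain on a long-format probe-signal table:
#' background subtraction, log2, cyclic loess across all
#' replicate/channel columns, then the per-replicate log2 ratio
#' treated minus control for every probe.
#'
#' @param signals Data frame with columns `mirna_id`, `probe_index`,
#'   `replicate` (1 or 2), `channel` (`"cy3_ova"` or `"cy5_pbs"`), `raw`,
#'   `background`.
#' @param floor Background-subtraction floor (default 1).
#' @param span,iterations Cyclic loess parameters.
#' @return Data frame with columns `mirna_id`, `probe_index`, `replicate`,
#'   `log_ratio`; one row per probe per replicate.
#' @export
normalize_probe_signals <- function(signals, floor = 1, span = 0.4,
                                    iterations = 3) {
  mat <- .signal_matrix(signals, floor = floor)
  norm <- cyclic_loess_normalize(mat, span = span, iterations = iterations)
  reps <- sort(unique(signals$replicate))
  out <- do.call(rbind, lapply(reps, function(r) {
    ova <- norm[, paste0("r", r, "_cy3_ova")]
    pbs <- norm[, paste0("r", r, "_cy5_pbs")]
    key <- strsplit(rownames(norm), "\r", fixed = TRUE)
    data.frame(mirna_id = attr(mat, "mirna_id"),
               probe_index = as.integer(vapply(key, `[[`, character(1), 2L)),
               replicate = r,
               log_ratio = ova - pbs,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize normalized ratios into miRNA measurements
#'
#' Applies [fold_and_pvalue()] per miRNA across all probes and replicates.
#'
#' @param ratios Data frame as returned by [normalize_probe_signals()].
#' @param timepoint Single time-point label attached to the output.
#' @return Data frame with `mirna_id`, `timepoint`, `fold_induction`,
#'   `p_value`, `n_obs`.
#' @export
summarize_mirna_measurements <- function(ratios, timepoint) {
  timepoint <- as.character(as_timepoint(timepoint))
  ids <- unique(ratios$mirna_id)
  res <- lapply(ids, function(id) {
    fp <- fold_and_pvalue(ratios$log_ratio[ratios$mirna_id == id])
    data.frame(mirna_id = id, timepoint = timepoint,
               fold_induction = fp$fold_induction, p_value = fp$p_value,
               n_obs = fp$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$mirna_id), , drop = FALSE]
}
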
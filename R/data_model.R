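# Domain types and readers/writers for the tabular inputs and outputs.
# All tables are UTF-8, tab-separated, with a mandatory header row.

#' Normalize a gene identifier
#'
#' Gene symbols arrive from several resources (expression arrays, target
#' prediction databases, pathway gene sets) with inconsistent casing
#' ("Arid4b" vs "ARID4B"). All cross-referencing in the pipeline is done on
#' the upper-cased, whitespace-stripped symbol.
#'
#' @param raw Character vector of raw identifiers.
#' @return Character vector of normalized symbols. Idempotent.
#' @examples
#' normalize_gene_id(c("Arid4b", " il6 "))
#' @export
normalize_gene_id <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(trimws(raw))
  if (any(is.na(out) | out == "")) {
    stop("invalid gene identifier: empty string or NA")
  }
  out
}

#' Validate and order time-point labels
#'
#' @param tp Character vector of time-point labels.
#' @return Ordered factor with levels ST < IT < LT.
#' @export
as_timepoint <- function(tp) {
  tp <- as.character(tp)
  bad <- setdiff(unique(tp), TIMEPOINTS)
  if (length(bad)) {
    stop("unknown time point(s): ", paste(bad, collapse = ", "))
  }
  factor(tp, levels = TIMEPOINTS, ordered = TRUE)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "#", check.names = FALSE,
             fileEncoding = "UTF-8")
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Read a miRNA measurement table
#'
#' One row per (miRNA, time point): the fold induction (treated/control
#' expression ratio) and the associated t-test p-value.
#'
#' @param path Path to a tab-separated file with header columns
#'   `mirna_id`, `timepoint`, `fold_induction`, `p_value`.
#' @return A data frame of validated measurements.
#' @export
read_mirna_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("mirna_id", "timepoint", "fold_induction",
                         "p_value"), path)
  df$fold_induction <- as.numeric(df$fold_induction)
  df$p_value <- as.numeric(df$p_value)
  validate_mirna_measurements(df, path = path)
}

#' Validate miRNA measurement invariants
#'
#' @param df Data frame with `mirna_id`, `timepoint`, `fold_induction`,
#'   `p_value`.
#' @param path Label used in error messages.
#' @return The validated data frame (timepoint coerced to ordered factor).
#' @export
validate_mirna_measurements <- function(df, path = "<data>") {
  bad_fi <- which(!is.finite(df$fold_induction) | df$fold_induction <= 0)
  if (length(bad_fi)) {
    stop("'", path, "': non-positive or missing fold induction at row(s) ",
         paste(head(bad_fi, 5), collapse = ", "))
  }
  bad_p <- which(!is.finite(df$p_value) | df$p_value < 0 | df$p_value > 1)
  if (length(bad_p)) {
    stop("'", path, "': p-value outside [0, 1] at row(s) ",
         paste(head(bad_p, 5), collapse = ", "))
  }
  df$timepoint <- as_timepoint(df$timepoint)
  key <- paste(df$mirna_id, df$timepoint)
  if (anyDuplicated(key)) {
    stop("'", path, "': duplicated (mirna_id, timepoint) entries")
  }
  df
}

#' Read mRNA probe-level log2 ratios
#'
#' Probe-level log2 ratios of each of two treated pools against the control
#' pool. A gene may own several probes; the probe identifier is unique.
#'
#' @param path Path to a tab-separated file with header columns `gene_id`,
#'   `probe_id`, `log_ratio_pool1`, `log_ratio_pool2` (and optionally
#'   `timepoint`).
#' @return A data frame with normalized gene symbols.
#' @export
read_mrna_ratios <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("gene_id", "probe_id", "log_ratio_pool1",
                         "log_ratio_pool2"), path)
  df$gene_id <- normalize_gene_id(df$gene_id)
  df$log_ratio_pool1 <- as.numeric(df$log_ratio_pool1)
  df$log_ratio_pool2 <- as.numeric(df$log_ratio_pool2)
  if (any(!is.finite(df$log_ratio_pool1)) ||
      any(!is.finite(df$log_ratio_pool2))) {
    stop("'", path, "': non-finite log ratio")
  }
  if (anyDuplicated(df$probe_id) &&
      !("timepoint" %in% names(df) &&
        !anyDuplicated(paste(df$probe_id, df$timepoint)))) {
    stop("'", path, "': duplicated probe_id")
  }
  df
}

#' Read a GMT pathway file
#'
#' Standard gene-set exchange format: one set per line, fields
#' `name <tab> description <tab> gene1 <tab> gene2 ...`. Gene symbols are
#' normalized and duplicates within a line collapsed.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (gene sets); the
#'   `"description"` attribute carries the second field per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short)) {
    stop("'", path, "': GMT line(s) with fewer than 3 fields: line ",
         paste(head(short, 5), collapse = ", "))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) unique(normalize_gene_id(f[-(1:2)])))
  if (any(lengths(genes) == 0L)) stop("'", path, "': empty gene set")
  if (anyDuplicated(ids)) stop("'", path, "': duplicated pathway id")
  pathways <- setNames(genes, ids)
  attr(pathways, "description") <- setNames(desc, ids)
  pathways
}

#' Write pathways to a GMT file
#'
#' @param pathways Named list of character vectors as returned by
#'   [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  desc <- attr(pathways, "description")
  if (is.null(desc)) desc <- setNames(names(pathways), names(pathways))
  lines <- vapply(names(pathways), function(id) {
    paste(c(id, desc[[id]], pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a target-prediction table
#'
#' One predicted (miRNA, gene) interaction per row with the prediction
#' p-value assigned by the source database. Duplicate predictions for the
#' same (miRNA, gene) pair - e.g. multiple transcript sites - are collapsed
#' keeping the minimum p-value. No p-value filtering is applied at read
#' time; the pairing stage owns that threshold.
#'
#' @param path Path to a tab-separated file with header columns `mirna_id`,
#'   `gene_id`, `p_value`.
#' @param source_db One of `"microcosm"`, `"targetscan"`.
#' @return A data frame with columns `mirna_id`, `gene_id`, `p_value`,
#'   `source_db`.
#' @export
read_target_predictions <- function(path,
                                    source_db = c("microcosm",
                                                  "targetscan")) {
  source_db <- match.arg(source_db)
  df <- .read_tsv(path)
  .require_columns(df, c("mirna_id", "gene_id", "p_value"), path)
  df$p_value <- as.numeric(df$p_value)
  if (any(!is.finite(df$p_value) | df$p_value < 0 | df$p_value > 1)) {
    stop("'", path, "': malformed prediction p-value")
  }
  df$gene_id <- normalize_gene_id(df$gene_id)
  dedup_predictions(data.frame(mirna_id = df$mirna_id,
                               gene_id = df$gene_id,
                               p_value = df$p_value,
                               source_db = source_db,
                               stringsAsFactors = FALSE))
}

#' Collapse duplicate target predictions
#'
#' Keeps the minimum p-value per (miRNA, gene, source database) triple.
#'
#' @param predictions Data frame with `mirna_id`, `gene_id`, `p_value`,
#'   `source_db`.
#' @return De-duplicated data frame, sorted by (mirna_id, gene_id).
#' @export
dedup_predictions <- function(predictions) {
  key <- paste(predictions$mirna_id, predictions$gene_id,
               predictions$source_db, sep = "\r")
  if (anyDuplicated(key)) {
    p_min <- tapply(predictions$p_value, key, min)
    keep <- !duplicated(key)
    predictions <- predictions[keep, , drop = FALSE]
    predictions$p_value <- as.numeric(p_min[key[keep]])
  }
  predictions[order(predictions$mirna_id, predictions$gene_id), ,
              drop = FALSE]
}

#' Construct a measurement universe
#'
#' The reference sets for enrichment: the miRNA chip content (nominally 566
#' probes in the emulated design) and the expression-array gene content
#' (nominally 20461 genes).
#'
#' @param mirna_ids Character vector of chip miRNA identifiers.
#' @param gene_ids Character vector of array gene symbols (normalized).
#' @return An object of class `mirpath_universe`.
#' @export
make_universe <- function(mirna_ids, gene_ids) {
  structure(list(mirna_ids = unique(as.character(mirna_ids)),
                 gene_ids = unique(normalize_gene_id(gene_ids))),
            class = "mirpath_universe")
}

#' @export
print.mirpath_universe <- function(x, ...) {
  cat("measurement universe:", length(x$mirna_ids), "miRNAs,",
      length(x$gene_ids), "genes\n")
  invisible(x)
}

#' Check measurements against a universe
#'
#' Every measured miRNA must be a member of the declared chip universe.
#'
#' @param measurements Data frame with a `mirna_id` column.
#' @param universe A `mirpath_universe`.
#' @return `measurements`, invisibly, if the check passes.
#' @export
check_universe_membership <- function(measurements, universe) {
  stray <- setdiff(unique(measurements$mirna_id), universe$mirna_ids)
  if (length(stray)) {
    stop("measurement(s) outside the chip universe: ",
         paste(head(stray, 5), collapse = ", "))
  }
  invisible(measurements)
}

#' Write a data frame as a provenance-stamped TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @param provenance Optional named list written as `# key: value` comment
#'   lines before the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
    }
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write universe sizes and provenance as a JSON sidecar
#'
#' @param universe A `mirpath_universe`.
#' @param path Output path.
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_universe_sidecar <- function(universe, path, extra = NULL) {
  payload <- c(list(n_mirnas = length(universe$mirna_ids),
                    n_genes = length(universe$gene_ids)), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
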
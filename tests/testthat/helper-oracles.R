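# Independent oracles used to cross-check the analytical routines, kept
# deliberately naive: enumeration and closed-form summation only.

# Exact permutation tail by exhaustive enumeration of all modulated-set
# choices of size m from the universe.
exact_permutation_tail <- function(pathway_genes, modulated, universe,
                                   predictions) {
  observed <- count_target_pairs(pathway_genes, modulated, predictions)
  subsets <- utils::combn(universe, length(modulated), simplify = FALSE)
  counts <- vapply(subsets, function(s) {
    count_target_pairs(pathway_genes, s, predictions)
  }, numeric(1))
  mean(counts >= observed)
}

# Upper-tail hypergeometric probability by direct summation of binomial
# coefficients.
brute_hypergeom_tail <- function(k, n_universe, n_modulated, n_pathway) {
  js <- k:min(n_modulated, n_pathway)
  sum(choose(n_modulated, js) *
        choose(n_universe - n_modulated, n_pathway - js)) /
    choose(n_universe, n_pathway)
}

# Small deterministic prediction table builder.
toy_predictions <- function(..., db = "microcosm", p = 0.001) {
  edges <- list(...)
  data.frame(mirna_id = vapply(edges, `[[`, character(1), 1L),
             gene_id = vapply(edges, `[[`, character(1), 2L),
             p_value = p, source_db = db, stringsAsFactors = FALSE)
}

# Measurement-table builder for calling tests.
toy_measurements <- function(ids, fi, p, tp = "ST") {
  data.frame(mirna_id = ids, timepoint = tp, fold_induction = fi,
             p_value = p, stringsAsFactors = FALSE)
}
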
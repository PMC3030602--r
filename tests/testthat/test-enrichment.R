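test_that("pair counting counts each qualifying (miRNA, gene) pair once", {
  pred <- toy_predictions(c("M1", "G1"), c("M1", "G2"), c("M1", "G3"),
                          c("M2", "G1"))
  expect_equal(count_target_pairs(c("G1", "G2"), "M1", pred), 2)
  expect_equal(count_target_pairs(c("G1", "G2"), character(), pred), 0)
  expect_equal(count_target_pairs("G1", c("M1", "M2"), pred), 2)
})

test_that("permutation p-value matches exhaustive enumeration", {
  universe <- paste0("M", 1:5)
  genes <- paste0("G", 1:3)
  pred <- toy_predictions(c("M1", "G1"), c("M1", "G2"), c("M2", "G1"),
                          c("M3", "G3"), c("M4", "G2"))
  modulated <- c("M1", "M3")
  exact <- exact_permutation_tail(genes, modulated, universe, pred)
  got <- permutation_pvalue(genes, modulated, universe, pred,
                            permutation_config(n_trials = 10000,
                                               seed = 5))
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(got$p_mirna - exact), 3 * se + 1e-12)
  expect_equal(got$observed_pairs,
               count_target_pairs(genes, modulated, pred))
})

test_that("permutation p-value degenerate cases", {
  universe <- paste0("M", 1:5)
  pred <- toy_predictions(c("M1", "G1"))
  # observed 0: every trial count >= 0, so p = 1
  got0 <- permutation_pvalue("G9", c("M2", "M3"), universe, pred)
  expect_equal(got0$p_mirna, 1)
  # modulated = universe: every trial reproduces the same set
  gotU <- permutation_pvalue("G1", universe, universe, pred)
  expect_equal(gotU$p_mirna, 1)
  expect_error(permutation_pvalue("G1", "M9", universe, pred),
               "universe")
})

test_that("hypergeometric p-value matches brute-force summation", {
  # closed-form example: universe 10, modulated 4, pathway 3, k = 2
  uni <- paste0("g", 1:10)
  modulated <- uni[1:4]
  pathway <- c("g1", "g2", "g5")
  expect_equal(hypergeom_pvalue(pathway, modulated, uni), 1 / 3)
  # brute-force oracle over many random configurations, universes <= 50
  set.seed(51)
  for (i in 1:25) {
    n_u <- sample(10:50, 1)
    u <- paste0("g", seq_len(n_u))
    mod <- sample(u, sample(0:n_u, 1))
    pw <- sample(u, sample(1:n_u, 1))
    k <- length(intersect(pw, mod))
    expect_equal(hypergeom_pvalue(pw, mod, u),
                 brute_hypergeom_tail(k, n_u, length(mod), length(pw)),
                 tolerance = 1e-12)
  }
  # degenerate tails
  expect_equal(hypergeom_pvalue(c("g1", "g2"), character(), uni), 1)
  expect_equal(hypergeom_pvalue(uni, uni, uni), 1)
  expect_warning(p <- hypergeom_pvalue("NOTHERE", uni[1:2], uni),
                 "no genes")
  expect_equal(p, 1)
})

test_that("Stouffer combination matches the closed normal form and its identities", {
  expect_equal(stouffer_combine(0.5, 0.5), 0.5)
  z <- qnorm(1 - 0.05)
  expect_equal(stouffer_combine(0.05, 0.05),
               1 - pnorm(2 * z / sqrt(2)), tolerance = 1e-12)
  expect_lt(abs(stouffer_combine(0.05, 0.05) - 0.00999), 1e-4)
  # antisymmetry and argument symmetry
  for (p in c(0.1, 0.25, 0.4)) {
    expect_equal(stouffer_combine(p, 1 - p), 0.5)
  }
  expect_equal(stouffer_combine(0.01, 0.2), stouffer_combine(0.2, 0.01))
  # evidence accumulation
  for (p in c(0.01, 0.2, 0.4)) expect_lt(stouffer_combine(p, p), p)
  for (p in c(0.6, 0.9)) expect_gt(stouffer_combine(p, p), p)
  # monotone in each argument
  grid <- seq(0.05, 0.95, by = 0.15)
  vals <- stouffer_combine(grid, 0.3)
  expect_true(all(diff(vals) > 0))
  expect_error(stouffer_combine(-0.1, 0.5), "0, 1")
})

test_that("the full pathway analysis selects a planted pathway and is seeded", {
  sim <- simulate_study(simulation_config(seed = 61))
  mirna_sets <- list(); gene_sets <- list()
  for (tp in TIMEPOINTS) {
    truth <- sim$truth$modulated_mirnas[[tp]]
    mirna_sets[[tp]] <- modulated_set(
      tp,
      up = data.frame(id = truth$mirna_id[truth$direction == "up"],
                      fold_induction =
                        truth$fold_induction[truth$direction == "up"]),
      down = data.frame(id = truth$mirna_id[truth$direction == "down"],
                        fold_induction =
                          truth$fold_induction[truth$direction == "down"]),
      kind = "mirna")
    gt <- sim$truth$modulated_genes[[tp]]
    gene_sets[[tp]] <- modulated_set(
      tp,
      up = data.frame(id = gt$gene_id[gt$direction == "up"],
                      fold_induction = 2^gt$log2_fc[gt$direction == "up"]),
      down = data.frame(id = gt$gene_id[gt$direction == "down"],
                        fold_induction =
                          2^gt$log2_fc[gt$direction == "down"]),
      kind = "mrna", rule_tag = "both_pools")
  }
  cfg <- permutation_config(n_trials = 500, seed = 7)
  run1 <- run_pathway_analysis(sim$pathways, mirna_sets, gene_sets,
                               sim$predictions, sim$universe, cfg)
  planted <- sim$truth$planted_pathways
  for (db in SOURCE_DBS) for (tp in TIMEPOINTS) {
    sub <- run1$results[run1$results$source_db == db &
                          run1$results$timepoint == tp, ]
    expect_equal(sub$pathway_id[which.min(sub$p_combined)], planted)
  }
  # unplanted pathways sit far from the selection threshold on average
  null_p <- run1$results$p_combined[
    run1$results$pathway_id != planted]
  expect_gt(median(null_p), 0.2)
  # bit-for-bit reproducibility under the same seed
  run2 <- run_pathway_analysis(sim$pathways, mirna_sets, gene_sets,
                               sim$predictions, sim$universe, cfg)
  expect_identical(run1, run2)
  # empty modulated sets select nothing (all p = 1 -> combined >= 0.5)
  empty_m <- lapply(mirna_sets, function(s) {
    modulated_set(s$timepoint,
                  data.frame(id = character(), fold_induction = numeric()),
                  data.frame(id = character(), fold_induction = numeric()),
                  kind = "mirna")
  })
  empty_g <- lapply(gene_sets, function(s) {
    modulated_set(s$timepoint,
                  data.frame(id = character(), fold_induction = numeric()),
                  data.frame(id = character(), fold_induction = numeric()),
                  kind = "mrna", rule_tag = "both_pools")
  })
  run0 <- run_pathway_analysis(sim$pathways, empty_m, empty_g,
                               sim$predictions, sim$universe, cfg)
  expect_equal(nrow(run0$selected), 0L)
  expect_true(all(run0$results$p_combined >= 0.5))
})

test_that("overlap summary partitions selections by time-point count", {
  got <- overlap_summary(list(ST = c("A", "B"), IT = c("B", "C"),
                              LT = "B"))
  expect_equal(got$exactly_1, 2L)
  expect_equal(got$exactly_2, 0L)
  expect_equal(got$exactly_3, 1L)
  expect_equal(got$all_three, "B")
  disjoint <- overlap_summary(list(ST = "A", IT = "B", LT = "C"))
  expect_equal(disjoint$exactly_1, 3L)
  same <- overlap_summary(list(ST = letters[1:4], IT = letters[1:4],
                               LT = letters[1:4]))
  expect_equal(same$exactly_3, 4L)
  # counts sum to the size of the union
  expect_equal(got$exactly_1 + got$exactly_2 + got$exactly_3, 3L)
})
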
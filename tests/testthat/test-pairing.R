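toy_mirna_set <- function(tp = "ST") {
  modulated_set(tp,
                up = data.frame(id = c("mmu-miR-223", "mmu-miR-146b"),
                                fold_induction = c(1.99, 1.91),
                                p_value = 0.001),
                down = data.frame(id = "mmu-miR-483",
                                  fold_induction = 0.39,
                                  p_value = 0.001),
                kind = "mirna")
}

toy_gene_set <- function(tp = "ST") {
  modulated_set(tp,
                up = data.frame(id = "GMNN", fold_induction = 1.62),
                down = data.frame(id = c("ARID4B", "CARD10", "IL6"),
                                  fold_induction = c(0.64, 0.55, 0.47)),
                kind = "mrna")
}

test_that("inverse pairing crosses sets with predictions under the p cutoff", {
  pred <- toy_predictions(
    c("mmu-miR-223", "ARID4B"),    # up miRNA vs down gene -> pair
    c("mmu-miR-146b", "CARD10"),   # up miRNA vs down gene -> pair
    c("mmu-miR-483", "GMNN"),      # down miRNA vs up gene -> pair
    c("mmu-miR-223", "GMNN"),      # up miRNA vs up gene -> no pair
    c("mmu-miR-146b", "IL6"))
  pred$p_value <- c(0.0009, 0.0003, 0.0455, 0.001, 0.08)
  pairs <- inverse_pairs(toy_mirna_set(), toy_gene_set(), pred)
  expect_equal(nrow(pairs), 3L)
  got_223 <- pairs[pairs$mirna_id == "mmu-miR-223", ]
  expect_equal(got_223$gene_id, "ARID4B")
  expect_equal(got_223$prediction_p, 0.0009)
  expect_equal(got_223$mirna_fi, 1.99)
  expect_equal(got_223$gene_fi, 0.64)
  # same-direction pair excluded
  expect_false(any(pairs$mirna_id == "mmu-miR-223" &
                     pairs$gene_id == "GMNN"))
  # prediction p >= 0.05 excluded
  expect_false("IL6" %in% pairs$gene_id)
  expect_true(all(pairs$mirna_direction != pairs$gene_direction))
  expect_error(inverse_pairs(toy_mirna_set("ST"), toy_gene_set("IT"),
                             pred), "mismatch")
})

test_that("pair output is independent of input row order and bounded", {
  pred <- toy_predictions(
    c("mmu-miR-223", "ARID4B"), c("mmu-miR-146b", "CARD10"),
    c("mmu-miR-483", "GMNN"), c("mmu-miR-223", "CFLAR"))
  a <- inverse_pairs(toy_mirna_set(), toy_gene_set(), pred)
  b <- inverse_pairs(toy_mirna_set(), toy_gene_set(),
                     pred[rev(seq_len(nrow(pred))), ])
  expect_equal(a, b)
  ms <- toy_mirna_set(); gs <- toy_gene_set()
  bound <- length(set_members(ms, "up")) *
    length(set_members(gs, "down")) +
    length(set_members(ms, "down")) * length(set_members(gs, "up"))
  expect_lte(nrow(a), min(nrow(pred), bound))
})

test_that("recurrent pairs intersect on identity and keep per-time-point direction", {
  # a direction flip between time points (down->up miRNA, up->down gene)
  st <- inverse_pairs(
    modulated_set("ST", up = data.frame(id = character(),
                                        fold_induction = numeric()),
                  down = data.frame(id = "mmu-miR-483",
                                    fold_induction = 0.39),
                  kind = "mirna"),
    modulated_set("ST", up = data.frame(id = "GMNN",
                                        fold_induction = 1.62),
                  down = data.frame(id = character(),
                                    fold_induction = numeric()),
                  kind = "mrna"),
    toy_predictions(c("mmu-miR-483", "GMNN"), p = 0.0455))
  lt <- inverse_pairs(
    modulated_set("LT", up = data.frame(id = "mmu-miR-483",
                                        fold_induction = 116.16),
                  down = data.frame(id = character(),
                                    fold_induction = numeric()),
                  kind = "mirna"),
    modulated_set("LT", up = data.frame(id = character(),
                                        fold_induction = numeric()),
                  down = data.frame(id = "GMNN",
                                    fold_induction = 0.55),
                  kind = "mrna"),
    toy_predictions(c("mmu-miR-483", "GMNN"), p = 0.0455))
  rec <- recurrent_pairs(st, lt)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$mirna_direction_st, "down")
  expect_equal(rec$mirna_direction_lt, "up")
  expect_equal(rec$gene_fi_lt, 0.55)
  # a pair present at one time point only is dropped
  expect_equal(nrow(recurrent_pairs(st, st[0, ])), 0L)
  expect_equal(nrow(recurrent_pairs(st[0, ], lt[0, ])), 0L)
})

test_that("planted inverse pairs are recovered without false pairs", {
  # simulated study: pairs between called modulated sets and planted
  # guaranteed edges must all be found; pairs never contradict direction
  sim <- simulate_study(simulation_config(seed = 41))
  ratios <- normalize_probe_signals(sim$probe_signals$ST)
  meas <- summarize_mirna_measurements(ratios, "ST")
  ms <- call_modulated_mirnas(meas)
  gs <- call_modulated_genes(sim$mrna_ratios$ST, timepoint = "ST")
  pairs <- inverse_pairs(ms, gs, sim$predictions$microcosm)
  planted <- sim$truth$planted_pairs$ST
  truth_m <- sim$truth$modulated_mirnas$ST
  truth_g <- sim$truth$modulated_genes$ST
  # restrict to planted pairs whose members were indeed called
  active <- planted[planted$mirna_id %in% set_members(ms) &
                      planted$gene_id %in% set_members(gs), ]
  key <- function(d) paste(d$mirna_id, d$gene_id)
  expect_true(all(key(active) %in% key(pairs)))
  # every reported pair respects opposite planted directions
  dir_m <- truth_m$direction[match(pairs$mirna_id, truth_m$mirna_id)]
  dir_g <- truth_g$direction[match(pairs$gene_id, truth_g$gene_id)]
  known <- !is.na(dir_m) & !is.na(dir_g)
  expect_true(all(dir_m[known] != dir_g[known]))
})
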
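test_that("miRNA calling applies inclusive fold and strict p thresholds", {
  meas <- toy_measurements(
    c("a", "b", "c", "d", "e", "f"),
    fi = c(1.91, 1.4, 1.5, 0.66, 2.5, 1 / 1.5),
    p = c(0.003, 0.001, 0.0099, 0.005, 0.01, 0.002))
  set <- call_modulated_mirnas(meas)
  expect_setequal(set_members(set, "up"), c("a", "c"))   # 1.5 inclusive
  expect_setequal(set_members(set, "down"), c("d", "f")) # 1/1.5 inclusive
  expect_false("e" %in% set_members(set))                # p = 0.01 strict
  expect_false("b" %in% set_members(set))                # below fold

  expect_error(call_modulated_mirnas(
    rbind(meas, toy_measurements("g", 2, 0.001, tp = "IT"))),
    "mix time points")
})

test_that("raising the fold threshold never grows the modulated sets", {
  set.seed(21)
  meas <- toy_measurements(paste0("m", 1:200),
                           fi = 2^rnorm(200, 0, 1),
                           p = runif(200, 0, 0.02))
  prev_n <- Inf
  for (fc in c(1.2, 1.5, 2, 3)) {
    n <- nrow(call_modulated_mirnas(meas, fc_min = fc)$members)
    expect_lte(n, prev_n)
    prev_n <- n
  }
})

test_that("inverting fold inductions swaps up and down exactly", {
  set.seed(22)
  meas <- toy_measurements(paste0("m", 1:100),
                           fi = 2^rnorm(100, 0, 1),
                           p = runif(100, 0, 0.02))
  fwd <- call_modulated_mirnas(meas)
  inv <- meas; inv$fold_induction <- 1 / inv$fold_induction
  rev <- call_modulated_mirnas(inv)
  expect_setequal(set_members(fwd, "up"), set_members(rev, "down"))
  expect_setequal(set_members(fwd, "down"), set_members(rev, "up"))
})

test_that("gene calling follows the log-ratio and probe-consistency rules", {
  pr <- data.frame(
    gene_id = c("A", "B", "B", "C", "C", "D"),
    probe_id = paste0("p", 1:6),
    log_ratio_pool1 = c(0.7, 0.8, -0.1, 0.65, 0.2, -0.9),
    log_ratio_pool2 = c(0.7, 0.8, -0.1, 0.65, 0.2, -0.9))
  set <- call_modulated_genes(pr, timepoint = "ST")
  expect_true("A" %in% set_members(set, "up"))     # single probe past 0.6
  expect_false("B" %in% set_members(set))          # inconsistent direction
  expect_true("C" %in% set_members(set, "up"))     # one passes, signs agree
  expect_true("D" %in% set_members(set, "down"))
})

test_that("both-pools rule requires the fold change in each pool", {
  pr <- data.frame(
    gene_id = c("A", "B", "C"),
    probe_id = paste0("p", 1:3),
    log_ratio_pool1 = c(0.7, 0.7, 0.6),
    log_ratio_pool2 = c(0.9, 0.3, 0.6))
  set <- call_modulated_genes_both_pools(pr, timepoint = "ST")
  expect_true("A" %in% set_members(set, "up"))
  expect_false("B" %in% set_members(set))  # second pool below 1.5-fold
  # log2(1.5) = 0.585, so exactly 0.6 in both pools passes
  expect_true("C" %in% set_members(set, "up"))
})

test_that("recurrence over the reference fixture reproduces the published sets", {
  meas <- fixture_mirna_measurements()
  sets <- lapply(TIMEPOINTS, function(tp) {
    call_modulated_mirnas(meas[meas$timepoint == tp, ])
  })
  # only mmu-miR-146b is modulated at all three time points
  r3 <- recurrent_mirnas(sets, k = 3)
  expect_equal(r3$mirna_id, "mmu-miR-146b")
  expect_equal(r3$st_direction, "up")
  # thirteen miRNAs recur at two or more time points
  r2 <- recurrent_mirnas(sets, k = 2)
  expect_equal(nrow(r2), 13L)
  fix3 <- load_fixtures()$table3_recurrent
  expect_setequal(r2$mirna_id, fix3$mirna_id)
  # k = 1 is the union of the three membership sets
  r1 <- recurrent_mirnas(sets, k = 1)
  expect_setequal(r1$mirna_id, unique(unlist(lapply(sets, set_members))))
  # degenerate: no members at all
  empty <- lapply(TIMEPOINTS, function(tp) {
    modulated_set(tp, data.frame(id = character(),
                                 fold_induction = numeric()),
                  data.frame(id = character(),
                             fold_induction = numeric()), kind = "mirna")
  })
  expect_equal(nrow(recurrent_mirnas(empty, k = 1)), 0L)
})
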
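test_that("gene identifier normalization case-folds, trims and is idempotent", {
  expect_equal(normalize_gene_id("Arid4b"), "ARID4B")
  expect_equal(normalize_gene_id(" il6 "), "IL6")
  expect_equal(normalize_gene_id(normalize_gene_id("Arid4b")), "ARID4B")
  # order independence
  ids <- c("Arid4b", "Gmnn", "tOp2a")
  expect_equal(normalize_gene_id(rev(ids)), rev(normalize_gene_id(ids)))
  expect_error(normalize_gene_id(""), "invalid gene identifier")
})

test_that("miRNA tables parse, enforce invariants and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(mirna_id = c("mmu-miR-146b", "mmu-miR-223"),
                   timepoint = "ST",
                   fold_induction = c(1.91, 1.99),
                   p_value = c(0.003, 0.004))
  write_tsv(df, path)
  got <- read_mirna_table(path)
  expect_equal(nrow(got), 2L)
  expect_equal(got$fold_induction[got$mirna_id == "mmu-miR-146b"], 1.91)
  # round trip preserves the row multiset
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(got, path2)
  again <- read_mirna_table(path2)
  expect_equal(again[order(again$mirna_id), c(1, 3, 4)],
               got[order(got$mirna_id), c(1, 3, 4)])

  # empty file with header -> empty collection
  write_tsv(df[0, ], path)
  expect_equal(nrow(read_mirna_table(path)), 0L)

  # invariant violations are parse errors
  bad <- df; bad$fold_induction[1] <- 0
  write_tsv(bad, path)
  expect_error(read_mirna_table(path), "fold induction")
  bad <- df; bad$p_value[2] <- 1.2
  write_tsv(bad, path)
  expect_error(read_mirna_table(path), "p-value")
  write_tsv(df[, -4], path)
  expect_error(read_mirna_table(path), "missing column")
  dup <- rbind(df, df[1, ])
  write_tsv(dup, path)
  expect_error(read_mirna_table(path), "duplicated")
})

test_that("GMT reading normalizes genes, collapses duplicates, rejects short lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("WP441\tMMP pathway\tMMP2\tTIMP2",
               "WPX\tdup set\tIl6\til6\tIL6"), path)
  pw <- read_gmt(path)
  expect_equal(length(pw), 2L)
  expect_setequal(pw$WP441, c("MMP2", "TIMP2"))
  expect_equal(pw$WPX, "IL6")
  expect_equal(attr(pw, "description")[["WP441"]], "MMP pathway")

  writeLines("WPbad\tno genes", path)
  expect_error(read_gmt(path), "fewer than 3 fields")

  # a synthetic 117-set file yields 117 pathways and round-trips
  big <- setNames(lapply(1:117, function(i) paste0("G", i, "_", 1:5)),
                  paste0("WP", 1:117))
  write_gmt(big, path)
  back <- read_gmt(path)
  expect_equal(length(back), 117L)
  expect_equal(unname(lengths(back)), rep(5L, 117))
})

test_that("target predictions keep the minimum p-value per edge and do not pre-filter", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(mirna_id = c("mmu-miR-223", "mmu-miR-223",
                                "mmu-miR-223", "mmu-miR-1"),
                   gene_id = c("Arid4b", "ARID4B", "Cflar", "Fn1"),
                   p_value = c(0.01, 0.0009, 0.0068, 0.2))
  write_tsv(df, path)
  got <- read_target_predictions(path, "microcosm")
  expect_equal(nrow(got), 3L)
  expect_equal(got$p_value[got$gene_id == "ARID4B"], 0.0009)
  # an above-threshold prediction is retained at read time; filtering is
  # the pairing stage's job
  expect_true("FN1" %in% got$gene_id)
  expect_true(all(got$source_db == "microcosm"))

  bad <- df; bad$p_value[1] <- -1
  write_tsv(bad, path)
  expect_error(read_target_predictions(path, "microcosm"), "p-value")
})

test_that("universe membership is enforced at load", {
  uni <- make_universe(c("mmu-miR-1", "mmu-miR-223"), c("IL6", "FN1"))
  meas <- toy_measurements(c("mmu-miR-1", "mmu-miR-999"), c(2, 2), 0.001)
  expect_error(check_universe_membership(meas, uni), "mmu-miR-999")
  expect_silent(check_universe_membership(meas[1, ], uni))
})
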
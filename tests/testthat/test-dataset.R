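# Association tables, negative sampling, folds, masking, noise injection.

test_that("association tables truncate, collapse, and tally correctly", {
  t1 <- association_table(data.frame(drug_id = "d1", atc_code = "A03AA"),
                          level = 2, drug_universe = "d1")
  expect_identical(t1$codes, "A03")
  expect_identical(unname(t1$matrix[1, 1]), 1L)
  # truncation collapse: two leaves under one level-1 code share a column
  t2 <- association_table(data.frame(drug_id = c("d1", "d2"),
                                     atc_code = c("A03AA", "A09XX")),
                          level = 1, drug_universe = c("d1", "d2"))
  expect_identical(dim(t2$matrix), c(2L, 1L))
  expect_identical(unname(t2$matrix[, 1]), c(1L, 1L))
  # hand tally on 6 pairs across 3 drugs at level 3
  pr <- data.frame(drug_id = c("d1", "d1", "d2", "d2", "d3", "d3"),
                   atc_code = c("A03AA", "A03BX", "A03AC", "B01AA",
                                "B01AB", "B01AC"))
  t3 <- association_table(pr, 3, c("d1", "d2", "d3"))
  expect_identical(t3$codes, c("A03A", "A03B", "B01A"))
  expect_equal(unname(rowSums(t3$matrix)), c(2, 2, 1))
  expect_equal(unname(colSums(t3$matrix)), c(2, 1, 2))
  expect_error(association_table(pr, 3, c("d1", "d2")), "not in")
})

test_that("negative sampling balances labels and is seed-reproducible", {
  st <- small_study(n_drugs = 30, seed = 3)
  ps <- negative_sample(st$table, seed = 5)
  expect_identical(sum(ps$label == 1), sum(st$table$matrix == 1L))
  expect_identical(sum(ps$label == 0), sum(ps$label == 1))
  expect_true(all(st$table$matrix[cbind(ps$drug, ps$code)] == ps$label))
  neg <- ps[ps$label == 0, ]
  expect_false(anyDuplicated(neg[c("drug", "code")]) > 0)
  expect_identical(negative_sample(st$table, seed = 5), ps)
  expect_false(identical(negative_sample(st$table, seed = 6), ps))
  # degenerate: an all-ones table has no negatives to draw
  full <- association_table(data.frame(drug_id = c("d1", "d2", "d1", "d2"),
                                       atc_code = c("A01", "A01", "B02", "B02")),
                            2, c("d1", "d2"))
  expect_error(negative_sample(full, 1), "zero cells")
})

test_that("folds stratify by label and partition the pair set", {
  st <- small_study(n_drugs = 40, seed = 4)
  ps <- negative_sample(st$table, seed = 2)
  fd <- make_folds(ps, n_folds = 10, seed = 2)
  expect_setequal(unique(fd$fold), 1:10)
  # partition: every pair in exactly one test fold
  expect_identical(nrow(fd), nrow(ps))
  for (lab in 0:1) {
    sizes <- table(fd$fold[fd$label == lab])
    expect_lte(diff(range(sizes)), 1)
  }
  # 20 balanced pairs over 10 folds: one of each label per fold
  small <- ps[c(which(ps$label == 1)[1:10], which(ps$label == 0)[1:10]), ]
  fs <- make_folds(small, 10, seed = 1)
  expect_true(all(table(fs$fold, fs$label) == 1))
  expect_error(make_folds(ps[1:5, ], 10, 1), "fewer pairs")
})

test_that("masking zeroes test and target cells on a copy", {
  tab <- toy_table()
  before <- tab$matrix
  test_pairs <- data.frame(drug = 1L, code = 1L)
  target <- list(drug = 2L, code = 1L)
  mk <- mask_associations(tab, test_pairs, target)
  expect_identical(tab$matrix, before)         # copy-on-mask contract
  expect_identical(unname(mk$matrix[1, 1]), 0L)
  expect_identical(unname(mk$matrix[2, 1]), 0L)
  expect_identical(sum(before) - sum(mk$matrix), 2L)
  # masking a negative (already-zero) pair changes nothing
  mk2 <- mask_associations(tab, NULL, list(drug = 3L, code = 1L))
  expect_identical(mk2$matrix, before)
  expect_error(mask_associations(tab, data.frame(drug = 9L, code = 1L)),
               "out of bounds")
})

test_that("label-noise injection has exact floor counts and no duplicates", {
  st <- small_study(n_drugs = 50, seed = 9)
  ps <- negative_sample(st$table, seed = 3)
  P <- sum(ps$label == 1)
  expect_identical(inject_label_noise(ps, 0, "false_negative", st$table, 1),
                   as.data.frame(ps))
  fn <- inject_label_noise(ps, 0.2, "false_negative", st$table, seed = 4)
  expect_identical(nrow(fn), nrow(ps))
  expect_identical(sum(ps$label == 1) - sum(fn$label == 1),
                   as.integer(floor(0.2 * P)))
  fp <- inject_label_noise(ps, 0.2, "false_positive", st$table, seed = 4)
  expect_identical(nrow(fp), nrow(ps) + as.integer(floor(0.2 * P)))
  added <- fp[(nrow(ps) + 1):nrow(fp), ]
  expect_true(all(added$label == 1))
  expect_true(all(st$table$matrix[cbind(added$drug, added$code)] == 0L))
  expect_false(anyDuplicated(fp[c("drug", "code")]) > 0)
  expect_identical(inject_label_noise(ps, 0.2, "false_positive", st$table, 4),
                   fp)
  expect_error(inject_label_noise(ps, 0.7, "false_negative", st$table, 1),
               "0.5")
})

test_that("association TSV round-trips", {
  pr <- data.frame(drug_id = c("d1", "d2"), atc_code = c("A03AA", "B01AC"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_associations(pr, tmp)
  expect_identical(read_associations(tmp), pr)
})
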
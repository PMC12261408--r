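# Metrics against brute-force oracles, cross-validation mechanics, and
# the study runners.

test_that("auroc matches hand cases and the pairwise-count oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("auprc matches hand cases and the threshold-sweep oracle", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)),
               oracle_auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)))
  # single positive ranked last among N contributes precision 1/N
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1)), 1 / 4)
  expect_error(auprc(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("metrics agree with brute-force oracles on random instances", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))        # both classes present
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # coarse rounding => ties
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-9)
    expect_equal(auprc(scores, labels), oracle_auprc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("auroc is invariant under strictly monotone score transforms", {
  set.seed(77)
  scores <- runif(40); labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0, 1)
  a0 <- auroc(scores, labels)
  expect_equal(auroc(qlogis(scores), labels), a0)
  expect_equal(auroc(scores^3 + 2, labels), a0)
})

test_that("curve exports are consistent with the scalar metrics", {
  set.seed(9)
  scores <- runif(30); labels <- c(0, 1, rbinom(28, 1, 0.4))
  pr <- pr_points(scores, labels)
  expect_equal(sum(diff(c(0, pr$recall)) * pr$precision), auprc(scores, labels))
  rc <- roc_points(scores, labels)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("cross-validation aggregates fold metrics correctly", {
  st <- small_study(n_drugs = 25, seed = 33)
  cv <- ct_cv(st$table, st$sims["cs"], st$atc, n_folds = 5,
              config = ct_config(conv_kernel = 8, conv_stride = 4,
                                 model_width = 8, n_heads = 2, ffn_hidden = 8,
                                 n_blocks = 1, seed = 2),
              train = train_config(epochs = 1, batch_size = 16, seed = 3),
              seed = 5, tag = "toy")
  expect_length(cv$auroc, 5)
  expect_equal(cv$auroc_mean, mean(cv$auroc))
  expect_equal(cv$auroc_sd, stats::sd(cv$auroc))
  expect_true(all(cv$auroc >= 0 & cv$auroc <= 1))
  expect_setequal(unique(cv$predictions$fold), 1:5)
  # per-fold metrics recompute from that fold's predictions only
  f2 <- cv$predictions[cv$predictions$fold == 2, ]
  expect_equal(auroc(f2$score, f2$label), cv$auroc[2])
  expect_output(print(cv), "AUROC")
  # identical seeds reproduce the whole result
  cv2 <- ct_cv(st$table, st$sims["cs"], st$atc, n_folds = 5,
               config = cv$config, train = cv$train, seed = 5, tag = "toy")
  expect_identical(cv$auroc, cv2$auroc)
  expect_identical(cv$predictions$score, cv2$predictions$score)
})

test_that("channel subsets enumerate and adapt the head width", {
  st <- small_study(n_drugs = 20, seed = 37)
  cfg <- ct_config(conv_kernel = 8, conv_stride = 4, model_width = 8,
                   n_heads = 2, ffn_hidden = 8, n_blocks = 1, seed = 2)
  trn <- train_config(epochs = 1, batch_size = 16, seed = 3)
  res <- feature_combination_study(st$table, st$sims[c("cs", "ddi")], st$atc,
                                   n_folds = 3, config = cfg, train = trn,
                                   seed = 5)
  expect_named(res, c("cs", "ddi", "cs+ddi"))
  expect_identical(res$cs$channels, "cs")
  expect_error(feature_combination_study(st$table, st$sims, st$atc,
                                         subsets = list(character(0))),
               "non-empty")
  summ <- eval_summary(res)
  expect_identical(nrow(summ), 6L)
  tmpj <- withr::local_tempfile(fileext = ".json")
  tmpc <- withr::local_tempfile(fileext = ".csv")
  write_eval_results(res, tmpj, tmpc)
  expect_length(jsonlite::read_json(tmpj), 3)
  expect_identical(nrow(utils::read.csv(tmpc)), 6L)
})

test_that("the channel carrying planted signal wins the single-channel race", {
  # corpus where only chemical structure is enriched within branches
  st <- small_study(n_drugs = 60, seed = 41, shared_bits = 48L,
                    ddi_within = 0.01, se_pool = 0L)
  cfg <- ct_config(conv_kernel = 8, conv_stride = 4, model_width = 16,
                   n_heads = 4, ffn_hidden = 16, n_blocks = 1, seed = 2)
  trn <- train_config(epochs = 10, batch_size = 16, learning_rate = 5e-3,
                      seed = 3)
  res <- feature_combination_study(st$table, st$sims, st$atc,
                                   subsets = list("cs", "ddi", "se"),
                                   n_folds = 3, config = cfg, train = trn,
                                   seed = 7)
  expect_gt(res$cs$auroc_mean, res$ddi$auroc_mean)
  expect_gt(res$cs$auroc_mean, res$se$auroc_mean)
})

test_that("robustness runner perturbs training folds only, with exact counts", {
  st <- small_study(n_drugs = 30, seed = 43)
  cfg <- ct_config(conv_kernel = 8, conv_stride = 4, model_width = 8,
                   n_heads = 2, ffn_hidden = 8, n_blocks = 1, seed = 2)
  trn <- train_config(epochs = 1, batch_size = 16, seed = 3)
  res <- robustness_study(st$table, st$sims["cs"], st$atc,
                          fractions = c(-0.2, 0, 0.2), n_folds = 3,
                          config = cfg, train = trn, seed = 9)
  expect_named(res, c("-20%", "0%", "+20%"))
  base <- ct_cv(st$table, st$sims["cs"], st$atc, n_folds = 3, config = cfg,
                train = trn, seed = 9)
  # fraction 0 reproduces plain cross-validation exactly
  expect_identical(res[["0%"]]$auroc, base$auroc)
  expect_identical(res[["0%"]]$predictions$score, base$predictions$score)
  # evaluation label sets are untouched by the perturbations
  for (r in res)
    expect_identical(r$predictions[c("drug", "code", "label")],
                     base$predictions[c("drug", "code", "label")])
  expect_error(robustness_study(st$table, st$sims["cs"], st$atc,
                                fractions = 0.9), "0.5")
})
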
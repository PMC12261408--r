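# Evaluation: threshold-free metrics, cross-validation, and the runners
# for the channel-ablation and label-perturbation study designs.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the fraction of
#' (positive, negative) score pairs where the positive scores higher,
#' counting ties as one half. Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  .check_scores(scores, labels)
  pos <- labels == 1L
  if (!any(pos) || all(pos))
    stop_validation("AUROC needs both classes present")
  r <- rank(scores)
  np <- sum(pos); nn <- sum(!pos)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-curve (no interpolation) area: thresholds sweep the distinct score
#' values from high to low; tied scores enter together; the area is
#' `sum over steps of (recall increment) * precision at that step`.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  .check_scores(scores, labels)
  P <- sum(labels == 1L)
  if (P == 0L) stop_validation("AUPRC needs at least one positive label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # last index within each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

.check_scores <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) == 0L)
    stop_validation("scores and labels must be non-empty and of equal length")
  if (!all(labels %in% c(0L, 1L)))
    stop_validation("labels must be 0/1")
}

#' ROC / precision-recall curve points
#'
#' One row per distinct score threshold, for plotting or CSV export.
#'
#' @inheritParams auroc
#' @return data frame: `threshold`, `fpr`, `tpr` for [roc_points()];
#'   `threshold`, `recall`, `precision` for [pr_points()].
#' @export
roc_points <- function(scores, labels) {
  .check_scores(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  data.frame(threshold = s[last], fpr = fp / max(sum(1 - y), 1L),
             tpr = tp / max(sum(y), 1L))
}

#' @rdname roc_points
#' @export
pr_points <- function(scores, labels) {
  .check_scores(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  data.frame(threshold = s[last], recall = tp / sum(y),
             precision = tp / (tp + fp))
}

#' Cross-validated training and evaluation
#'
#' The full protocol: balanced negative sampling over the association
#' table, label-stratified fold assignment, per-fold fitting with
#' test-fold masking, and per-fold AUROC/AUPRC on that fold's test pairs
#' only (metrics are averaged over folds, never pooled).
#'
#' @param table an [association_table()].
#' @param drug_sims named list of drug-similarity matrices (the channels).
#' @param atc_sim ATC-code similarity matrix, or a
#'   `function(train_pairs, table)` returning one — the functional form is
#'   re-evaluated on each fold's training pairs, which keeps
#'   frequency-dependent measures (NPSim weights) free of test-fold
#'   information.
#' @param n_folds number of folds (default 10).
#' @param config a [ct_config()]; per-fold weight seeds are derived from
#'   `seed`.
#' @param train a [train_config()].
#' @param seed master seed for sampling, folding, initialisation and
#'   training.
#' @param shuffle_labels permute the sampled labels before folding — a
#'   null control that destroys every label-feature relation, so the
#'   expected AUROC is 0.5.
#' @param perturb optional `function(train_pairs, fold)` applied to each
#'   fold's training pairs (the robustness hook); evaluation labels are
#'   never touched.
#' @param leakage_check assert that every test-pair cell is zero in the
#'   masked table each fold trains on, and that test features carry zeroed
#'   target cells.
#' @param tag free-text experiment label carried into the result.
#' @param verbose print per-fold progress.
#' @return an object of class `"ct_cv"`: per-fold metrics, their
#'   mean/standard deviation, and all test-pair predictions.
#' @export
ct_cv <- function(table, drug_sims, atc_sim, n_folds = 10L,
                  config = ct_config(), train = train_config(), seed = 1L,
                  shuffle_labels = FALSE, perturb = NULL,
                  leakage_check = TRUE, tag = "cv", verbose = FALSE) {
  channels <- .check_channels(drug_sims)
  pairs <- negative_sample(table, seed)
  if (shuffle_labels) {
    set.seed(split_seed(seed, 4L))
    pairs$label <- sample(pairs$label)
  }
  pairs <- make_folds(pairs, n_folds, seed)
  fold_auroc <- numeric(n_folds); fold_auprc <- numeric(n_folds)
  preds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- pairs[pairs$fold == f, ]
    tr <- pairs[pairs$fold != f, ]
    if (!is.null(perturb)) tr <- perturb(tr, f)
    if (leakage_check) {
      masked <- mask_associations(table, test)
      if (any(masked$matrix[cbind(test$drug, test$code)] != 0))
        stop("leakage: a test-pair cell survived masking", call. = FALSE)
    }
    cfg_f <- config; cfg_f$seed <- split_seed(seed, 100L + f)
    trn_f <- train; trn_f$seed <- split_seed(seed, 300L + f)
    atc_f <- if (is.function(atc_sim)) atc_sim(tr, table) else atc_sim
    fit <- ct_fit(tr, table, drug_sims, atc_f, test_pairs = test,
                  config = cfg_f, train = trn_f)
    if (leakage_check) {
      fts <- batch_features(test, drug_sims[[1L]], atc_f, table, test)
      bad <- vapply(seq_along(fts), function(i) {
        fts[[i]][1L, test$code[i]] != 0 ||
          fts[[i]][2L, ncol(table$matrix) + test$drug[i]] != 0
      }, logical(1L))
      if (any(bad)) stop("leakage: unmasked target cell in a test feature",
                         call. = FALSE)
    }
    sc <- predict(fit, test)
    fold_auroc[f] <- auroc(sc, test$label)
    fold_auprc[f] <- auprc(sc, test$label)
    preds[[f]] <- data.frame(test[c("drug", "code", "label", "fold")], score = sc)
    if (verbose)
      message(sprintf("fold %2d/%d  AUROC %.4f  AUPRC %.4f",
                      f, n_folds, fold_auroc[f], fold_auprc[f]))
  }
  structure(list(tag = tag, level = table$level, channels = channels,
                 n_folds = n_folds, auroc = fold_auroc, auprc = fold_auprc,
                 auroc_mean = mean(fold_auroc), auroc_sd = stats::sd(fold_auroc),
                 auprc_mean = mean(fold_auprc), auprc_sd = stats::sd(fold_auprc),
                 predictions = do.call(rbind, preds),
                 config = config, train = train, seed = seed),
            class = "ct_cv")
}

#' @export
print.ct_cv <- function(x, ...) {
  cat(sprintf("<ct_cv> %s | level %d | channels %s | %d folds\n",
              x$tag, x$level, paste(x$channels, collapse = "+"), x$n_folds))
  cat(sprintf("  AUROC %.4f +/- %.4f   AUPRC %.4f +/- %.4f\n",
              x$auroc_mean, x$auroc_sd, x$auprc_mean, x$auprc_sd))
  invisible(x)
}

#' @export
summary.ct_cv <- function(object, ...) {
  print(object)
  print(data.frame(fold = seq_len(object$n_folds), auroc = round(object$auroc, 4),
                   auprc = round(object$auprc, 4)), row.names = FALSE)
  invisible(object)
}

#' Channel-ablation study
#'
#' Cross-validates every requested subset of the similarity channels; the
#' prediction head adapts its width to the number of channels present, so
#' single-channel runs use a one-embedding head.
#'
#' @inheritParams ct_cv
#' @param subsets list of character vectors (channel subsets); default all
#'   non-empty subsets of the supplied channels.
#' @param ... passed to [ct_cv()].
#' @return named list of `ct_cv` results, one per subset.
#' @export
feature_combination_study <- function(table, drug_sims, atc_sim,
                                      subsets = NULL, ...) {
  channels <- .check_channels(drug_sims)
  if (is.null(subsets)) {
    subsets <- unlist(lapply(seq_along(channels), function(k)
      utils::combn(channels, k, simplify = FALSE)), recursive = FALSE)
  }
  if (any(lengths(subsets) == 0L)) stop_validation("channel subsets must be non-empty")
  out <- lapply(subsets, function(ss) {
    if (!all(ss %in% channels))
      stop_validation("unknown channel in subset: %s", paste(ss, collapse = "+"))
    ct_cv(table, drug_sims[ss], atc_sim, tag = paste(ss, collapse = "+"), ...)
  })
  stats::setNames(out, vapply(subsets, paste, character(1L), collapse = "+"))
}

#' Label-perturbation robustness study
#'
#' Re-runs cross-validation while corrupting each fold's training labels:
#' negative fractions relabel that share of the training positives as
#' negatives (false negatives); positive fractions add that share of fresh
#' unobserved pairs as positives (false positives); 0 is the untouched
#' baseline. Test labels are never modified, so the reported change in
#' AUROC/AUPRC measures tolerance to training-set corruption.
#'
#' @inheritParams ct_cv
#' @param fractions signed perturbation strengths in `[-0.5, 0.5]`,
#'   e.g. `c(-0.2, -0.1, 0, 0.1, 0.2)`.
#' @param ... passed to [ct_cv()].
#' @return named list of `ct_cv` results, one per fraction (names like
#'   `"-20%"`, `"0%"`, `"+20%"`).
#' @export
robustness_study <- function(table, drug_sims, atc_sim,
                             fractions = c(-0.2, -0.1, 0, 0.1, 0.2),
                             seed = 1L, ...) {
  if (any(abs(fractions) > 0.5))
    stop_validation("perturbation fractions must lie within [-0.5, 0.5]")
  out <- lapply(fractions, function(f) {
    hook <- if (f == 0) NULL else {
      mode <- if (f < 0) "false_negative" else "false_positive"
      function(tr, fold)
        inject_label_noise(tr, abs(f), mode, table,
                           seed = split_seed(seed, 400L + fold))
    }
    tag <- sprintf("%+d%%", round(100 * f))
    ct_cv(table, drug_sims, atc_sim, seed = seed, perturb = hook,
          tag = if (f == 0) "0%" else tag, ...)
  })
  stats::setNames(out, vapply(out, `[[`, character(1L), "tag"))
}

#' Flatten evaluation results into a summary table
#'
#' @param results a `ct_cv` or a (possibly named) list of them.
#' @return data frame with columns `experiment`, `level`, `metric`,
#'   `mean`, `sd`.
#' @export
eval_summary <- function(results) {
  if (inherits(results, "ct_cv")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(experiment = r$tag, level = r$level,
               metric = c("auroc", "auprc"),
               mean = c(r$auroc_mean, r$auprc_mean),
               sd = c(r$auroc_sd, r$auprc_sd))))
}

#' Write evaluation results as JSON and CSV
#'
#' JSON carries the per-fold metric arrays plus the summary; CSV is the
#' flat [eval_summary()] table.
#'
#' @param results a `ct_cv` or list of them.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @export
write_eval_results <- function(results, json_path = NULL, csv_path = NULL) {
  if (inherits(results, "ct_cv")) results <- list(results)
  if (!is.null(json_path)) {
    payload <- lapply(results, function(r)
      list(tag = r$tag, level = r$level, channels = r$channels,
           auroc = r$auroc, auprc = r$auprc,
           auroc_mean = r$auroc_mean, auroc_sd = r$auroc_sd,
           auprc_mean = r$auprc_mean, auprc_sd = r$auprc_sd))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv_path))
    utils::write.csv(eval_summary(results), csv_path, row.names = FALSE)
  invisible(results)
}
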
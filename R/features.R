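# Per-pair feature aggregation: one 2 x (m + n) matrix per (drug, code)
# target and per similarity channel, combining the masked association
# table, one drug-drug similarity matrix, and the code-code similarity
# matrix.

#' Aggregate the per-pair feature matrix for one target
#'
#' Layout (columns align across the two rows; block order is
#' `[ATC block | drug block]`):
#' \itemize{
#'   \item row 1: the target drug's association row over the `m` codes,
#'     then its drug-drug similarity row over the `n` drugs;
#'   \item row 2: the target code's ATC-ATC similarity row over the `m`
#'     codes, then its association column over the `n` drugs.
#' }
#' So ATC-block column `j` pairs "does the drug carry code j" with "how
#' close is code j to the target code", and drug-block column `i` pairs
#' "how similar is drug i to the target drug" with "does drug i carry the
#' target code" — the aligned evidence the encoder consumes.
#'
#' `masked_table` must already be masked for this target (its cell zeroed);
#' [batch_features()] handles that bookkeeping. When `check_masked = TRUE`
#' the target positions are asserted to be zero.
#'
#' @param drug_index,code_index 1-based indices of the target pair.
#' @param drug_sim `n x n` drug similarity matrix.
#' @param atc_sim `m x m` ATC-code similarity matrix.
#' @param masked_table the masked [association_table()] (`n x m`).
#' @param check_masked assert the masked-target invariant.
#' @return a `2 x (m + n)` numeric matrix with attributes `drug_index`,
#'   `code_index`.
#' @export
aggregate_features <- function(drug_index, code_index, drug_sim, atc_sim,
                               masked_table, check_masked = TRUE) {
  stopifnot(inherits(masked_table, "assoc_table"))
  A <- masked_table$matrix
  n <- nrow(A); m <- ncol(A)
  if (!is.matrix(drug_sim) || nrow(drug_sim) != n || ncol(drug_sim) != n)
    stop_validation("`drug_sim` must be %d x %d (the drug axis), got %d x %d",
                    n, n, NROW(drug_sim), NCOL(drug_sim))
  if (!is.matrix(atc_sim) || nrow(atc_sim) != m || ncol(atc_sim) != m)
    stop_validation("`atc_sim` must be %d x %d (the code axis), got %d x %d",
                    m, m, NROW(atc_sim), NCOL(atc_sim))
  assert_scalar_int(drug_index, "drug_index", min = 1L, max = n)
  assert_scalar_int(code_index, "code_index", min = 1L, max = m)
  f <- rbind(c(A[drug_index, ], drug_sim[drug_index, ]),
             c(atc_sim[code_index, ], A[, code_index]))
  if (check_masked &&
      (f[1L, code_index] != 0 || f[2L, m + drug_index] != 0))
    stop_validation("target association cell is not masked: pair (%d, %d)",
                    drug_index, code_index)
  dimnames(f) <- NULL
  attr(f, "drug_index") <- drug_index
  attr(f, "code_index") <- code_index
  f
}

#' Assemble feature matrices for a batch of pairs, one channel
#'
#' Applies the two-stage masking protocol: the supplied table is first
#' masked for the current fold's test pairs, then each sample's own target
#' cell is zeroed on the fly, so every sample sees a table with its own
#' label hidden. Output order matches input pair order.
#'
#' @param pairs data frame with columns `drug`, `code`.
#' @param drug_sim `n x n` drug similarity matrix for one channel.
#' @param atc_sim `m x m` ATC similarity matrix.
#' @param table the unmasked [association_table()].
#' @param test_pairs pairs to mask out for the whole batch (the current
#'   fold's test set), or `NULL`.
#' @return list of `2 x (m + n)` matrices, one per input pair.
#' @export
batch_features <- function(pairs, drug_sim, atc_sim, table, test_pairs = NULL) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) return(list())
  fold_masked <- mask_associations(table, test_pairs)
  A <- fold_masked$matrix
  n <- nrow(A); m <- ncol(A)
  lapply(seq_len(nrow(pairs)), function(i) {
    d <- pairs$drug[i]; cc <- pairs$code[i]
    r1 <- c(A[d, ], drug_sim[d, ])
    r2 <- c(atc_sim[cc, ], A[, cc])
    r1[cc] <- 0          # target masking: the pair's own cell, both views
    r2[m + d] <- 0
    f <- rbind(r1, r2)
    dimnames(f) <- NULL
    attr(f, "drug_index") <- d
    attr(f, "code_index") <- cc
    f
  })
}

#' Export one pair's per-channel feature matrices as CSV (debug aid)
#'
#' @param features named list of feature matrices (one per channel), as
#'   produced by [aggregate_features()]/[batch_features()].
#' @param dir output directory; one `feature_<channel>.csv` per channel.
#' @export
write_feature_csv <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(features))
    utils::write.csv(features[[ch]], file.path(dir, paste0("feature_", ch, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}
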
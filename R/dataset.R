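# Drug-ATC association tables, balanced negative sampling, stratified
# cross-validation folds, leakage masking, and robustness-test label
# perturbation.

# vectorised truncation/validation of a code column; falls back to
# atc_parse() on the first bad entry to produce the positional error
.atc_truncate_vec <- function(codes, level) {
  codes <- toupper(trimws(codes))
  need <- ATC_LEVEL_LENGTHS[level]
  pat <- c("^[A-Z]$", "^[A-Z][0-9]{2}$", "^[A-Z][0-9]{2}[A-Z]$",
           "^[A-Z][0-9]{2}[A-Z]{2}$")[level]
  out <- substr(codes, 1L, need)
  bad <- which(nchar(codes) < need | !grepl(pat, out))
  if (length(bad)) atc_parse(codes[bad[1L]], level)  # raises the detailed error
  out
}

#' Build a binary drug x ATC-code association table at one level
#'
#' Codes are truncated to `level`; duplicate (drug, truncated-code) pairs
#' collapse onto the same cell. Cell `(i, j)` is 1 iff drug `i` carries
#' code `j`.
#'
#' @param pairs data frame (or 2-column object) with columns `drug_id` and
#'   `atc_code`, one row per known association.
#' @param level hierarchy level in 1..4.
#' @param drug_universe ordered character vector of all drug ids (rows of
#'   the table); every drug in `pairs` must appear here.
#' @return an object of class `"assoc_table"`: list with `matrix`
#'   (n x m binary, dimnamed), `level`, and the label vectors `drugs`,
#'   `codes`.
#' @export
association_table <- function(pairs, level, drug_universe) {
  assert_scalar_int(level, "level", min = 1L, max = 4L)
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) stop_validation("`pairs` needs columns drug_id, atc_code")
  drug_universe <- as.character(drug_universe)
  if (anyDuplicated(drug_universe)) stop_validation("duplicate ids in `drug_universe`")
  d <- as.character(pairs[[1L]])
  missing <- setdiff(unique(d), drug_universe)
  if (length(missing))
    stop_validation("drugs present in `pairs` but not in `drug_universe`: %s",
                    paste(missing, collapse = ", "))
  codes <- .atc_truncate_vec(as.character(pairs[[2L]]), level)
  code_labels <- sort(unique(codes))
  mat <- matrix(0L, length(drug_universe), length(code_labels),
                dimnames = list(drug_universe, code_labels))
  mat[cbind(match(d, drug_universe), match(codes, code_labels))] <- 1L
  structure(list(matrix = mat, level = as.integer(level),
                 drugs = drug_universe, codes = code_labels),
            class = "assoc_table")
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("<assoc_table> level %d: %d drugs x %d codes, %d positive cells\n",
              x$level, nrow(x$matrix), ncol(x$matrix), sum(x$matrix)))
  invisible(x)
}

#' Balanced positive/negative pair set from an association table
#'
#' Returns every positive cell plus an equal number of distinct zero cells
#' drawn uniformly at random, the balanced design the model is trained on.
#'
#' @param table an [association_table()].
#' @param seed RNG seed; the same seed reproduces the same pair list.
#' @return data frame of class `"pair_set"` with integer columns `drug`,
#'   `code` (indices into the table) and `label` (1/0).
#' @export
negative_sample <- function(table, seed) {
  stopifnot(inherits(table, "assoc_table"))
  pos <- which(table$matrix == 1L)
  zero <- which(table$matrix == 0L)
  if (length(pos) == 0L) stop_validation("association table has no positive cells")
  if (length(zero) < length(pos))
    stop_validation("not enough zero cells (%d) to balance %d positives",
                    length(zero), length(pos))
  neg <- local({
    set.seed(split_seed(seed, 1L))
    sample(zero, length(pos))
  })
  idx <- c(pos, neg)
  out <- data.frame(drug = row(table$matrix)[idx], code = col(table$matrix)[idx],
                    label = rep(1:0, c(length(pos), length(neg))))
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Stratified cross-validation folds over labeled pairs
#'
#' Partitions the pair list into `n_folds` test folds, stratified by label
#' so every fold keeps the overall positive/negative ratio; per label
#' stratum, fold sizes differ by at most one.
#'
#' @param pairs a labeled pair data frame (columns `drug`, `code`, `label`).
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed.
#' @return `pairs` with an added integer `fold` column in `1..n_folds`.
#' @export
make_folds <- function(pairs, n_folds = 10L, seed = 1L) {
  assert_scalar_int(n_folds, "n_folds", min = 2L)
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < n_folds)
    stop_validation("fewer pairs (%d) than folds (%d)", nrow(pairs), n_folds)
  fold <- integer(nrow(pairs))
  set.seed(split_seed(seed, 2L))
  for (lab in unique(pairs$label)) {
    idx <- which(pairs$label == lab)
    fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  pairs$fold <- fold
  class(pairs) <- c("pair_set", "data.frame")
  pairs
}

#' Mask test-fold and target cells of an association table
#'
#' Returns a copy of the table in which every test pair's cell and the
#' target pair's cell are set to 0; the input is left untouched. This is
#' the leakage guard: features built from the masked table never expose
#' the label of a test pair or of the pair currently being scored. Only
#' positive cells actually change (negative cells are already 0).
#'
#' @param table an [association_table()].
#' @param test_pairs data frame with columns `drug`, `code` (the current
#'   fold's test pairs); may be `NULL`.
#' @param target optional single pair (list or one-row data frame with
#'   `drug`, `code`) additionally zeroed.
#' @return a new `assoc_table`.
#' @export
mask_associations <- function(table, test_pairs = NULL, target = NULL) {
  stopifnot(inherits(table, "assoc_table"))
  m <- table$matrix
  zero_at <- function(d, cc) {
    if (any(d < 1 | d > nrow(m) | cc < 1 | cc > ncol(m)))
      stop_validation("pair indices out of bounds")
    m[cbind(d, cc)] <<- 0L
  }
  if (!is.null(test_pairs) && NROW(test_pairs) > 0L)
    zero_at(test_pairs$drug, test_pairs$code)
  if (!is.null(target)) zero_at(target$drug, target$code)
  out <- table
  out$matrix <- m
  out
}

#' Inject label noise into a training pair list (robustness protocol)
#'
#' Two perturbation modes over a pair list with `P` positives:
#' `"false_negative"` relabels `floor(fraction * P)` randomly chosen
#' positives as 0 (known associations planted in the negative set);
#' `"false_positive"` adds `floor(fraction * P)` fresh zero cells, not
#' already present in `pairs`, labeled 1 (unverified associations planted
#' in the positive set).
#'
#' @param pairs labeled pair data frame.
#' @param fraction perturbation strength in `[0, 0.5]`.
#' @param mode `"false_negative"` or `"false_positive"`.
#' @param table the [association_table()] the pairs refer to (source of
#'   fresh zero cells for `"false_positive"`).
#' @param seed RNG seed.
#' @return the perturbed pair list.
#' @export
inject_label_noise <- function(pairs, fraction,
                               mode = c("false_negative", "false_positive"),
                               table, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 0.5)
    stop_validation("`fraction` must lie in [0, 0.5]")
  pairs <- as.data.frame(pairs)
  p_idx <- which(pairs$label == 1L)
  n_flip <- floor(fraction * length(p_idx))
  if (n_flip == 0L) return(pairs)
  set.seed(split_seed(seed, 3L))
  if (mode == "false_negative") {
    pairs$label[sample(p_idx, n_flip)] <- 0L
  } else {
    stopifnot(inherits(table, "assoc_table"))
    zero <- which(table$matrix == 0L)
    used <- (pairs$code - 1L) * nrow(table$matrix) + pairs$drug
    avail <- setdiff(zero, used)
    if (length(avail) < n_flip)
      stop_validation("only %d unused zero cells available, need %d",
                      length(avail), n_flip)
    add <- sample(avail, n_flip)
    extra <- data.frame(drug = row(table$matrix)[add], code = col(table$matrix)[add],
                        label = 1L)
    for (cc in setdiff(names(pairs), names(extra))) extra[[cc]] <- NA
    pairs <- rbind(pairs, extra[names(pairs)])
  }
  class(pairs) <- c("pair_set", "data.frame")
  pairs
}

# --- delimited-text interfaces ---------------------------------------------

#' Read a drug-ATC association pair list
#'
#' TSV with header columns `drug_id`, `atc_code`.
#'
#' @param path file path.
#' @return data frame with columns `drug_id`, `atc_code`.
#' @export
read_associations <- function(path) {
  df <- .read_tsv(path, 2L, "association")
  data.frame(drug_id = df[[1L]], atc_code = toupper(df[[2L]]))
}

#' Write a drug-ATC association pair list
#' @param pairs data frame with columns `drug_id`, `atc_code`.
#' @param path output file.
#' @export
write_associations <- function(pairs, path) {
  utils::write.table(pairs[c("drug_id", "atc_code")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export labeled (and optionally folded) pairs as TSV
#'
#' Columns `drug_id`, `atc_code`, `label`, and `fold` when present,
#' resolving indices against the table's labels.
#'
#' @param pairs labeled pair data frame (indices into `table`).
#' @param table the [association_table()] the indices refer to.
#' @param path output file.
#' @export
write_pairs_tsv <- function(pairs, table, path) {
  out <- data.frame(drug_id = table$drugs[pairs$drug],
                    atc_code = table$codes[pairs$code],
                    label = pairs$label)
  if (!is.null(pairs$fold)) out$fold <- pairs$fold
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
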
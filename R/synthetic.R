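# Seeded synthetic corpora: an ATC-like prefix hierarchy, drugs assigned
# to leaves, and three feature channels whose within-branch enrichment is
# the planted, tunable signal every pipeline stage is tested against.

#' Synthetic corpus configuration
#'
#' Drugs are assigned uniformly to leaf codes of a fixed-depth ATC-format
#' hierarchy. The signal is planted per *branch* (level-2 subtree): every
#' drug in a branch carries the branch's shared fingerprint bits and
#' side-effect pool and interacts preferentially within the branch, on top
#' of sparse background noise. Label noise removes annotations (1 -> 0,
#' the missing-annotation failure mode) at the leaf level, so truth tables
#' at different levels stay consistent under prefix truncation; 0 -> 1
#' corruption is the job of [inject_label_noise()].
#'
#' @param n_drugs number of drugs.
#' @param branching children per hierarchy level, length 4
#'   (default `c(4, 3, 2, 2)`: 4 level-1 groups, 48 leaves).
#' @param n_bits fingerprint width.
#' @param shared_bits fingerprint bits shared by every drug of a branch.
#' @param bit_background per-bit background set probability.
#' @param ddi_within within-branch interaction edge probability.
#' @param ddi_background between-branch edge probability.
#' @param se_pool size of each branch's shared side-effect pool (drugs
#'   carry each pool member with probability 0.6).
#' @param se_background per-side-effect background carry probability.
#' @param se_universe number of distinct side-effect ids.
#' @param label_noise probability a (drug, leaf) annotation is dropped
#'   (< 0.5; a drug always keeps at least one annotation).
#' @param multi_code probability a drug carries a second, random leaf code.
#' @param seed RNG seed; the corpus is fully determined by it.
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_drugs = 200L, branching = c(4L, 3L, 2L, 2L),
                             n_bits = 1024L, shared_bits = 32L,
                             bit_background = 0.01, ddi_within = 0.3,
                             ddi_background = 0.01, se_pool = 20L,
                             se_background = 0.01, se_universe = 500L,
                             label_noise = 0.05, multi_code = 0.3,
                             seed = 1L) {
  assert_scalar_int(n_drugs, "n_drugs", min = 2L)
  if (length(branching) != 4L || any(branching < 1L))
    stop_validation("`branching` must give >= 1 children for each of the 4 levels")
  if (branching[1L] > 26L || branching[3L] > 26L || branching[4L] > 26L ||
      branching[2L] > 99L)
    stop_validation("branching exceeds the ATC label alphabet (26/99/26/26)")
  for (p in c(bit_background, ddi_within, ddi_background, se_background,
              multi_code))
    if (p < 0 || p > 1) stop_validation("probabilities must lie in [0, 1]")
  if (label_noise < 0 || label_noise >= 0.5)
    stop_validation("`label_noise` must lie in [0, 0.5)")
  assert_scalar_int(shared_bits, "shared_bits", min = 0L, max = n_bits)
  structure(as.list(environment()), class = "synthetic_config")
}

# all codes at each level, in ATC string format
.hierarchy_codes <- function(branching) {
  l1 <- LETTERS[seq_len(branching[1L])]
  l2 <- as.vector(t(outer(l1, sprintf("%02d", seq_len(branching[2L])), paste0)))
  l3 <- as.vector(t(outer(l2, LETTERS[seq_len(branching[3L])], paste0)))
  l4 <- as.vector(t(outer(l3, LETTERS[seq_len(branching[4L])], paste0)))
  list(l1, l2, l3, l4)
}

#' Generate a synthetic drug-ATC corpus
#'
#' @param config a [synthetic_config()].
#' @return an object of class `"synthetic_corpus"`: list with `drugs` (a
#'   [drug_set()]), `codes` (codes per level), `truth` (an
#'   [association_table()] per level, after label noise), `annotations`
#'   (the noisy drug/leaf pair list), and `config`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(split_seed(cfg$seed, 30L))
  codes <- .hierarchy_codes(cfg$branching)
  leaves <- codes[[4L]]
  branches <- codes[[2L]]
  n <- cfg$n_drugs
  drug_ids <- sprintf("D%04d", seq_len(n))

  # leaf assignment + optional second code
  leaf1 <- sample(leaves, n, replace = TRUE)
  extra <- stats::runif(n) < cfg$multi_code
  leaf2 <- ifelse(extra, sample(leaves, n, replace = TRUE), NA_character_)
  leaf2[!is.na(leaf2) & leaf2 == leaf1] <- NA_character_
  ann <- data.frame(drug_id = c(drug_ids, drug_ids[!is.na(leaf2)]),
                    atc_code = c(leaf1, leaf2[!is.na(leaf2)]))

  # label noise: drop annotations, never a drug's last one
  if (cfg$label_noise > 0) {
    drop_flag <- stats::runif(nrow(ann)) < cfg$label_noise
    for (i in which(drop_flag)) {  # never drop a drug's last annotation
      if (sum(ann$drug_id == ann$drug_id[i] & !drop_flag) == 0L)
        drop_flag[i] <- FALSE
    }
    ann <- ann[!drop_flag, , drop = FALSE]
  }

  branch_of <- substr(leaf1, 1L, 3L)  # features follow the primary leaf's branch

  # fingerprints: branch-shared bits + background
  pool_bits <- lapply(stats::setNames(branches, branches), function(b)
    sample.int(cfg$n_bits, cfg$shared_bits) - 1L)
  fingerprints <- lapply(seq_len(n), function(i) {
    bg <- which(stats::runif(cfg$n_bits) < cfg$bit_background) - 1L
    sort(unique(c(pool_bits[[branch_of[i]]], bg)))
  })
  names(fingerprints) <- drug_ids

  # undirected DDI edges, denser within branch
  pr <- outer(branch_of, branch_of, function(a, b)
    ifelse(a == b, cfg$ddi_within, cfg$ddi_background))
  up <- upper.tri(pr)
  edge <- up & matrix(stats::runif(n * n), n, n) < pr
  ei <- which(edge, arr.ind = TRUE)
  ddi <- lapply(stats::setNames(seq_len(n), drug_ids), function(i)
    drug_ids[c(ei[ei[, 1L] == i, 2L], ei[ei[, 2L] == i, 1L])])

  # side effects: branch pool (carried with prob 0.6) + background
  se_ids <- sprintf("SE%04d", seq_len(cfg$se_universe))
  pool_se <- lapply(stats::setNames(branches, branches), function(b)
    sample(se_ids, min(cfg$se_pool, cfg$se_universe)))
  side_effects <- lapply(seq_len(n), function(i) {
    own <- pool_se[[branch_of[i]]][stats::runif(cfg$se_pool) < 0.6]
    bg <- se_ids[stats::runif(cfg$se_universe) < cfg$se_background]
    unique(c(own, bg))
  })
  names(side_effects) <- drug_ids

  drugs <- drug_set(drug_ids, fingerprints, ddi, side_effects, cfg$n_bits)
  truth <- lapply(1:4, function(k) association_table(ann, k, drug_ids))
  structure(list(drugs = drugs, codes = codes, truth = truth,
                 annotations = ann, config = cfg),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d drugs | hierarchy %s (%d leaves) | %d annotations\n",
              x$config$n_drugs, paste(x$config$branching, collapse = "x"),
              length(x$codes[[4L]]), nrow(x$annotations)))
  invisible(x)
}

#' Planted-signal diagnostic for one channel
#'
#' Mean within-group minus mean between-group drug similarity, where two
#' drugs are grouped together when they share at least one true code at
#' `level`. Near zero when no signal is planted; grows with the sharing
#' parameters. Invariant to drug relabeling.
#'
#' @param corpus a [generate_corpus()] result.
#' @param channel `"cs"`, `"ddi"`, or `"se"`.
#' @param level grouping level (default 2, the branch level).
#' @return a single number (within minus between mean similarity).
#' @export
planted_signal_strength <- function(corpus, channel = c("cs", "ddi", "se"),
                                    level = 2L) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  channel <- match.arg(channel)
  sim <- drug_similarity_matrix(corpus$drugs, channel)
  A <- corpus$truth[[level]]$matrix
  shared <- tcrossprod(A) > 0
  up <- upper.tri(sim)
  mean(sim[up & shared]) - mean(sim[up & !shared])
}

#' Write a corpus in the package's TSV dialects
#'
#' Emits `drugs.tsv`, `fingerprints.tsv` (bit-position dialect),
#' `ddi.tsv`, `side_effects.tsv`, `associations.tsv` (leaf-level pairs),
#' and `manifest.json` (config + seed), readable back with the package's
#' readers.
#'
#' @param corpus a [generate_corpus()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- corpus$drugs
  utils::write.table(data.frame(drug_id = d$drug_ids), file.path(dir, "drugs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(drug_id = d$drug_ids,
               fingerprint = vapply(d$fingerprints[d$drug_ids], paste,
                                    character(1L), collapse = ",")),
    file.path(dir, "fingerprints.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  edges <- do.call(rbind, lapply(d$drug_ids, function(id) {
    p <- d$ddi_partners[[id]]
    p <- p[p > id]  # each undirected edge once
    if (length(p)) data.frame(drug_id_a = id, drug_id_b = p) else NULL
  }))
  if (is.null(edges)) edges <- data.frame(drug_id_a = character(0),
                                          drug_id_b = character(0))
  utils::write.table(edges, file.path(dir, "ddi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  se <- do.call(rbind, lapply(d$drug_ids, function(id) {
    s <- d$side_effects[[id]]
    if (length(s)) data.frame(drug_id = id, side_effect_id = s) else NULL
  }))
  if (is.null(se)) se <- data.frame(drug_id = character(0),
                                    side_effect_id = character(0))
  utils::write.table(se, file.path(dir, "side_effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_associations(corpus$annotations, file.path(dir, "associations.tsv"))
  jsonlite::write_json(c(unclass(corpus$config), list(format = "atcct-corpus")),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a corpus directory back into its components
#'
#' Counterpart of [write_corpus()]; also the input layer for real data
#' laid out in the same TSV dialects.
#'
#' @param dir directory holding `drugs.tsv`, `fingerprints.tsv`,
#'   `ddi.tsv`, `side_effects.tsv`, `associations.tsv`.
#' @param n_bits fingerprint width.
#' @return list with `drugs` (a [drug_set()]) and `annotations` (data
#'   frame `drug_id`, `atc_code`).
#' @export
read_corpus <- function(dir, n_bits = 1024L) {
  ids <- .read_tsv(file.path(dir, "drugs.tsv"), 1L, "drug list")[[1L]]
  drugs <- drug_set(ids,
                    fingerprints = read_fingerprints(file.path(dir, "fingerprints.tsv"),
                                                     n_bits),
                    ddi_partners = read_ddi(file.path(dir, "ddi.tsv")),
                    side_effects = read_side_effects(file.path(dir, "side_effects.tsv")),
                    n_bits = n_bits)
  list(drugs = drugs,
       annotations = read_associations(file.path(dir, "associations.tsv")))
}
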
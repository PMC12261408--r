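# Shared fixtures: tiny hand-built corpora, independent oracles, and a
# cache for the expensive study runs so several test files can share them.

# a 3-drug / 2-code toy with hand-checkable similarities
toy_table <- function() {
  pairs <- data.frame(drug_id = c("d1", "d2", "d3"),
                      atc_code = c("A01AA", "A01AB", "B02BC"))
  association_table(pairs, level = 2L, drug_universe = c("d1", "d2", "d3"))
}

toy_drug_set <- function() {
  drug_set(c("d1", "d2", "d3"),
           fingerprints = list(d1 = c(1L, 2L, 3L), d2 = c(2L, 3L, 4L),
                               d3 = c(10L, 11L)),
           ddi_partners = list(d1 = "d3", d3 = c("d1", "d2"), d2 = "d3"),
           side_effects = list(d1 = c("s1", "s2"), d2 = c("s1", "s2"),
                               d3 = "s9"))
}

# brute-force metric oracles, deliberately independent of the package path
oracle_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

oracle_auprc <- function(scores, labels) {
  P <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0; prev_rec <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# a small corpus + the matrices the model consumes, for pipeline tests
small_study <- function(n_drugs = 60L, seed = 7L, level = 3L, ...) {
  corpus <- generate_corpus(synthetic_config(n_drugs = n_drugs, seed = seed, ...))
  table <- corpus$truth[[level]]
  sims <- stats::setNames(lapply(c("cs", "ddi", "se"), function(ch)
    drug_similarity_matrix(corpus$drugs, ch)), c("cs", "ddi", "se"))
  atc <- atc_similarity_matrix(table$codes, "whs", level)
  list(corpus = corpus, table = table, sims = sims, atc = atc, level = level)
}

# configuration of the planted-signal study shared by the acceptance
# surface; results are computed once and cached across test blocks
.acc_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (!exists("rob", envir = .acc_cache)) {
    st <- small_study(n_drugs = 200L, seed = 11L, level = 3L)
    cfg <- ct_config(model_width = 32L, n_heads = 4L, n_blocks = 2L, seed = 5L)
    trn <- train_config(epochs = 20L, batch_size = 32L, learning_rate = 1e-2,
                        seed = 5L)
    .acc_cache$study <- st
    .acc_cache$rob <- robustness_study(st$table, st$sims, st$atc,
                                       fractions = c(-0.2, 0, 0.2),
                                       n_folds = 5L, config = cfg, train = trn,
                                       seed = 11L)
    .acc_cache$control <- ct_cv(st$table, st$sims, st$atc, n_folds = 5L,
                                config = cfg, train = trn, seed = 11L,
                                shuffle_labels = TRUE, tag = "permuted")
  }
  as.list(.acc_cache)
}
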
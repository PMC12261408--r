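# ATC hierarchy: parsing, prefix sets, and the three similarity measures.

test_that("parsing yields the prefix-set decomposition", {
  a <- atc_parse("A03AA", 4)
  expect_identical(a$prefixes, c("A", "A03", "A03A", "A03AA"))
  expect_identical(atc_parse("A03AA", 1)$prefixes, "A")
  # deeper-than-level codes truncate (level-5 annotation, level-4 analysis)
  expect_identical(atc_parse("B01AC06", 4)$prefixes,
                   c("B", "B01", "B01A", "B01AC"))
  expect_identical(atc_parse("a03aa", 2)$code, "A03")
})

test_that("malformed codes fail with a positional message", {
  expect_error(atc_parse("1XYZZ", 4), "position 1")
  expect_error(atc_parse("AX3AA", 4), "position 2")
  expect_error(atc_parse("A033A", 4), "position 4")
  expect_error(atc_parse("A0", 2), "too short")
  expect_error(atc_parse("", 1), "non-empty")
  expect_error(atc_parse("A03AA", 5), "<=")
})

test_that("shared prefix levels match the worked decomposition", {
  expect_identical(atc_shared_levels("A03AA", "A03BB", 4), 2L)
  expect_identical(atc_shared_levels("A03AA", "A03AA", 4), 4L)
  expect_identical(atc_shared_levels("A03AA", "B03AA", 4), 0L)
  for (k in 1:4)
    expect_identical(atc_shared_levels("C10AB05", "C10AB05", k), k)
})

test_that("level weights follow the quadratic-increment sum", {
  expect_identical(atc_level_weight(4, 0), 0)
  expect_identical(atc_level_weight(4, 2), 25)   # 16 + 9
  expect_identical(atc_level_weight(1, 1), 1)
  expect_identical(atc_level_weight(4, 4), 30)   # 16 + 9 + 4 + 1
  # increments are (k - n)^2, strictly decreasing in n
  for (k in 1:4) {
    inc <- diff(vapply(0:k, function(n) atc_level_weight(k, n), numeric(1)))
    expect_equal(inc, (k - (0:(k - 1)))^2)
    if (k > 1) expect_true(all(diff(inc) < 0))
  }
  expect_error(atc_level_weight(3, 4), ">= |<=")
})

test_that("weighted-hierarchical similarity matches hand evaluation", {
  # N = 2 shared levels: (2*25 + 16) / (2*30 + 16)
  expect_equal(atc_whs("A03AA", "A03BB", 4), 66 / 76)
  expect_equal(atc_whs("A03AA", "A03AA", 4), 1.0)
  # lower bound at full mismatch: k^2 / (2 Wkk + k^2)
  for (k in 1:4)
    expect_equal(atc_whs("A03AA", "B05BA", k),
                 k^2 / (2 * atc_level_weight(k, k) + k^2))
})

test_that("comparator similarities match their closed forms", {
  expect_equal(atc_rnpsim("A03AA", "A03BB", 4), 5 / 9)
  expect_equal(atc_rnpsim("A03AA", "A03AA", 3), 1.0)
  expect_equal(atc_rnpsim("A03AA", "B03AA", 1), 1 / 3)
  p1 <- npsim_params(c(A03AA = 1, A03BB = 1))
  expect_equal(atc_npsim("A03AA", "A03AA", p1, 4), 1.0)
  # d = 2 (k - N) = 4 under the tree-distance convention
  expect_equal(atc_npsim("A03AA", "A03BB", p1, 4), exp(-0.25 * 4))
  # inverse-frequency weights are unbounded above
  p2 <- npsim_params(c(A03AA = 0.5, A03BB = 0.25))
  expect_equal(atc_npsim("A03AA", "A03AA", p2, 4), 4.0)
  expect_equal(atc_npsim("A03BB", "A03BB", p2, 4), 16.0)
  expect_error(atc_npsim("A03AA", "Z99ZZ", p1, 4), "missing")
})

test_that("similarity measures are symmetric and monotone in shared depth", {
  set.seed(42)
  codes <- apply(expand.grid(LETTERS[1:3], "0", 1:3, LETTERS[1:2],
                             LETTERS[1:2]),
                 1, paste, collapse = "")
  # one frequency map per level: the weights live at the comparison level
  prms <- lapply(1:4, function(k) {
    lv <- unique(vapply(codes, function(cd) atc_parse(cd, k)$code, ""))
    npsim_params(stats::setNames(rep(1 / length(lv), length(lv)), lv))
  })
  for (i in 1:25) {
    a <- sample(codes, 1); b <- sample(codes, 1); k <- sample(1:4, 1)
    prm <- prms[[k]]
    expect_identical(atc_whs(a, b, k), atc_whs(b, a, k))
    expect_identical(atc_rnpsim(a, b, k), atc_rnpsim(b, a, k))
    expect_identical(atc_npsim(a, b, prm, k), atc_npsim(b, a, prm, k))
    expect_gte(atc_whs(a, b, k), k^2 / (2 * atc_level_weight(k, k) + k^2))
    expect_lte(atc_whs(a, b, k), 1)
  }
  # strict monotonicity in N at fixed k, via a nested code ladder
  ladder <- c("B02BA", "B02BB", "B02CA", "B03AA", "C03AA")  # N = 4,3,2,1,0 vs ref
  ref <- "B02BA"
  whs_vals <- vapply(ladder, function(cd) atc_whs(ref, cd, 4), numeric(1))
  rnp_vals <- vapply(ladder, function(cd) atc_rnpsim(ref, cd, 4), numeric(1))
  expect_true(all(diff(whs_vals) < 0))
  expect_true(all(diff(rnp_vals) < 0))
})

test_that("code frequencies are positive-sample proportions", {
  fr <- code_frequencies(c("A01AA", "A01AB", "B02BC", "A01AA"), level = 2)
  expect_equal(fr, c(A01 = 0.75, B02 = 0.25))
})

test_that("similarity matrices match element-wise brute force", {
  codes <- c("A03AA", "A03BB", "B01AC")
  for (meas in c("whs", "rnpsim")) {
    fn <- if (meas == "whs") atc_whs else atc_rnpsim
    for (k in c(1L, 2L, 4L)) {
      m <- atc_similarity_matrix(codes, meas, k)
      expect_true(isSymmetric(unname(m)))
      expect_equal(unname(diag(m)), rep(1, nrow(m)))
      trunc <- vapply(codes, function(cd) atc_parse(cd, k)$code, "")
      for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
        expect_equal(m[i, j], fn(rownames(m)[i], colnames(m)[j], k))
    }
  }
  prm <- npsim_params(c(A03A = 0.5, A03B = 0.25, B01A = 0.25))
  m <- atc_similarity_matrix(codes, "npsim", 3, prm)
  for (i in 1:3) for (j in 1:3)
    expect_equal(m[i, j], atc_npsim(rownames(m)[i], colnames(m)[j], prm, 3))
  # truncation duplicates collapse to one row
  m1 <- atc_similarity_matrix(c("A03AA", "A03AB"), "whs", 3)
  expect_identical(dim(m1), c(1L, 1L))
  expect_identical(atc_similarity_matrix("A03AA", "whs", 4)[1, 1], 1.0)
})
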
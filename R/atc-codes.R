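# ATC code hierarchy: parsing, prefix sets, and the three code-code
# similarity measures (weighted-hierarchical similarity and the two
# comparator formulas used by earlier kernel/residual-network predictors).

# Cumulative code length at each ATC level: 1 letter, +2 digits, +1 letter,
# +1 letter (level 5, the substance designation, is out of scope).
ATC_LEVEL_LENGTHS <- c(1L, 3L, 4L, 5L)

# regexes for the character class of each position range, used to point at
# the first offending position on parse failure
.atc_pos_class <- function(pos) {
  # positions: 1 letter, 2-3 digit, 4 letter, 5 letter
  if (pos == 1L || pos >= 4L) "[A-Z]" else "[0-9]"
}

#' Parse an ATC code at a given hierarchy level
#'
#' Validates the code against the ATC string format (letter, two digits,
#' letter, letter for levels 1-4), truncates it to `level`, and returns the
#' code together with its prefix set: the truncations to levels `1..level`.
#' Because prefixes nest, the size of the intersection of two codes' prefix
#' sets equals the number of hierarchy levels they share.
#'
#' Codes supplied deeper than `level` (including level-5 strings such as
#' `"B01AC06"`) are truncated, not rejected: real annotation files carry
#' level-4/5 codes while analyses run at levels 1-4.
#'
#' @param code ATC code string, e.g. `"A03AA"`. Case-insensitive; stored
#'   uppercase.
#' @param level target hierarchy level, integer in 1..4.
#' @return an object of class `"atc_code"`: a list with elements `code`
#'   (the truncated string), `level`, and `prefixes` (character vector of
#'   length `level`).
#' @examples
#' atc_parse("A03AA", 4)$prefixes  # "A" "A03" "A03A" "A03AA"
#' atc_parse("A03AA", 1)$prefixes  # "A"
#' @export
atc_parse <- function(code, level) {
  assert_scalar_int(level, "level", min = 1L, max = 4L)
  if (!is.character(code) || length(code) != 1L || is.na(code) || !nzchar(code))
    stop_validation("`code` must be a single non-empty string")
  code <- toupper(trimws(code))
  need <- ATC_LEVEL_LENGTHS[level]
  if (nchar(code) < need)
    stop_validation("ATC code '%s' is too short for level %d (need %d characters)",
                    code, level, need)
  code <- substr(code, 1L, need)
  for (pos in seq_len(need)) {
    ch <- substr(code, pos, pos)
    if (!grepl(paste0("^", .atc_pos_class(pos), "$"), ch))
      stop_validation("malformed ATC code '%s': character '%s' at position %d must match %s",
                      code, ch, pos, .atc_pos_class(pos))
  }
  structure(
    list(code = code, level = as.integer(level),
         prefixes = substr(rep(code, level), 1L, ATC_LEVEL_LENGTHS[seq_len(level)])),
    class = "atc_code"
  )
}

#' @export
print.atc_code <- function(x, ...) {
  cat(sprintf("<atc_code> %s (level %d): {%s}\n",
              x$code, x$level, paste(x$prefixes, collapse = ", ")))
  invisible(x)
}

# accept either an atc_code or a raw string wherever a code is expected
as_atc_code <- function(x, level) {
  if (inherits(x, "atc_code")) {
    if (x$level < level)
      stop_validation("code '%s' was parsed at level %d but level %d is required",
                      x$code, x$level, level)
    return(x)
  }
  atc_parse(x, level)
}

#' Number of hierarchy levels shared by two ATC codes
#'
#' The size of the intersection of the two codes' level-`k` prefix sets.
#' Prefixes nest, so this equals the depth of the longest common prefix
#' chain, an integer in `0..k`.
#'
#' @param a,b ATC codes (`atc_code` objects or strings).
#' @param k comparison level in 1..4.
#' @return integer in `0..k`.
#' @examples
#' atc_shared_levels("A03AA", "A03BB", 4)  # 2
#' @export
atc_shared_levels <- function(a, b, k) {
  assert_scalar_int(k, "k", min = 1L, max = 4L)
  a <- as_atc_code(a, k); b <- as_atc_code(b, k)
  sum(a$prefixes[seq_len(k)] == b$prefixes[seq_len(k)])
}

#' Cumulative hierarchy level weight
#'
#' The weight given to sharing the first `n` of `k` levels:
#' \eqn{W_k^n = \sum_{i=0}^{n-1} (k-i)^2}, with \eqn{W_k^0 = 0}. The
#' increment from `n` to `n+1` is \eqn{(k-n)^2}, so agreement at shallow
#' (anatomical/therapeutic) levels is rewarded more strongly than agreement
#' at deep (pharmacological/chemical) levels, where categories are finer.
#'
#' @param k target level, integer >= 1.
#' @param n number of shared levels, integer in `0..k`.
#' @return the integer-valued weight.
#' @examples
#' atc_level_weight(4, 0)  # 0
#' atc_level_weight(4, 2)  # 16 + 9 = 25
#' @export
atc_level_weight <- function(k, n) {
  assert_scalar_int(k, "k", min = 1L)
  assert_scalar_int(n, "n", min = 0L, max = k)
  if (n == 0L) return(0)
  i <- 0:(n - 1L)
  sum((k - i)^2)
}

#' Weighted-hierarchical similarity between two ATC codes
#'
#' \deqn{WHS_k(a_i, a_j) = \frac{2 W_k^{N_k(a_i,a_j)} + k^2}{2 W_k^k + k^2}}
#' where \eqn{N_k} is the number of shared levels ([atc_shared_levels()])
#' and \eqn{W_k^n} the cumulative level weight ([atc_level_weight()]). The
#' value lies in \eqn{(0, 1]}, is symmetric, and equals 1 iff the codes
#' agree through level `k`. At `k = 1` it coincides exactly with
#' [atc_rnpsim()].
#'
#' @inheritParams atc_shared_levels
#' @return similarity in `(0, 1]`.
#' @examples
#' atc_whs("A03AA", "A03BB", 4)  # (2*25 + 16) / (2*30 + 16) = 66/76
#' @export
atc_whs <- function(a, b, k) {
  n <- atc_shared_levels(a, b, k)
  (2 * atc_level_weight(k, n) + k^2) / (2 * atc_level_weight(k, k) + k^2)
}

#' Unweighted prefix-overlap similarity (residual-network comparator)
#'
#' \deqn{RNPSim_k(a_i, a_j) = \frac{2 N_k(a_i,a_j) + 1}{2k + 1}} — every
#' shared level counts equally. Range `[1/(2k+1), 1]`.
#'
#' @inheritParams atc_shared_levels
#' @return similarity in `[1/(2k+1), 1]`.
#' @export
atc_rnpsim <- function(a, b, k) {
  n <- atc_shared_levels(a, b, k)
  (2 * n + 1) / (2 * k + 1)
}

#' Frequency-weight parameters for the kernel-method ATC similarity
#'
#' The kernel-method comparator weights each code by the inverse of the
#' proportion of positive samples it occupies at its level, and decays with
#' tree distance. `code_frequency` must map every code that will be compared
#' to a frequency in `(0, 1]`; [code_frequencies()] computes it from an
#' association pair list (use the training split only, to avoid leaking
#' test-set frequencies into features).
#'
#' @param code_frequency named numeric vector: code -> proportion of
#'   positive samples, each in `(0, 1]`.
#' @param distance_scale decay rate on the tree distance; the published
#'   formula fixes 0.25.
#' @return an object of class `"npsim_params"`.
#' @export
npsim_params <- function(code_frequency, distance_scale = 0.25) {
  if (is.null(names(code_frequency)) || any(!nzchar(names(code_frequency))))
    stop_validation("`code_frequency` must be a named vector (names are ATC codes)")
  if (any(!is.finite(code_frequency)) || any(code_frequency <= 0) || any(code_frequency > 1))
    stop_validation("all code frequencies must lie in (0, 1]")
  structure(list(code_frequency = code_frequency,
                 distance_scale = distance_scale),
            class = "npsim_params")
}

#' Positive-sample frequency of each ATC code
#'
#' Proportion of association pairs (at one level) carrying each code; the
#' basis of the inverse-frequency weight in [atc_npsim()].
#'
#' @param codes character vector of ATC codes, one entry per positive
#'   association pair (repeats expected).
#' @param level hierarchy level used to truncate the codes.
#' @return named numeric vector of frequencies summing to 1.
#' @export
code_frequencies <- function(codes, level) {
  assert_scalar_int(level, "level", min = 1L, max = 4L)
  if (length(codes) == 0L) stop_validation("no codes supplied")
  codes <- vapply(codes, function(cd) atc_parse(cd, level)$code, character(1L),
                  USE.NAMES = FALSE)
  tab <- table(codes)
  stats::setNames(as.numeric(tab) / length(codes), names(tab))
}

#' Frequency-weighted exponential-decay ATC similarity (kernel comparator)
#'
#' \deqn{NPSim(a_i, a_j) = w(a_i)\, w(a_j)\, \exp(-0.25\, d(a_i, a_j))}
#' with \eqn{w(a) = 1/\mathrm{freq}(a)} and tree distance
#' \eqn{d(a_i,a_j) = 2 (k - N_k(a_i,a_j))}, the number of edges on the path
#' through the deepest common ancestor in the prefix tree. Unlike the other
#' two measures the value is not bounded by 1: rare codes have weights well
#' above 1 and the formula carries no normaliser.
#'
#' @inheritParams atc_shared_levels
#' @param params an [npsim_params()] object covering both codes.
#' @return non-negative similarity (unbounded above).
#' @export
atc_npsim <- function(a, b, params, k) {
  if (!inherits(params, "npsim_params"))
    stop_validation("`params` must be an npsim_params object")
  assert_scalar_int(k, "k", min = 1L, max = 4L)
  a <- as_atc_code(a, k); b <- as_atc_code(b, k)
  fa <- params$code_frequency[a$code]
  fb <- params$code_frequency[b$code]
  if (is.na(fa)) stop_validation("code '%s' missing from the frequency map", a$code)
  if (is.na(fb)) stop_validation("code '%s' missing from the frequency map", b$code)
  d <- 2 * (k - atc_shared_levels(a, b, k))
  unname((1 / fa) * (1 / fb) * exp(-params$distance_scale * d))
}

#' Pairwise ATC-code similarity matrix
#'
#' Assembles the code-code similarity matrix used in feature aggregation.
#' Codes are truncated to `level` first; duplicates arising from truncation
#' are collapsed to a single row/column (matrix labels must be unique keys).
#'
#' @param codes character vector of ATC codes (or list of `atc_code`s).
#' @param measure `"whs"`, `"rnpsim"`, or `"npsim"`.
#' @param level comparison level in 1..4.
#' @param params an [npsim_params()] object; required for `"npsim"`.
#' @return a symmetric numeric matrix with code dimnames; unit diagonal for
#'   `"whs"` and `"rnpsim"`.
#' @export
atc_similarity_matrix <- function(codes, measure = c("whs", "rnpsim", "npsim"),
                                  level, params = NULL) {
  measure <- match.arg(measure)
  assert_scalar_int(level, "level", min = 1L, max = 4L)
  if (length(codes) == 0L) stop_validation("`codes` must be non-empty")
  if (is.list(codes)) codes <- vapply(codes, function(x) as_atc_code(x, level)$code, character(1L))
  codes <- vapply(codes, function(cd) atc_parse(cd, level)$code, character(1L),
                  USE.NAMES = FALSE)
  codes <- unique(codes)
  m <- length(codes)

  # shared-level counts for all pairs: prefixes nest, so summing per-level
  # equality indicators gives the common-prefix depth directly
  nk <- matrix(0L, m, m)
  for (i in seq_len(level)) {
    p <- substr(codes, 1L, ATC_LEVEL_LENGTHS[i])
    nk <- nk + outer(p, p, "==")
  }

  sim <- switch(measure,
    whs = {
      w <- vapply(0:level, function(n) atc_level_weight(level, n), numeric(1L))
      (2 * matrix(w[nk + 1L], m, m) + level^2) / (2 * w[level + 1L] + level^2)
    },
    rnpsim = (2 * nk + 1) / (2 * level + 1),
    npsim = {
      if (is.null(params)) stop_validation("measure 'npsim' requires `params`")
      freq <- params$code_frequency[codes]
      if (anyNA(freq))
        stop_validation("codes missing from the frequency map: %s",
                        paste(codes[is.na(freq)], collapse = ", "))
      wts <- 1 / freq
      outer(wts, wts) * exp(-params$distance_scale * 2 * (level - nk))
    })
  dimnames(sim) <- list(codes, codes)
  sim
}
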
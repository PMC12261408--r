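# Drug-drug similarity channels: chemical structure (Tanimoto over
# fingerprint bit sets), drug-drug interactions and side effects (Jaccard
# over partner / side-effect sets).

DRUG_CHANNELS <- c("cs", "ddi", "se")

#' Build a drug corpus container
#'
#' Bundles, per drug, the three feature sets the similarity channels are
#' computed from: fingerprint bit positions, undirected interaction
#' partners, and side-effect identifiers. Drugs missing from a component
#' get the empty set.
#'
#' @param drug_ids character vector of unique drug identifiers; fixes row
#'   order everywhere downstream.
#' @param fingerprints named list (by drug id) of integer vectors of set-bit
#'   positions in `0..n_bits-1`.
#' @param ddi_partners named list of character vectors of interacting drug
#'   ids; a drug must not list itself.
#' @param side_effects named list of character vectors of side-effect ids.
#' @param n_bits fingerprint width (default 1024).
#' @return an object of class `"drug_set"`.
#' @export
drug_set <- function(drug_ids, fingerprints = list(), ddi_partners = list(),
                     side_effects = list(), n_bits = 1024L) {
  if (length(drug_ids) == 0L) stop_validation("`drug_ids` must be non-empty")
  if (anyDuplicated(drug_ids))
    stop_validation("duplicate drug ids: %s",
                    paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", "))
  assert_scalar_int(n_bits, "n_bits", min = 1L)
  fill <- function(lst, empty) {
    out <- stats::setNames(rep(list(empty), length(drug_ids)), drug_ids)
    keep <- intersect(names(lst), drug_ids)
    out[keep] <- lapply(lst[keep], unique)
    out
  }
  fp <- fill(fingerprints, integer(0))
  bad <- names(fp)[vapply(fp, function(b) length(b) && (min(b) < 0 || max(b) >= n_bits),
                          logical(1L))]
  if (length(bad))
    stop_validation("fingerprint bits out of range [0, %d) for: %s",
                    n_bits, paste(bad, collapse = ", "))
  ddi <- fill(ddi_partners, character(0))
  selfp <- names(ddi)[mapply(function(id, p) id %in% p, names(ddi), ddi)]
  if (length(selfp))
    stop_validation("drugs listed as their own interaction partner: %s",
                    paste(selfp, collapse = ", "))
  structure(list(drug_ids = as.character(drug_ids), fingerprints = fp,
                 ddi_partners = ddi, side_effects = fill(side_effects, character(0)),
                 n_bits = as.integer(n_bits)),
            class = "drug_set")
}

#' @export
print.drug_set <- function(x, ...) {
  nset <- function(l) sum(lengths(l) > 0)
  cat(sprintf("<drug_set> %d drugs | fingerprints: %d (width %d) | DDI: %d | SE: %d\n",
              length(x$drug_ids), nset(x$fingerprints), x$n_bits,
              nset(x$ddi_partners), nset(x$side_effects)))
  invisible(x)
}

#' Tanimoto coefficient between two bit sets
#'
#' Intersection over union of set-bit positions, the standard chemical
#' fingerprint similarity. Defined as 0 when both sets are empty: a drug
#' with no recorded bits carries no evidence of similarity.
#'
#' @param a,b integer vectors of set-bit positions.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) jaccard(a, b)

#' Jaccard coefficient between two sets
#'
#' `|a n b| / |a u b|`, with the empty-vs-empty case defined as 0 (no
#' shared evidence, rather than NaN or vacuous identity).
#'
#' @param a,b vectors interpreted as sets.
#' @return similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(a) + length(b) - (i <- length(intersect(a, b)))
  if (u == 0L) 0 else i / u
}

# intersection-over-union for a list of sets via a dense indicator matrix;
# empty-set rows (and the 0/0 diagonal they create) map to similarity 0
.set_overlap_matrix <- function(sets, ids) {
  universe <- unique(unlist(sets, use.names = FALSE))
  n <- length(sets)
  if (length(universe) == 0L)
    return(matrix(0, n, n, dimnames = list(ids, ids)))
  x <- matrix(0, n, length(universe))
  for (i in seq_len(n)) x[i, match(sets[[i]], universe)] <- 1
  inter <- tcrossprod(x)
  sizes <- rowSums(x)
  un <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(un == 0, 0, inter / un)
  dimnames(sim) <- list(ids, ids)
  sim
}

#' Pairwise drug-drug similarity matrix for one channel
#'
#' Applies [tanimoto()] to fingerprints (`"cs"`) or [jaccard()] to DDI
#' partner sets (`"ddi"`) / side-effect sets (`"se"`) for every drug pair.
#' Row/column order follows `drugs$drug_ids`. Diagonal entries are 1 except
#' for drugs whose feature set is empty, which are 0 by the empty-set
#' convention.
#'
#' @param drugs a [drug_set()].
#' @param channel one of `"cs"`, `"ddi"`, `"se"`.
#' @return symmetric numeric matrix in `[0, 1]` with drug-id dimnames and
#'   attribute `channel`.
#' @export
drug_similarity_matrix <- function(drugs, channel = c("cs", "ddi", "se")) {
  channel <- match.arg(channel)
  if (!inherits(drugs, "drug_set")) stop_validation("`drugs` must be a drug_set")
  sets <- switch(channel, cs = drugs$fingerprints, ddi = drugs$ddi_partners,
                 se = drugs$side_effects)
  sim <- .set_overlap_matrix(sets, drugs$drug_ids)
  attr(sim, "channel") <- channel
  sim
}

# --- delimited-text readers -------------------------------------------------

.read_tsv <- function(path, n_cols, what) {
  if (!file.exists(path)) stop_validation("%s file not found: %s", what, path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < n_cols)
    stop_validation("%s file %s needs >= %d tab-separated columns, found %d",
                    what, path, n_cols, ncol(df))
  df
}

#' Read a drug fingerprint table
#'
#' TSV with header columns `drug_id` and `fingerprint`. Two fingerprint
#' dialects are auto-detected per file: a hex string of exactly
#' `n_bits / 4` characters (bit 0 = most significant bit of the first hex
#' digit), or a comma-separated list of 0-based set-bit positions (empty
#' string = no bits set).
#'
#' @param path file path.
#' @param n_bits fingerprint width.
#' @return named list of integer bit-position vectors.
#' @export
read_fingerprints <- function(path, n_bits = 1024L) {
  df <- .read_tsv(path, 2L, "fingerprint")
  vals <- df[[2L]]
  hex_len <- n_bits %/% 4L
  is_hex <- all(nchar(vals) == hex_len & grepl("^[0-9a-fA-F]+$", vals))
  parse_one <- function(v) {
    if (is_hex) {
      nib <- strtoi(strsplit(v, "")[[1L]], base = 16L)
      bits <- which(as.logical(bitwAnd(rep(nib, each = 4L), c(8L, 4L, 2L, 1L)))) - 1L
      bits
    } else if (!nzchar(trimws(v))) integer(0)
    else {
      b <- suppressWarnings(as.integer(strsplit(v, ",")[[1L]]))
      if (anyNA(b)) stop_validation("unparseable fingerprint entry: '%s'", v)
      sort(unique(b))
    }
  }
  stats::setNames(lapply(vals, parse_one), df[[1L]])
}

#' Read an undirected drug-drug interaction edge list
#'
#' TSV with header columns `drug_id_a`, `drug_id_b`. Duplicate and
#' reversed-duplicate edges are collapsed; self-loops are dropped with a
#' warning.
#'
#' @param path file path.
#' @return named list: drug id -> character vector of partner ids.
#' @export
read_ddi <- function(path) {
  df <- .read_tsv(path, 2L, "DDI")
  a <- df[[1L]]; b <- df[[2L]]
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropping %d self-interaction edge(s)", sum(self)))
    a <- a[!self]; b <- b[!self]
  }
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]
  partners <- split(c(b, a), c(a, b))
  lapply(partners, unique)
}

#' Read a drug - side-effect pair list
#'
#' TSV with header columns `drug_id`, `side_effect_id`.
#'
#' @param path file path.
#' @return named list: drug id -> character vector of side-effect ids.
#' @export
read_side_effects <- function(path) {
  df <- .read_tsv(path, 2L, "side-effect")
  lapply(split(df[[2L]], df[[1L]]), unique)
}

#' Write a similarity matrix as CSV
#'
#' Header row plus first-column labels, the interchange format for all
#' similarity matrices (drug-drug and code-code).
#'
#' @param sim square matrix with dimnames.
#' @param path output file.
#' @export
write_similarity_csv <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, row.names = TRUE)
  invisible(path)
}

# --- optional SMILES -> circular fingerprint adapter ------------------------

#' Circular fingerprints from SMILES strings (optional chemistry adapter)
#'
#' Computes hashed circular (Morgan/ECFP-type) fingerprints by delegating to
#' an RDKit helper script run through the system `python`. This is an
#' optional convenience: the package's native input is a precomputed
#' fingerprint table ([read_fingerprints()]), and this adapter exists for
#' users who start from structures.
#'
#' Unparseable SMILES are reported via a warning and skipped, never silently
#' dropped; the skipped ids are attached as attribute `"skipped"`.
#'
#' @param smiles named character vector: drug id -> SMILES string.
#' @param radius circular neighbourhood radius (default 2, the
#'   ECFP4-equivalent setting).
#' @param n_bits fingerprint width (default 1024).
#' @param python path to a python executable with RDKit available.
#' @return named list of integer bit-position vectors for the parseable
#'   entries.
#' @export
fingerprints_from_smiles <- function(smiles, radius = 2L, n_bits = 1024L,
                                     python = Sys.which("python")) {
  if (length(smiles) == 0L) return(list())
  if (is.null(names(smiles)) || any(!nzchar(names(smiles))))
    stop_validation("`smiles` must be a named character vector (names are drug ids)")
  script <- system.file("python", "ecfp_bits.py", package = "atcct")
  ok <- nzchar(python) && nzchar(script) &&
    identical(suppressWarnings(
      system2(python, c("-c", shQuote("import rdkit")), stdout = FALSE, stderr = FALSE)), 0L)
  if (!ok)
    stop("no usable chemistry toolkit (python + rdkit) found; supply precomputed ",
         "fingerprints via read_fingerprints() instead", call. = FALSE)
  infile <- tempfile(fileext = ".tsv"); on.exit(unlink(infile), add = TRUE)
  utils::write.table(data.frame(id = names(smiles), smiles = unname(smiles)),
                     infile, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  out <- system2(python, c(script, infile, as.character(radius), as.character(n_bits)),
                 stdout = TRUE, stderr = FALSE)
  status <- attr(out, "status") %||% 0L
  if (status != 0L) stop("fingerprint helper failed (exit ", status, ")", call. = FALSE)
  parts <- strsplit(out, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  bits <- lapply(parts, function(p) if (length(p) < 2L || p[[2L]] == "FAIL") NULL
                 else if (!nzchar(p[[2L]])) integer(0)
                 else as.integer(strsplit(p[[2L]], ",")[[1L]]))
  failed <- ids[vapply(bits, is.null, logical(1L))]
  if (length(failed))
    warning(sprintf("skipped %d unparseable SMILES: %s", length(failed),
                    paste(failed, collapse = ", ")))
  keep <- !vapply(bits, is.null, logical(1L))
  res <- stats::setNames(bits[keep], ids[keep])
  attr(res, "skipped") <- failed
  res
}
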
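## Pairwise alignment, E-values, hit tables, best hits and reciprocal best
## hits.
##
## Alignment is delegated to Biostrings::pairwiseAlignment (BLOSUM62, affine
## gaps open 11 / extend 1).  Local raw scores are converted to bit scores
## with the published gapped BLOSUM62 Karlin-Altschul constants
## (lambda = 0.267, K = 0.041) and E-values follow E = m * n * 2^(-S'), a
## deterministic stand-in for a BLAST search whose database size is the
## total residue count of the subject set.

KA_LAMBDA <- 0.267
KA_K <- 0.041
GAP_OPEN <- 11
GAP_EXTEND <- 1

## BLOSUM62 matrix cached from Biostrings on first use.
.pkgCache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkgCache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$BLOSUM62 <- e$BLOSUM62
  }
  .pkgCache$BLOSUM62
}

.checkSeq <- function(x, what = "sequence") {
  if (is(x, "AAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    .stopf("%s must be a single non-empty amino-acid string", what)
  x
}

#' Global alignment score and identity of two sequences
#'
#' Needleman-Wunsch with BLOSUM62, affine gaps (open 11, extend 1) and
#' penalized end gaps.  Identity is the number of identical aligned residue
#' pairs divided by the total number of alignment columns, gap columns
#' included in the denominator (the strictest common convention).
#'
#' @param a,b Amino-acid strings.
#' @return `alignGlobal`: list with `score` (raw, matrix units) and
#'   `identity` (fraction in \[0, 1\]); `globalIdentity`: the identity alone.
#' @export
#' @examples
#' globalIdentity("AAAA", "AATA")  # 0.75
alignGlobal <- function(a, b) {
  a <- .checkSeq(a); b <- .checkSeq(b)
  aln <- pairwiseAlignment(AAString(a), AAString(b), type = "global",
                           substitutionMatrix = .blosum62(),
                           gapOpening = GAP_OPEN, gapExtension = GAP_EXTEND)
  list(score = score(aln), identity = nmatch(aln) / nchar(aln))
}

#' @rdname alignGlobal
#' @export
globalIdentity <- function(a, b) alignGlobal(a, b)$identity

#' Local alignment score in bits
#'
#' Smith-Waterman with BLOSUM62, affine gaps (open 11, extend 1); the raw
#' score S is converted to bits via S' = (lambda * S - ln K) / ln 2 with
#' lambda = 0.267, K = 0.041 (gapped BLOSUM62 constants).
#'
#' @param a,b Amino-acid strings.
#' @return `alignLocal`: list with `score` (raw) and `bits`;
#'   `localScore`: the bit score alone.
#' @export
alignLocal <- function(a, b) {
  a <- .checkSeq(a); b <- .checkSeq(b)
  aln <- pairwiseAlignment(AAString(a), AAString(b), type = "local",
                           substitutionMatrix = .blosum62(),
                           gapOpening = GAP_OPEN, gapExtension = GAP_EXTEND)
  raw <- max(0, score(aln))
  list(score = raw, bits = .rawToBits(raw))
}

#' @rdname alignGlobal
#' @export
localScore <- function(a, b) alignLocal(a, b)$bits

.rawToBits <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)

#' Karlin-Altschul expectation value
#'
#' `E = queryLen * dbResidues * 2^(-bits)`: monotone decreasing in the bit
#' score and linear in either length.
#'
#' @param bits Bit score.
#' @param queryLen Query length in residues (> 0).
#' @param dbResidues Total residues in the searched database (> 0).
#' @return Expectation value.
#' @export
eValue <- function(bits, queryLen, dbResidues) {
  if (any(queryLen <= 0) || any(dbResidues <= 0))
    .stopf("queryLen and dbResidues must be positive")
  queryLen * dbResidues * 2^(-bits)
}

#' Apply similarity-search thresholds to a hit table
#'
#' Both bounds are inclusive: rows pass with
#' `global_identity >= minIdentity` and `evalue <= maxEvalue`.
#'
#' @param hits Hit table with columns `global_identity` and `evalue`.
#' @param thresholds A [SearchThresholds-class].
#' @return The passing rows.
#' @export
filterHits <- function(hits, thresholds) {
  validObject(thresholds)
  hits[hits$global_identity >= thresholds@minIdentity &
         hits$evalue <= thresholds@maxEvalue, , drop = FALSE]
}

## Local raw scores of one query against a subject set (vectorized).
.localScoresVec <- function(subjectSet, querySeq) {
  pmax(0, pairwiseAlignment(subjectSet, querySeq, type = "local",
                            substitutionMatrix = .blosum62(),
                            gapOpening = GAP_OPEN,
                            gapExtension = GAP_EXTEND, scoreOnly = TRUE))
}

## Global identities of one query against a subject set (vectorized).
.globalIdentitiesVec <- function(subjectSet, querySeq) {
  aln <- pairwiseAlignment(subjectSet, querySeq, type = "global",
                           substitutionMatrix = .blosum62(),
                           gapOpening = GAP_OPEN, gapExtension = GAP_EXTEND)
  nmatch(aln) / nchar(aln)
}

## All-pairs local bit scores between two id sets, exploiting symmetry when
## the sets are identical.  Returns data.frame(query_id, subject_id, bits)
## with both orientations present and self-pairs excluded.
.pairBits <- function(qseqs, sseqs) {
  symmetric <- identical(names(qseqs), names(sseqs))
  qs <- lapply(seq_along(qseqs), function(i) {
    js <- if (symmetric) seq_len(i - 1L) else seq_along(sseqs)
    js <- js[names(sseqs)[js] != names(qseqs)[i]]
    if (!length(js)) return(NULL)
    raw <- .localScoresVec(sseqs[js], qseqs[[i]])
    data.frame(query_id = names(qseqs)[i], subject_id = names(sseqs)[js],
               bits = .rawToBits(raw), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, qs)
  if (is.null(res))
    res <- data.frame(query_id = character(), subject_id = character(),
                      bits = numeric(), stringsAsFactors = FALSE)
  if (symmetric && nrow(res)) {
    res <- rbind(res, data.frame(query_id = res$subject_id,
                                 subject_id = res$query_id,
                                 bits = res$bits, stringsAsFactors = FALSE))
  }
  res
}

## Compute global identities for a set of (query, subject) id pairs,
## computing each unordered pair once.
.identitiesForPairs <- function(pairs, seqs) {
  if (!nrow(pairs)) return(numeric())
  key <- ifelse(pairs$query_id < pairs$subject_id,
                paste(pairs$query_id, pairs$subject_id),
                paste(pairs$subject_id, pairs$query_id))
  uniq <- !duplicated(key)
  up <- pairs[uniq, , drop = FALSE]
  ident <- numeric(nrow(up))
  byQuery <- split(seq_len(nrow(up)), up$query_id)
  for (q in names(byQuery)) {
    rows <- byQuery[[q]]
    ident[rows] <- .globalIdentitiesVec(seqs[up$subject_id[rows]], seqs[[q]])
  }
  stats::setNames(ident, key[uniq])[key]
}

#' All-versus-all similarity search between two proteome sets
#'
#' Computes local bit scores for every query-subject pair (self-pairs
#' excluded), converts them to E-values against a database size equal to
#' the total residue count of the subject set, and keeps pairs passing both
#' thresholds; pairwise global identities are computed for the E-value
#' survivors only (raising `minIdentity` or lowering `maxEvalue` can
#' therefore only remove rows, never add them).
#'
#' @param query,subject [ProteomeSet-class] objects sharing a registry; the
#'   same object may be passed twice for a within-set search.
#' @param thresholds A [SearchThresholds-class].
#' @return data.frame with columns `query_id`, `subject_id`, `query_taxon`,
#'   `subject_taxon`, `bit_score`, `evalue`, `global_identity`, sorted by
#'   (query_id, subject_id).
#' @export
searchHits <- function(query, subject, thresholds = searchThresholds()) {
  validObject(thresholds)
  qseqs <- proteinSequences(query)
  sseqs <- proteinSequences(subject)
  if (!length(qseqs) || !length(sseqs))
    .stopf("query and subject sets must be non-empty")
  dbRes <- sum(width(sseqs))
  bits <- .pairBits(qseqs, sseqs)
  .hitsFromBits(bits, query, subject, dbRes, thresholds)
}

## Shared tail of searchHits: E-value filter, identity computation and
## filter, taxon annotation, canonical sort.
.hitsFromBits <- function(bits, query, subject, dbRes, thresholds,
                          identities = NULL) {
  qw <- stats::setNames(width(proteinSequences(query)), proteinIds(query))
  bits$evalue <- eValue(bits$bits, qw[bits$query_id], dbRes)
  bits <- bits[bits$evalue <= thresholds@maxEvalue, , drop = FALSE]
  if (nrow(bits)) {
    if (is.null(identities)) {
      seqs <- c(proteinSequences(query), proteinSequences(subject))
      seqs <- seqs[!duplicated(names(seqs))]
      bits$global_identity <- .identitiesForPairs(bits, seqs)
    } else {
      key <- .pairKey(bits$query_id, bits$subject_id)
      bits$global_identity <- unname(identities[key])
    }
    bits <- bits[bits$global_identity >= thresholds@minIdentity, ,
                 drop = FALSE]
  } else {
    bits$global_identity <- numeric()
  }
  qt <- proteinTaxon(query)
  st <- proteinTaxon(subject)
  out <- data.frame(query_id = bits$query_id, subject_id = bits$subject_id,
                    query_taxon = unname(qt[bits$query_id]),
                    subject_taxon = unname(st[bits$subject_id]),
                    bit_score = bits$bits, evalue = bits$evalue,
                    global_identity = bits$global_identity,
                    stringsAsFactors = FALSE)
  out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.pairKey <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))

#' Best hits from a hit table
#'
#' For each query (and, with `by = "subject_taxon"`, each subject
#' proteome), the passing hit with the highest bit score; ties are broken
#' by lower E-value, then by lexicographically smaller subject id.  Queries
#' without any passing hit are absent.  `by = "subject_set"` (one best hit
#' over the whole subject set) is the mode used for reciprocal best cluster
#' votes; `by = "subject_taxon"` (one best hit per subject proteome, the
#' classic orthology convention) is the mode feeding reciprocal best hits
#' for family clustering.
#'
#' @param hits Hit table from [searchHits()].
#' @param by `"subject_set"` or `"subject_taxon"`.
#' @return The selected rows of `hits`.
#' @export
bestHits <- function(hits, by = c("subject_set", "subject_taxon")) {
  by <- match.arg(by)
  if (!nrow(hits)) return(hits)
  o <- order(hits$query_id, -hits$bit_score, hits$evalue, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  key <- if (by == "subject_taxon")
    paste(h$query_id, h$subject_taxon) else h$query_id
  h <- h[!duplicated(key), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Reciprocal best hits
#'
#' A pair \{a, b\} is reciprocal iff b is a's best hit and a is b's best
#' hit (within the grouping the best-hit tables were computed under).  For
#' a within-set search pass the same best-hit table twice.
#'
#' @param bhAB,bhBA Best-hit tables from [bestHits()].
#' @return data.frame with columns `a`, `b` (`a < b`), each row one
#'   unordered reciprocal pair.
#' @export
reciprocalBestHits <- function(bhAB, bhBA = bhAB) {
  if (!nrow(bhAB) || !nrow(bhBA))
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  fwd <- paste(bhAB$query_id, bhAB$subject_id)
  rev <- paste(bhBA$subject_id, bhBA$query_id)
  keep <- bhAB[fwd %in% rev, , drop = FALSE]
  a <- pmin(keep$query_id, keep$subject_id)
  b <- pmax(keep$query_id, keep$subject_id)
  pairs <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}
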
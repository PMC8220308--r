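## Presence-absence pattern matrices and deterministic row/column orderings.

#' Build a presence-absence pattern matrix
#'
#' Cell (f, c) is true iff row f (a family or EPC) has at least one member
#' protein in taxon/group c.  In group mode, archaeal groups with fewer
#' registry members than `minGroupMembers` are pooled into a single
#' `"Other Archaea"` column (default 15, the usual figure-legend cutoff).
#'
#' @param membership data.frame `row_id`, `protein_id` (for EPC matrices,
#'   pass the union of the member proteins of each EPC's linked clusters).
#' @param proteomes [ProteomeSet-class] resolving protein taxa.
#' @param columns `"taxon"` or `"group"`.
#' @param minGroupMembers Pooling cutoff for archaeal groups in group mode.
#' @return A [PAPMatrix-class]; rows and columns are sorted by key.
#' @export
buildPap <- function(membership, proteomes, columns = c("taxon", "group"),
                     minGroupMembers = 15L) {
  columns <- match.arg(columns)
  reg <- proteomes@registry
  tab <- taxonTable(reg)
  ptax <- proteinTaxon(proteomes)
  tax <- unname(ptax[membership$protein_id])
  if (anyNA(tax))
    .stopf("member protein(s) missing from the proteome set: %s",
           paste(utils::head(
             membership$protein_id[is.na(tax)], 3L), collapse = ", "))
  if (columns == "taxon") {
    colKey <- tax
    meta <- data.frame(column = tab$taxon_id, domain = tab$domain,
                       group = tab$group, stringsAsFactors = FALSE)
  } else {
    grp <- taxonField(reg, "group")
    dom <- taxonField(reg, "domain")
    groupSizes <- table(tab$group[tab$domain == "archaea"])
    poolName <- "Other Archaea"
    colOf <- function(t) {
      g <- grp[t]
      ifelse(dom[t] == "archaea" & groupSizes[g] < minGroupMembers,
             poolName, g)
    }
    colKey <- unname(colOf(tax))
    meta <- unique(data.frame(column = unname(colOf(tab$taxon_id)),
                              domain = tab$domain,
                              stringsAsFactors = FALSE))
    meta$group <- ifelse(meta$column == poolName, poolName, meta$column)
  }
  rows <- sort(unique(membership$row_id))
  cols <- sort(unique(meta$column))
  meta <- meta[!duplicated(meta$column), , drop = FALSE]
  meta <- meta[match(cols, meta$column), , drop = FALSE]
  rownames(meta) <- NULL
  m <- matrix(FALSE, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(membership$row_id, rows), match(colKey, cols))] <- TRUE
  new("PAPMatrix", mat = m, colMeta = meta)
}

#' Sort PAP rows by their eukaryotic supergroup distribution
#'
#' Rows are ordered by (number of supergroups present, descending), then by
#' the 6-bit presence pattern read as a binary number (descending; bit
#' order follows the supergroup list), then by row key (ascending) -- a
#' fully deterministic composite key.
#'
#' @param pap A [PAPMatrix-class].
#' @param supergroups Supergroup list defining the bit order.
#' @return Character vector of row keys in sorted order.
#' @export
sortRowsBySupergroupPattern <- function(pap,
                                        supergroups = eukSupergroups()) {
  m <- papMatrix(pap)
  meta <- papColumnMeta(pap)
  pres <- vapply(supergroups, function(g) {
    cols <- meta$column[!is.na(meta$group) & meta$group == g &
                          meta$domain == "eukaryote"]
    if (!length(cols)) return(rep(FALSE, nrow(m)))
    if (length(cols) == 1L) m[, cols] else rowSums(m[, cols, drop = FALSE]) > 0
  }, logical(nrow(m)))
  if (nrow(m) == 1L) pres <- matrix(pres, nrow = 1L)
  counts <- rowSums(pres)
  patternKey <- as.vector(pres %*% 2^(rev(seq_along(supergroups)) - 1L))
  rownames(m)[order(-counts, -patternKey, rownames(m))]
}

## Jaccard distance between logical columns; two all-empty profiles are at
## distance 0 (dist(method = "binary") would yield NaN there).
.jaccardDist <- function(mat) {
  d <- stats::dist(Matrix::t(mat), method = "binary")
  d[is.na(d)] <- 0
  d
}

## Deterministic leaf order from an hclust tree: at every merge the subtree
## containing the lexicographically smallest label goes left.
.orderedLeaves <- function(hc) {
  n <- length(hc$labels)
  if (n == 1L) return(hc$labels)
  walk <- function(k) {
    if (k < 0L) return(hc$labels[-k])
    left <- walk(hc$merge[k, 1L])
    right <- walk(hc$merge[k, 2L])
    if (min(right) < min(left)) c(right, left) else c(left, right)
  }
  walk(nrow(hc$merge))
}

#' Deterministic hierarchical leaf order of matrix rows or columns
#'
#' Average-linkage agglomerative clustering on Jaccard distances (boolean
#' input) or Euclidean distances (counts), with a deterministic tie rule
#' for the leaf order: at each merge the subtree containing the
#' lexicographically smallest key goes left.  Inputs are canonically
#' sorted first, so the result is invariant to input row/column order;
#' identical vectors end up adjacent.
#'
#' @param mat Logical or numeric matrix with dimnames.
#' @param axis `"columns"` or `"rows"`.
#' @param distance `"jaccard"` (boolean profiles) or `"euclidean"`.
#' @return Character vector of keys in leaf order.
#' @export
hierarchicalOrder <- function(mat, axis = c("columns", "rows"),
                              distance = c("jaccard", "euclidean")) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  if (axis == "rows") mat <- t(mat)
  if (ncol(mat) == 0L) .stopf("axis of length 0")
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  if (ncol(mat) == 1L) return(colnames(mat))
  d <- if (distance == "jaccard") .jaccardDist(mat) else
    stats::dist(t(mat), method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  .orderedLeaves(hc)
}
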
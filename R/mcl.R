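## Similarity graph construction and Markov clustering.
##
## MCL alternates expansion (matrix power of the column-stochastic flow
## matrix) and inflation (entrywise power followed by renormalization) with
## pruning of tiny entries, until the matrix stops changing.  Clusters are
## read off as attractor systems (rows retaining positive diagonal mass)
## together with the nodes flowing into them.

.makeSimilarityGraph <- function(edges) {
  if (nrow(edges)) {
    a <- pmin(edges$a, edges$b)
    b <- pmax(edges$a, edges$b)
    e <- unique(data.frame(a = a, b = b, weight = edges$weight,
                           stringsAsFactors = FALSE))
    if (anyDuplicated(paste(e$a, e$b)))
      .stopf("conflicting weights for a duplicated edge")
    e <- e[order(e$a, e$b), , drop = FALSE]
    rownames(e) <- NULL
  } else {
    e <- data.frame(a = character(), b = character(), weight = numeric(),
                    stringsAsFactors = FALSE)
  }
  new("SimilarityGraph", edges = e)
}

#' Build a similarity graph from reciprocal best hit pairs
#'
#' One undirected edge per reciprocal pair, weighted by 100 x the pairwise
#' global identity taken from the hit table.  Duplicated pairs collapse to
#' a single edge; proteins without any reciprocal pair are not nodes.
#'
#' @param rbhPairs data.frame with columns `a`, `b` from
#'   [reciprocalBestHits()].
#' @param hits Hit table containing every reciprocal pair (either
#'   orientation) with its `global_identity`.
#' @return A [SimilarityGraph-class].
#' @export
buildSimilarityGraph <- function(rbhPairs, hits) {
  if (!nrow(rbhPairs))
    return(.makeSimilarityGraph(data.frame(a = character(), b = character(),
                                           weight = numeric(),
                                           stringsAsFactors = FALSE)))
  idByKey <- stats::setNames(hits$global_identity,
                             .pairKey(hits$query_id, hits$subject_id))
  key <- .pairKey(rbhPairs$a, rbhPairs$b)
  ident <- idByKey[key]
  if (anyNA(ident))
    .stopf("reciprocal pair(s) missing from the hit table: %s",
           paste(utils::head(key[is.na(ident)], 3L), collapse = ", "))
  .makeSimilarityGraph(data.frame(a = rbhPairs$a, b = rbhPairs$b,
                                  weight = 100 * unname(ident),
                                  stringsAsFactors = FALSE))
}

## Column-normalize a sparse matrix in place.
.colNormalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

## Minimal union-find for attractor systems.
.unionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  list(find = find, union = union)
}

#' Markov clustering of a similarity graph
#'
#' Adds a self-loop to every node weighted by its maximum incident edge
#' weight (the standard regularization against bipartite oscillation),
#' column-normalizes to a stochastic flow matrix, then iterates expansion
#' (matrix power), inflation (entrywise power plus renormalization) and
#' pruning of entries below `params@prune` until the maximum absolute
#' change falls below `params@tol` or `params@maxIter` is hit (the latter
#' emits a warning and clusters the final matrix).  Attractors are rows
#' with positive diagonal mass; overlapping attractors merge into one
#' system; every remaining node joins the system receiving its largest
#' flow mass, ties resolved toward the system with the lexicographically
#' smallest attractor id.  Cluster ids are content-addressed hashes of the
#' sorted member ids.
#'
#' @param graph A [SimilarityGraph-class].
#' @param params An [MclParams-class].
#' @param nodes Optional additional node ids (isolated nodes become
#'   singleton clusters).
#' @param idPrefix Prefix for the content-addressed cluster ids.
#' @return A [FamilyClustering-class] (with empty `unclustered`; singleton
#'   handling is the caller's concern).
#' @export
mclCluster <- function(graph, params = mclParams(), nodes = NULL,
                       idPrefix = "c") {
  validObject(params)
  nodeIds <- sort(unique(c(graphNodes(graph), nodes)))
  n <- length(nodeIds)
  if (n == 0L) return(FamilyClustering(list()))
  e <- graphEdges(graph)
  ai <- match(e$a, nodeIds)
  bi <- match(e$b, nodeIds)
  ## symmetric adjacency with self-loops at the max incident weight
  selfw <- rep(1, n)
  if (nrow(e)) {
    mx <- tapply(c(e$weight, e$weight), c(ai, bi), max)
    selfw[as.integer(names(mx))] <- mx
  }
  M <- Matrix::sparseMatrix(i = c(ai, bi, seq_len(n)),
                            j = c(bi, ai, seq_len(n)),
                            x = c(e$weight, e$weight, selfw),
                            dims = c(n, n))
  M <- .colNormalize(M)
  converged <- FALSE
  for (iter in seq_len(params@maxIter)) {
    Mnew <- M
    for (k in seq_len(params@expansion - 1L)) Mnew <- Mnew %*% M
    Mnew <- Mnew^params@inflation
    Mnew <- Matrix::drop0(Mnew * (Mnew >= params@prune))
    Mnew <- .colNormalize(Mnew)
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < params@tol) { converged <- TRUE; break }
  }
  if (!converged)
    .warnf("MCL did not converge within %d iterations; clustering the final matrix",
           params@maxIter)
  M <- as(M, "TsparseMatrix")
  dg <- Matrix::diag(M)
  attractors <- which(dg > 0)
  if (!length(attractors)) attractors <- seq_len(n)  # degenerate safeguard
  ## merge attractors that exchange flow into systems
  uf <- .unionFind(n)
  isAttr <- logical(n); isAttr[attractors] <- TRUE
  ii <- M@i + 1L; jj <- M@j + 1L
  link <- isAttr[ii] & isAttr[jj]
  for (k in which(link)) uf$union(ii[k], jj[k])
  sysOf <- integer(n)
  for (a in attractors) sysOf[a] <- uf$find(a)
  ## assign every non-attractor column to the system with the largest
  ## incoming flow mass; ties toward the lexicographically smallest
  ## attractor id
  mass <- new.env(parent = emptyenv())
  rows <- which(isAttr[ii])
  for (k in rows) {
    key <- paste(jj[k], sysOf[ii[k]])
    mass[[key]] <- (if (is.null(mass[[key]])) 0 else mass[[key]]) + M@x[k]
  }
  minAttr <- vapply(split(nodeIds[attractors], sysOf[attractors]),
                    min, "")
  assign_of <- integer(n)
  for (j in seq_len(n)) {
    if (isAttr[j]) { assign_of[j] <- sysOf[j]; next }
    keys <- ls(mass, pattern = paste0("^", j, " "))
    if (!length(keys)) { assign_of[j] <- -j; next }  # isolated: own cluster
    systems <- as.integer(sub("^\\d+ ", "", keys))
    masses <- vapply(keys, function(k) mass[[k]], 0)
    best <- masses == max(masses)
    cand <- systems[best]
    assign_of[j] <- cand[order(minAttr[as.character(cand)])][1L]
  }
  groups <- split(nodeIds, assign_of)
  members <- lapply(groups, sort)
  ids <- vapply(members, .contentId, "", prefix = idPrefix)
  names(members) <- ids
  if (anyDuplicated(ids))
    .stopf("cluster id hash collision; use a longer hash")
  FamilyClustering(members)
}

#' Cluster an arbitrary taxon subset into protein families
#'
#' Runs the full within-set pipeline on a subset of proteomes:
#' all-versus-all search, per-proteome best hits, reciprocal best hits,
#' similarity graph and MCL.  Used for within-group family inventories
#' (e.g. families of the asgard archaea alone).
#'
#' @param proteomes A [ProteomeSet-class] covering at least two taxa.
#' @param thresholds A [SearchThresholds-class] (clustering defaults).
#' @param params An [MclParams-class].
#' @param idPrefix Cluster id prefix.
#' @param hits Optional precomputed hit table for exactly this set, as from
#'   [searchHits()] (computed when missing).
#' @return List with elements `clustering` (a
#'   [FamilyClustering-class]; proteins without a reciprocal best hit are
#'   reported in its `unclustered` slot), `presence` (data.frame
#'   `cluster_id`, `taxon_id`, `n_proteins`), and `hits`.
#' @export
clusterProteomes <- function(proteomes, thresholds = searchThresholds(),
                             params = mclParams(), idPrefix = "c",
                             hits = NULL) {
  taxa <- unique(proteomes@taxon)
  if (length(taxa) < 2L) .stopf("need at least two taxa to cluster")
  if (is.null(hits)) hits <- searchHits(proteomes, proteomes, thresholds)
  bh <- bestHits(hits, by = "subject_taxon")
  rbh <- reciprocalBestHits(bh)
  graph <- buildSimilarityGraph(rbh, hits)
  clustering <- mclCluster(graph, params, idPrefix = idPrefix)
  clustered <- clusterMembership(clustering)$protein_id
  uncl <- setdiff(proteinIds(proteomes), clustered)
  clustering <- FamilyClustering(clusterMembers(clustering),
                                 unclustered = uncl)
  m <- clusterMembership(clustering)
  ptax <- proteinTaxon(proteomes)
  if (nrow(m)) {
    pres <- as.data.frame(table(cluster_id = m$cluster_id,
                                taxon_id = unname(ptax[m$protein_id])),
                          stringsAsFactors = FALSE)
    names(pres)[3L] <- "n_proteins"
    pres <- pres[pres$n_proteins > 0L, , drop = FALSE]
    pres <- pres[order(pres$cluster_id, pres$taxon_id), , drop = FALSE]
    rownames(pres) <- NULL
  } else {
    pres <- data.frame(cluster_id = character(), taxon_id = character(),
                       n_proteins = integer(), stringsAsFactors = FALSE)
  }
  list(clustering = clustering, presence = pres, hits = hits)
}
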
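## S4 classes, validity, constructors, accessors and show methods.

## ---------------------------------------------------------------------------
## TaxonRegistry
## ---------------------------------------------------------------------------

#' Registry of taxa and their taxonomic labels
#'
#' Maps opaque taxon ids to a name, a domain (eukaryote, bacteria or
#' archaea), a group label and a genus.  For eukaryotes the group must be
#' one of the six supergroups returned by [eukSupergroups()]; for archaea
#' the reserved group value `"asgard"` marks members of the asgard
#' superphylum; for bacteria the group is a phylum/class label.  The genus
#' feeds the same-genus exclusion rule of the hit-category analysis.
#'
#' @slot table data.frame with columns `taxon_id`, `name`, `domain`,
#'   `group`, `genus`.
#' @export
setClass("TaxonRegistry", slots = c(table = "data.frame"))

setValidity("TaxonRegistry", function(object) {
  tab <- object@table
  need <- c("taxon_id", "name", "domain", "group", "genus")
  if (!all(need %in% colnames(tab)))
    return(sprintf("registry table must have columns %s",
                   paste(need, collapse = ", ")))
  if (anyDuplicated(tab$taxon_id))
    return(sprintf("duplicate taxon_id: %s",
                   paste(unique(tab$taxon_id[duplicated(tab$taxon_id)]),
                         collapse = ", ")))
  bad <- setdiff(unique(tab$domain), DOMAINS)
  if (length(bad))
    return(sprintf("unknown domain value(s): %s", paste(bad, collapse = ", ")))
  euk <- tab$domain == "eukaryote"
  badg <- setdiff(unique(tab$group[euk]), eukSupergroups())
  if (length(badg))
    return(sprintf(
      "eukaryote group(s) outside the six supergroups: %s",
      paste(badg, collapse = ", ")))
  TRUE
})

#' @describeIn TaxonRegistry-class Construct a registry from a data.frame.
#' @param table data.frame with columns `taxon_id`, `name`, `domain`,
#'   `group`, `genus`.
#' @return A `TaxonRegistry`.
#' @export
TaxonRegistry <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  ## canonical row order makes the registry independent of input row order
  table <- table[order(table$taxon_id), , drop = FALSE]
  rownames(table) <- NULL
  new("TaxonRegistry", table = table)
}

#' Accessors for TaxonRegistry
#'
#' `taxonTable()` returns the underlying data.frame; `taxonIds()` the taxon
#' keys; `taxonField()` one named column as a vector indexed by taxon id.
#'
#' @param object,registry A [TaxonRegistry-class].
#' @param field Column name, e.g. `"domain"` or `"genus"`.
#' @return `taxonTable`: data.frame; `taxonIds`: character;
#'   `taxonField`: named character vector.
#' @export
taxonTable <- function(object) object@table

#' @rdname taxonTable
#' @export
taxonIds <- function(object) object@table$taxon_id

#' @rdname taxonTable
#' @export
taxonField <- function(registry, field) {
  tab <- registry@table
  stats::setNames(tab[[field]], tab$taxon_id)
}

setMethod("show", "TaxonRegistry", function(object) {
  tab <- object@table
  cat(sprintf("TaxonRegistry with %d taxa (%s)\n", nrow(tab),
              paste(sprintf("%s: %d", DOMAINS,
                            vapply(DOMAINS, function(d) sum(tab$domain == d),
                                   0L)),
                    collapse = ", ")))
})

## ---------------------------------------------------------------------------
## ProteomeSet
## ---------------------------------------------------------------------------

#' A pooled set of amino-acid proteomes with taxon provenance
#'
#' Holds all protein sequences of one or more proteomes as an
#' [Biostrings::AAStringSet] whose names are globally unique protein ids of
#' the form `taxonid|localid`, a parallel taxon assignment, and the taxon
#' registry.  Residues are restricted to the 20 standard amino acids plus X
#' (the alphabet on which the scoring matrices are defined).
#'
#' @slot sequences `AAStringSet`, names are protein ids.
#' @slot taxon character vector, parallel to `sequences`, taxon id of each
#'   protein.
#' @slot registry [TaxonRegistry-class].
#' @export
setClass("ProteomeSet",
         slots = c(sequences = "AAStringSet", taxon = "character",
                   registry = "TaxonRegistry"))

setValidity("ProteomeSet", function(object) {
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    return("protein ids must be present and globally unique")
  if (length(object@taxon) != length(object@sequences))
    return("taxon vector and sequence set lengths differ")
  unknown <- setdiff(unique(object@taxon), taxonIds(object@registry))
  if (length(unknown))
    return(sprintf("taxa missing from registry: %s",
                   paste(unknown, collapse = ", ")))
  if (length(object@sequences)) {
    if (any(width(object@sequences) < 1L))
      return("empty sequences are not allowed")
    freq <- alphabetFrequency(object@sequences, collapse = TRUE)
    allowed <- c(AA20, "X")
    bad <- freq[setdiff(names(freq), allowed)]
    if (sum(bad) > 0)
      return(sprintf("residues outside the 20 standard amino acids + X: %s",
                     paste(names(bad)[bad > 0], collapse = ", ")))
  }
  TRUE
})

#' @describeIn ProteomeSet-class Constructor.
#' @param sequences Named `AAStringSet` (or named character vector).
#' @param taxon Character vector of taxon ids, one per sequence.
#' @param registry [TaxonRegistry-class].
#' @return A `ProteomeSet`.
#' @export
ProteomeSet <- function(sequences, taxon, registry) {
  if (!is(sequences, "AAStringSet")) sequences <- AAStringSet(sequences)
  new("ProteomeSet", sequences = sequences, taxon = as.character(taxon),
      registry = registry)
}

#' Accessors for ProteomeSet
#'
#' @param object A [ProteomeSet-class].
#' @param taxa,domains Optional taxon ids / domain names to subset to.
#' @return `proteinIds`: character; `proteinSequences`: `AAStringSet`;
#'   `proteinTaxon`: named character (taxon id per protein id);
#'   `subsetProteomes`: a `ProteomeSet`.
#' @export
proteinIds <- function(object) names(object@sequences)

#' @rdname proteinIds
#' @export
proteinSequences <- function(object) object@sequences

#' @rdname proteinIds
#' @export
proteinTaxon <- function(object)
  stats::setNames(object@taxon, names(object@sequences))

#' @rdname proteinIds
#' @export
subsetProteomes <- function(object, taxa = NULL, domains = NULL) {
  keep <- rep(TRUE, length(object@sequences))
  dom <- taxonField(object@registry, "domain")
  if (!is.null(domains)) keep <- keep & dom[object@taxon] %in% domains
  if (!is.null(taxa)) keep <- keep & object@taxon %in% taxa
  new("ProteomeSet", sequences = object@sequences[keep],
      taxon = object@taxon[keep], registry = object@registry)
}

setMethod("show", "ProteomeSet", function(object) {
  cat(sprintf("ProteomeSet: %d proteins across %d taxa\n",
              length(object@sequences), length(unique(object@taxon))))
  dom <- taxonField(object@registry, "domain")[object@taxon]
  for (d in DOMAINS) {
    n <- sum(dom == d)
    if (n) cat(sprintf("  %s: %d proteins, %d taxa\n", d, n,
                       length(unique(object@taxon[dom == d]))))
  }
})

## Combine proteome sets sharing a registry.
.bindProteomes <- function(sets) {
  sets <- sets[vapply(sets, function(s) length(s@sequences) > 0L, TRUE)]
  stopifnot(length(sets) >= 1L)
  seqs <- do.call(c, lapply(sets, proteinSequences))
  taxa <- unlist(lapply(sets, function(s) s@taxon), use.names = FALSE)
  new("ProteomeSet", sequences = seqs, taxon = taxa,
      registry = sets[[1L]]@registry)
}

## ---------------------------------------------------------------------------
## SearchThresholds / MclParams
## ---------------------------------------------------------------------------

#' Similarity search thresholds
#'
#' Both thresholds are inclusive: a hit passes with identity >= `minIdentity`
#' and E-value <= `maxEvalue` ("at least 25\% identity" semantics).  The
#' clustering stage uses `maxEvalue = 1e-10`; the per-proteome hit-category
#' analysis uses the laxer `1e-5`.
#'
#' @slot minIdentity Global identity fraction in \[0, 1\] (default 0.25).
#' @slot maxEvalue Positive E-value ceiling.
#' @export
setClass("SearchThresholds",
         slots = c(minIdentity = "numeric", maxEvalue = "numeric"))

setValidity("SearchThresholds", function(object) {
  if (length(object@minIdentity) != 1L || object@minIdentity < 0 ||
      object@minIdentity > 1)
    return("minIdentity must be a single value in [0, 1]")
  if (length(object@maxEvalue) != 1L || object@maxEvalue <= 0)
    return("maxEvalue must be a single positive value")
  TRUE
})

#' @describeIn SearchThresholds-class Constructor.
#' @param minIdentity,maxEvalue See slots.
#' @return A `SearchThresholds`.
#' @export
searchThresholds <- function(minIdentity = 0.25, maxEvalue = 1e-10) {
  new("SearchThresholds", minIdentity = minIdentity, maxEvalue = maxEvalue)
}

setMethod("show", "SearchThresholds", function(object) {
  cat(sprintf("SearchThresholds: identity >= %g, E-value <= %g\n",
              object@minIdentity, object@maxEvalue))
})

#' Markov clustering parameters
#'
#' @slot inflation Entrywise power applied after expansion (> 1, default 2).
#' @slot expansion Matrix power of the expansion step (integer >= 2).
#' @slot prune Entries below this are dropped each iteration (default 1e-5).
#' @slot maxIter Iteration cap (default 100).
#' @slot tol Convergence tolerance on the max absolute matrix change.
#' @export
setClass("MclParams",
         slots = c(inflation = "numeric", expansion = "integer",
                   prune = "numeric", maxIter = "integer", tol = "numeric"))

setValidity("MclParams", function(object) {
  if (object@inflation <= 1) return("inflation must be > 1")
  if (object@expansion < 2L) return("expansion power must be >= 2")
  if (object@prune < 0) return("prune threshold must be >= 0")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (object@tol <= 0) return("tol must be > 0")
  TRUE
})

#' @describeIn MclParams-class Constructor.
#' @param inflation,expansion,prune,maxIter,tol See slots.
#' @return An `MclParams`.
#' @export
mclParams <- function(inflation = 2, expansion = 2L, prune = 1e-5,
                      maxIter = 100L, tol = 1e-8) {
  new("MclParams", inflation = inflation, expansion = as.integer(expansion),
      prune = prune, maxIter = as.integer(maxIter), tol = tol)
}

## ---------------------------------------------------------------------------
## SimilarityGraph
## ---------------------------------------------------------------------------

#' Undirected weighted protein similarity graph
#'
#' One edge per reciprocal best hit pair, weighted by the pairwise global
#' identity as a percentage in (0, 100].  Proteins without any reciprocal
#' best hit are not nodes (they are reported separately as unclustered).
#'
#' @slot edges data.frame with columns `a`, `b`, `weight`, with `a < b`.
#' @export
setClass("SimilarityGraph", slots = c(edges = "data.frame"))

setValidity("SimilarityGraph", function(object) {
  e <- object@edges
  if (!all(c("a", "b", "weight") %in% colnames(e)))
    return("edges must have columns a, b, weight")
  if (nrow(e)) {
    if (any(e$a == e$b)) return("self-loops are not allowed")
    if (any(e$weight <= 0 | e$weight > 100))
      return("edge weights must lie in (0, 100]")
    if (anyDuplicated(paste(e$a, e$b))) return("duplicate edges")
    if (any(e$a > e$b)) return("edges must be stored with a < b")
  }
  TRUE
})

#' @describeIn SimilarityGraph-class Node keys of the graph.
#' @param object A `SimilarityGraph`.
#' @return Character vector of node ids, sorted.
#' @export
graphNodes <- function(object)
  sort(unique(c(object@edges$a, object@edges$b)))

#' @describeIn SimilarityGraph-class Edge table of the graph.
#' @export
graphEdges <- function(object) object@edges

setMethod("show", "SimilarityGraph", function(object) {
  cat(sprintf("SimilarityGraph: %d nodes, %d edges\n",
              length(graphNodes(object)), nrow(object@edges)))
})

## ---------------------------------------------------------------------------
## FamilyClustering
## ---------------------------------------------------------------------------

#' A protein family clustering (partition of clustered proteins)
#'
#' Clusters are pairwise disjoint and non-empty; proteins that entered the
#' pipeline but obtained no reciprocal best hit are carried in `unclustered`.
#' Cluster ids are content-addressed (hash of the sorted member ids), so the
#' same member set always receives the same id.
#'
#' @slot membership data.frame with columns `cluster_id`, `protein_id`.
#' @slot unclustered character vector of protein ids outside any cluster.
#' @export
setClass("FamilyClustering",
         slots = c(membership = "data.frame", unclustered = "character"))

setValidity("FamilyClustering", function(object) {
  m <- object@membership
  if (!all(c("cluster_id", "protein_id") %in% colnames(m)))
    return("membership must have columns cluster_id, protein_id")
  if (anyDuplicated(m$protein_id))
    return("clusters must be disjoint (duplicated protein_id)")
  if (length(intersect(m$protein_id, object@unclustered)))
    return("a protein cannot be both clustered and unclustered")
  TRUE
})

#' @describeIn FamilyClustering-class Constructor from a membership list.
#' @param members Named list: cluster id -> character vector of protein ids,
#'   or a membership data.frame with columns `cluster_id`, `protein_id`.
#' @param unclustered Character vector of unclustered protein ids.
#' @return A `FamilyClustering`.
#' @export
FamilyClustering <- function(members, unclustered = character()) {
  if (is.data.frame(members)) {
    m <- members[, c("cluster_id", "protein_id")]
  } else if (!length(members)) {
    m <- data.frame(cluster_id = character(), protein_id = character(),
                    stringsAsFactors = FALSE)
  } else {
    m <- data.frame(
      cluster_id = rep(names(members), lengths(members)),
      protein_id = unlist(members, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  m <- m[order(m$cluster_id, m$protein_id), , drop = FALSE]
  rownames(m) <- NULL
  new("FamilyClustering", membership = m, unclustered = sort(unclustered))
}

#' Accessors for FamilyClustering
#'
#' @param object A [FamilyClustering-class].
#' @param cluster Optional cluster id for `clusterMembers`.
#' @return `clusterIds`: character; `nClusters`: integer; `clusterMembers`:
#'   list (or character for a single cluster); `clusterMembership`: the
#'   two-column data.frame; `unclusteredProteins`: character.
#' @export
clusterIds <- function(object) unique(object@membership$cluster_id)

#' @rdname clusterIds
#' @export
nClusters <- function(object) length(clusterIds(object))

#' @rdname clusterIds
#' @export
clusterMembers <- function(object, cluster = NULL) {
  m <- object@membership
  if (!is.null(cluster)) return(m$protein_id[m$cluster_id == cluster])
  split(m$protein_id, m$cluster_id)
}

#' @rdname clusterIds
#' @export
clusterMembership <- function(object) object@membership

#' @rdname clusterIds
#' @export
unclusteredProteins <- function(object) object@unclustered

setMethod("show", "FamilyClustering", function(object) {
  sizes <- table(object@membership$cluster_id)
  cat(sprintf(
    "FamilyClustering: %d clusters over %d proteins (+%d unclustered)\n",
    length(sizes), nrow(object@membership), length(object@unclustered)))
  if (length(sizes))
    cat(sprintf("  cluster sizes: min %d, median %g, max %d\n",
                min(sizes), stats::median(as.numeric(sizes)), max(sizes)))
})

## ---------------------------------------------------------------------------
## EPCSet
## ---------------------------------------------------------------------------

#' Eukaryote-prokaryote clusters (EPCs)
#'
#' One row per eukaryotic family that was reciprocally merged with an
#' archaeal and/or a bacterial family.  The category is `EA` when only an
#' archaeal partner exists, `EB` for only a bacterial partner, and `EAB`
#' for both.
#'
#' @slot table data.frame with columns `epc_id`, `euk_cluster`,
#'   `arch_cluster`, `bact_cluster`, `category`, and the four link supports
#'   `euk_arch_support`, `arch_euk_support`, `euk_bact_support`,
#'   `bact_euk_support` (NA where no link exists).
#' @export
setClass("EPCSet", slots = c(table = "data.frame"))

setValidity("EPCSet", function(object) {
  tab <- object@table
  need <- c("epc_id", "euk_cluster", "arch_cluster", "bact_cluster",
            "category")
  if (!all(need %in% colnames(tab)))
    return(sprintf("EPC table must have columns %s",
                   paste(need, collapse = ", ")))
  if (!nrow(tab)) return(TRUE)
  if (anyDuplicated(tab$epc_id)) return("duplicate epc_id")
  hasA <- !is.na(tab$arch_cluster)
  hasB <- !is.na(tab$bact_cluster)
  if (any(!hasA & !hasB))
    return("every EPC needs an archaeal or a bacterial partner")
  want <- ifelse(hasA & hasB, "EAB", ifelse(hasA, "EA", "EB"))
  if (!identical(as.character(tab$category), as.character(want)))
    return("category inconsistent with linked partners")
  TRUE
})

#' @describeIn EPCSet-class The EPC table.
#' @param object An `EPCSet`.
#' @return data.frame.
#' @export
epcTable <- function(object) object@table

setMethod("show", "EPCSet", function(object) {
  s <- summarizeEpcs(object)
  cat(sprintf(
    "EPCSet: %d EPCs (EA %d, EB %d, EAB %d); %d (%s%%) with archaea\n",
    s$total, s$ea, s$eb, s$eab, s$with_archaea,
    format(s$pct_with_archaea)))
})

## ---------------------------------------------------------------------------
## PAPMatrix
## ---------------------------------------------------------------------------

#' Presence-absence pattern matrix
#'
#' Boolean matrix of family (or EPC) occurrence across taxa or taxon groups,
#' with column metadata retained for supergroup-aware row sorting.
#'
#' @slot mat Logical matrix; rownames are family/EPC keys, colnames taxon or
#'   group keys.
#' @slot colMeta data.frame with columns `column`, `domain`, `group`.
#' @export
setClass("PAPMatrix", slots = c(mat = "matrix", colMeta = "data.frame"))

setValidity("PAPMatrix", function(object) {
  if (!is.logical(object@mat)) return("matrix must be logical")
  if (anyDuplicated(rownames(object@mat))) return("duplicate row keys")
  if (anyDuplicated(colnames(object@mat))) return("duplicate column keys")
  if (!identical(object@colMeta$column, colnames(object@mat)))
    return("colMeta rows must match matrix columns")
  TRUE
})

#' @describeIn PAPMatrix-class The logical matrix.
#' @param object A `PAPMatrix`.
#' @return `papMatrix`: logical matrix; `papColumnMeta`: data.frame.
#' @export
papMatrix <- function(object) object@mat

#' @rdname papMatrix
#' @export
papColumnMeta <- function(object) object@colMeta

setMethod("show", "PAPMatrix", function(object) {
  cat(sprintf("PAPMatrix: %d rows x %d columns, %d presences\n",
              nrow(object@mat), ncol(object@mat), sum(object@mat)))
})

## ---------------------------------------------------------------------------
## ResultBundle
## ---------------------------------------------------------------------------

#' Result bundle of a pipeline run
#'
#' @slot results Named list of stage outputs (tables, clusterings, EPCs,
#'   profiles, PAP matrices, summary statistics).
#' @slot manifest Named list with the run manifest (config hash, seed,
#'   package version, stage timings and row counts, content hash).
#' @export
setClass("ResultBundle", slots = c(results = "list", manifest = "list"))

#' @describeIn ResultBundle-class Access one result element or the full list.
#' @param object A `ResultBundle`.
#' @param name Optional element name.
#' @return The element (or list of all results).
#' @export
bundleResults <- function(object, name = NULL) {
  if (is.null(name)) object@results else object@results[[name]]
}

#' @rdname bundleResults
#' @export
bundleManifest <- function(object) object@manifest

setMethod("show", "ResultBundle", function(object) {
  cat("ResultBundle\n")
  cat(sprintf("  stages: %s\n", paste(names(object@results), collapse = ", ")))
  cat(sprintf("  seed %s, content hash %s\n",
              format(object@manifest$seed), object@manifest$content_hash))
})
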
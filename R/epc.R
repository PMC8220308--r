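## Eukaryote-prokaryote cluster (EPC) integration: reciprocal best cluster
## votes and merging, EPC assembly and classification, LECA filtering, and
## the lineage-unique contribution statistics.

#' Best-cluster votes between two clusterings
#'
#' For every source cluster, the fraction of its members whose best
#' cross-set hit lands in each target cluster (members without a passing
#' hit, or whose best hit falls outside every target cluster, abstain but
#' stay in the denominator).  The candidate link of a source cluster is
#' its maximum-support target; ties mean no candidate.
#'
#' @param sourceClustering,targetClustering [FamilyClustering-class]
#'   objects.
#' @param crossBest Best-hit table (one best hit per source protein over
#'   the whole target set, from `bestHits(..., by = "subject_set")`).
#' @return data.frame `source`, `target`, `support`, `is_candidate`.
#' @export
bestClusterVotes <- function(sourceClustering, targetClustering, crossBest) {
  sm <- clusterMembership(sourceClustering)
  tm <- clusterMembership(targetClustering)
  tclusterOf <- stats::setNames(tm$cluster_id, tm$protein_id)
  sizes <- table(sm$cluster_id)
  bestTarget <- stats::setNames(crossBest$subject_id, crossBest$query_id)
  src <- sm$cluster_id
  tgt <- unname(tclusterOf[unname(bestTarget[sm$protein_id])])
  ok <- !is.na(tgt)
  if (!any(ok))
    return(data.frame(source = character(), target = character(),
                      support = numeric(), is_candidate = logical(),
                      stringsAsFactors = FALSE))
  votes <- as.data.frame(table(source = src[ok], target = tgt[ok]),
                         stringsAsFactors = FALSE)
  votes <- votes[votes$Freq > 0L, , drop = FALSE]
  votes$support <- votes$Freq / as.numeric(sizes[votes$source])
  votes$Freq <- NULL
  ## candidate: unique maximum-support target per source
  votes$is_candidate <- FALSE
  for (s in unique(votes$source)) {
    rows <- which(votes$source == s)
    mx <- max(votes$support[rows])
    top <- rows[votes$support[rows] == mx]
    if (length(top) == 1L) votes$is_candidate[top] <- TRUE
  }
  votes <- votes[order(votes$source, votes$target), , drop = FALSE]
  rownames(votes) <- NULL
  votes
}

#' Reciprocal best cluster merge
#'
#' A link (E, P) is accepted iff E's candidate target is P with support >=
#' `minSupport` and P's candidate target is E with support >= `minSupport`
#' ("at least 50\% of all sequences ... and vice versa"; the bound is
#' inclusive).
#'
#' @param votesFwd,votesRev Vote tables from [bestClusterVotes()] in the
#'   two directions.
#' @param minSupport Support threshold (default 0.5).
#' @return data.frame `source`, `target`, `support_fwd`, `support_rev`.
#' @export
reciprocalBestClusterMerge <- function(votesFwd, votesRev,
                                       minSupport = 0.5) {
  fwd <- votesFwd[votesFwd$is_candidate &
                    votesFwd$support >= minSupport, , drop = FALSE]
  rev <- votesRev[votesRev$is_candidate &
                    votesRev$support >= minSupport, , drop = FALSE]
  key <- paste(fwd$source, fwd$target)
  revKey <- paste(rev$target, rev$source)
  keep <- fwd[key %in% revKey, , drop = FALSE]
  out <- data.frame(source = keep$source, target = keep$target,
                    support_fwd = keep$support,
                    support_rev = rev$support[match(
                      paste(keep$source, keep$target), revKey)],
                    stringsAsFactors = FALSE)
  out[order(out$source), , drop = FALSE]
}

#' Assemble EPCs from the two independent reciprocal merges
#'
#' One EPC per eukaryotic cluster holding at least one accepted link;
#' category EA with only an archaeal partner, EB with only a bacterial
#' partner, EAB with both (a three-domain cluster can only arise by double
#' linkage because archaea and bacteria are clustered separately).
#'
#' @param archLinks,bactLinks Link tables from
#'   [reciprocalBestClusterMerge()] (eukaryote side as `source`).
#' @return An [EPCSet-class].
#' @export
assembleEpcs <- function(archLinks, bactLinks) {
  euks <- sort(unique(c(archLinks$source, bactLinks$source)))
  ai <- match(euks, archLinks$source)
  bi <- match(euks, bactLinks$source)
  hasA <- !is.na(ai)
  hasB <- !is.na(bi)
  tab <- data.frame(
    epc_id = vapply(euks, function(e) .contentId(e, "epc"), ""),
    euk_cluster = euks,
    arch_cluster = ifelse(hasA, archLinks$target[ai], NA_character_),
    bact_cluster = ifelse(hasB, bactLinks$target[bi], NA_character_),
    category = ifelse(hasA & hasB, "EAB", ifelse(hasA, "EA", "EB")),
    euk_arch_support = ifelse(hasA, archLinks$support_fwd[ai], NA_real_),
    arch_euk_support = ifelse(hasA, archLinks$support_rev[ai], NA_real_),
    euk_bact_support = ifelse(hasB, bactLinks$support_fwd[bi], NA_real_),
    bact_euk_support = ifelse(hasB, bactLinks$support_rev[bi], NA_real_),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("EPCSet", table = tab)
}

#' Summarize EPC category counts
#'
#' `summarizeEpcCounts` works from plain counts; `summarizeEpcs` recounts
#' an assembled [EPCSet-class].  `with_archaea = EA + EAB`;
#' `pct_with_archaea` is reported to one decimal (half-up).
#'
#' @param ea,eb,eab Category counts.
#' @return Named list `ea`, `eb`, `eab`, `total`, `with_archaea`,
#'   `pct_with_archaea` (NA with a flag when the total is zero).
#' @export
#' @examples
#' summarizeEpcCounts(330, 1723, 537)  # 867 with archaea, 33.5%
summarizeEpcCounts <- function(ea, eb, eab) {
  total <- ea + eb + eab
  withA <- ea + eab
  pct <- if (total > 0) .roundHalfUp(100 * withA / total, 1L) else NA_real_
  list(ea = ea, eb = eb, eab = eab, total = total, with_archaea = withA,
       pct_with_archaea = pct, pct_defined = total > 0)
}

#' @rdname summarizeEpcCounts
#' @param epcs An [EPCSet-class].
#' @export
summarizeEpcs <- function(epcs) {
  cat0 <- epcTable(epcs)$category
  summarizeEpcCounts(sum(cat0 == "EA"), sum(cat0 == "EB"),
                     sum(cat0 == "EAB"))
}

## Group labels of a cluster's member taxa.
.clusterGroups <- function(clustering, proteomes, cluster) {
  ptax <- proteinTaxon(proteomes)
  grp <- taxonField(proteomes@registry, "group")
  unique(unname(grp[ptax[clusterMembers(clustering, cluster)]]))
}

#' Filter clusters for LECA candidacy (six-supergroup coverage)
#'
#' Keeps exactly the clusters whose eukaryotic member taxa cover all
#' required supergroups (at least one protein from at least one member of
#' each).  Requiring more supergroups can only shrink the result.
#'
#' @param clustering A [FamilyClustering-class] of eukaryotic families.
#' @param proteomes [ProteomeSet-class] with the registry.
#' @param supergroups Required supergroups (default all six).
#' @return Character vector of passing cluster ids.
#' @export
filterLeca <- function(clustering, proteomes, supergroups = eukSupergroups()) {
  reg <- proteomes@registry
  present <- unique(taxonTable(reg)$group[
    taxonTable(reg)$domain == "eukaryote"])
  if (!all(supergroups %in% present))
    .warnf("registry lacks supergroup(s) %s; the LECA filter can only return an empty set",
           paste(setdiff(supergroups, present), collapse = ", "))
  m <- clusterMembership(clustering)
  ptax <- proteinTaxon(proteomes)
  grp <- taxonField(reg, "group")
  memberGroup <- unname(grp[unname(ptax[m$protein_id])])
  keep <- vapply(split(memberGroup, m$cluster_id),
                 function(g) all(supergroups %in% g), TRUE)
  sort(names(keep)[keep])
}

#' EA clusters with an exclusively asgard archaeal side
#'
#' Returns the EA-category EPCs whose linked archaeal cluster contains
#' asgard taxa only -- the lineage-unique contribution detector.  EAB
#' clusters are excluded by definition even when their archaeal side is
#' asgard-only.
#'
#' @param epcs An [EPCSet-class].
#' @param archClustering The archaeal [FamilyClustering-class] the EPC
#'   links point into.
#' @param proteomes [ProteomeSet-class] with the registry.
#' @return data.frame of the qualifying EPC rows.
#' @export
asgardUniqueEA <- function(epcs, archClustering, proteomes) {
  tab <- epcTable(epcs)
  tab <- tab[tab$category == "EA", , drop = FALSE]
  if (!nrow(tab)) return(tab)
  keep <- vapply(tab$arch_cluster, function(cl) {
    g <- .clusterGroups(archClustering, proteomes, cl)
    length(g) > 0L && all(g == ASGARD_GROUP)
  }, TRUE)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contribution percentage
#'
#' `100 * nUnique / nReference`, rounded half-up to the requested number of
#' decimals (presentation-layer rounding; carry raw fractions internally).
#'
#' @param nUnique Count of lineage-unique families (0 <= nUnique <=
#'   nReference).
#' @param nReference Reference family count (> 0).
#' @param decimals Decimals to round to.
#' @return The rounded percentage.
#' @export
#' @examples
#' contributionPercent(6, 1880)    # 0.3191
#' contributionPercent(6, 239012)  # 0.0025
contributionPercent <- function(nUnique, nReference, decimals = 4L) {
  if (nReference <= 0) .stopf("nReference must be positive")
  if (nUnique < 0 || nUnique > nReference)
    .stopf("nUnique must lie in [0, nReference]")
  .roundHalfUp(100 * nUnique / nReference, as.integer(decimals))
}
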
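## Per-proteome hit-category profiling with genus exclusion, and protein
## length-distribution statistics for proteins with vs without hits.

HIT_CATEGORIES <- c("E", "A", "B", "EA", "EB", "AB", "EAB", "none")

## Encode the set of domains present among surviving hits.
.domainCategory <- function(hasE, hasA, hasB) {
  code <- paste0(ifelse(hasE, "E", ""), ifelse(hasA, "A", ""),
                 ifelse(hasB, "B", ""))
  ifelse(code == "", "none", code)
}

#' Classify proteins by the domains of their database hits
#'
#' Applies the hit-analysis thresholds, drops hits whose subject shares the
#' query taxon's exclusion-rank label (genus by default; `"phylum"` uses
#' the registry group label, the stricter missing-data simulation), and
#' reports per query the set of domains with at least one surviving hit
#' (any qualifying subject counts, not only the best hit), encoded
#' E/A/B/EA/EB/AB/EAB, or `"none"`.
#'
#' @param queryIds Character vector of proteins to classify.
#' @param hits Hit table of the queries against the labeled databases
#'   (self-hits are ignored).
#' @param proteomes [ProteomeSet-class] resolving taxa and labels.
#' @param thresholds Hit-analysis [SearchThresholds-class]
#'   (identity >= 0.25, E <= 1e-5 defaults).
#' @param exclusionRank `"genus"` or `"phylum"`.
#' @return Named character vector query id -> category.
#' @export
classifyProteins <- function(queryIds, hits, proteomes,
                             thresholds = searchThresholds(
                               minIdentity = 0.25, maxEvalue = 1e-5),
                             exclusionRank = c("genus", "phylum")) {
  exclusionRank <- match.arg(exclusionRank)
  reg <- proteomes@registry
  labField <- if (exclusionRank == "genus") "genus" else "group"
  lab <- taxonField(reg, labField)
  dom <- taxonField(reg, "domain")
  h <- filterHits(hits, thresholds)
  h <- h[h$query_id %in% queryIds & h$query_id != h$subject_id, ,
         drop = FALSE]
  if (anyNA(dom[h$subject_taxon]))
    .stopf("hit subject taxa missing from registry")
  keep <- lab[h$query_taxon] != lab[h$subject_taxon]
  h <- h[keep, , drop = FALSE]
  sdom <- unname(dom[h$subject_taxon])
  hasE <- tapply(sdom == "eukaryote", h$query_id, any)
  hasA <- tapply(sdom == "archaea", h$query_id, any)
  hasB <- tapply(sdom == "bacteria", h$query_id, any)
  cats <- stats::setNames(rep("none", length(queryIds)), queryIds)
  hitQ <- names(hasE)
  cats[hitQ] <- .domainCategory(unname(hasE), unname(hasA), unname(hasB))
  cats
}

#' Hit-category profile of one proteome
#'
#' Counts per category over every protein of the taxon; counts sum to the
#' proteome size (conservation).
#'
#' @param proteomes [ProteomeSet-class].
#' @param taxonId The proteome to profile.
#' @param hits Hit table of (at least) this proteome's proteins against the
#'   labeled databases.
#' @param thresholds,exclusionRank Passed to [classifyProteins()].
#' @return data.frame `taxon_id`, `category`, `count` in canonical category
#'   order.
#' @export
profileProteome <- function(proteomes, taxonId, hits,
                            thresholds = searchThresholds(
                              minIdentity = 0.25, maxEvalue = 1e-5),
                            exclusionRank = c("genus", "phylum")) {
  ids <- proteinIds(proteomes)[proteomes@taxon == taxonId]
  if (!length(ids)) .stopf("taxon %s has no proteins loaded", taxonId)
  cats <- classifyProteins(ids, hits, proteomes, thresholds, exclusionRank)
  counts <- table(factor(cats, levels = HIT_CATEGORIES))
  data.frame(taxon_id = taxonId, category = HIT_CATEGORIES,
             count = as.integer(counts), stringsAsFactors = FALSE)
}

#' @rdname profileProteome
#' @param taxa Taxa to profile (default all in the set).
#' @return `hitProfiles`: long data.frame over all requested taxa.
#' @export
hitProfiles <- function(proteomes, hits,
                        thresholds = searchThresholds(
                          minIdentity = 0.25, maxEvalue = 1e-5),
                        exclusionRank = c("genus", "phylum"),
                        taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(unique(proteomes@taxon))
  out <- do.call(rbind, lapply(taxa, function(t)
    profileProteome(proteomes, t, hits, thresholds, exclusionRank)))
  rownames(out) <- NULL
  out
}

#' Mean per-proteome count of one hit category
#'
#' E.g. the average number of proteins per asgard proteome whose homologs
#' are unique to eukaryotes (category `"E"`).
#'
#' @param profiles Long profile data.frame from [hitProfiles()].
#' @param category One of `r paste(HIT_CATEGORIES, collapse = ", ")`.
#' @return Arithmetic mean of the per-taxon counts.
#' @export
meanCategoryCount <- function(profiles, category) {
  rows <- profiles[profiles$category == category, , drop = FALSE]
  if (!nrow(rows)) .stopf("no profiles for category %s", category)
  mean(rows$count)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the exact supremum over pooled points of the absolute ECDF
#' difference; the two-sided p-value comes from the asymptotic Kolmogorov
#' distribution with effective sample size `n_x n_y / (n_x + n_y)`
#' (lengths are integer-valued, so ties occur; D remains exact and the
#' asymptotic p is used regardless).
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with `D` and `p`.
#' @export
ksTwoSample <- function(x, y) {
  if (!length(x) || !length(y)) .stopf("both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) m / j`, restored to the
#' input order; q lies in \[p, 1\].
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
bhFdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

## Box-plot statistics under the linear-interpolation quartile convention,
## whiskers at 1.5 x IQR clamped to the data range.
.lengthStats <- function(lengths) {
  q <- unname(stats::quantile(lengths, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  list(n = length(lengths), q1 = q[1L], median = q[2L], q3 = q[3L],
       whisker_low = max(min(lengths), q[1L] - 1.5 * iqr),
       whisker_high = min(max(lengths), q[3L] + 1.5 * iqr))
}

#' Protein length report for proteins with vs without hits
#'
#' Splits each proteome's lengths into with-hit (category != "none") and
#' no-hit groups, summarizes each non-empty group (n, quartiles by linear
#' interpolation, whiskers at 1.5 x IQR clamped to the data range), and
#' runs all pairwise two-sided KS tests across the (sample, status) groups
#' with BH correction over that whole comparison family.
#'
#' @param proteomes [ProteomeSet-class].
#' @param categories Named category vector from [classifyProteins()]
#'   covering the proteins to report.
#' @param pool `"taxon"` (default) keeps per-proteome samples; `"group"`
#'   pools proteomes by registry group label.
#' @return List with `stats` (one row per non-empty group) and `tests`
#'   (`group_a`, `group_b`, `n_a`, `n_b`, `D`, `p`, `q`).
#' @export
lengthReport <- function(proteomes, categories, pool = c("taxon", "group")) {
  pool <- match.arg(pool)
  ids <- names(categories)
  ptax <- proteinTaxon(proteomes)[ids]
  unit <- if (pool == "taxon") ptax else
    taxonField(proteomes@registry, "group")[ptax]
  status <- ifelse(categories == "none", "no_hit", "with_hit")
  lens <- width(proteinSequences(proteomes)[ids])
  key <- paste(unit, status, sep = ":")
  samples <- split(lens, key)
  stats_df <- do.call(rbind, lapply(sort(names(samples)), function(k) {
    s <- .lengthStats(samples[[k]])
    parts <- strsplit(k, ":", fixed = TRUE)[[1L]]
    data.frame(sample = parts[1L], status = parts[2L], n = s$n,
               q1 = s$q1, median = s$median, q3 = s$q3,
               whisker_low = s$whisker_low, whisker_high = s$whisker_high,
               stringsAsFactors = FALSE)
  }))
  keys <- sort(names(samples))
  tests <- NULL
  if (length(keys) >= 2L) {
    combs <- utils::combn(keys, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1L, i]; b <- combs[2L, i]
      ks <- ksTwoSample(samples[[a]], samples[[b]])
      data.frame(group_a = a, group_b = b,
                 n_a = length(samples[[a]]), n_b = length(samples[[b]]),
                 D = ks$D, p = ks$p, stringsAsFactors = FALSE)
    }))
    tests$q <- bhFdr(tests$p)
  } else {
    tests <- data.frame(group_a = character(), group_b = character(),
                        n_a = integer(), n_b = integer(), D = numeric(),
                        p = numeric(), q = numeric(),
                        stringsAsFactors = FALSE)
  }
  rownames(stats_df) <- NULL
  rownames(tests) <- NULL
  list(stats = stats_df, tests = tests)
}
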
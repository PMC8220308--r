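## End-to-end pipeline: (generate | load) -> per-domain all-vs-all search ->
## RBH -> MCL per domain -> cross-domain best hits -> reciprocal best
## cluster merge -> EPC assembly -> LECA filter -> lineage-unique
## contribution -> hit profiles + length statistics -> PAP matrices.

#' Pipeline configuration
#'
#' Aggregates every tunable of the analysis: the synthetic community (or a
#' FASTA directory), the two independent threshold blocks (clustering:
#' identity >= 0.25, E <= 1e-10; hit analysis: identity >= 0.25,
#' E <= 1e-5), the MCL parameters, the reciprocal-best-cluster support
#' bound (0.5), the supergroup list, and the hit-exclusion rank.
#'
#' @slot mode `"synthetic"` or `"fasta-dir"`.
#' @slot synth [SynthConfig-class] (synthetic mode).
#' @slot fastaDir,taxonTablePath Input location (fasta-dir mode).
#' @slot clustering,hitAnalysis [SearchThresholds-class] blocks.
#' @slot mcl [MclParams-class].
#' @slot minSupport Reciprocal best cluster support bound.
#' @slot exclusionRank `"genus"` or `"phylum"`.
#' @slot supergroups Required supergroups for the LECA filter.
#' @slot seed Integer seed (synthetic mode).
#' @slot verbose Emit stage log lines.
#' @export
setClass("PipelineConfig", slots = c(
  mode = "character", synth = "SynthConfig", fastaDir = "character",
  taxonTablePath = "character", clustering = "SearchThresholds",
  hitAnalysis = "SearchThresholds", mcl = "MclParams",
  minSupport = "numeric", exclusionRank = "character",
  supergroups = "character", seed = "integer", verbose = "logical"))

setValidity("PipelineConfig", function(object) {
  if (!object@mode %in% c("synthetic", "fasta-dir"))
    return("mode must be 'synthetic' or 'fasta-dir'")
  if (object@mode == "fasta-dir" &&
      (!nzchar(object@fastaDir) || !nzchar(object@taxonTablePath)))
    return("fasta-dir mode needs fastaDir and taxonTablePath")
  if (object@minSupport < 0 || object@minSupport > 1)
    return("minSupport must lie in [0, 1]")
  if (!object@exclusionRank %in% c("genus", "phylum"))
    return("exclusionRank must be 'genus' or 'phylum'")
  if (object@mode == "synthetic" && is.na(object@seed))
    return("synthetic mode requires a seed")
  TRUE
})

#' @describeIn PipelineConfig-class Constructor with full defaults.
#' @param mode,synth,fastaDir,taxonTablePath,clustering,hitAnalysis,mcl,minSupport,exclusionRank,supergroups,seed,verbose
#'   See slots.
#' @return A validated `PipelineConfig`.
#' @export
pipelineConfig <- function(mode = "synthetic",
                           synth = synthConfig(seed = seed),
                           fastaDir = "", taxonTablePath = "",
                           clustering = searchThresholds(0.25, 1e-10),
                           hitAnalysis = searchThresholds(0.25, 1e-5),
                           mcl = mclParams(), minSupport = 0.5,
                           exclusionRank = "genus",
                           supergroups = eukSupergroups(),
                           seed = 1L, verbose = FALSE) {
  new("PipelineConfig", mode = mode, synth = synth, fastaDir = fastaDir,
      taxonTablePath = taxonTablePath, clustering = clustering,
      hitAnalysis = hitAnalysis, mcl = mcl, minSupport = minSupport,
      exclusionRank = exclusionRank, supergroups = supergroups,
      seed = as.integer(seed), verbose = verbose)
}

## ---------------------------------------------------------------------------
## Config file validation
## ---------------------------------------------------------------------------

.CONFIG_KEYS <- list(
  top = c("mode", "seed", "exclusion_rank", "min_support", "supergroups",
          "fasta_dir", "taxon_table", "verbose", "synthetic", "clustering",
          "hit_analysis", "mcl"),
  synthetic = c("euk_per_supergroup", "n_bacteria", "n_bacterial_genera",
                "n_archaea", "n_archaeal_groups", "n_asgard",
                "family_counts", "within_identity", "between_ceiling",
                "length_range", "orphan_fraction", "orphan_meanlog_asgard",
                "orphan_sdlog_asgard", "orphan_meanlog_other",
                "orphan_sdlog_other", "leca_complete_fraction",
                "indel_rate"),
  clustering = c("min_identity", "max_evalue"),
  hit_analysis = c("min_identity", "max_evalue"),
  mcl = c("inflation", "expansion", "prune", "max_iter", "tol"))

.checkKeys <- function(given, section) {
  known <- .CONFIG_KEYS[[section]]
  unknown <- setdiff(names(given), known)
  if (length(unknown))
    .stopf("unknown config key '%s'%s; did you mean '%s'?",
           unknown[1L],
           if (section == "top") "" else sprintf(" in section '%s'", section),
           .suggestKey(unknown[1L], known))
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML file with sections `synthetic`, `clustering`,
#' `hit_analysis`, `mcl` and flat top-level keys, applies documented
#' defaults for everything absent (logging each applied default when
#' `verbose`), rejects unknown keys with a nearest-key suggestion, and
#' returns a fully validated [PipelineConfig-class].  An empty file yields
#' the all-defaults configuration.
#'
#' @param path YAML config file, or a pre-parsed named list.
#' @param verbose Log applied defaults.
#' @return A [PipelineConfig-class].
#' @export
validateConfig <- function(path, verbose = FALSE) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) .stopf("no such config file: %s", path)
    yaml::read_yaml(path)
  } else path
  if (is.null(cfg)) cfg <- list()
  .checkKeys(cfg, "top")
  for (sec in c("synthetic", "clustering", "hit_analysis", "mcl"))
    if (!is.null(cfg[[sec]])) .checkKeys(cfg[[sec]], sec)
  pick <- function(section, key, default) {
    v <- if (is.null(section)) cfg[[key]] else cfg[[section]][[key]]
    if (is.null(v)) {
      if (verbose)
        message(sprintf("config: using default %s%s = %s",
                        if (is.null(section)) "" else paste0(section, "."),
                        key, paste(format(default), collapse = ",")))
      default
    } else v
  }
  seed <- as.integer(pick(NULL, "seed", 1L))
  sy <- cfg$synthetic
  fam <- pick("synthetic", "family_counts",
              list(E = 10L, A = 8L, B = 8L, EA = 10L, EB = 10L, EAB = 10L,
                   EA_asgard_only = 4L))
  synth <- synthConfig(
    eukPerSupergroup = pick("synthetic", "euk_per_supergroup", 2L),
    nBacteria = pick("synthetic", "n_bacteria", 6L),
    nBacterialGenera = pick("synthetic", "n_bacterial_genera", 3L),
    nArchaea = pick("synthetic", "n_archaea", 6L),
    nArchaealGroups = pick("synthetic", "n_archaeal_groups", 3L),
    nAsgard = pick("synthetic", "n_asgard", 6L),
    familyCounts = unlist(fam),
    withinIdentity = pick("synthetic", "within_identity", 0.7),
    betweenCeiling = pick("synthetic", "between_ceiling", 0.1),
    lengthRange = unlist(pick("synthetic", "length_range",
                              c(120L, 240L))),
    orphanFraction = pick("synthetic", "orphan_fraction", 0.1),
    orphanMeanlogAsgard = pick("synthetic", "orphan_meanlog_asgard",
                               log(120)),
    orphanSdlogAsgard = pick("synthetic", "orphan_sdlog_asgard", 0.6),
    orphanMeanlogOther = pick("synthetic", "orphan_meanlog_other",
                              log(245)),
    orphanSdlogOther = pick("synthetic", "orphan_sdlog_other", 0.35),
    lecaCompleteFraction = pick("synthetic", "leca_complete_fraction", 0.5),
    indelRate = pick("synthetic", "indel_rate", 0),
    seed = seed)
  clustering <- searchThresholds(
    minIdentity = pick("clustering", "min_identity", 0.25),
    maxEvalue = pick("clustering", "max_evalue", 1e-10))
  hitAnalysis <- searchThresholds(
    minIdentity = pick("hit_analysis", "min_identity", 0.25),
    maxEvalue = pick("hit_analysis", "max_evalue", 1e-5))
  mcl <- mclParams(
    inflation = pick("mcl", "inflation", 2),
    expansion = pick("mcl", "expansion", 2L),
    prune = pick("mcl", "prune", 1e-5),
    maxIter = pick("mcl", "max_iter", 100L),
    tol = pick("mcl", "tol", 1e-8))
  pipelineConfig(
    mode = pick(NULL, "mode", "synthetic"), synth = synth,
    fastaDir = pick(NULL, "fasta_dir", ""),
    taxonTablePath = pick(NULL, "taxon_table", ""),
    clustering = clustering, hitAnalysis = hitAnalysis, mcl = mcl,
    minSupport = pick(NULL, "min_support", 0.5),
    exclusionRank = pick(NULL, "exclusion_rank", "genus"),
    supergroups = unlist(pick(NULL, "supergroups", eukSupergroups())),
    seed = seed, verbose = isTRUE(pick(NULL, "verbose", FALSE)))
}

## ---------------------------------------------------------------------------
## Run
## ---------------------------------------------------------------------------

.log <- function(config, fmt, ...) {
  if (config@verbose)
    message(sprintf("[lecatrace] %s", sprintf(fmt, ...)))
}

## Hit table for (query set, subject set) sliced out of the cached
## all-vs-all bit scores + identities.
.cachedHits <- function(cache, query, subject, thresholds) {
  qids <- proteinIds(query)
  sids <- proteinIds(subject)
  b <- cache$bits
  sel <- b$query_id %in% qids & b$subject_id %in% sids
  .hitsFromBits(b[sel, , drop = FALSE], query, subject,
                sum(width(proteinSequences(subject))), thresholds,
                identities = cache$identities)
}

## Precompute all-vs-all bit scores once, plus global identities for every
## pair that could pass any stage's E-value bound (the bound is evaluated
## against the smallest database the subject appears in across stages).
.alignmentCache <- function(proteomes, maxEvalue) {
  seqs <- proteinSequences(proteomes)
  bits <- .pairBits(seqs, seqs)
  dom <- taxonField(proteomes@registry, "domain")
  grp <- taxonField(proteomes@registry, "group")
  pdom <- unname(dom[proteomes@taxon])
  pgrp <- unname(grp[proteomes@taxon])
  domRes <- vapply(split(width(seqs), pdom), sum, 0)
  minDb <- domRes[pdom]
  asgRes <- sum(width(seqs)[pgrp == ASGARD_GROUP])
  if (asgRes > 0) minDb[pgrp == ASGARD_GROUP] <- asgRes
  names(minDb) <- proteinIds(proteomes)
  qw <- stats::setNames(width(seqs), proteinIds(proteomes))
  eMin <- eValue(bits$bits, qw[bits$query_id], minDb[bits$subject_id])
  eligible <- bits[eMin <= maxEvalue, , drop = FALSE]
  identities <- .identitiesForPairs(eligible, seqs)
  identities <- identities[!duplicated(names(identities))]
  list(bits = bits, identities = identities)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input (synthetic generation or FASTA loading), one
#' all-versus-all alignment pass, per-domain reciprocal best hits and MCL
#' (bacteria and archaea clustered separately, eukaryotes with the same
#' method), cross-domain best hits and reciprocal best cluster merges
#' (eukaryote-archaea, eukaryote-bacteria), EPC assembly and summary, the
#' LECA six-supergroup filter, lineage-unique (asgard) EA detection and
#' contribution percentages, per-proteome hit-category profiles and
#' protein-length statistics, a within-asgard family inventory, and PAP
#' matrices with deterministic orderings.  Internal consistency
#' (partition, conservation and count identities) is asserted before the
#' bundle is returned; a fixed seed yields a bit-identical bundle.
#'
#' @param config A [PipelineConfig-class].
#' @param outDir Optional directory; when given the bundle is written with
#'   [writeResultBundle()].
#' @return A [ResultBundle-class].
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  validObject(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, expr) {
    s <- proc.time()[["elapsed"]]
    v <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - s, 3)
    .log(config, "stage %-18s %8.1fs", stage, timings[[stage]])
    v
  }

  community <- NULL
  if (config@mode == "synthetic") {
    community <- tick("generate", generateCommunity(config@synth))
    proteomes <- communityProteomes(community)
  } else {
    proteomes <- tick("load", {
      reg <- readTaxonTable(config@taxonTablePath)
      loadProteomeDir(config@fastaDir, reg)
    })
  }
  reg <- proteomes@registry
  dom <- taxonField(reg, "domain")
  grp <- taxonField(reg, "group")

  cache <- tick("align", .alignmentCache(
    proteomes, max(config@clustering@maxEvalue,
                   config@hitAnalysis@maxEvalue)))

  sets <- list(
    eukaryote = subsetProteomes(proteomes, domains = "eukaryote"),
    bacteria = subsetProteomes(proteomes, domains = "bacteria"),
    archaea = subsetProteomes(proteomes, domains = "archaea"))

  prefixes <- c(eukaryote = "e", bacteria = "b", archaea = "a")
  emptyClustering <- list(
    clustering = FamilyClustering(list()),
    presence = data.frame(cluster_id = character(),
                          taxon_id = character(), n_proteins = integer(),
                          stringsAsFactors = FALSE),
    hits = NULL)
  clusterings <- tick("cluster", {
    lapply(stats::setNames(names(sets), names(sets)), function(d) {
      if (!length(proteinIds(sets[[d]]))) return(emptyClustering)
      hits <- .cachedHits(cache, sets[[d]], sets[[d]], config@clustering)
      clusterProteomes(sets[[d]], config@clustering, config@mcl,
                       idPrefix = prefixes[[d]], hits = hits)
    })
  })

  rbc <- tick("rbc_merge", {
    emptyLinks <- data.frame(source = character(), target = character(),
                             support_fwd = numeric(),
                             support_rev = numeric(),
                             stringsAsFactors = FALSE)
    crossLink <- function(prokDomain) {
      if (!length(proteinIds(sets$eukaryote)) ||
          !length(proteinIds(sets[[prokDomain]])))
        return(emptyLinks)
      bhFwd <- bestHits(.cachedHits(cache, sets$eukaryote,
                                    sets[[prokDomain]], config@clustering),
                        by = "subject_set")
      bhRev <- bestHits(.cachedHits(cache, sets[[prokDomain]],
                                    sets$eukaryote, config@clustering),
                        by = "subject_set")
      vFwd <- bestClusterVotes(clusterings$eukaryote$clustering,
                               clusterings[[prokDomain]]$clustering, bhFwd)
      vRev <- bestClusterVotes(clusterings[[prokDomain]]$clustering,
                               clusterings$eukaryote$clustering, bhRev)
      reciprocalBestClusterMerge(vFwd, vRev, config@minSupport)
    }
    list(archaea = crossLink("archaea"), bacteria = crossLink("bacteria"))
  })

  epcs <- tick("epc", assembleEpcs(rbc$archaea, rbc$bacteria))
  epcSummary <- summarizeEpcs(epcs)

  lecaIds <- tick("leca", filterLeca(clusterings$eukaryote$clustering,
                                     proteomes, config@supergroups))
  asgardEA <- tick("asgard_unique",
                   asgardUniqueEA(epcs, clusterings$archaea$clustering,
                                  proteomes))
  nEukClusters <- nClusters(clusterings$eukaryote$clustering)
  contributions <- list(
    n_asgard_unique_ea = nrow(asgardEA),
    n_leca = length(lecaIds),
    n_euk_clusters = nEukClusters,
    leca_pct = if (length(lecaIds) > 0)
      contributionPercent(nrow(asgardEA), length(lecaIds), 4L) else NA_real_,
    all_euk_pct = if (nEukClusters > 0)
      contributionPercent(nrow(asgardEA), nEukClusters, 4L) else NA_real_)

  profiling <- tick("profiles", {
    nonEmpty <- names(sets)[vapply(sets, function(s)
      length(proteinIds(s)) > 0L, TRUE)]
    profHits <- do.call(rbind, lapply(nonEmpty, function(d)
      .cachedHits(cache, proteomes, sets[[d]], config@hitAnalysis)))
    cats <- classifyProteins(proteinIds(proteomes), profHits, proteomes,
                             config@hitAnalysis, config@exclusionRank)
    profiles <- hitProfiles(proteomes, profHits, config@hitAnalysis,
                            config@exclusionRank)
    lengths <- lengthReport(proteomes, cats, pool = "taxon")
    list(categories = cats, profiles = profiles, lengths = lengths)
  })

  asgardInventory <- tick("asgard_families", {
    asgSet <- subsetProteomes(proteomes,
                              taxa = names(grp)[grp == ASGARD_GROUP])
    if (length(unique(asgSet@taxon)) >= 2L && length(proteinIds(asgSet))) {
      hits <- .cachedHits(cache, asgSet, asgSet, config@clustering)
      clusterProteomes(asgSet, config@clustering, config@mcl,
                       idPrefix = "asg", hits = hits)
    } else NULL
  })

  paps <- tick("pap", {
    out <- list()
    etab <- epcTable(epcs)
    withArch <- etab[etab$category %in% c("EA", "EAB"), , drop = FALSE]
    if (nrow(withArch)) {
      mem <- do.call(rbind, lapply(seq_len(nrow(withArch)), function(i) {
        ids <- c(
          clusterMembers(clusterings$eukaryote$clustering,
                         withArch$euk_cluster[i]),
          if (!is.na(withArch$arch_cluster[i]))
            clusterMembers(clusterings$archaea$clustering,
                           withArch$arch_cluster[i]),
          if (!is.na(withArch$bact_cluster[i]))
            clusterMembers(clusterings$bacteria$clustering,
                           withArch$bact_cluster[i]))
        data.frame(row_id = withArch$epc_id[i], protein_id = ids,
                   stringsAsFactors = FALSE)
      }))
      pap <- buildPap(mem, proteomes, columns = "taxon")
      out$epc_pap <- pap
      out$epc_row_order <- sortRowsBySupergroupPattern(pap,
                                                       config@supergroups)
    }
    if (!is.null(asgardInventory) &&
        nClusters(asgardInventory$clustering) > 0L) {
      m <- clusterMembership(asgardInventory$clustering)
      pap <- buildPap(data.frame(row_id = m$cluster_id,
                                 protein_id = m$protein_id,
                                 stringsAsFactors = FALSE),
                      proteomes, columns = "taxon")
      out$asgard_pap <- pap
      out$asgard_col_order <- hierarchicalOrder(papMatrix(pap), "columns",
                                                "jaccard")
    }
    out
  })

  recovery <- NULL
  if (!is.null(community))
    recovery <- tick("recovery", .recoveryMetrics(community, clusterings,
                                                  epcs, lecaIds, asgardEA))

  results <- list(
    registry = taxonTable(reg),
    proteomes = proteomes,
    community = community,
    clusterings = clusterings,
    rbc_links = rbc,
    epcs = epcs,
    epc_summary = epcSummary,
    leca_clusters = lecaIds,
    asgard_unique_ea = asgardEA,
    contributions = contributions,
    profiling = profiling,
    asgard_inventory = asgardInventory,
    paps = paps,
    recovery = recovery)

  .checkBundleConsistency(results)

  manifest <- list(
    package_version = as.character(utils::packageVersion("lecatrace")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = config@mode,
    seed = config@seed,
    config_hash = .polyHash(paste(deparse(config), collapse = "\n")),
    content_hash = .bundleContentHash(results),
    timings = timings,
    total_elapsed = round(proc.time()[["elapsed"]] - t0, 3))
  bundle <- new("ResultBundle", results = results, manifest = manifest)
  if (!is.null(outDir)) writeResultBundle(bundle, outDir)
  bundle
}

## Planted-truth recovery metrics for synthetic runs.
##
## Planted families can span domains, but the method clusters each domain
## separately and reunites families through the EPC merge; end-to-end
## recovery therefore relabels every cluster participating in an EPC with
## the EPC id before comparing to the planted memberships.  The
## within-domain ARI compares each domain's MCL partition to the planted
## (family x domain) cells.
.recoveryMetrics <- function(community, clusterings, epcs, lecaIds,
                             asgardEA) {
  fams <- communityFamilies(community)
  planted <- plantedFamilies(community)
  predicted <- do.call(rbind, lapply(clusterings, function(cl)
    clusterMembership(cl$clustering)))
  predLab <- stats::setNames(predicted$cluster_id, predicted$protein_id)
  ids <- names(planted)
  pred <- predLab[ids]
  pred[is.na(pred)] <- paste0("singleton_", ids[is.na(pred)])
  ## relabel clusters merged into an EPC with the EPC id
  etab <- epcTable(epcs)
  epcOf <- character()
  for (col in c("euk_cluster", "arch_cluster", "bact_cluster")) {
    known <- !is.na(etab[[col]]) & !(etab[[col]] %in% names(epcOf))
    epcOf[etab[[col]][known]] <- etab$epc_id[known]
  }
  merged <- ifelse(pred %in% names(epcOf), epcOf[pred], pred)
  haveMclust <- requireNamespace("mclust", quietly = TRUE)
  ari <- if (haveMclust) mclust::adjustedRandIndex(planted, merged) else
    NA_real_
  domOf <- taxonField(communityProteomes(community)@registry, "domain")
  ptax <- proteinTaxon(communityProteomes(community))
  plantedCell <- paste(planted, unname(domOf[ptax[ids]]))
  ariDomain <- if (haveMclust)
    mclust::adjustedRandIndex(plantedCell, pred) else NA_real_
  ## exact set comparison of recovered (EPC-merged) vs planted memberships
  plantedSets <- lapply(split(ids, planted), sort)
  predSets <- lapply(split(ids, merged), sort)
  exact <- length(plantedSets) == length(predSets) &&
    setequal(vapply(plantedSets, paste, "", collapse = ","),
             vapply(predSets, paste, "", collapse = ","))
  nPlantedAsgard <- sum(fams$asgard_unique)
  nPlantedLeca <- sum(fams$leca_complete)
  plantedRatio <- if (nPlantedLeca > 0)
    contributionPercent(nPlantedAsgard, nPlantedLeca, 4L) else NA_real_
  list(ari = ari, ari_within_domains = ariDomain, exact_match = exact,
       planted_families = nrow(fams),
       planted_asgard_unique = nPlantedAsgard,
       recovered_asgard_unique = nrow(asgardEA),
       planted_leca = nPlantedLeca,
       recovered_leca = length(lecaIds),
       planted_contribution_pct = plantedRatio)
}

## Internal consistency: partition, conservation, count identities.
.checkBundleConsistency <- function(results) {
  proteomes <- results$proteomes
  dom <- taxonField(proteomes@registry, "domain")[proteomes@taxon]
  for (d in names(results$clusterings)) {
    cl <- results$clusterings[[d]]$clustering
    covered <- c(clusterMembership(cl)$protein_id, unclusteredProteins(cl))
    domIds <- proteinIds(proteomes)[dom == d]
    if (!setequal(covered, domIds) || anyDuplicated(covered))
      .stopf("clustering of %s is not a partition of its proteins", d)
  }
  s <- results$epc_summary
  if (s$ea + s$eb + s$eab != s$total)
    .stopf("EPC categories do not partition the EPC set")
  prof <- results$profiling$profiles
  sizes <- table(proteomes@taxon)
  bySum <- tapply(prof$count, prof$taxon_id, sum)
  if (!all(bySum[names(sizes)] == as.integer(sizes)))
    .stopf("hit-category counts do not sum to proteome sizes")
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Persistence
## ---------------------------------------------------------------------------

.bundleTables <- function(results) {
  tabs <- list(registry = results$registry)
  for (d in names(results$clusterings)) {
    tabs[[paste0("clusters_", d)]] <-
      clusterMembership(results$clusterings[[d]]$clustering)
    tabs[[paste0("unclustered_", d)]] <- data.frame(
      protein_id = unclusteredProteins(results$clusterings[[d]]$clustering),
      stringsAsFactors = FALSE)
  }
  tabs$rbc_links_archaea <- results$rbc_links$archaea
  tabs$rbc_links_bacteria <- results$rbc_links$bacteria
  tabs$epcs <- epcTable(results$epcs)
  tabs$leca_clusters <- data.frame(cluster_id = results$leca_clusters,
                                   stringsAsFactors = FALSE)
  tabs$asgard_unique_ea <- results$asgard_unique_ea
  tabs$hit_profiles <- results$profiling$profiles
  tabs$length_stats <- results$profiling$lengths$stats
  tabs$ks_tests <- results$profiling$lengths$tests
  if (!is.null(results$asgard_inventory)) {
    tabs$asgard_families <-
      clusterMembership(results$asgard_inventory$clustering)
    tabs$asgard_presence <- results$asgard_inventory$presence
  }
  if (!is.null(results$paps$epc_pap)) {
    m <- papMatrix(results$paps$epc_pap)
    m <- m[results$paps$epc_row_order, , drop = FALSE]
    tabs$epc_pap <- data.frame(row_id = rownames(m),
                               as.data.frame(m + 0L),
                               check.names = FALSE,
                               stringsAsFactors = FALSE)
  }
  if (!is.null(results$paps$asgard_pap)) {
    m <- papMatrix(results$paps$asgard_pap)
    m <- m[, results$paps$asgard_col_order, drop = FALSE]
    tabs$asgard_pap <- data.frame(row_id = rownames(m),
                                  as.data.frame(m + 0L),
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE)
  }
  tabs
}

.bundleScalars <- function(results) {
  out <- list(epc_summary = results$epc_summary[
    c("ea", "eb", "eab", "total", "with_archaea", "pct_with_archaea")],
    contributions = results$contributions)
  if (!is.null(results$recovery)) out$recovery <- results$recovery
  out
}

.bundleContentHash <- function(results) {
  tabs <- .bundleTables(results)
  parts <- vapply(names(tabs), function(nm) {
    df <- tabs[[nm]]
    paste(nm, paste(utils::capture.output(
      utils::write.table(format(df, digits = 12), sep = "\t",
                         quote = FALSE, row.names = FALSE)),
      collapse = "\n"), sep = "\n")
  }, "")
  scal <- as.character(jsonlite::toJSON(.bundleScalars(results),
                                        auto_unbox = TRUE, digits = NA,
                                        na = "null"))
  .polyHash(paste(c(parts, scal), collapse = "\n\n"))
}

#' Write a result bundle to a directory
#'
#' Persists every stage table as TSV plus `summary.json` (EPC summary,
#' contributions, recovery metrics) and `manifest.json` (versions, seed,
#' config and content hashes, timings).
#'
#' @param bundle A [ResultBundle-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
writeResultBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- .bundleTables(bundle@results)
  for (nm in names(tabs))
    utils::write.table(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(.bundleScalars(bundle@results),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  jsonlite::write_json(bundle@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
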
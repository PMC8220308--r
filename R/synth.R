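## Synthetic proteome communities with planted family structure.
##
## The generator is the ground-truth side of every recovery test: it plants
## gene families with controlled domain/group sharing profiles (E, A, B, EA,
## EB, EAB, and EA with asgard-exclusive archaeal membership), evolves one
## descendant per seeded taxon from a random ancestor under a
## substitution-only star model, and adds per-taxon orphan proteins whose
## length law differs between asgard and non-asgard taxa.

FAMILY_PROFILES <- c("E", "A", "B", "EA", "EB", "EAB", "EA_asgard_only")

#' Configuration of a synthetic proteome community
#'
#' Defaults describe a desk-scale community: two eukaryotes per supergroup
#' (12), six bacteria in three genera, six non-asgard archaea in three
#' classes, six asgard archaea, and sixty planted families with a target
#' pairwise within-family identity of 0.7 against a between-family identity
#' ceiling of 0.1 -- well separated relative to the 25% clustering cutoff.
#'
#' @slot eukPerSupergroup Eukaryotic taxa per supergroup (>= 1).
#' @slot nBacteria,nBacterialGenera Bacterial taxa and genera (>= 2 genera).
#' @slot nArchaea,nArchaealGroups Non-asgard archaeal taxa and classes
#'   (>= 2 classes).
#' @slot nAsgard Asgard taxa (>= 2).
#' @slot familyCounts Named integer vector over the profiles
#'   `r paste(FAMILY_PROFILES, collapse = ", ")`.
#' @slot withinIdentity Target pairwise identity between members of a
#'   family, in (0.25, 1]; the per-descendant identity to the family
#'   ancestor is derived from it under the substitution model.
#' @slot betweenCeiling Upper bound on expected between-family identity;
#'   must stay below the clustering identity threshold (families have
#'   independent random ancestors, whose expected identity is ~0.05).
#' @slot lengthRange Integer range of family ancestor lengths (residues).
#' @slot orphanFraction Per planted protein, the probability of adding one
#'   orphan protein to the same taxon (in \[0, 1)).
#' @slot orphanMeanlogAsgard,orphanSdlogAsgard Log-normal length parameters
#'   for asgard orphans.
#' @slot orphanMeanlogOther,orphanSdlogOther Log-normal length parameters
#'   for all other taxa's orphans.
#' @slot lecaCompleteFraction Fraction of eukaryote-containing families
#'   seeded into all six supergroups.
#' @slot indelRate Reserved extension; must be 0 (substitution-only model).
#' @slot seed Base seed; every family and every taxon's orphan draw uses an
#'   independent stream derived from it.
#' @export
setClass("SynthConfig", slots = c(
  eukPerSupergroup = "integer", nBacteria = "integer",
  nBacterialGenera = "integer", nArchaea = "integer",
  nArchaealGroups = "integer", nAsgard = "integer",
  familyCounts = "integer", withinIdentity = "numeric",
  betweenCeiling = "numeric", lengthRange = "integer",
  orphanFraction = "numeric", orphanMeanlogAsgard = "numeric",
  orphanSdlogAsgard = "numeric", orphanMeanlogOther = "numeric",
  orphanSdlogOther = "numeric", lecaCompleteFraction = "numeric",
  indelRate = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (object@eukPerSupergroup < 1L)
    return("need at least one eukaryote per supergroup")
  if (object@nBacterialGenera < 2L || object@nBacteria < object@nBacterialGenera)
    return("need at least two bacterial genera")
  if (object@nArchaealGroups < 2L || object@nArchaea < object@nArchaealGroups)
    return("need at least two non-asgard archaeal groups")
  if (object@nAsgard < 2L) return("need at least two asgard taxa")
  if (!identical(sort(names(object@familyCounts)), sort(FAMILY_PROFILES)))
    return(sprintf("familyCounts must name exactly the profiles %s",
                   paste(FAMILY_PROFILES, collapse = ", ")))
  if (any(object@familyCounts < 0L)) return("family counts must be >= 0")
  if (object@withinIdentity <= 0.25 || object@withinIdentity > 1)
    return("withinIdentity must lie in (0.25, 1]")
  if (object@betweenCeiling >= 0.25)
    return("betweenCeiling must stay below the 25% clustering threshold")
  if (length(object@lengthRange) != 2L || object@lengthRange[1L] < 10L ||
      diff(object@lengthRange) < 0L)
    return("lengthRange must be an increasing pair of lengths >= 10")
  if (object@orphanFraction < 0 || object@orphanFraction >= 1)
    return("orphanFraction must lie in [0, 1)")
  if (object@lecaCompleteFraction < 0 || object@lecaCompleteFraction > 1)
    return("lecaCompleteFraction must lie in [0, 1]")
  if (object@indelRate != 0)
    return("indelRate is a reserved extension and must be 0")
  TRUE
})

#' @describeIn SynthConfig-class Constructor with the default community.
#' @param eukPerSupergroup,nBacteria,nBacterialGenera,nArchaea,nArchaealGroups,nAsgard
#'   Taxon layout, see slots.
#' @param familyCounts,withinIdentity,betweenCeiling,lengthRange Family
#'   structure, see slots.
#' @param orphanFraction,orphanMeanlogAsgard,orphanSdlogAsgard,orphanMeanlogOther,orphanSdlogOther
#'   Orphan model, see slots.
#' @param lecaCompleteFraction,indelRate,seed See slots.
#' @return A validated `SynthConfig`.
#' @export
synthConfig <- function(eukPerSupergroup = 2L,
                        nBacteria = 6L, nBacterialGenera = 3L,
                        nArchaea = 6L, nArchaealGroups = 3L,
                        nAsgard = 6L,
                        familyCounts = c(E = 10L, A = 8L, B = 8L, EA = 10L,
                                         EB = 10L, EAB = 10L,
                                         EA_asgard_only = 4L),
                        withinIdentity = 0.7, betweenCeiling = 0.1,
                        lengthRange = c(120L, 240L),
                        orphanFraction = 0.1,
                        orphanMeanlogAsgard = log(120),
                        orphanSdlogAsgard = 0.6,
                        orphanMeanlogOther = log(245),
                        orphanSdlogOther = 0.35,
                        lecaCompleteFraction = 0.5,
                        indelRate = 0, seed = 1L) {
  fc <- as.integer(familyCounts)
  names(fc) <- names(familyCounts)
  new("SynthConfig",
      eukPerSupergroup = as.integer(eukPerSupergroup),
      nBacteria = as.integer(nBacteria),
      nBacterialGenera = as.integer(nBacterialGenera),
      nArchaea = as.integer(nArchaea),
      nArchaealGroups = as.integer(nArchaealGroups),
      nAsgard = as.integer(nAsgard),
      familyCounts = fc, withinIdentity = withinIdentity,
      betweenCeiling = betweenCeiling,
      lengthRange = as.integer(lengthRange),
      orphanFraction = orphanFraction,
      orphanMeanlogAsgard = orphanMeanlogAsgard,
      orphanSdlogAsgard = orphanSdlogAsgard,
      orphanMeanlogOther = orphanMeanlogOther,
      orphanSdlogOther = orphanSdlogOther,
      lecaCompleteFraction = lecaCompleteFraction,
      indelRate = indelRate, seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d euk, %d bact, %d arch, %d asgard taxa; %d families\n",
    6L * object@eukPerSupergroup, object@nBacteria, object@nArchaea,
    object@nAsgard, sum(object@familyCounts)))
  cat(sprintf("  within-family identity %.2f, orphan fraction %.2f, seed %d\n",
              object@withinIdentity, object@orphanFraction, object@seed))
})

#' A generated community: proteomes plus planted ground truth
#'
#' @slot proteomes [ProteomeSet-class] of all generated proteins.
#' @slot proteins data.frame `protein_id`, `taxon_id`, `family_id` (NA for
#'   orphans), `is_orphan`.
#' @slot families data.frame `family_id`, `profile`, `asgard_unique`,
#'   `leca_complete`, `length`.
#' @slot cells data.frame `family_id`, `domain`, `group` of the seeded
#'   (domain, group) cells.
#' @slot config The generating [SynthConfig-class].
#' @export
setClass("SyntheticCommunity", slots = c(
  proteomes = "ProteomeSet", proteins = "data.frame",
  families = "data.frame", cells = "data.frame", config = "SynthConfig"))

#' @describeIn SyntheticCommunity-class Accessors.
#' @param object A `SyntheticCommunity`.
#' @return `communityProteomes`: [ProteomeSet-class]; `communityTruth`:
#'   protein-level truth data.frame; `communityFamilies`: family-level truth;
#'   `communityCells`: seeded (family, domain, group) cells.
#' @export
communityProteomes <- function(object) object@proteomes

#' @rdname communityProteomes
#' @export
communityTruth <- function(object) object@proteins

#' @rdname communityProteomes
#' @export
communityFamilies <- function(object) object@families

#' @rdname communityProteomes
#' @export
communityCells <- function(object) object@cells

setMethod("show", "SyntheticCommunity", function(object) {
  cat(sprintf(
    "SyntheticCommunity: %d proteins (%d orphans), %d planted families\n",
    nrow(object@proteins), sum(object@proteins$is_orphan),
    nrow(object@families)))
  show(object@proteomes)
})

## Ancestor-to-leaf identity d realizing a target pairwise leaf-leaf
## identity t under independent uniform substitution to a different
## residue:  t = d^2 + (1 - d)^2 / 19  =>  20 d^2 - 2 d + 1 - 19 t = 0.
.leafIdentityForPairwise <- function(t) {
  disc <- 1520 * t - 76
  if (disc < 0) .stopf("pairwise identity %g not realizable", t)
  d <- (2 + sqrt(disc)) / 40
  min(d, 1)
}

#' Mutate an amino-acid sequence to a target identity
#'
#' Substitutes a Bernoulli(1 - targetIdentity) fraction of positions with a
#' uniformly chosen different residue; no indels.  Uses the current RNG
#' stream.
#'
#' @param seq Amino-acid string.
#' @param targetIdentity Fraction in (0, 1].
#' @return Mutated sequence string.
#' @export
mutateSequence <- function(seq, targetIdentity) {
  if (!nzchar(seq)) .stopf("cannot mutate an empty sequence")
  if (targetIdentity <= 0 || targetIdentity > 1)
    .stopf("targetIdentity must lie in (0, 1]")
  if (targetIdentity == 1) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- stats::runif(length(chars)) < (1 - targetIdentity)
  if (any(hit)) {
    idx <- which(hit)
    repl <- vapply(chars[idx],
                   function(a) sample(setdiff(AA20, a), 1L), "",
                   USE.NAMES = FALSE)
    chars[idx] <- repl
  }
  paste(chars, collapse = "")
}

.randomSequence <- function(len)
  paste(sample(AA20, len, replace = TRUE), collapse = "")

## Registry layout for a config: deterministic, no RNG.
.synthRegistry <- function(config) {
  sg <- eukSupergroups()
  euk <- do.call(rbind, lapply(seq_along(sg), function(i) {
    data.frame(
      taxon_id = sprintf("E%02d", (i - 1L) * config@eukPerSupergroup +
                           seq_len(config@eukPerSupergroup)),
      name = sprintf("%s sp. %d", sg[i], seq_len(config@eukPerSupergroup)),
      domain = "eukaryote", group = sg[i],
      genus = sprintf("Eukgenus%02d", (i - 1L) * config@eukPerSupergroup +
                        seq_len(config@eukPerSupergroup)),
      stringsAsFactors = FALSE)
  }))
  bgen <- rep_len(seq_len(config@nBacterialGenera), config@nBacteria)
  bact <- data.frame(
    taxon_id = sprintf("B%02d", seq_len(config@nBacteria)),
    name = sprintf("Bacterium %d", seq_len(config@nBacteria)),
    domain = "bacteria",
    group = sprintf("Bactphylum%d", rep_len(seq_len(2L), config@nBacteria)),
    genus = sprintf("Bactgenus%d", sort(bgen)),
    stringsAsFactors = FALSE)
  agrp <- sort(rep_len(seq_len(config@nArchaealGroups), config@nArchaea))
  arch <- data.frame(
    taxon_id = sprintf("A%02d", seq_len(config@nArchaea)),
    name = sprintf("Archaeon %d", seq_len(config@nArchaea)),
    domain = "archaea",
    group = c("Euryarchaeota", "Crenarchaeota", "Thaumarchaeota",
              sprintf("Archclass%d", 4:10))[agrp],
    genus = sprintf("Archgenus%02d", seq_len(config@nArchaea)),
    stringsAsFactors = FALSE)
  asg <- data.frame(
    taxon_id = sprintf("G%02d", seq_len(config@nAsgard)),
    name = sprintf("Asgard archaeon %d", seq_len(config@nAsgard)),
    domain = "archaea", group = ASGARD_GROUP,
    genus = sprintf("Asgardgenus%02d", seq_len(config@nAsgard)),
    stringsAsFactors = FALSE)
  TaxonRegistry(rbind(euk, bact, arch, asg))
}

## Choose the seeded (domain, group) cells and taxa for one family.
## Returns list(taxa = character, cells = data.frame, leca = flag).
.seedFamily <- function(profile, reg, config) {
  tab <- taxonTable(reg)
  sg <- eukSupergroups()
  taxa <- character()
  cells <- data.frame(domain = character(), group = character(),
                      stringsAsFactors = FALSE)
  leca <- FALSE
  hasE <- profile %in% c("E", "EA", "EB", "EAB", "EA_asgard_only")
  hasA <- profile %in% c("A", "EA", "EAB", "EA_asgard_only")
  hasB <- profile %in% c("B", "EB", "EAB")
  if (hasE) {
    leca <- stats::runif(1) < config@lecaCompleteFraction
    groups <- if (leca) sg else
      sample(sg, sample.int(5L, 1L))   # proper subset: never all six
    for (g in groups) {
      taxa <- c(taxa, tab$taxon_id[tab$domain == "eukaryote" &
                                     tab$group == g])
    }
    cells <- rbind(cells, data.frame(domain = "eukaryote", group = groups))
  }
  if (hasA) {
    if (profile == "EA_asgard_only") {
      asg <- tab$taxon_id[tab$group == ASGARD_GROUP]
      taxa <- c(taxa, sort(sample(asg, max(2L, sample.int(length(asg), 1L)))))
      cells <- rbind(cells, data.frame(domain = "archaea",
                                       group = ASGARD_GROUP))
    } else {
      ngrps <- setdiff(unique(tab$group[tab$domain == "archaea"]),
                       ASGARD_GROUP)
      pick <- sample(ngrps, sample.int(min(2L, length(ngrps)), 1L))
      for (g in pick)
        taxa <- c(taxa, tab$taxon_id[tab$group == g])
      cells <- rbind(cells, data.frame(domain = "archaea", group = pick))
      if (stats::runif(1) < 0.5) {   # asgard joins many mixed families
        asg <- tab$taxon_id[tab$group == ASGARD_GROUP]
        taxa <- c(taxa, sort(sample(asg, sample.int(length(asg), 1L))))
        cells <- rbind(cells, data.frame(domain = "archaea",
                                         group = ASGARD_GROUP))
      }
    }
  }
  if (hasB) {
    bt <- tab$taxon_id[tab$domain == "bacteria"]
    pick <- sort(sample(bt, max(2L, sample.int(length(bt), 1L))))
    taxa <- c(taxa, pick)
    cells <- rbind(cells, unique(
      data.frame(domain = "bacteria",
                 group = tab$group[match(pick, tab$taxon_id)])))
  }
  list(taxa = unique(taxa), cells = unique(cells), leca = leca && hasE)
}

#' Generate a synthetic proteome community with planted ground truth
#'
#' Deterministic for a fixed config seed: every family and every taxon's
#' orphan draw runs on an independent RNG stream derived from (seed, id),
#' so adding families does not perturb existing ones.  Each planted family
#' draws a random ancestor at a length in the configured range and emits
#' one descendant per seeded taxon, mutated so that the expected pairwise
#' identity between members matches `withinIdentity`.  Orphans are added
#' per taxon with binomially distributed counts and log-normally
#' distributed lengths (asgard taxa use their own length law).
#'
#' @param config A [SynthConfig-class].
#' @return A [SyntheticCommunity-class].
#' @export
generateCommunity <- function(config) {
  validObject(config)
  reg <- .synthRegistry(config)
  tab <- taxonTable(reg)
  d <- .leafIdentityForPairwise(config@withinIdentity)
  profiles <- rep(names(config@familyCounts), config@familyCounts)
  famIds <- sprintf("fam%03d", seq_along(profiles))

  seqs <- character()
  ptax <- character()
  prot <- list()
  fams <- list()
  cells <- list()
  for (i in seq_along(profiles)) {
    fid <- famIds[i]
    .withSeed(.deriveSeed(config@seed, "family", fid), {
      len <- sample(seq(config@lengthRange[1L], config@lengthRange[2L]), 1L)
      anc <- .randomSequence(len)
      seeded <- .seedFamily(profiles[i], reg, config)
      members <- vapply(seeded$taxa, function(t) mutateSequence(anc, d), "")
    })
    ids <- paste0(seeded$taxa, "|", fid)
    seqs[ids] <- unname(members)
    ptax[ids] <- seeded$taxa
    prot[[fid]] <- data.frame(protein_id = ids, taxon_id = seeded$taxa,
                              family_id = fid, is_orphan = FALSE,
                              stringsAsFactors = FALSE)
    fams[[fid]] <- data.frame(
      family_id = fid, profile = profiles[i],
      asgard_unique = profiles[i] == "EA_asgard_only",
      leca_complete = seeded$leca, length = len, stringsAsFactors = FALSE)
    cells[[fid]] <- cbind(family_id = fid, seeded$cells)
  }

  planted <- do.call(rbind, prot)
  for (tid in tab$taxon_id) {
    nPlanted <- sum(planted$taxon_id == tid)
    if (!nPlanted || config@orphanFraction == 0) next
    asgard <- tab$group[tab$taxon_id == tid] == ASGARD_GROUP
    .withSeed(.deriveSeed(config@seed, "orphans", tid), {
      nOrph <- stats::rbinom(1L, nPlanted, config@orphanFraction)
      if (nOrph > 0L) {
        lens <- orphanLengths(nOrph, config, asgard = asgard)
        oseqs <- vapply(lens, .randomSequence, "")
      }
    })
    if (nOrph > 0L) {
      ids <- sprintf("%s|orph%03d", tid, seq_len(nOrph))
      seqs[ids] <- oseqs
      ptax[ids] <- rep(tid, nOrph)
      prot[[paste0("orph_", tid)]] <- data.frame(
        protein_id = ids, taxon_id = tid, family_id = NA_character_,
        is_orphan = TRUE, stringsAsFactors = FALSE)
    }
  }

  proteins <- do.call(rbind, prot)
  rownames(proteins) <- NULL
  new("SyntheticCommunity",
      proteomes = ProteomeSet(seqs, ptax, reg),
      proteins = proteins,
      families = do.call(rbind, fams),
      cells = do.call(rbind, cells),
      config = config)
}

#' Draw orphan protein lengths from the configured length law
#'
#' Orphan lengths are log-normal, with separate parameters for asgard and
#' non-asgard taxa (the configured contrast behind the with-/without-hit
#' length comparison), truncated below at 10 residues.  Uses the current
#' RNG stream.
#'
#' @param n Number of lengths.
#' @param config A [SynthConfig-class].
#' @param asgard Draw from the asgard law?
#' @return Integer vector of lengths.
#' @export
orphanLengths <- function(n, config, asgard = FALSE) {
  ml <- if (asgard) config@orphanMeanlogAsgard else config@orphanMeanlogOther
  sl <- if (asgard) config@orphanSdlogAsgard else config@orphanSdlogOther
  pmax(10L, as.integer(round(stats::rlnorm(n, ml, sl))))
}

#' Planted family memberships as a clustering-comparable labeling
#'
#' @param community A [SyntheticCommunity-class].
#' @param domains Optional domain restriction (e.g. `"eukaryote"`).
#' @return Named character vector protein_id -> planted family id, covering
#'   non-orphan proteins only.
#' @export
plantedFamilies <- function(community, domains = NULL) {
  tr <- communityTruth(community)
  tr <- tr[!tr$is_orphan, ]
  if (!is.null(domains)) {
    dom <- taxonField(communityProteomes(community)@registry, "domain")
    tr <- tr[dom[tr$taxon_id] %in% domains, ]
  }
  stats::setNames(tr$family_id, tr$protein_id)
}
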
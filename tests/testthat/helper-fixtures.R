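## Shared fixtures, built in code.  Expensive objects (pipeline runs) are
## memoised so several test files can share one computation.

.fixtureCache <- new.env(parent = emptyenv())

## Small community: one taxon per supergroup, 2 bacteria / 2 genera,
## 2 non-asgard archaea / 2 classes, 2 asgard; one family per profile.
tinySynthConfig <- function(seed = 11L, ...) {
  synthConfig(eukPerSupergroup = 1L, nBacteria = 2L, nBacterialGenera = 2L,
              nArchaea = 2L, nArchaealGroups = 2L, nAsgard = 2L,
              familyCounts = c(E = 1L, A = 1L, B = 1L, EA = 1L, EB = 1L,
                               EAB = 1L, EA_asgard_only = 1L),
              lengthRange = c(60L, 100L), seed = seed, ...)
}

tinyCommunity <- function() {
  if (is.null(.fixtureCache$tinyCommunity))
    .fixtureCache$tinyCommunity <- generateCommunity(tinySynthConfig())
  .fixtureCache$tinyCommunity
}

tinyBundle <- function() {
  if (is.null(.fixtureCache$tinyBundle))
    .fixtureCache$tinyBundle <- runPipeline(
      pipelineConfig(seed = 11L, synth = tinySynthConfig()))
  .fixtureCache$tinyBundle
}

## The default study-condition community/pipeline (used by the recovery
## and invariant checks); computed once per session.
defaultBundle <- function() {
  if (is.null(.fixtureCache$defaultBundle))
    .fixtureCache$defaultBundle <- runPipeline(pipelineConfig(seed = 1L))
  .fixtureCache$defaultBundle
}

## Hand-made three-taxon registry for unit tests of classification etc.
miniRegistry <- function() {
  TaxonRegistry(data.frame(
    taxon_id = c("E1", "E2", "A1", "A2", "G1", "B1", "B2", "B3"),
    name = c("Euk one", "Euk two", "Arch one", "Arch two", "Asgard one",
             "Bact one", "Bact two", "Bact three"),
    domain = c("eukaryote", "eukaryote", "archaea", "archaea", "archaea",
               "bacteria", "bacteria", "bacteria"),
    group = c("Opisthokonta", "SAR", "Euryarchaeota", "Crenarchaeota",
              "asgard", "Bactphylum1", "Bactphylum1", "Bactphylum2"),
    genus = c("Homo", "Thalassiosira", "Methanococcus", "Sulfolobus",
              "Prometheoarchaeum", "Bacillus", "Bacillus", "Escherichia"),
    stringsAsFactors = FALSE))
}

## Minimal hit-table row builder (fields the filters/classifiers read).
hitRow <- function(q, s, qt, st, bits = 100, evalue = 1e-30,
                   identity = 0.5) {
  n <- length(q)
  data.frame(query_id = q, subject_id = s,
             query_taxon = rep_len(qt, n), subject_taxon = rep_len(st, n),
             bit_score = rep_len(bits, n), evalue = rep_len(evalue, n),
             global_identity = rep_len(identity, n),
             stringsAsFactors = FALSE)
}
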
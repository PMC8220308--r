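## Cluster-level vote/merge machinery on hand-built clusterings.

test_that("best-cluster votes compute member-fraction support", {
  src <- FamilyClustering(list(E1 = paste0("e", 1:4)))
  tgt <- FamilyClustering(list(P1 = paste0("p", 1:3), P2 = "p4"))
  best <- hitRow(paste0("e", 1:3), c("p1", "p2", "p4"), "T", "U")
  v <- bestClusterVotes(src, tgt, best)
  ## 2 of 4 members into P1, 1 of 4 into P2; e4 abstains
  expect_identical(v$support[v$target == "P1"], 0.5)
  expect_identical(v$support[v$target == "P2"], 0.25)
  expect_identical(v$is_candidate, c(TRUE, FALSE))
  ## 3 of 4 members into one target: support 0.75
  best2 <- hitRow(paste0("e", 1:3), c("p1", "p2", "p3"), "T", "U")
  v2 <- bestClusterVotes(src, tgt, best2)
  expect_identical(v2$support[v2$target == "P1"], 0.75)
})

test_that("a split vote yields no candidate and no hits yield no votes", {
  src <- FamilyClustering(list(E1 = c("e1", "e2")))
  tgt <- FamilyClustering(list(P1 = "p1", P2 = "p2"))
  v <- bestClusterVotes(src, tgt, hitRow(c("e1", "e2"), c("p1", "p2"),
                                         "T", "U"))
  expect_false(any(v$is_candidate))
  v0 <- bestClusterVotes(src, tgt,
                         hitRow(character(), character(), character(),
                                character()))
  expect_identical(nrow(v0), 0L)
  ## a best hit outside every target cluster counts as abstention
  v1 <- bestClusterVotes(src, tgt, hitRow(c("e1", "e2"), c("p1", "zzz"),
                                          "T", "U"))
  expect_identical(v1$support, 0.5)
})

votesDf <- function(source, target, support) {
  data.frame(source = source, target = target, support = support,
             is_candidate = TRUE, stringsAsFactors = FALSE)
}

test_that("reciprocal merging enforces the inclusive 50% rule both ways", {
  expect_identical(nrow(reciprocalBestClusterMerge(
    votesDf("E1", "P1", 0.75), votesDf("P1", "E1", 0.6))), 1L)
  expect_identical(nrow(reciprocalBestClusterMerge(
    votesDf("E1", "P1", 0.75), votesDf("P1", "E1", 0.4))), 0L)
  ## support exactly 0.5 on both sides merges ("at least 50%")
  m <- reciprocalBestClusterMerge(votesDf("E1", "P1", 0.5),
                                  votesDf("P1", "E1", 0.5))
  expect_identical(nrow(m), 1L)
  expect_identical(m$support_fwd, 0.5)
  expect_identical(m$support_rev, 0.5)
})

test_that("EPC categories reflect the linked partners", {
  arch <- data.frame(source = c("E1", "E3"), target = c("A1", "A3"),
                     support_fwd = 1, support_rev = 1,
                     stringsAsFactors = FALSE)
  bact <- data.frame(source = c("E2", "E3"), target = c("B1", "B3"),
                     support_fwd = 1, support_rev = 1,
                     stringsAsFactors = FALSE)
  epcs <- assembleEpcs(arch, bact)
  tab <- epcTable(epcs)
  expect_identical(stats::setNames(tab$category, tab$euk_cluster),
                   c(E1 = "EA", E2 = "EB", E3 = "EAB"))
  ## a eukaryotic cluster with no link is absent
  expect_false("E4" %in% tab$euk_cluster)
  s <- summarizeEpcs(epcs)
  expect_identical(s$total, s$ea + s$eb + s$eab)
})

test_that("EPC summaries compute with-archaea counts and percentages", {
  s <- summarizeEpcCounts(0, 10, 0)
  expect_identical(s$with_archaea, 0)
  expect_identical(s$pct_with_archaea, 0)
  expect_identical(summarizeEpcCounts(1, 0, 0)$pct_with_archaea, 100)
  empty <- summarizeEpcCounts(0, 0, 0)
  expect_true(is.na(empty$pct_with_archaea))
  expect_false(empty$pct_defined)
})

test_that("the LECA filter keeps exactly six-supergroup-complete clusters", {
  comm <- tinyCommunity()
  pro <- communityProteomes(comm)
  tr <- communityTruth(comm)
  fams <- communityFamilies(comm)
  ## planted families as clusters (eukaryotic members only)
  dom <- taxonField(pro@registry, "domain")
  eukTr <- tr[!tr$is_orphan & dom[tr$taxon_id] == "eukaryote", ]
  clustering <- FamilyClustering(split(eukTr$protein_id, eukTr$family_id))
  kept <- filterLeca(clustering, pro)
  expect_setequal(kept, fams$family_id[fams$leca_complete])
  ## requiring fewer supergroups can only grow the kept set
  keptLax <- filterLeca(clustering, pro,
                        supergroups = eukSupergroups()[1:3])
  expect_true(all(kept %in% keptLax))
  ## a cluster covering five of six supergroups is dropped
  five <- eukTr[eukTr$family_id == kept[1], ]
  grp <- taxonField(pro@registry, "group")
  drop1 <- five[grp[five$taxon_id] != "Opisthokonta", ]
  expect_identical(
    filterLeca(FamilyClustering(list(c5 = drop1$protein_id)), pro),
    character(0))
})

test_that("asgard-unique detection requires EA category and asgard-only partners", {
  reg <- miniRegistry()
  pro <- ProteomeSet(
    c("G1|x" = "MKVL", "G1|x2" = "MKVA", "A1|y" = "MKVL",
      "E1|z" = "MKVL"),
    c("G1", "G1", "A1", "E1"), reg)
  archCl <- FamilyClustering(list(pureAsgard = "G1|x",
                                  mixed = c("G1|x2", "A1|y")))
  mkEpc <- function(category, arch) {
    new("EPCSet", table = data.frame(
      epc_id = "epc1", euk_cluster = "E1c",
      arch_cluster = if (category == "EB") NA_character_ else arch,
      bact_cluster = if (category %in% c("EB", "EAB")) "B1c"
                     else NA_character_,
      category = category, euk_arch_support = 1, arch_euk_support = 1,
      euk_bact_support = 1, bact_euk_support = 1,
      stringsAsFactors = FALSE))
  }
  expect_identical(
    nrow(asgardUniqueEA(mkEpc("EA", "pureAsgard"), archCl, pro)), 1L)
  expect_identical(
    nrow(asgardUniqueEA(mkEpc("EA", "mixed"), archCl, pro)), 0L)
  ## EAB with an asgard-only archaeal side is excluded by definition
  expect_identical(
    nrow(asgardUniqueEA(mkEpc("EAB", "pureAsgard"), archCl, pro)), 0L)
})

test_that("contribution percentages round half-up at the requested precision", {
  expect_identical(contributionPercent(0, 1880, 4), 0)
  expect_identical(contributionPercent(1, 1, 1), 100)
  expect_identical(contributionPercent(1, 3, 2), 33.33)
  expect_identical(contributionPercent(1, 800, 1), 0.1)  # 0.125 -> 0.1
  expect_identical(contributionPercent(1, 400, 1), 0.3)  # 0.25 -> 0.3 (half-up)
  expect_error(contributionPercent(1, 0), "positive")
  expect_error(contributionPercent(5, 3), "nUnique")
})
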
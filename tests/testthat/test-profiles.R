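test_that("hit categories encode the domains of surviving subjects", {
  reg <- miniRegistry()
  pro <- ProteomeSet(
    c("G1|q" = "MKVL", "B1|s1" = "MKVL", "B3|s2" = "MKVL",
      "E1|s3" = "MKVL", "A1|s4" = "MKVL", "G1|s5" = "MKVA"),
    c("G1", "B1", "B3", "E1", "A1", "G1"), reg)
  thr <- searchThresholds(0.25, 1e-5)
  ## hits only in two bacteria of different genera -> "B"
  hits <- hitRow(c("G1|q", "G1|q"), c("B1|s1", "B3|s2"), "G1",
                 c("B1", "B3"))
  expect_identical(unname(classifyProteins("G1|q", hits, pro, thr)), "B")
  ## only hit shares the query's genus -> excluded -> "none"
  own <- hitRow("G1|q", "G1|s5", "G1", "G1")
  expect_identical(unname(classifyProteins("G1|q", own, pro, thr)),
                   "none")
  ## eukaryote + archaeon -> "EA"
  ea <- hitRow(c("G1|q", "G1|q"), c("E1|s3", "A1|s4"), "G1",
               c("E1", "A1"))
  expect_identical(unname(classifyProteins("G1|q", ea, pro, thr)), "EA")
  ## permuting hit rows changes nothing
  expect_identical(classifyProteins("G1|q", ea[2:1, ], pro, thr),
                   classifyProteins("G1|q", ea, pro, thr))
})

test_that("phylum-level exclusion uses the registry group label", {
  reg <- miniRegistry()
  pro <- ProteomeSet(c("B1|q" = "MKVL", "B2|s" = "MKVL"),
                     c("B1", "B2"), reg)
  ## B1 and B2 share a phylum but not a genus? (same genus here: Bacillus)
  hits <- hitRow("B1|q", "B2|s", "B1", "B2")
  expect_identical(
    unname(classifyProteins("B1|q", hits, pro, exclusionRank = "genus")),
    "none")  # same genus Bacillus
  ## different-genus, same-phylum subject: genus keeps it, phylum drops it
  pro2 <- ProteomeSet(c("B3|q" = "MKVL", "B1|s" = "MKVL"),
                      c("B3", "B1"), reg)
  h2 <- hitRow("B3|q", "B1|s", "B3", "B1")
  expect_identical(
    unname(classifyProteins("B3|q", h2, pro2, exclusionRank = "genus")),
    "B")
  ## same phylum would still pass (different phyla here), so force one:
  h3 <- hitRow("B1|q", "B2|s", "B1", "B2")
  expect_identical(
    unname(classifyProteins("B1|q", h3, pro, exclusionRank = "phylum")),
    "none")  # Bactphylum1 shared
})

test_that("profiles conserve proteome size and orphans land in 'none'", {
  bundle <- tinyBundle()
  prof <- bundleResults(bundle, "profiling")$profiles
  pro <- bundleResults(bundle, "proteomes")
  sizes <- table(proteinTaxon(pro))
  agg <- tapply(prof$count, prof$taxon_id, sum)
  expect_identical(as.integer(agg[names(sizes)]),
                   as.integer(unname(sizes)))
  ## planted orphans are category "none" under default thresholds
  comm <- bundleResults(bundle, "community")
  tr <- communityTruth(comm)
  cats <- bundleResults(bundle, "profiling")$categories
  expect_true(all(cats[tr$protein_id[tr$is_orphan]] == "none"))
})

test_that("tightening thresholds only shrinks category domain sets", {
  bundle <- tinyBundle()
  pro <- bundleResults(bundle, "proteomes")
  comm <- bundleResults(bundle, "community")
  hits <- searchHits(pro, pro, searchThresholds(0.25, 1e-5))
  lax <- classifyProteins(proteinIds(pro), hits, pro,
                          searchThresholds(0.25, 1e-5))
  strict <- classifyProteins(proteinIds(pro), hits, pro,
                             searchThresholds(0.4, 1e-20))
  toSet <- function(cat) if (cat == "none") character() else
    strsplit(cat, "")[[1]]
  for (id in names(lax))
    expect_true(all(toSet(strict[[id]]) %in% toSet(lax[[id]])))
})

test_that("mean category counts average across proteomes", {
  prof <- data.frame(taxon_id = c("t1", "t2"), category = "E",
                     count = c(2L, 4L), stringsAsFactors = FALSE)
  expect_identical(meanCategoryCount(prof, "E"), 3)
  expect_identical(meanCategoryCount(prof[1, ], "E"), 2)
  expect_error(meanCategoryCount(prof, "Z"), "no profiles")
})

test_that("KS statistics match the pooled-ECDF brute force", {
  expect_identical(ksTwoSample(1:5, 1:5)$D, 0)
  expect_identical(ksTwoSample(1:4, 5:8)$D, 1)
  expect_identical(ksTwoSample(c(1, 3), c(2, 4))$D, 0.5)
  expect_error(ksTwoSample(numeric(), 1:3), "non-empty")
  set.seed(99)
  for (i in 1:100) {
    x <- sample(50:400, sample(3:40, 1), replace = TRUE)
    y <- sample(50:400, sample(3:40, 1), replace = TRUE)
    res <- ksTwoSample(x, y)
    expect_equal(res$D, oracleKsD(x, y))
    expect_equal(res$D, ksTwoSample(y, x)$D)
  }
})

test_that("BH adjustment equals the direct step-up formula", {
  expect_identical(bhFdr(0.04), 0.04)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bhFdr(c(1, 1)), c(1, 1))
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    q <- bhFdr(p)
    expect_equal(q, oracleBH(p))
    expect_true(all(q >= p & q <= 1))
    ## permutation equivariance
    perm <- sample(length(p))
    expect_equal(bhFdr(p[perm]), q[perm])
  }
})

test_that("length reports use interpolated quartiles and clamped whiskers", {
  reg <- miniRegistry()
  seqs <- c("E1|a" = strrep("A", 100), "E1|b" = strrep("A", 200),
            "E1|c" = strrep("A", 300))
  pro <- ProteomeSet(seqs, rep("E1", 3), reg)
  cats <- stats::setNames(c("EA", "B", "none"), names(seqs))
  rep1 <- lengthReport(pro, cats)
  with_hit <- rep1$stats[rep1$stats$status == "with_hit", ]
  expect_identical(with_hit$n, 2L)
  no_hit <- rep1$stats[rep1$stats$status == "no_hit", ]
  expect_identical(no_hit$median, 300)
  ## quartile convention on {100, 200, 300}
  cats2 <- stats::setNames(c("EA", "B", "AB"), names(seqs))
  rep2 <- lengthReport(pro, cats2)
  expect_identical(rep2$stats$q1, 150)
  expect_identical(rep2$stats$median, 200)
  expect_identical(rep2$stats$q3, 250)
  ## all proteins with hits: no-hit group omitted
  expect_identical(rep2$stats$status, "with_hit")
  ## whiskers clamped to the data range
  expect_identical(rep2$stats$whisker_low, 100)
  expect_identical(rep2$stats$whisker_high, 300)
})
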
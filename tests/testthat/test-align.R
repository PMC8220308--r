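test_that("global identity matches hand-checked alignments", {
  expect_identical(globalIdentity("MKVL", "MKVL"), 1)
  ## gapless optimum with 3/4 matches
  expect_identical(globalIdentity("AAAA", "AATA"), 0.75)
  ## MKVLA / MKV-A: 4 matches over 5 columns (score pinned by the DP
  ## oracle below)
  expect_identical(globalIdentity("MKVLA", "MKVA"), 0.8)
  expect_identical(globalIdentity("MKVLA", "MKVA"),
                   globalIdentity("MKVA", "MKVLA"))
  expect_error(globalIdentity("", "MKV"), "non-empty")
})

test_that("alignment scores equal the brute-force DP oracle", {
  set.seed(42)
  for (i in 1:50) {
    a <- oracleRandSeq(sample(5:40, 1))
    b <- oracleRandSeq(sample(5:40, 1))
    expect_equal(alignGlobal(a, b)$score, oracleGlobalScore(a, b))
    expect_equal(alignLocal(a, b)$score, oracleLocalScore(a, b))
  }
})

test_that("local bit scores follow the Karlin-Altschul transform", {
  ## WWWWW vs itself: raw 5 x 11 = 55 by the oracle
  raw <- oracleLocalScore("WWWWW", "WWWWW")
  expect_equal(localScore("WWWWW", "WWWWW"),
               (0.267 * raw - log(0.041)) / log(2))
  expect_gt(localScore("WWWWW", "WWWWW"), 0)
  ## disjoint residue usage: no positive-scoring local alignment
  res <- alignLocal("AAAA", "WWWW")
  expect_identical(res$score, 0)
  expect_lt(res$bits, 5)
  ## symmetry on random pairs
  set.seed(7)
  for (i in 1:20) {
    a <- oracleRandSeq(25); b <- oracleRandSeq(30)
    expect_equal(localScore(a, b), localScore(b, a))
  }
})

test_that("E-values obey the m*n*2^-S algebra", {
  m <- 350; n <- 1e6
  sPrime <- log2(m * n)
  expect_equal(eValue(sPrime, m, n), 1.0)
  expect_equal(eValue(40, m, 2 * n), 2 * eValue(40, m, n))
  expect_equal(eValue(50, m, n), eValue(40, m, n) / 1024)
  expect_error(eValue(40, 0, n), "positive")
})

test_that("threshold filtering is inclusive at both boundaries", {
  thr <- searchThresholds(minIdentity = 0.25, maxEvalue = 1e-10)
  hits <- hitRow(rep("q", 4), paste0("s", 1:4), "T", "T",
                 identity = c(0.25, 0.2499, 0.26, 0.25),
                 evalue = c(1e-10, 1e-12, 2e-10, 1e-12))
  kept <- filterHits(hits, thr)
  ## identity exactly 0.25 passes; E-value exactly 1e-10 passes
  expect_setequal(kept$subject_id, c("s1", "s4"))
})

test_that("searchHits finds close pairs and respects thresholds", {
  reg <- miniRegistry()
  base <- withr::with_seed(1, oracleRandSeq(120))
  rel <- withr::with_seed(2, mutateSequence(base, 0.85))
  far <- withr::with_seed(3, oracleRandSeq(120))
  pro <- ProteomeSet(c("E1|a" = base, "E2|b" = rel, "A1|c" = far),
                     c("E1", "E2", "A1"), reg)
  hits <- searchHits(pro, pro, searchThresholds(0.25, 1e-5))
  key <- paste(hits$query_id, hits$subject_id)
  expect_true(all(c("E1|a E2|b", "E2|b E1|a") %in% key))
  expect_false(any(grepl("A1\\|c", key)))        # unrelated: no hit
  expect_false(any(hits$query_id == hits$subject_id))  # no self-hits
  ## identity symmetric across orientations
  expect_equal(
    hits$global_identity[key == "E1|a E2|b"],
    hits$global_identity[key == "E2|b E1|a"])
})

test_that("best-hit selection breaks ties by E-value then subject id", {
  hits <- hitRow(rep("q", 3), c("T|b", "T|a", "T|c"), "X",
                 c("T", "T", "U"),
                 bits = c(50, 50, 40), evalue = c(1e-20, 1e-20, 1e-15))
  bh <- bestHits(hits, by = "subject_set")
  expect_identical(bh$subject_id, "T|a")  # lexicographic tie-break
  bh2 <- bestHits(hits, by = "subject_taxon")
  expect_setequal(bh2$subject_id, c("T|a", "T|c"))
  ## permuting input rows changes nothing
  bh3 <- bestHits(hits[c(3, 1, 2), ], by = "subject_set")
  expect_identical(bh3$subject_id, bh$subject_id)
})

test_that("reciprocal best hits require mutual best status", {
  bhAB <- hitRow(c("a", "x"), c("b", "b"), "T", "U")
  bhBA <- hitRow("b", "a", "U", "T")
  rbh <- reciprocalBestHits(bhAB, bhBA)
  expect_identical(nrow(rbh), 1L)
  expect_identical(rbh$a, "a"); expect_identical(rbh$b, "b")
  ## a's best is b but b's best is c: excluded
  rbh2 <- reciprocalBestHits(hitRow("a", "b", "T", "U"),
                             hitRow("b", "c", "U", "T"))
  expect_identical(nrow(rbh2), 0L)
  empty <- hitRow(character(), character(), character(), character())
  expect_identical(nrow(reciprocalBestHits(empty, empty)), 0L)
})

test_that("tightening thresholds never adds hit rows", {
  comm <- tinyCommunity()
  pro <- communityProteomes(comm)
  lax <- searchHits(pro, pro, searchThresholds(0.25, 1e-5))
  strict <- searchHits(pro, pro, searchThresholds(0.4, 1e-20))
  laxKey <- paste(lax$query_id, lax$subject_id)
  strictKey <- paste(strict$query_id, strict$subject_id)
  expect_true(all(strictKey %in% laxKey))
  expect_gt(length(laxKey), length(strictKey))
})
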
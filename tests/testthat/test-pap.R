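test_that("presence-absence cells are backed by member proteins", {
  reg <- miniRegistry()
  seqs <- stats::setNames(rep("MKVL", 4),
                          c("E1|p1", "E2|p2", "A1|p3", "B1|p4"))
  pro <- ProteomeSet(seqs, c("E1", "E2", "A1", "B1"), reg)
  mem <- data.frame(row_id = c("f1", "f1", "f2"),
                    protein_id = c("E1|p1", "A1|p3", "B1|p4"),
                    stringsAsFactors = FALSE)
  pap <- buildPap(mem, pro, columns = "taxon")
  m <- papMatrix(pap)
  expect_identical(dim(m), c(2L, 8L))
  expect_true(m["f1", "E1"] && m["f1", "A1"] && m["f2", "B1"])
  ## true-cell count equals the distinct (row, taxon) incidences
  scan <- unique(paste(mem$row_id,
                       proteinTaxon(pro)[mem$protein_id]))
  expect_identical(sum(m), length(scan))
  ## empty membership: zero rows
  expect_identical(nrow(papMatrix(buildPap(mem[0, ], pro))), 0L)
  ## unknown member protein errors
  expect_error(buildPap(data.frame(row_id = "f", protein_id = "Z|q"),
                        pro), "missing")
})

test_that("small archaeal groups pool into 'Other Archaea' in group mode", {
  reg <- miniRegistry()
  seqs <- stats::setNames(rep("MKVL", 3), c("A1|p1", "A2|p2", "G1|p3"))
  pro <- ProteomeSet(seqs, c("A1", "A2", "G1"), reg)
  mem <- data.frame(row_id = "f1", protein_id = names(seqs),
                    stringsAsFactors = FALSE)
  pap <- buildPap(mem, pro, columns = "group", minGroupMembers = 15L)
  expect_true("Other Archaea" %in% colnames(papMatrix(pap)))
  expect_false(any(c("Euryarchaeota", "asgard") %in%
                     colnames(papMatrix(pap))))
  ## with a lower cutoff the groups stay separate
  pap2 <- buildPap(mem, pro, columns = "group", minGroupMembers = 1L)
  expect_true(all(c("Euryarchaeota", "Crenarchaeota", "asgard") %in%
                    colnames(papMatrix(pap2))))
})

supergroupPap <- function(mat) {
  sg <- eukSupergroups()
  colnames(mat) <- sg
  new("PAPMatrix", mat = mat,
      colMeta = data.frame(column = sg, domain = "eukaryote", group = sg,
                           stringsAsFactors = FALSE))
}

test_that("rows sort by supergroup count, then pattern, then key", {
  mat <- rbind(r_mid = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
               r_all = rep(TRUE, 6),
               r_all2 = rep(TRUE, 6),
               r_head = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
               r_tail = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  ord <- sortRowsBySupergroupPattern(supergroupPap(mat))
  ## count-6 rows first (tie broken by key), then count 3, then count 2,
  ## where equal counts order by the binary pattern, high bits first
  expect_identical(ord, c("r_all", "r_all2", "r_mid", "r_head", "r_tail"))
  ## single row unchanged
  expect_identical(
    sortRowsBySupergroupPattern(supergroupPap(mat[2, , drop = FALSE])),
    "r_all")
})

test_that("hierarchical leaf order follows a hand-executed average-linkage trace", {
  m <- cbind(c1 = c(TRUE, TRUE, FALSE, FALSE),
             c2 = c(TRUE, TRUE, TRUE, FALSE),
             c3 = c(FALSE, FALSE, TRUE, TRUE),
             c4 = c(FALSE, FALSE, FALSE, TRUE))
  ## Jaccard distances: d12 = 1/3, d34 = 1/2, d13 = d14 = d24 = 1,
  ## d23 = 3/4; average linkage merges (c1,c2), then (c3,c4), then joins
  ## them; smallest-key-left puts c1's subtree first
  expect_identical(hierarchicalOrder(m, "columns", "jaccard"),
                   c("c1", "c2", "c3", "c4"))
  ## invariant under input column shuffling
  expect_identical(hierarchicalOrder(m[, c(3, 1, 4, 2)], "columns",
                                     "jaccard"),
                   c("c1", "c2", "c3", "c4"))
  ## identical columns end up adjacent
  m2 <- cbind(a = c(TRUE, FALSE, TRUE), z = c(TRUE, FALSE, TRUE),
              q = c(FALSE, TRUE, FALSE))
  ord <- hierarchicalOrder(m2, "columns", "jaccard")
  expect_identical(abs(diff(match(c("a", "z"), ord))), 1L)
  ## single column
  expect_identical(hierarchicalOrder(m[, 1, drop = FALSE], "columns"),
                   "c1")
  expect_error(hierarchicalOrder(m[, 0], "columns"), "length 0")
})

test_that("orderings are permutations of the key sets", {
  bundle <- tinyBundle()
  paps <- bundleResults(bundle, "paps")
  if (!is.null(paps$epc_pap)) {
    expect_setequal(paps$epc_row_order, rownames(papMatrix(paps$epc_pap)))
  }
  if (!is.null(paps$asgard_pap)) {
    expect_setequal(paps$asgard_col_order,
                    colnames(papMatrix(paps$asgard_pap)))
  }
})
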
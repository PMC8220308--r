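## Builds small graphs by hand; cluster identity is checked as member-set
## partitions (ids are content hashes).
partitionOf <- function(clustering) {
  unname(lapply(clusterMembers(clustering), sort))
}

test_that("similarity graphs are built from RBH pairs with identity weights", {
  rbh <- data.frame(a = "T|p1", b = "T|p2", stringsAsFactors = FALSE)
  hits <- hitRow("T|p1", "T|p2", "T", "T", identity = 0.8)
  g <- buildSimilarityGraph(rbh, hits)
  expect_identical(graphEdges(g)$weight, 80)
  ## duplicated pair collapses to one edge
  g2 <- buildSimilarityGraph(rbind(rbh, rbh), hits)
  expect_identical(graphEdges(g2), graphEdges(g))
  ## empty RBH set gives an empty graph
  g3 <- buildSimilarityGraph(rbh[0, ], hits)
  expect_identical(length(graphNodes(g3)), 0L)
  ## a pair missing from the hit table is an error
  expect_error(
    buildSimilarityGraph(data.frame(a = "T|p1", b = "T|p9"), hits),
    "missing")
})

test_that("disconnected cliques cluster as separate components", {
  cl6 <- expand.grid(a = paste0("x", 1:3), b = paste0("x", 1:3),
                     stringsAsFactors = FALSE)
  cl6 <- cl6[cl6$a < cl6$b, ]
  cl6b <- data.frame(a = sub("x", "y", cl6$a), b = sub("x", "y", cl6$b))
  edges <- rbind(cbind(cl6, weight = 50), cbind(cl6b, weight = 60))
  g <- buildSimilarityGraph(edges[, 1:2],
                            hitRow(edges$a, edges$b, "T", "T",
                                   identity = edges$weight / 100))
  part <- partitionOf(mclCluster(g))
  expect_setequal(part, list(paste0("x", 1:3), paste0("y", 1:3)))
})

test_that("an isolated node becomes a singleton cluster", {
  g <- buildSimilarityGraph(data.frame(a = character(), b = character()),
                            hitRow(character(), character(),
                                   character(), character()))
  part <- partitionOf(mclCluster(g, nodes = "solo"))
  expect_identical(part, list("solo"))
})

test_that("an equal-weight star collapses into one cluster, as the dense oracle predicts", {
  edges <- data.frame(a = c("hub", "hub", "hub"),
                      b = c("leaf1", "leaf2", "leaf3"),
                      weight = 50, stringsAsFactors = FALSE)
  g <- buildSimilarityGraph(edges[, 1:2],
                            hitRow(edges$a, edges$b, "T", "T",
                                   identity = 0.5))
  part <- partitionOf(mclCluster(g))
  oracle <- oracleMcl(c("hub", "leaf1", "leaf2", "leaf3"), edges)
  expect_setequal(part, oracle)
  expect_identical(part, list(sort(c("hub", "leaf1", "leaf2", "leaf3"))))
})

test_that("MCL output is a disjoint cover with deterministic ids", {
  comm <- tinyCommunity()
  pro <- subsetProteomes(communityProteomes(comm), domains = "eukaryote")
  res <- clusterProteomes(pro)
  m <- clusterMembership(res$clustering)
  covered <- c(m$protein_id, unclusteredProteins(res$clustering))
  expect_setequal(covered, proteinIds(pro))
  expect_identical(anyDuplicated(covered), 0L)
  expect_true(all(table(m$cluster_id) >= 1L))
  ## permuting the input proteins leaves the partition unchanged
  perm <- withr::with_seed(1, sample(length(proteinIds(pro))))
  pro2 <- ProteomeSet(proteinSequences(pro)[perm], pro@taxon[perm],
                      pro@registry)
  res2 <- clusterProteomes(pro2)
  expect_identical(partitionOf(res$clustering),
                   partitionOf(res2$clustering))
  expect_identical(sort(clusterIds(res$clustering)),
                   sort(clusterIds(res2$clustering)))
})

test_that("nodes in different components are never co-clustered", {
  set.seed(3)
  comp1 <- paste0("a", 1:5); comp2 <- paste0("b", 1:4)
  mk <- function(nodes) {
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.7
    data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
               weight = runif(sum(keep), 30, 90),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(cbind(mk(comp1)), cbind(mk(comp2)))
  g <- buildSimilarityGraph(edges[, 1:2],
                            hitRow(edges$a, edges$b, "T", "T",
                                   identity = edges$weight / 100))
  part <- partitionOf(mclCluster(g, nodes = c(comp1, comp2)))
  for (p in part)
    expect_true(all(p %in% comp1) || all(p %in% comp2))
})

test_that("within-group clustering recovers planted families of a taxon subset", {
  comm <- tinyCommunity()
  pro <- communityProteomes(comm)
  grp <- taxonField(pro@registry, "group")
  asg <- subsetProteomes(pro, taxa = names(grp)[grp == "asgard"])
  expect_error(clusterProteomes(subsetProteomes(pro, taxa = "E01")),
               "two taxa")
  res <- clusterProteomes(asg, idPrefix = "asg")
  ## every recovered cluster is a subset of one planted family
  tr <- communityTruth(comm)
  famOf <- setNames(tr$family_id, tr$protein_id)
  for (mem in clusterMembers(res$clustering))
    expect_identical(length(unique(famOf[mem])), 1L)
  ## presence counts cover exactly the clustered proteins
  expect_identical(sum(res$presence$n_proteins),
                   nrow(clusterMembership(res$clustering)))
})
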
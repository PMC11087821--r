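makeSets <- function(...) {
  sets <- list(...)
  drugGeneSets(sets)
}

test_that("hypergeometric enrichment matches closed forms and brute force", {
  # N = 10, K = 3, n = 3, k = 3 -> 1 / C(10, 3)
  sets <- list()
  for (i in 1:3) sets[[paste0("d", i)]] <- "gA"
  for (i in 4:10) sets[[paste0("d", i)]] <- paste0("g", i)
  targets <- list(t1 = c("d1", "d2", "d3"))
  tab <- targetGeneEnrichment(targets, sets, nDrugsTotal = 10)
  row <- tab[tab$gene == "gA", ]
  expect_equal(row$p, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(row$k, 3); expect_equal(row$K, 3); expect_equal(row$n, 3)

  # k = 0 would give p = 1, but untested genes are skipped by construction;
  # verify via phyper directly that the implementation's tail is P(X >= k)
  expect_equal(phyper(-1, 3, 7, 3, lower.tail = FALSE), 1)

  # exhaustive enumeration oracle for all N <= 12 configurations
  set.seed(1)
  for (rep in 1:30) {
    N <- sample(4:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    for (k in max(0, n + K - N):min(n, K)) {
      expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   enumHyperTail(k, K, N, n), tolerance = 1e-10)
    }
  }
})

test_that("enrichment drops small targets and BH-adjusts within target", {
  sets <- list(d1 = c("g1", "g2"), d2 = c("g1"), d3 = c("g1", "g3"),
               d4 = c("g2"), d5 = c("g3"))
  targets <- list(small = c("d1", "d2"),           # < 3 drugs: dropped
                  big = c("d1", "d2", "d3", "d4"))
  tab <- targetGeneEnrichment(targets, sets, nDrugsTotal = 5)
  expect_false("small" %in% tab$target)
  big <- tab[tab$target == "big", ]
  # reference step-up BH within the target
  o <- order(big$p)
  m <- nrow(big)
  ref <- pmin(1, rev(cummin(rev(big$p[o] * m / seq_len(m)))))[order(o)]
  expect_equal(big$q, ref, tolerance = 1e-12)
  expect_true(all(big$q >= big$p - 1e-15))
})

test_that("permuted-target calibration preserves sizes and detects planted signal", {
  set.seed(2)
  # 12 drugs; planted target t1's drugs all share gene gS
  sets <- list()
  for (i in 1:12) {
    sets[[sprintf("d%02d", i)]] <-
      unique(c(sample(paste0("g", 1:30), 4),
               if (i <= 4) "gS"))
  }
  targets <- list(t1 = sprintf("d%02d", 1:4), t2 = sprintf("d%02d", 5:8))
  cal <- permutedTargetCalibration(targets, sets, nDrugsTotal = 12,
                                   nPerm = 200, seed = 3)
  expect_equal(rownames(cal$nullMinP), c("t1", "t2"))
  expect_equal(ncol(cal$nullMinP), 200)
  # planted target beats most of its permuted versions
  expect_lt(cal$trueMinP[["t1"]], quantile(cal$nullMinP["t1", ], 0.05))
  # an unplanted target does not
  expect_gt(mean(cal$nullMinP["t2", ] <= cal$trueMinP[["t2"]]), 0.05)
})

test_that("permuted assignments preserve each target's drug count", {
  sets <- lapply(setNames(paste0("g", 1:8), paste0("d", 1:8)), c)
  targets <- list(a = paste0("d", 1:3), b = paste0("d", 4:8))
  cal <- permutedTargetCalibration(targets, sets, nDrugsTotal = 8,
                                   nPerm = 5, seed = 1)
  # sizes are preserved implicitly: min-p rows exist for every permutation
  expect_true(all(dim(cal$nullMinP) == c(2, 5)))
})

test_that("pair overlap test agrees with the hypergeometric tail under uniform weights", {
  gw <- setNames(rep(1, 8), paste0("g", 1:8))
  a <- paste0("g", 1:3); b <- paste0("g", 1:4)
  res <- pairOverlapTest(a, b, gw, nSim = 10000, seed = 5)
  expect_equal(res$overlap, 3L)
  exact <- choose(4, 3) * choose(4, 0) / choose(8, 3)  # 4/56
  mcse <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(res$p - exact), 3 * mcse + 1e-4)
  # degenerate cases
  expect_equal(pairOverlapTest(paste0("g", 1:8), b, gw, nSim = 100, seed = 1)$p, 1)
  expect_equal(pairOverlapTest(c("g5", "g6"), c("g7", "g8"), gw,
                               nSim = 100, seed = 1)$p, 1)
  expect_error(pairOverlapTest(c("gX"), b, gw), "subsets")
})

test_that("weighted sampling shifts overlap toward heavy genes", {
  # B holds the heavy genes: random draws overlap B more when B is heavy,
  # making a fixed observed overlap less surprising
  gw1 <- setNames(c(10, 10, 1, 1, 1, 1), paste0("g", 1:6))
  gw2 <- setNames(rep(1, 6), paste0("g", 1:6))
  a <- c("g1", "g2"); b <- c("g1", "g2")
  p1 <- pairOverlapTest(a, b, gw1, nSim = 4000, seed = 7)$p
  p2 <- pairOverlapTest(a, b, gw2, nSim = 4000, seed = 7)$p
  expect_gt(p1, p2)
})

test_that("the overlap network connects exactly the significant pairs", {
  # all drugs share an identical large set over a big weighted universe
  shared <- paste0("s", 1:10)
  universe <- c(shared, paste0("u", 1:90))
  sets <- list(d1 = shared, d2 = shared, d3 = shared)
  # pad the universe with singleton drugs so weights cover unrelated genes
  for (i in seq(4, 30)) sets[[paste0("d", i)]] <- sample(universe, 3)
  set.seed(8)
  net <- buildNetwork(sets, pThreshold = 0.05, nSim = 400, seed = 9)
  e <- net@edges
  core <- e[e$drug_a %in% c("d1", "d2", "d3") & e$drug_b %in% c("d1", "d2", "d3"), ]
  expect_equal(nrow(core), 3)  # complete triangle among the planted drugs
  expect_true(all(core$overlap == 10))
  # pairwise-disjoint sets yield an empty edge set
  disjoint <- list(a = c("g1", "g2"), b = c("g3", "g4"), c = c("g5", "g6"))
  netD <- buildNetwork(disjoint, nSim = 50, seed = 1)
  expect_equal(nrow(netD@edges), 0)
  # edge annotations reproduce a direct call with the derived per-pair seed
  pair <- e[1, ]
  dgs <- drugGeneSets(sets)
  sa <- dgs$sets[[pair$drug_a]]; sb <- dgs$sets[[pair$drug_b]]
  if (length(sa) > length(sb)) { tmp <- sa; sa <- sb; sb <- tmp }
  redo <- pairOverlapTest(sa, sb, dgs$geneWeight, nSim = 400,
                          seed = draphnet:::.stringSeed(
                            9, paste(pair$drug_a, pair$drug_b, sep = "|")))
  expect_equal(pair$p, redo$p)
  expect_equal(pair$overlap, redo$overlap)
})

test_that("network construction is invariant to drug input order", {
  set.seed(10)
  sets <- lapply(setNames(seq_len(8), paste0("d", 1:8)), function(i)
    sample(paste0("g", 1:15), 5))
  n1 <- buildNetwork(sets, nSim = 200, seed = 3)
  n2 <- buildNetwork(rev(sets), nSim = 200, seed = 3)
  expect_equal(n1@edges, n2@edges)
})

test_that("maximal cliques match exhaustive subset enumeration", {
  # hand cases: a triangle; a path of 4
  tri <- list(a = c("x", "y"), b = c("x", "y"), c = c("x", "y"))
  adj <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  net <- new("DrugNetwork", graph = g,
             edges = data.frame(drug_a = "a", drug_b = "b", overlap = 1, p = 0),
             pThreshold = 0.05)
  expect_equal(findCliques(net), list(c("a", "b", "c")))
  pathAdj <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  pathAdj[cbind(1:3, 2:4)] <- 1; pathAdj <- pathAdj + t(pathAdj)
  gPath <- igraph::graph_from_adjacency_matrix(pathAdj, mode = "undirected")
  netPath <- new("DrugNetwork", graph = gPath, edges = net@edges,
                 pThreshold = 0.05)
  expect_equal(findCliques(netPath), list())

  # 100 random graphs on 12 nodes against the brute-force oracle
  set.seed(11)
  for (rep in 1:100) {
    nv <- 12
    adj <- matrix(0, nv, nv, dimnames = list(sprintf("n%02d", 1:nv),
                                             sprintf("n%02d", 1:nv)))
    up <- which(upper.tri(adj))
    adj[sample(up, round(0.35 * length(up)))] <- 1
    adj <- adj + t(adj)
    gR <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    netR <- new("DrugNetwork", graph = gR, edges = net@edges,
                pThreshold = 0.05)
    expect_identical(findCliques(netR, minSize = 3),
                     bruteMaximalCliques(adj, minSize = 3))
  }
})

test_that("the visualisation filter applies both gene criteria strictly", {
  enr <- data.frame(target = "t", gene = c("g1", "g2", "g3"),
                    q = c(0.001, 0.5, 0.005))
  sets <- c(
    lapply(setNames(seq_len(14), paste0("a", 1:14)), function(i) "g1"),
    lapply(setNames(seq_len(15), paste0("b", 1:15)), function(i) "g3"),
    list(z = "g2"))
  # g1: significant, 14 drugs -> kept; g3: significant, 15 drugs -> dropped
  # g2: 1 drug but not significant -> dropped
  expect_equal(vizGeneFilter(sets, enr), "g1")
})

test_that("network export writes edge list, GraphML and cliques", {
  sets <- list(d1 = c("g1", "g2"), d2 = c("g1", "g2"), d3 = c("g1", "g2"),
               d4 = c("g9"))
  net <- buildNetwork(sets, pThreshold = 1, nSim = 50, seed = 2)
  dir <- withr::local_tempdir()
  exportNetwork(net, dir)
  expect_true(file.exists(file.path(dir, "edges.tsv")))
  expect_true(file.exists(file.path(dir, "network.graphml")))
  cl <- readLines(file.path(dir, "cliques.tsv"))
  expect_equal(cl, "d1\td2\td3")
})
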
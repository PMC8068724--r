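test_that("phi matches direct counts on hand-built graphs", {
  # complete K5: all nodes qualify at k = 2, all edges present
  expect_equal(phiCoefficient(adj2bg(completeGraph(5)), 2), 1)

  # 5-node graph where the two degree-3 nodes share no edge: phi = 0
  A <- matrix(0, 5, 5)
  for (p in list(c(1, 3), c(1, 4), c(1, 5), c(2, 3), c(2, 4), c(2, 5)))
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  expect_equal(phiCoefficient(adj2bg(A), 2), 0)

  # star: only the center qualifies at k = 1 -> undefined
  expect_true(is.na(phiCoefficient(adj2bg(starGraph(3)), 1)))
})

test_that("phi agrees with the brute-force oracle and is monotone-undefined", {
  set.seed(21)
  for (r in 1:30) {
    A <- rAdj(sample(5:9, 1), runif(1, 0.3, 0.8))
    g <- adj2bg(A)
    ks <- 0:(max(rowSums(A)))
    mine <- sapply(ks, function(k) phiCoefficient(g, k))
    orac <- sapply(ks, function(k) o_phi(A, k))
    expect_equal(mine, orac, tolerance = 1e-12)
    # once undefined, stays undefined
    und <- is.na(mine)
    if (any(und)) expect_true(all(und[seq(min(which(und)), length(und))]))
  }
})

test_that("degree-preserving rewiring keeps degrees and edges exactly", {
  set.seed(31)
  A <- rAdj(30, 0.3)
  g <- adj2bg(A)
  for (s in 1:10) {
    gr <- degreePreservingRewire(g, seed = s)
    expect_equal(rowSums(adjacencyMatrix(gr)), rowSums(A))
    expect_equal(edgeCount(gr), sum(A) / 2)
    expect_equal(diag(adjacencyMatrix(gr)), rep(0, 30))
  }
  # triangle admits no valid swap: returned unchanged
  K3 <- adj2bg(completeGraph(3))
  expect_identical(adjacencyMatrix(degreePreservingRewire(K3, seed = 1)),
                   adjacencyMatrix(K3))
  # rewiring is reproducible per seed
  r1 <- degreePreservingRewire(g, seed = 5)
  r2 <- degreePreservingRewire(g, seed = 5)
  expect_identical(adjacencyMatrix(r1), adjacencyMatrix(r2))
})

test_that("rich-club profile normalizes against nulls and finds planted cores", {
  # planted core: dense hub block on a sparse background
  set.seed(41)
  spec <- syntheticSpec(nNodes = 60, nPerGroup = c(A = 1),
                        hubFraction = 10 / 60, hubCoreBoost = 3,
                        seed = 17)
  base <- generateBaseNetwork(spec)
  g <- sparsityBinarize(base$template, 0.2)
  prof <- richClubProfile(g, nRandom = 80, seed = 4)
  expect_s4_class(prof, "RichClubProfile")
  hubDeg <- rowSums(adjacencyMatrix(g))[nodeIds(g) %in% base$hubs]
  planted <- (min(hubDeg) - 1):(max(hubDeg) - 1)
  expect_gt(length(intersect(prof@sigRange, planted)), 0)
  # phi_norm above 1 inside the significant regime by construction
  expect_true(all(prof@phiNorm[prof@kLevels %in% prof@sigRange] > 1))

  # one null network only: p cannot drop below 1/2
  prof1 <- richClubProfile(g, nRandom = 1, seed = 9)
  expect_true(all(prof1@pPerm[!is.na(prof1@pPerm)] >= 0.5))
})

test_that("profile is reproducible for a fixed seed", {
  set.seed(43)
  g <- adj2bg(rAdj(40, 0.3))
  p1 <- richClubProfile(g, nRandom = 30, seed = 7)
  p2 <- richClubProfile(g, nRandom = 30, seed = 7)
  expect_identical(phiTable(p1), phiTable(p2))
})

test_that("group-average network applies the occurrence rule inclusively", {
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1
  B <- matrix(0, 4, 4)
  gs <- c(replicate(4, adj2bg(A), simplify = FALSE),
          list(adj2bg(B)))
  # edge in 4 of 5 subjects at occurrence 0.8: retained (boundary)
  avg <- groupAverageNetwork(gs, 0.8)
  expect_equal(adjacencyMatrix(avg)[1, 2], 1)
  # edge in 3 of 5: dropped
  gs2 <- c(replicate(3, adj2bg(A), simplify = FALSE),
           replicate(2, adj2bg(B), simplify = FALSE))
  expect_equal(adjacencyMatrix(groupAverageNetwork(gs2, 0.8))[1, 2], 0)
  # occurrence 1 is the intersection
  expect_equal(sum(adjacencyMatrix(groupAverageNetwork(gs, 1))), 0)
  expect_error(groupAverageNetwork(list()), "empty")
})

test_that("hub identification applies strict degree thresholds", {
  # degrees 5,4,3,2,2,2,1,1 via a hand-built graph
  A <- matrix(0, 8, 8)
  for (p in list(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(1, 6), c(2, 3),
                 c(2, 7), c(2, 8), c(3, 4), c(5, 6)))
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  g <- adj2bg(A)
  deg <- rowSums(A)
  hubs <- identifyHubs(g, kStar = 2)
  expect_setequal(hubs, nodeIds(g)[deg > 2])
  expect_warning(h0 <- identifyHubs(g, kStar = max(deg)), "empty")
  expect_length(h0, 0)
  # mean + SD rule
  hm <- identifyHubs(g, rule = "meanSD", sdFactor = 1)
  expect_setequal(hm, nodeIds(g)[deg > mean(deg) + sd(deg)])
})

test_that("planted hubs are recovered from the synthetic generator", {
  spec <- syntheticSpec(nNodes = 90, nPerGroup = c(A = 1),
                        hubCoreBoost = 3, seed = 23)
  base <- generateBaseNetwork(spec)
  g <- sparsityBinarize(base$template, 0.2)
  prof <- richClubProfile(g, nRandom = 100, seed = 6)
  hubs <- identifyHubs(g, prof, kStar = "auto")
  shared <- length(intersect(hubs, base$hubs))
  jacc <- shared / length(union(hubs, base$hubs))
  expect_gte(jacc, 0.6)
  expect_gte(shared / length(base$hubs), 0.8)
})

test_that("edge classification partitions edges by hub membership", {
  # hubs {a, b}; edges a-b, a-c, c-d
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1; A[1, 3] <- A[3, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  g <- adj2bg(A, ids = c("a", "b", "c", "d"))
  dec <- classifyEdges(g, c("a", "b"))
  expect_equal(unname(dec@classCounts), c(1, 1, 1))

  # degenerate hub sets
  expect_equal(unname(classifyEdges(g, character(0))@classCounts),
               c(0, 0, 3))
  allHub <- classifyEdges(g, c("a", "b", "c", "d"))
  expect_equal(unname(allHub@classCounts), c(3, 0, 0))
  expect_equal(unname(allHub@classProportions), c(1, 0, 0))

  expect_error(classifyEdges(g, "zz"), "subset")
})

test_that("edge classes always partition the edge set with unit proportions", {
  set.seed(61)
  for (r in 1:100) {
    n <- sample(8:20, 1)
    M <- rWeighted(n, runif(1, 0.2, 0.8))
    ids <- nodeIds(M)
    hubs <- sample(ids, sample(0:n, 1))
    dec <- classifyEdges(M, hubs)
    expect_equal(sum(dec@classCounts), edgeCount(M))
    if (edgeCount(M) > 0)
      expect_lt(abs(sum(dec@classProportions) - 1), 1e-12)
    expect_equal(sum(dec@classStrengths), sum(weightMatrix(M)) / 2,
                 tolerance = 1e-9)
  }
})

test_that("integrated class strengths accumulate weights over the sweep", {
  set.seed(71)
  M <- rWeighted(20, 0.8)
  sw <- suppressWarnings(sparsitySweep(M, 0.1, 0.3, 0.1))
  hubs <- nodeIds(M)[1:4]
  tab <- classStrengthSweep(M, sw, hubs)
  expect_equal(nrow(tab), 3 * 3)
  # strengths at each sparsity sum to the surviving total weight
  for (i in seq_along(sw@sparsities)) {
    s <- sw@sparsities[i]
    Wk <- weightMatrix(M) * adjacencyMatrix(sw@graphs[[i]])
    expect_equal(sum(tab$strength[tab$sparsity == s]), sum(Wk) / 2,
                 tolerance = 1e-9)
  }
  ints <- integratedClassStrengths(M, sw, hubs)
  expect_named(ints, c("rich", "feeder", "local"))
  expect_equal(unname(ints["rich"]),
               integrateCurve(tab$strength[tab$class == "rich"], 0.1))
})
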
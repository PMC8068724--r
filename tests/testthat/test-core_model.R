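test_that("connectome reading validates, symmetrizes and errors on bad input", {
  d <- withr::local_tempdir()
  f <- file.path(d, "m.tsv")

  write.table(matrix(c(0, 5, 0, 5, 0, 2, 0, 2, 0), 3, 3), f,
              sep = "\t", row.names = FALSE, col.names = FALSE)
  M <- readConnectome(f)
  expect_s4_class(M, "ConnectomeMatrix")
  expect_equal(edgeCount(M), 2)

  # near-symmetric input is averaged within tolerance
  W <- matrix(0, 3, 3); W[1, 2] <- 5; W[2, 1] <- 4.9999999
  W[2, 3] <- W[3, 2] <- 1
  write.table(W, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  M <- readConnectome(f)
  expect_equal(weightMatrix(M)[1, 2], (5 + 4.9999999) / 2)
  expect_equal(weightMatrix(M)[1, 2], weightMatrix(M)[2, 1])

  # strong asymmetry refused (directed input guard)
  W[2, 1] <- 4
  write.table(W, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(readConnectome(f), "asymmetry")

  # dimension mismatch against the node table
  nt <- data.frame(node_id = c("a", "b"), label = c("A", "B"),
                   hemisphere = c("left", "right"),
                   homologue_id = c("b", "a"))
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  write.table(W, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(readConnectome(f, nodeTable = nt), "dimension mismatch")

  # negative and NaN entries refused
  W2 <- matrix(0, 3, 3); W2[1, 2] <- W2[2, 1] <- -1
  write.table(W2, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(readConnectome(f), "negative")

  # comma-delimited files are accepted too
  W3 <- matrix(c(0, 2, 0, 2, 0, 3, 0, 3, 0), 3, 3)
  write.table(W3, f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(weightMatrix(readConnectome(f))[2, 3], 3)
})

test_that("ConnectomeMatrix validity enforces its invariants", {
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  expect_s4_class(ConnectomeMatrix(W), "ConnectomeMatrix")
  bad <- W; bad[1, 2] <- 2            # asymmetric
  expect_error(ConnectomeMatrix(bad), "symmetric")
  bad <- W; diag(bad) <- 1
  expect_error(ConnectomeMatrix(bad), "diagonal")
  expect_error(ConnectomeMatrix(matrix(0, 2, 2)), "3 nodes")
  expect_error(ConnectomeMatrix(W, nodeIds = c("a", "a", "b")), "unique")
})

test_that("streamline filter removes weak edges with strict inequality", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 4
  W[2, 3] <- W[3, 2] <- 3
  W[3, 4] <- W[4, 3] <- 2
  M <- ConnectomeMatrix(W)
  F3 <- streamlineFilter(M, 3)
  expect_equal(edgeCount(F3), 1)         # only the weight-4 edge survives
  expect_equal(max(weightMatrix(F3)), 4)

  zero <- ConnectomeMatrix(matrix(0, 4, 4))
  expect_equal(weightMatrix(streamlineFilter(zero, 3)),
               matrix(0, 4, 4))
  expect_equal(weightMatrix(streamlineFilter(M, 0)), W)
})

test_that("sparsity binarization keeps the strongest edges with a deterministic tie rule", {
  set.seed(42)
  n <- 6
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  W[ut] <- c(10, 9, 8, rep(1, nrow(ut) - 3))
  W <- W + t(W)
  g <- sparsityBinarize(ConnectomeMatrix(W), 0.2)  # 15 pairs -> 3 edges
  expect_equal(edgeCount(g), 3)
  expect_true(all(adjacencyMatrix(g)[W == 10 | W == 9 | W == 8] == 1))

  # tie at the cut rank: lexicographically smallest pair wins, repeatably
  W2 <- matrix(0, n, n)
  W2[1, 2] <- W2[2, 1] <- 5
  W2[2, 3] <- W2[3, 2] <- 3
  W2[1, 4] <- W2[4, 1] <- 3
  g1 <- sparsityBinarize(ConnectomeMatrix(W2), 2 / 15)
  g2 <- sparsityBinarize(ConnectomeMatrix(W2), 2 / 15)
  expect_identical(adjacencyMatrix(g1), adjacencyMatrix(g2))
  expect_equal(adjacencyMatrix(g1)[1, 4], 1)  # (1,4) beats (2,3)
  expect_equal(adjacencyMatrix(g1)[2, 3], 0)

  # saturation: sparsity 1 on a complete weighted graph
  Wc <- completeGraph(5) * 2
  expect_equal(edgeCount(sparsityBinarize(ConnectomeMatrix(Wc), 1)), 10)

  # too few nonzero weights: warn and keep all, record achieved sparsity
  expect_warning(gs <- sparsityBinarize(ConnectomeMatrix(W2), 0.9),
                 "achieved")
  expect_equal(edgeCount(gs), 3)
  expect_equal(sparsity(gs), 3 / 15)
})

test_that("binarization is idempotent on binary graphs", {
  set.seed(7)
  for (r in 1:20) {
    M <- rWeighted(12, 0.5)
    s <- runif(1, 0.1, 0.4)
    g1 <- sparsityBinarize(M, s)
    g2 <- sparsityBinarize(g1, sparsity(g1))
    expect_identical(adjacencyMatrix(g1), adjacencyMatrix(g2))
  }
})

test_that("threshold sweep has 16 default levels with nested edge sets", {
  set.seed(11)
  M <- rWeighted(30, 0.6)
  sw <- suppressWarnings(sparsitySweep(M))
  expect_length(sw@sparsities, 16)
  expect_equal(sw@sparsities, seq(0.05, 0.20, by = 0.01))

  # nesting across the sweep for 100 random matrices
  ok <- TRUE
  for (r in 1:100) {
    M <- rWeighted(15, 0.7)
    sw <- suppressWarnings(sparsitySweep(M, 0.1, 0.3, 0.1))
    for (i in seq_len(length(sw@graphs) - 1)) {
      A1 <- adjacencyMatrix(sw@graphs[[i]])
      A2 <- adjacencyMatrix(sw@graphs[[i + 1]])
      ok <- ok && all(A2[A1 == 1] == 1)
    }
  }
  expect_true(ok)

  # degenerate single-level sweep
  sw1 <- suppressWarnings(sparsitySweep(M, 0.1, 0.1, 0.01))
  expect_length(sw1@graphs, 1)
  expect_error(suppressWarnings(sparsitySweep(M, 0.2, 0.1)), "sMin")
  expect_error(suppressWarnings(sparsitySweep(M, 0.05, 0.2, 0.07)),
               "divide")
})

test_that("filtering commutes with thresholding applied in one pass", {
  set.seed(13)
  for (r in 1:10) {
    W <- matrix(0, 15, 15)
    ut <- upper.tri(W)
    W[ut] <- rpois(sum(ut), 4)
    W <- W + t(W); diag(W) <- 0
    M <- ConnectomeMatrix(W)
    a <- sparsityBinarize(streamlineFilter(M, 3), 0.1)
    Wf <- W; Wf[Wf <= 3] <- 0
    b <- sparsityBinarize(ConnectomeMatrix(Wf), 0.1)
    expect_identical(adjacencyMatrix(a), adjacencyMatrix(b))
  }
})

test_that("curve integration matches trapezoid closed forms", {
  # constant c over [0.05, 0.20]
  expect_equal(integrateCurve(rep(3, 16), 0.01), 0.15 * 3)
  # two points
  expect_equal(integrateCurve(c(0, 1), 0.01), 0.005)
  # linear ramp over 16 points: half the constant-1 area
  expect_equal(integrateCurve(seq(0, 1, length.out = 16), 0.01), 0.075)
  # summation variant
  expect_equal(integrateCurve(c(1, 2), 0.5, method = "sum"), 1.5)
  expect_equal(integrateCurve(5, 0.01), 0)
})

test_that("node tables validate hemisphere labels and homologue symmetry", {
  nt <- readNodeTable(aalNodeTablePath())
  expect_equal(nrow(nt), 90)
  expect_setequal(unique(nt$hemisphere), c("left", "right"))
  d <- withr::local_tempdir()
  f <- file.path(d, "nodes.tsv")
  bad <- nt
  bad$homologue_id[1] <- bad$node_id[5]   # breaks symmetry
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readNodeTable(f), "symmetric")
})
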
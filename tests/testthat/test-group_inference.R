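test_that("residualization matches least squares", {
  age <- c(20, 30, 40, 50)
  expect_equal(residualize(2 * age, data.frame(age = age)), rep(0, 4))

  # orthogonal covariate: residuals are the centered values
  v <- c(1, -1, 2, -2)
  cov <- data.frame(x = c(1, 1, -1, -1))
  expect_equal(residualize(v, cov), v - mean(v))

  # 4-point example against lm()
  set.seed(5)
  y <- rnorm(10); x <- rnorm(10); z <- rnorm(10)
  expect_equal(residualize(y, data.frame(x = x, z = z)),
               unname(resid(lm(y ~ x + z))), tolerance = 1e-12)

  expect_error(residualize(y, data.frame(a = x, b = 2 * x)),
               "rank-deficient")
})

test_that("permutation test handles degenerate and strong effects", {
  v <- rep(c(1, 2, 3), 2)
  g <- rep(c("a", "b"), each = 3)
  r <- suppressWarnings(permTest(v, g, nPerm = 200, seed = 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_perm, 1)

  set.seed(2)
  x <- c(rnorm(30), rnorm(30) + 5)
  g <- rep(c("a", "b"), each = 30)
  r <- permTest(x, g, nPerm = 2000, seed = 3)
  expect_lte(r$p_perm, 0.001)
  expect_equal(r$design, "two-group")

  expect_error(permTest(x, rep("a", 60)), "two groups")
  expect_warning(permTest(x, g, nPerm = 50, seed = 1), "coarse")
})

test_that("three-group design uses the F statistic and detects shifts", {
  set.seed(4)
  x <- c(rnorm(20), rnorm(20) + 3, rnorm(20) - 3)
  g <- rep(c("a", "b", "c"), each = 20)
  r <- permTest(x, g, nPerm = 1000, seed = 5)
  expect_equal(r$design, "k-group")
  expect_lte(r$p_perm, 0.005)
  # F statistic agrees with aov
  f <- summary(aov(x ~ g))[[1]]$`F value`[1]
  expect_equal(r$statistic, f, tolerance = 1e-10)
})

test_that("permutation p-values are invariant to affine rescaling", {
  set.seed(6)
  x <- rnorm(40)
  g <- rep(c("a", "b"), 20)
  p1 <- permTest(x, g, nPerm = 500, seed = 11)$p_perm
  p2 <- permTest(5 * x - 3, g, nPerm = 500, seed = 11)$p_perm
  expect_identical(p1, p2)
})

test_that("covariate adjustment removes injected confounds", {
  set.seed(7)
  n <- 60
  g <- rep(c("a", "b"), each = n / 2)
  age <- rnorm(n, 40, 10) + 15 * (g == "b")
  y <- 0.5 * age + rnorm(n)        # group effect only through age
  pAdj <- permTest(y, g, nPerm = 1000, covariates = data.frame(age = age),
                   seed = 8)$p_perm
  pRaw <- permTest(y, g, nPerm = 1000, seed = 8)$p_perm
  expect_lt(pRaw, 0.05)
  expect_gt(pAdj, 0.05)
})

test_that("Bonferroni node control uses strict alpha/N", {
  p <- rep(1, 90)
  expect_length(bonferroniNodes(p), 0)
  p[5] <- 1e-5
  expect_equal(bonferroniNodes(p), 5)
  # boundary: p exactly alpha/N is not significant
  p[5] <- 0.05 / 90
  expect_length(bonferroniNodes(p), 0)
  expect_error(bonferroniNodes(numeric(0)), "empty")
  named <- setNames(c(1e-6, 0.2), c("INS.L", "FFG.L"))
  expect_equal(bonferroniNodes(named), "INS.L")
})

test_that("partial correlation matches its closed form", {
  set.seed(9)
  x <- rnorm(30); z <- rnorm(30)
  r <- partialCorrelation(x, x, data.frame(z = z))
  expect_equal(r$r, 1, tolerance = 1e-12)

  # recursive formula oracle: r_xy.z
  y <- 0.5 * x + 0.3 * z + rnorm(30)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  mine <- partialCorrelation(x, y, data.frame(z = z))
  expect_equal(mine$r, oracle, tolerance = 1e-10)
  expect_equal(mine$df, 30 - 1 - 2)

  # y driven by the covariate, x independent: association vanishes
  # after control (averaged over repeated draws)
  rs <- replicate(50, {
    z2 <- rnorm(100)
    partialCorrelation(rnorm(100), z2 + rnorm(100, sd = 0.1),
                       data.frame(z = z2))$r
  })
  expect_lt(abs(mean(rs)), 0.05)

  expect_error(partialCorrelation(1:3, 1:3, data.frame(a = 1:3)),
               "degrees of freedom")
})

test_that("NBS finds planted components and behaves at degenerate thresholds", {
  set.seed(10)
  n <- 16
  ids <- paste0("n", 1:n)
  # base weights, with a connected chain of 6 edges weakened in group b
  planted <- cbind(1:6, 2:7)
  mk <- function(effect) {
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    W[ut] <- rlnorm(sum(ut), 2, 0.3)
    W <- W + t(W); diag(W) <- 0
    for (r in seq_len(nrow(planted))) {
      i <- planted[r, 1]; j <- planted[r, 2]
      W[i, j] <- W[j, i] <- W[i, j] * effect
    }
    ConnectomeMatrix(W, nodeIds = ids)
  }
  subjects <- c(replicate(15, mk(1), simplify = FALSE),
                replicate(15, mk(0.45), simplify = FALSE))
  ch <- CohortDataset(subjects, rep(c("a", "b"), each = 15),
                      subjectIds = paste0("s", 1:30))
  res <- nbs(ch, c("a", "b"), pEdge = 0.01, nPerm = 300, seed = 11)
  expect_s4_class(res, "NBSResult")
  expect_gte(length(res@components), 1)
  expect_lt(res@pFwe[1], 0.05)
  top <- res@components[[1]]
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  got <- key(match(top$node_i, ids), match(top$node_j, ids))
  want <- key(planted[, 1], planted[, 2])
  expect_gte(length(intersect(got, want)) / length(want), 0.8)

  # p_edge = 1: every varying edge is supra-threshold, one component
  resAll <- nbs(ch, c("a", "b"), pEdge = 1, nPerm = 10, seed = 1)
  expect_equal(length(resAll@components), 1)
  expect_equal(nrow(resAll@components[[1]]),
               sum(resAll@edgeStats$supra))
  expect_equal(sum(resAll@edgeStats$supra), n * (n - 1) / 2)
})

test_that("NBS supra-edge counts are monotone nonincreasing in p_edge", {
  set.seed(12)
  n <- 12
  subjects <- replicate(20, rWeighted(n, 0.9), simplify = FALSE)
  ch <- CohortDataset(subjects, rep(c("a", "b"), 10),
                      subjectIds = paste0("s", 1:20))
  sizes <- sapply(c(0.5, 0.1, 0.01), function(pe)
    sum(nbs(ch, c("a", "b"), pEdge = pe, nPerm = 5, seed = 2)@edgeStats$supra))
  expect_true(all(diff(sizes) <= 0))
})

test_that("NBS with no supra-threshold edges returns an empty result", {
  set.seed(13)
  subjects <- replicate(12, {
    W <- completeGraph(8) * 5
    ConnectomeMatrix(W + 0)
  }, simplify = FALSE)
  # identical matrices: zero-variance edges, nothing survives
  ch <- CohortDataset(subjects, rep(c("a", "b"), 6),
                      subjectIds = paste0("s", 1:12))
  res <- nbs(ch, c("a", "b"), pEdge = 0.01, nPerm = 10, seed = 3)
  expect_length(res@components, 0)
  expect_length(res@pFwe, 0)
})
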
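# Rich-club coefficient, null normalization, hubs and edge classes.

# phi for every k level given degrees and edge endpoints; NA where fewer
# than 2 nodes qualify. Definedness depends only on the degree sequence,
# so it is identical across degree-preserving nulls.
.phiCurve <- function(deg, ei, ej, kLevels) {
  vapply(kLevels, function(k) {
    qual <- deg > k
    nk <- sum(qual)
    if (nk < 2L) return(NA_real_)
    ek <- sum(qual[ei] & qual[ej])
    ek / (nk * (nk - 1) / 2)
  }, numeric(1))
}

#' Rich-club coefficient at one degree level
#'
#' phi(k) = E_k / [N_k (N_k - 1) / 2], where N_k nodes have degree
#' strictly greater than k and E_k edges join two such nodes.  Undefined
#' (NA) when fewer than two nodes qualify; once undefined at some k it
#' stays undefined for all larger k.
#'
#' @param G a \linkS4class{BinaryGraph}.
#' @param k degree threshold.
#' @return phi(k) in [0, 1], or NA.
#' @export
phiCoefficient <- function(G, k) {
  stopifnot(is(G, "BinaryGraph"), k >= 0)
  A <- adjacencyMatrix(G)
  ut <- .upperTri(nrow(A))
  on <- A[ut] > 0
  .phiCurve(rowSums(A), ut[on, "i"], ut[on, "j"], as.integer(k))
}

#' Degree-preserving randomization (double-edge swaps)
#'
#' Maslov-Sneppen rewiring: repeated double-edge swaps that preserve every
#' node's degree exactly and never introduce self-loops or multi-edges.
#' Reproducible for a fixed seed.  Graphs admitting no valid swap (e.g. a
#' triangle) are returned unchanged.
#'
#' @param G a \linkS4class{BinaryGraph} with at least 2 edges.
#' @param nSwapAttempts swap attempts (default 10 times the edge count).
#' @param seed RNG seed.
#' @return A rewired \linkS4class{BinaryGraph} with identical degree
#'   sequence and edge count.
#' @export
degreePreservingRewire <- function(G, nSwapAttempts = NULL, seed = NULL) {
  stopifnot(is(G, "BinaryGraph"))
  m <- edgeCount(G)
  if (m < 2L) {
    warning("fewer than 2 edges: no swap possible, returning input")
    return(G)
  }
  if (is.null(nSwapAttempts)) nSwapAttempts <- 10L * m
  g <- .asIgraph(G)
  gr <- withSeed(seed,
    rewire(g, keeping_degseq(loops = FALSE, niter = nSwapAttempts)))
  A <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
  .BinaryGraph(A, nodeIds = G@nodeIds, sourceSubject = G@sourceSubject)
}

#' Rich-club profile with degree-preserving null normalization
#'
#' Computes phi(k) across degree levels, the null distribution of phi(k)
#' over \code{nRandom} degree-preserving rewired networks, the normalized
#' coefficient phi_norm(k) = phi(k) / mean null phi(k) (values above 1
#' indicate rich-club organization) and a permutation p-value per k,
#' p(k) = (1 + #\{null phi >= observed phi\}) / (1 + nRandom).  The
#' longest contiguous k-range with phi_norm > 1 and p < 0.05 is stored as
#' the significant regime.
#'
#' @param G a \linkS4class{BinaryGraph}.
#' @param nRandom number of null networks (default 1000).
#' @param seed RNG seed.
#' @param kLevels degree thresholds (default 1 to max degree - 1).
#' @param swapFactor swap attempts per null as a multiple of edge count.
#' @return A \linkS4class{RichClubProfile}.
#' @export
richClubProfile <- function(G, nRandom = 1000, seed = NULL,
                            kLevels = NULL, swapFactor = 10) {
  stopifnot(is(G, "BinaryGraph"), nRandom >= 1)
  A <- adjacencyMatrix(G)
  deg <- rowSums(A)
  if (max(deg) < 2) stop("degenerate graph: maximum degree below 2")
  if (is.null(kLevels)) kLevels <- seq_len(max(deg) - 1L)
  kLevels <- as.integer(kLevels)
  ut <- .upperTri(nrow(A))
  on <- A[ut] > 0
  ei <- ut[on, "i"]; ej <- ut[on, "j"]
  phi <- .phiCurve(deg, ei, ej, kLevels)

  g <- .asIgraph(G)
  m <- length(ei)
  nulls <- withSeed(seed, {
    vapply(seq_len(nRandom), function(r) {
      gr <- rewire(g, keeping_degseq(loops = FALSE,
                                     niter = swapFactor * m))
      el <- igraph::as_edgelist(gr, names = FALSE)
      .phiCurve(deg, el[, 1L], el[, 2L], kLevels)
    }, numeric(length(kLevels)))
  })
  nulls <- matrix(nulls, nrow = length(kLevels))
  mu <- rowMeans(nulls)
  sdv <- apply(nulls, 1L, stats::sd)
  phiNorm <- ifelse(is.na(phi) | is.na(mu) | mu == 0, NA_real_, phi / mu)
  pPerm <- vapply(seq_along(kLevels), function(i) {
    if (is.na(phi[i])) return(NA_real_)
    (1 + sum(nulls[i, ] >= phi[i])) / (1 + nRandom)
  }, numeric(1))

  sig <- !is.na(phiNorm) & phiNorm > 1 & !is.na(pPerm) & pPerm < 0.05
  sigRange <- integer(0)
  if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    sigRange <- kLevels[starts[best]:ends[best]]
  }
  new("RichClubProfile", kLevels = kLevels, phi = phi, phiRandMean = mu,
      phiRandSd = sdv, phiNorm = phiNorm, pPerm = pPerm,
      nRandom = as.integer(nRandom),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      sigRange = as.integer(sigRange))
}

#' Group-average network by edge occurrence
#'
#' An edge is retained when present in at least \code{occurrence} of the
#' subjects' binary graphs (default 80\%, boundary inclusive).
#' \code{occurrence = 1} yields the intersection graph.
#'
#' @param graphs list of \linkS4class{BinaryGraph} sharing node order.
#' @param occurrence required presence fraction in (0, 1].
#' @return A \linkS4class{BinaryGraph}.
#' @export
groupAverageNetwork <- function(graphs, occurrence = 0.8) {
  if (length(graphs) == 0L) stop("empty subject list")
  stopifnot(occurrence > 0, occurrence <= 1)
  ids <- graphs[[1]]@nodeIds
  ok <- vapply(graphs, function(g) identical(g@nodeIds, ids), logical(1))
  if (!all(ok)) stop("graphs must share node ordering")
  count <- Reduce(`+`, lapply(graphs, adjacencyMatrix))
  A <- (count / length(graphs) >= occurrence - 1e-9) * 1
  .BinaryGraph(A, nodeIds = ids, sourceSubject = "group-average")
}

#' Identify rich-club hubs on a group-average network
#'
#' Default rule: hubs are nodes with degree strictly greater than k*,
#' where k* is the smallest k of the significant phi_norm > 1 regime of
#' the supplied profile (\code{kStar = "auto"}).  An alternative
#' mean + SD degree rule is available.
#'
#' @param avg group-average \linkS4class{BinaryGraph}.
#' @param profile \linkS4class{RichClubProfile} computed on \code{avg}
#'   (required for \code{kStar = "auto"}).
#' @param kStar "auto" or an explicit integer degree threshold.
#' @param rule "degree" (strict degree > k*) or "meanSD"
#'   (degree > mean + sdFactor * sd).
#' @param sdFactor SD multiplier for \code{rule = "meanSD"}.
#' @return Character vector of hub node ids (warning when empty).
#' @export
identifyHubs <- function(avg, profile = NULL, kStar = "auto",
                         rule = c("degree", "meanSD"), sdFactor = 1) {
  stopifnot(is(avg, "BinaryGraph"))
  rule <- match.arg(rule)
  deg <- rowSums(adjacencyMatrix(avg))
  hubs <- if (rule == "meanSD") {
    avg@nodeIds[deg > mean(deg) + sdFactor * stats::sd(deg)]
  } else {
    if (identical(kStar, "auto")) {
      if (is.null(profile) || length(profile@sigRange) == 0L)
        stop("kStar = 'auto' needs a profile with a significant regime")
      kStar <- min(profile@sigRange)
    }
    avg@nodeIds[deg > kStar]
  }
  if (length(hubs) == 0L) warning("empty hub set")
  hubs
}

#' Classify edges as rich, feeder or local
#'
#' Hub-hub edges are rich-club connections, hub-nonhub edges are feeders,
#' and nonhub-nonhub edges are local connections.  Strengths sum the
#' supplied weights per class (1 per edge for a binary graph);
#' proportions are by edge count and sum to 1.
#'
#' @param x a \linkS4class{ConnectomeMatrix} (weighted strengths) or
#'   \linkS4class{BinaryGraph}.
#' @param hubs character vector of hub node ids (subset of the node set).
#' @return An \linkS4class{EdgeClassDecomposition}.
#' @export
classifyEdges <- function(x, hubs) {
  W <- if (is(x, "BinaryGraph")) adjacencyMatrix(x) else {
    stopifnot(is(x, "ConnectomeMatrix")); weightMatrix(x)
  }
  ids <- nodeIds(x)
  if (!all(hubs %in% ids)) stop("hubs must be a subset of the node set")
  ut <- .upperTri(nrow(W))
  on <- W[ut] > 0
  ei <- ut[on, "i"]; ej <- ut[on, "j"]
  ih <- ids[ei] %in% hubs
  jh <- ids[ej] %in% hubs
  cls <- ifelse(ih & jh, "rich", ifelse(ih | jh, "feeder", "local"))
  w <- W[ut][on]
  edges <- data.frame(node_i = ids[ei], node_j = ids[ej],
                      class = cls, weight = w,
                      stringsAsFactors = FALSE)
  lv <- c("rich", "feeder", "local")
  counts <- stats::setNames(as.numeric(table(factor(cls, levels = lv))), lv)
  strengths <- stats::setNames(
    vapply(lv, function(l) sum(w[cls == l]), numeric(1)), lv)
  props <- if (sum(counts) > 0) counts / sum(counts) else
    stats::setNames(rep(NA_real_, 3L), lv)
  new("EdgeClassDecomposition", hubSet = as.character(hubs), edges = edges,
      classCounts = counts, classStrengths = strengths,
      classProportions = props)
}

#' Per-class connection strength across a sparsity sweep
#'
#' At each sparsity, the subject's pre-binarization weights are restricted
#' to the edges surviving that threshold and summed within each edge
#' class.
#'
#' @param M the subject's weighted \linkS4class{ConnectomeMatrix}.
#' @param sweep a \linkS4class{ThresholdSweep} of the same subject.
#' @param hubs hub node ids.
#' @return data.frame: sparsity, class, strength, proportion.
#' @export
classStrengthSweep <- function(M, sweep, hubs) {
  stopifnot(is(M, "ConnectomeMatrix"), is(sweep, "ThresholdSweep"))
  W <- weightMatrix(M)
  do.call(rbind, lapply(seq_along(sweep@sparsities), function(i) {
    g <- sweep@graphs[[i]]
    Wk <- W * adjacencyMatrix(g)
    dec <- classifyEdges(
      ConnectomeMatrix(Wk, nodeIds = M@nodeIds, subjectId = M@subjectId),
      hubs)
    data.frame(sparsity = sweep@sparsities[i],
               class = names(dec@classStrengths),
               strength = unname(dec@classStrengths),
               proportion = unname(dec@classProportions))
  }))
}

#' Integrated per-class strengths over the sweep
#'
#' Trapezoidal area of each class strength curve over the sparsity range
#' (see \code{\link{integrateCurve}}).
#'
#' @inheritParams classStrengthSweep
#' @return Named numeric vector over rich/feeder/local.
#' @export
integratedClassStrengths <- function(M, sweep, hubs) {
  tab <- classStrengthSweep(M, sweep, hubs)
  vapply(c(rich = "rich", feeder = "feeder", local = "local"),
         function(l) integrateCurve(tab$strength[tab$class == l],
                                    step = sweep@step),
         numeric(1))
}
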
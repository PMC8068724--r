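#' @importFrom igraph graph_from_adjacency_matrix distances transitivity
#'   mean_distance betweenness degree cluster_fast_greedy modularity
#'   rewire keeping_degseq membership induced_subgraph ecount
NULL

.asIgraph <- function(G) {
  graph_from_adjacency_matrix(adjacencyMatrix(G), mode = "undirected")
}

# Mean inverse shortest path length over ordered pairs; disconnected
# pairs contribute 0.
.efficiencyFromDist <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

.meanClustering <- function(g) {
  cc <- transitivity(g, type = "local", isolates = "zero")
  mean(cc)
}

# Characteristic path length over connected pairs only (harmonic-type
# convention: infinite distances are excluded rather than propagated).
.charPathLength <- function(g) {
  mean_distance(g, directed = FALSE, unconnected = TRUE)
}

.localEfficiency <- function(g) {
  n <- length(igraph::V(g))
  vapply(seq_len(n), function(i) {
    nb <- as.integer(igraph::neighbors(g, i))
    if (length(nb) < 2L) return(0)
    sub <- induced_subgraph(g, nb)
    .efficiencyFromDist(distances(sub))
  }, numeric(1))
}

#' Global graph metrics with random-network normalization
#'
#' Computes mean clustering C, characteristic path length L (over
#' connected pairs), global efficiency Eg, local efficiency Eloc and
#' modularity Q on a binary graph, then normalizes C and L against
#' \code{nRandom} degree-preserving rewired null networks: gamma =
#' C/C_rand, lambda = L/L_rand, and the small-worldness sigma =
#' gamma/lambda.  Reproducible for a fixed seed.
#'
#' @param G a \linkS4class{BinaryGraph} with at least one edge.
#' @param nRandom number of matched random networks (default 1000).
#' @param seed RNG seed for the null ensemble.
#' @param swapFactor double-edge-swap attempts per null network, as a
#'   multiple of the edge count (default 10).
#' @return One-row data.frame: C, L, gamma, lambda, sigma, Eg, Eloc, Q,
#'   sparsity.
#' @export
globalMetrics <- function(G, nRandom = 1000, seed = NULL, swapFactor = 10) {
  stopifnot(is(G, "BinaryGraph"))
  if (edgeCount(G) == 0L) stop("empty graph")
  if (nRandom < 1L) stop("nRandom must be >= 1")
  g <- .asIgraph(G)
  C <- .meanClustering(g)
  L <- .charPathLength(g)
  D <- distances(g)
  Eg <- .efficiencyFromDist(D)
  Eloc <- mean(.localEfficiency(g))
  Q <- modularityPartition(G)$Q
  m <- ecount(g)
  nulls <- withSeed(seed, {
    vapply(seq_len(nRandom), function(r) {
      gr <- rewire(g, keeping_degseq(loops = FALSE,
                                     niter = swapFactor * m))
      c(.meanClustering(gr), .charPathLength(gr))
    }, numeric(2))
  })
  gamma <- C / mean(nulls[1L, ])
  lambda <- L / mean(nulls[2L, ])
  data.frame(C = C, L = L, gamma = gamma, lambda = lambda,
             sigma = gamma / lambda, Eg = Eg, Eloc = Eloc, Q = Q,
             sparsity = sparsity(G))
}

#' Nodal graph metrics
#'
#' Degree centrality Dc, nodal efficiency Ne(i) = mean over j != i of
#' 1/d(i, j) (disconnected pairs contribute 0) and unnormalized
#' shortest-path betweenness centrality Bc with even splitting across
#' equal-length paths.
#'
#' @param G a \linkS4class{BinaryGraph}.
#' @return data.frame: node_id, Dc, Ne, Bc, sparsity, subject_id.
#' @export
nodalMetrics <- function(G) {
  stopifnot(is(G, "BinaryGraph"))
  g <- .asIgraph(G)
  n <- nNodes(G)
  D <- distances(g)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  data.frame(node_id = G@nodeIds,
             Dc = as.integer(rowSums(G@adjacency)),
             Ne = rowSums(inv) / (n - 1),
             Bc = betweenness(g, directed = FALSE),
             sparsity = sparsity(G),
             subject_id = G@sourceSubject)
}

#' Small-world compliance check
#'
#' Subjects whose sigma at the maximum sparsity does not exceed the
#' conventional bound (1.1) are flagged but never dropped; the check is
#' reporting only.
#'
#' @param sigmas per-subject sigma at the maximum threshold.
#' @param subjectIds optional identifiers for the report.
#' @param bound small-world bound (default 1.1).
#' @return list(pass = all above bound, flagged = ids/indices at or below).
#' @export
smallWorldCheck <- function(sigmas, subjectIds = NULL, bound = 1.1) {
  if (length(sigmas) == 0L) stop("no sigma values supplied")
  if (is.null(subjectIds)) subjectIds <- seq_along(sigmas)
  flagged <- subjectIds[sigmas <= bound]
  list(pass = length(flagged) == 0L, flagged = flagged, bound = bound)
}

#' Modularity-maximizing partition
#'
#' Greedy agglomerative modularity maximization; Q is the standard
#' within-community edge excess over the degree-matched expectation,
#' Q = sum_c (e_cc - a_c^2).  The greedy merge order is deterministic, so
#' results are reproducible; \code{seed} is accepted for interface
#' symmetry with the stochastic operations.
#'
#' @param G a \linkS4class{BinaryGraph} with at least one edge.
#' @param seed unused by the deterministic greedy algorithm.
#' @return list(membership = integer community labels, Q = modularity).
#' @export
modularityPartition <- function(G, seed = NULL) {
  stopifnot(is(G, "BinaryGraph"))
  if (edgeCount(G) == 0L) stop("edgeless graph has no modular structure")
  g <- .asIgraph(G)
  cl <- withSeed(seed, cluster_fast_greedy(g))
  mem <- as.integer(membership(cl))
  Q <- modularity(g, mem)
  # the single community always attains Q = 0, so never return worse
  if (Q < 0) {
    mem <- rep(1L, nNodes(G))
    Q <- 0
  }
  list(membership = mem, Q = Q)
}

#' Hemispheric asymmetry index
#'
#' [X(L) - X(R)] / [X(L) + X(R)] for a nonnegative metric aggregated per
#' hemisphere; positive values indicate leftward asymmetry.  Vectorized;
#' a zero denominator yields NA with a warning.
#'
#' @param xLeft,xRight nonnegative metric values for the left and right
#'   hemisphere.
#' @return Asymmetry values in [-1, 1] (NA where undefined).
#' @export
hemisphericAsymmetry <- function(xLeft, xRight) {
  stopifnot(length(xLeft) == length(xRight))
  if (any(xLeft < 0 | xRight < 0, na.rm = TRUE))
    stop("hemisphere values must be nonnegative")
  denom <- xLeft + xRight
  out <- (xLeft - xRight) / denom
  zero <- !is.na(denom) & denom == 0
  if (any(zero)) {
    warning("zero denominator: asymmetry undefined for ", sum(zero),
            " value(s)")
    out[zero] <- NA_real_
  }
  out
}
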
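#' @import methods
NULL

#' ConnectomeMatrix: a per-subject weighted structural connectivity matrix
#'
#' Symmetric nonnegative N x N weight matrix (streamline counts or
#' FA-weights) with node identity and a subject identifier.  Validity
#' enforces symmetry within 1e-9, a zero diagonal, N >= 3 and unique node
#' identifiers.
#'
#' @slot weights numeric N x N matrix of nonnegative connection weights.
#' @slot nodeIds character vector of N unique region identifiers.
#' @slot subjectId single character subject identifier.
#' @export
setClass("ConnectomeMatrix",
  representation(weights = "matrix", nodeIds = "character",
                 subjectId = "character"))

setValidity("ConnectomeMatrix", function(object) {
  W <- object@weights
  n <- nrow(W)
  msg <- character(0)
  if (!is.numeric(W) || nrow(W) != ncol(W))
    msg <- c(msg, "weights must be a square numeric matrix")
  else {
    if (n < 3L) msg <- c(msg, "at least 3 nodes are required")
    if (anyNA(W)) msg <- c(msg, "weights contain NA/NaN")
    else {
      if (any(W < 0)) msg <- c(msg, "weights must be nonnegative")
      if (max(abs(W - t(W))) > 1e-9)
        msg <- c(msg, "weights must be symmetric within 1e-9")
      if (any(diag(W) != 0)) msg <- c(msg, "diagonal must be zero")
    }
    if (length(object@nodeIds) != n)
      msg <- c(msg, "nodeIds length must equal matrix dimension")
    if (anyDuplicated(object@nodeIds))
      msg <- c(msg, "nodeIds must be unique")
  }
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a ConnectomeMatrix
#'
#' @param weights symmetric nonnegative numeric matrix with zero diagonal.
#' @param nodeIds region identifiers; defaults to \code{"n1"..."nN"}.
#' @param subjectId subject identifier.
#' @return A validated \linkS4class{ConnectomeMatrix}.
#' @export
ConnectomeMatrix <- function(weights, nodeIds = NULL, subjectId = "subject") {
  weights <- as.matrix(weights)
  dimnames(weights) <- NULL
  if (is.null(nodeIds)) nodeIds <- paste0("n", seq_len(nrow(weights)))
  new("ConnectomeMatrix", weights = weights,
      nodeIds = as.character(nodeIds), subjectId = as.character(subjectId))
}

#' BinaryGraph: a sparsity-thresholded binary network
#'
#' Undirected unweighted adjacency at a given sparsity (retained edges /
#' maximum possible edges).  The stored sparsity is the achieved ratio, so
#' \code{edgeCount(g) == round(sparsity(g) * N(N-1)/2)} holds exactly.
#'
#' @slot adjacency numeric N x N 0/1 matrix, symmetric, zero diagonal.
#' @slot sparsity achieved edge density in (0, 1].
#' @slot nodeIds character node identifiers.
#' @slot sourceSubject subject the graph was thresholded from.
#' @export
setClass("BinaryGraph",
  representation(adjacency = "matrix", sparsity = "numeric",
                 nodeIds = "character", sourceSubject = "character"))

setValidity("BinaryGraph", function(object) {
  A <- object@adjacency
  msg <- character(0)
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  else {
    if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency must be 0/1")
    if (any(A != t(A))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(A) != 0)) msg <- c(msg, "diagonal must be zero")
    if (length(object@nodeIds) != nrow(A))
      msg <- c(msg, "nodeIds length mismatch")
  }
  if (length(object@sparsity) != 1L || object@sparsity < 0 ||
      object@sparsity > 1)
    msg <- c(msg, "sparsity must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

.BinaryGraph <- function(adjacency, nodeIds, sourceSubject = "") {
  n <- nrow(adjacency)
  dimnames(adjacency) <- NULL
  new("BinaryGraph", adjacency = adjacency,
      sparsity = sum(adjacency) / 2 / .maxEdges(n),
      nodeIds = as.character(nodeIds),
      sourceSubject = as.character(sourceSubject))
}

#' ThresholdSweep: binary graphs across a sparsity range
#'
#' @slot sparsities strictly increasing sparsity levels.
#' @slot graphs list of \linkS4class{BinaryGraph}, one per sparsity,
#'   sharing node order; edge sets are nested across increasing sparsity.
#' @slot step sparsity increment.
#' @export
setClass("ThresholdSweep",
  representation(sparsities = "numeric", graphs = "list", step = "numeric"))

setValidity("ThresholdSweep", function(object) {
  msg <- character(0)
  if (length(object@graphs) != length(object@sparsities))
    msg <- c(msg, "one graph per sparsity required")
  if (length(object@sparsities) > 1L && any(diff(object@sparsities) <= 0))
    msg <- c(msg, "sparsities must be strictly increasing")
  ids <- lapply(object@graphs, function(g) g@nodeIds)
  if (length(ids) > 1L && !all(vapply(ids, identical, logical(1), ids[[1]])))
    msg <- c(msg, "identical node ordering required across graphs")
  if (length(msg)) msg else TRUE
})

#' CohortDataset: subjects with matrices, groups, covariates and scores
#'
#' @slot subjects list of \linkS4class{ConnectomeMatrix} sharing node order.
#' @slot group per-subject group label (e.g. CN / MDDNSI / MDDSI).
#' @slot covariates data.frame of per-subject numeric covariates
#'   (age, sex code, education, GM volume).
#' @slot scores data.frame of per-subject symptom scores (HAMD, HAMA, ...).
#' @slot nodeIds shared node identifiers.
#' @slot subjectIds per-subject identifiers.
#' @export
setClass("CohortDataset",
  representation(subjects = "list", group = "character",
                 covariates = "data.frame", scores = "data.frame",
                 nodeIds = "character", subjectIds = "character"))

setValidity("CohortDataset", function(object) {
  msg <- character(0)
  ns <- length(object@subjects)
  if (length(object@group) != ns) msg <- c(msg, "one group label per subject")
  if (anyNA(object@group)) msg <- c(msg, "missing group labels")
  if (nrow(object@covariates) && nrow(object@covariates) != ns)
    msg <- c(msg, "covariate rows must match subjects")
  if (nrow(object@scores) && nrow(object@scores) != ns)
    msg <- c(msg, "score rows must match subjects")
  if (length(object@subjectIds) != ns)
    msg <- c(msg, "one subjectId per subject")
  ok <- vapply(object@subjects, function(s)
    identical(s@nodeIds, object@nodeIds), logical(1))
  if (ns && !all(ok)) msg <- c(msg, "all subjects must share node ordering")
  if (length(msg)) msg else TRUE
})

#' CohortDataset constructor
#'
#' @param subjects list of \linkS4class{ConnectomeMatrix}.
#' @param group per-subject group labels.
#' @param covariates,scores per-subject data.frames (may be empty).
#' @param subjectIds identifiers; default taken from the matrices.
#' @return A validated \linkS4class{CohortDataset}.
#' @export
CohortDataset <- function(subjects, group,
                          covariates = data.frame(), scores = data.frame(),
                          subjectIds = NULL) {
  if (is.null(subjectIds))
    subjectIds <- vapply(subjects, function(s) s@subjectId, character(1))
  nodeIds <- if (length(subjects)) subjects[[1]]@nodeIds else character(0)
  new("CohortDataset", subjects = subjects, group = as.character(group),
      covariates = covariates, scores = scores,
      nodeIds = nodeIds, subjectIds = as.character(subjectIds))
}

#' RichClubProfile: rich-club coefficient across degree levels
#'
#' Per degree threshold k: the observed coefficient phi(k), the null
#' distribution summary over degree-preserving rewired graphs, the
#' normalized coefficient phi_norm(k) = phi(k) / mean null phi(k), and a
#' permutation p-value.  \code{sigRange} holds the contiguous k-range with
#' phi_norm > 1 and p < 0.05.
#'
#' @slot kLevels integer degree thresholds.
#' @slot phi,phiRandMean,phiRandSd,phiNorm,pPerm numeric per-k vectors.
#' @slot nRandom number of null networks.
#' @slot seed RNG seed used.
#' @slot sigRange integer k values of the significant regime.
#' @export
setClass("RichClubProfile",
  representation(kLevels = "integer", phi = "numeric",
                 phiRandMean = "numeric", phiRandSd = "numeric",
                 phiNorm = "numeric", pPerm = "numeric",
                 nRandom = "integer", seed = "integer",
                 sigRange = "integer"))

setValidity("RichClubProfile", function(object) {
  k <- length(object@kLevels)
  lens <- c(length(object@phi), length(object@phiRandMean),
            length(object@phiRandSd), length(object@phiNorm),
            length(object@pPerm))
  msg <- character(0)
  if (!all(lens == k)) msg <- c(msg, "per-k vectors must align with kLevels")
  p <- object@pPerm[!is.na(object@pPerm)]
  if (length(p) && (any(p <= 0) || any(p > 1)))
    msg <- c(msg, "pPerm must lie in (0, 1]")
  ph <- object@phi[!is.na(object@phi)]
  if (length(ph) && (any(ph < 0) || any(ph > 1)))
    msg <- c(msg, "phi must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' EdgeClassDecomposition: rich / feeder / local edge partition
#'
#' @slot hubSet node identifiers of the rich-club hubs.
#' @slot edges data.frame with columns node_i, node_j, class, weight.
#' @slot classCounts,classStrengths,classProportions named numeric vectors
#'   over c("rich", "feeder", "local"); proportions (by edge count) sum to 1.
#' @export
setClass("EdgeClassDecomposition",
  representation(hubSet = "character", edges = "data.frame",
                 classCounts = "numeric", classStrengths = "numeric",
                 classProportions = "numeric"))

setValidity("EdgeClassDecomposition", function(object) {
  msg <- character(0)
  cls <- c("rich", "feeder", "local")
  if (!identical(names(object@classCounts), cls) ||
      !identical(names(object@classStrengths), cls) ||
      !identical(names(object@classProportions), cls))
    msg <- c(msg, "class vectors must be named rich/feeder/local")
  if (nrow(object@edges)) {
    if (!all(object@edges$class %in% cls))
      msg <- c(msg, "edge classes must partition into rich/feeder/local")
    if (sum(object@classCounts) != nrow(object@edges))
      msg <- c(msg, "class counts must sum to the edge count")
    if (abs(sum(object@classProportions) - 1) > 1e-12)
      msg <- c(msg, "class proportions must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' NBSResult: network-based statistic inference result
#'
#' Per-edge statistics, supra-threshold connected components and their
#' family-wise error corrected permutation p-values (fraction of permuted
#' cohorts whose largest component size reaches the observed size).
#'
#' @slot edgeStats data.frame: node_i, node_j, stat, p, supra.
#' @slot pEdge per-edge threshold used.
#' @slot components list of per-component edge data.frames.
#' @slot componentSizes component sizes (extent = edge count).
#' @slot pFwe family-wise corrected p per component.
#' @slot nPerm,seed permutation settings.
#' @slot nullMaxSizes null distribution of the maximal component size.
#' @export
setClass("NBSResult",
  representation(edgeStats = "data.frame", pEdge = "numeric",
                 components = "list", componentSizes = "numeric",
                 pFwe = "numeric", nPerm = "integer", seed = "integer",
                 nullMaxSizes = "numeric"))

setValidity("NBSResult", function(object) {
  msg <- character(0)
  if (length(object@pFwe) != length(object@components))
    msg <- c(msg, "one pFwe per component")
  p <- object@pFwe
  if (length(p) && (any(p <= 0) || any(p > 1)))
    msg <- c(msg, "pFwe must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
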
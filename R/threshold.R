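#' Remove spurious low-streamline connections
#'
#' Deterministic tractography produces spurious connections from noise;
#' entries with weight less than or equal to \code{minStreamlines} are
#' zeroed (strict inequality: a count of exactly \code{minStreamlines} is
#' removed, counts above it are kept).
#'
#' @param M a \linkS4class{ConnectomeMatrix} of streamline counts.
#' @param minStreamlines threshold count (default 3).
#' @return Filtered \linkS4class{ConnectomeMatrix}.
#' @export
streamlineFilter <- function(M, minStreamlines = 3) {
  stopifnot(is(M, "ConnectomeMatrix"), minStreamlines >= 0)
  W <- M@weights
  W[W <= minStreamlines] <- 0
  ConnectomeMatrix(W, nodeIds = M@nodeIds, subjectId = M@subjectId)
}

#' Binarize a weighted network at a target sparsity
#'
#' Sparsity is the ratio of retained edges to the maximum possible
#' N(N-1)/2; the E = round(sparsity * N(N-1)/2) strongest-weight edges are
#' kept.  Ties at the cut rank are broken by lexicographic (i, j) node
#' order so the result is reproducible.  If fewer than E nonzero weights
#' exist, all nonzero edges are kept with a warning and the achieved
#' sparsity is recorded.
#'
#' @param M a \linkS4class{ConnectomeMatrix}, or a
#'   \linkS4class{BinaryGraph} (re-binarization is then idempotent at the
#'   same sparsity).
#' @param sparsity target edge density in (0, 1].
#' @return A \linkS4class{BinaryGraph}.
#' @export
sparsityBinarize <- function(M, sparsity) {
  stopifnot(length(sparsity) == 1L, sparsity > 0, sparsity <= 1)
  if (is(M, "BinaryGraph")) {
    W <- M@adjacency; ids <- M@nodeIds; sid <- M@sourceSubject
  } else {
    stopifnot(is(M, "ConnectomeMatrix"))
    W <- M@weights; ids <- M@nodeIds; sid <- M@subjectId
  }
  n <- nrow(W)
  ut <- .upperTri(n)
  w <- W[ut]
  E <- round(sparsity * .maxEdges(n))
  nnz <- sum(w > 0)
  if (E > nnz) {
    warning("requested ", E, " edges but only ", nnz,
            " nonzero weights; keeping all nonzero edges (achieved ",
            "sparsity ", format(round(nnz / .maxEdges(n), 4)), ")")
    E <- nnz
  }
  A <- matrix(0, n, n)
  if (E > 0L) {
    ord <- order(-w, ut[, "i"], ut[, "j"])
    keep <- ord[seq_len(E)]
    A[ut[keep, , drop = FALSE]] <- 1
    A <- A + t(A)
  }
  .BinaryGraph(A, nodeIds = ids, sourceSubject = sid)
}

#' Threshold sweep across a sparsity range
#'
#' Binarizes at each sparsity in \code{seq(sMin, sMax, by = step)}
#' (defaults 0.05 to 0.20 in increments of 0.01, i.e. 16 levels).  Edge
#' sets are nested: the graph at a lower sparsity is a subgraph of the
#' graph at any higher sparsity.  A warning flags sweeps whose minimum
#' sparsity yields mean degree 2E/N below ln(N), the usual lower guideline
#' for small-world estimation.
#'
#' @param M a \linkS4class{ConnectomeMatrix}.
#' @param sMin,sMax,step sweep range; \code{step} must divide the range.
#' @return A \linkS4class{ThresholdSweep}.
#' @export
sparsitySweep <- function(M, sMin = 0.05, sMax = 0.20, step = 0.01) {
  stopifnot(is(M, "ConnectomeMatrix"), sMin > 0, sMax <= 1, step > 0)
  if (sMin > sMax) stop("sMin must not exceed sMax")
  k <- (sMax - sMin) / step
  if (abs(k - round(k)) > 1e-9)
    stop("step must divide the sparsity range")
  sparsities <- sMin + step * (0:round(k))
  n <- nNodes(M)
  Emin <- round(sMin * .maxEdges(n))
  if (2 * Emin / n <= log(n))
    warning("mean degree ", format(round(2 * Emin / n, 2)),
            " at the minimum sparsity does not exceed ln(N) = ",
            format(round(log(n), 2)),
            "; metrics at the sparsest levels may be unstable")
  graphs <- lapply(sparsities, function(s) sparsityBinarize(M, s))
  new("ThresholdSweep", sparsities = sparsities, graphs = graphs,
      step = step)
}

#' Integrate a metric over a sparsity sweep
#'
#' Area under the metric-vs-sparsity curve, the summary used to compare
#' groups over the whole threshold range rather than at an arbitrary
#' single sparsity.  Trapezoidal by default; simple summation times step
#' is available behind \code{method = "sum"}.
#'
#' @param values metric values, one per sparsity level.
#' @param step sparsity increment between consecutive values.
#' @param method "trapezoid" (default) or "sum".
#' @return The integrated scalar.
#' @export
integrateCurve <- function(values, step, method = c("trapezoid", "sum")) {
  method <- match.arg(method)
  stopifnot(is.numeric(values), length(values) >= 1L, step > 0)
  if (length(values) == 1L) return(0)
  switch(method,
    trapezoid = step * (sum(values) -
                          (values[1L] + values[length(values)]) / 2),
    sum = step * sum(values))
}
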
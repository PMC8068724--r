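#' Accessors for richclubnet classes
#'
#' Slot access for the S4 containers: node counts and identifiers, weight
#' and adjacency matrices, sparsity and edge counts, cohort bookkeeping,
#' and tabular views of rich-club and edge-class results.
#'
#' @param x a richclubnet S4 object.
#' @return The requested component; \code{phiTable} and \code{edgeTable}
#'   return data.frames.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nNodes", "ConnectomeMatrix", function(x) nrow(x@weights))
#' @rdname accessors
setMethod("nNodes", "BinaryGraph", function(x) nrow(x@adjacency))
#' @rdname accessors
setMethod("nNodes", "CohortDataset", function(x) length(x@nodeIds))

#' @rdname accessors
setMethod("nodeIds", "ConnectomeMatrix", function(x) x@nodeIds)
#' @rdname accessors
setMethod("nodeIds", "BinaryGraph", function(x) x@nodeIds)
#' @rdname accessors
setMethod("nodeIds", "CohortDataset", function(x) x@nodeIds)

#' @rdname accessors
setMethod("weightMatrix", "ConnectomeMatrix", function(x) x@weights)

#' @rdname accessors
setMethod("adjacencyMatrix", "BinaryGraph", function(x) x@adjacency)

#' @rdname accessors
setMethod("sparsity", "BinaryGraph", function(x) x@sparsity)

#' @rdname accessors
setMethod("edgeCount", "BinaryGraph", function(x) sum(x@adjacency) / 2)
#' @rdname accessors
setMethod("edgeCount", "ConnectomeMatrix",
          function(x) sum(x@weights[upper.tri(x@weights)] > 0))

#' @rdname accessors
setMethod("subjectIds", "CohortDataset", function(x) x@subjectIds)
#' @rdname accessors
setMethod("groupLabels", "CohortDataset", function(x) x@group)
#' @rdname accessors
setMethod("covariates", "CohortDataset", function(x) x@covariates)
#' @rdname accessors
setMethod("scores", "CohortDataset", function(x) x@scores)

#' @rdname accessors
setMethod("hubSet", "EdgeClassDecomposition", function(x) x@hubSet)
#' @rdname accessors
setMethod("edgeTable", "EdgeClassDecomposition", function(x) x@edges)
#' @rdname accessors
setMethod("edgeTable", "NBSResult", function(x) x@edgeStats)

#' @rdname accessors
setMethod("phiTable", "RichClubProfile", function(x) {
  data.frame(k = x@kLevels, phi = x@phi, phi_rand_mean = x@phiRandMean,
             phi_rand_sd = x@phiRandSd, phi_norm = x@phiNorm,
             p_perm = x@pPerm)
})

setMethod("show", "ConnectomeMatrix", function(object) {
  cat("ConnectomeMatrix:", object@subjectId, "\n")
  cat("  nodes:", nNodes(object),
      " weighted edges:", edgeCount(object),
      " total strength:", format(sum(object@weights) / 2), "\n")
})

setMethod("show", "BinaryGraph", function(object) {
  cat("BinaryGraph (", object@sourceSubject, ")\n", sep = "")
  cat("  nodes:", nNodes(object), " edges:", edgeCount(object),
      " sparsity:", format(round(object@sparsity, 4)), "\n")
})

setMethod("show", "ThresholdSweep", function(object) {
  cat("ThresholdSweep:", length(object@sparsities), "levels",
      sprintf("[%.3f .. %.3f], step %.3f\n", min(object@sparsities),
              max(object@sparsities), object@step))
})

setMethod("show", "CohortDataset", function(object) {
  cat("CohortDataset:", length(object@subjects), "subjects x",
      nNodes(object), "nodes\n")
  print(table(object@group))
  if (ncol(object@covariates))
    cat("  covariates:", paste(names(object@covariates), collapse = ", "),
        "\n")
  if (ncol(object@scores))
    cat("  scores:", paste(names(object@scores), collapse = ", "), "\n")
})

setMethod("show", "RichClubProfile", function(object) {
  cat("RichClubProfile over k =", min(object@kLevels), "..",
      max(object@kLevels), sprintf("(%d null networks)\n", object@nRandom))
  if (length(object@sigRange))
    cat("  significant phi_norm > 1 regime: k in",
        min(object@sigRange), "..", max(object@sigRange), "\n")
  else cat("  no significant rich-club regime\n")
})

setMethod("show", "EdgeClassDecomposition", function(object) {
  cat("EdgeClassDecomposition:", length(object@hubSet), "hubs,",
      nrow(object@edges), "edges\n")
  print(rbind(count = object@classCounts,
              proportion = round(object@classProportions, 3),
              strength = round(object@classStrengths, 2)))
})

setMethod("show", "NBSResult", function(object) {
  cat("NBSResult: ", sum(object@edgeStats$supra, na.rm = TRUE),
      " supra-threshold edges (p_edge < ", object@pEdge, "), ",
      length(object@components), " component(s)\n", sep = "")
  if (length(object@components))
    print(data.frame(size = object@componentSizes, p_fwe = object@pFwe))
})
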
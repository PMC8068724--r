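# Depression-related circuit definitions over atlas regions and mapping
# of differential edges onto them.

#' Path to the bundled default circuit configuration
#'
#' A YAML file assigning AAL-90 region labels to the six
#' depression-related circuits (DMN, SC, NAC, PAC, AC, CCC) of the
#' large-scale circuit taxonomy.  The membership follows the main
#' anatomical descriptions of each circuit and is deliberately
#' approximate and user-editable; circuits may overlap.
#'
#' @return File path inside the installed package.
#' @export
defaultCircuitConfig <- function() {
  system.file("extdata", "circuits_aal90.yaml", package = "richclubnet",
              mustWork = TRUE)
}

#' Load a circuit atlas from a configuration file
#'
#' The config maps circuit names to lists of region labels or node ids.
#' Labels are resolved against the node table; unresolved labels are
#' reported (not an error) so approximate configs remain usable.
#'
#' @param config YAML file path, or a named list of character vectors.
#' @param nodes node table data.frame (see \code{\link{readNodeTable}}).
#' @return list with elements \code{circuits} (named list of node_id
#'   vectors), \code{unresolved} (named list of unmatched labels) and
#'   \code{source}.
#' @export
loadCircuitAtlas <- function(config, nodes) {
  src <- "<list>"
  if (is.character(config) && length(config) == 1L) {
    src <- config
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || length(config) == 0L ||
      is.null(names(config)) || any(names(config) == ""))
    stop("empty or unnamed circuit configuration")
  circuits <- list(); unresolved <- list()
  for (nm in names(config)) {
    labels <- as.character(unlist(config[[nm]]))
    if (length(labels) == 0L) stop("circuit '", nm, "' is empty")
    hit <- nodes$node_id[nodes$node_id %in% labels |
                           nodes$label %in% labels]
    miss <- setdiff(labels, c(nodes$node_id, nodes$label))
    circuits[[nm]] <- hit
    if (length(miss)) unresolved[[nm]] <- miss
  }
  list(circuits = circuits, unresolved = unresolved, source = src)
}

#' Map edges to circuits
#'
#' Annotates each edge with every circuit it belongs to.  Under the
#' default both-endpoints rule an edge is inside a circuit when both of
#' its regions belong to it; under the any-endpoint rule one member
#' suffices (per-circuit edge sets under "any" are supersets of those
#' under "both").  Edges matching no circuit are labeled
#' \code{unassigned}.  The assignment is deterministic and invariant to
#' edge order.
#'
#' @param edges data.frame with columns node_i, node_j and optionally a
#'   statistic column (carried through).
#' @param atlas result of \code{\link{loadCircuitAtlas}}.
#' @param rule "both" (default) or "any".
#' @return data.frame: node_i, node_j, circuit, plus any statistic
#'   columns of the input.
#' @export
mapEdgesToCircuits <- function(edges, atlas, rule = c("both", "any")) {
  rule <- match.arg(rule)
  circuits <- atlas$circuits
  out <- lapply(seq_len(nrow(edges)), function(r) {
    i <- edges$node_i[r]; j <- edges$node_j[r]
    hits <- names(circuits)[vapply(circuits, function(members) {
      if (rule == "both") (i %in% members) && (j %in% members)
      else (i %in% members) || (j %in% members)
    }, logical(1))]
    if (length(hits) == 0L) hits <- "unassigned"
    cbind(edges[rep(r, length(hits)), , drop = FALSE],
          circuit = hits, row.names = NULL)
  })
  do.call(rbind, out)
}
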
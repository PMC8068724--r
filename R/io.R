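#' Read a node table
#'
#' Tab-separated table with columns \code{node_id}, \code{label},
#' \code{hemisphere} (left/right) and \code{homologue_id} (contralateral
#' partner or empty).  The homologue relation must be symmetric.
#'
#' @param path path to a TSV file.
#' @return data.frame with the four columns, node_id unique.
#' @export
readNodeTable <- function(path) {
  nt <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  req <- c("node_id", "label", "hemisphere", "homologue_id")
  if (!all(req %in% names(nt)))
    stop("node table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(nt$node_id)) stop("node_id values must be unique")
  bad <- !nt$hemisphere %in% c("left", "right")
  if (any(bad))
    stop("hemisphere must be 'left' or 'right' (offending: ",
         paste(nt$node_id[bad], collapse = ", "), ")")
  hom <- stats::setNames(nt$homologue_id, nt$node_id)
  has <- !is.na(hom)
  back <- hom[hom[has]]
  if (any(is.na(back) | back != nt$node_id[has]))
    stop("homologue relation must be symmetric")
  nt
}

#' Read a connectivity matrix file
#'
#' Comma- or tab-delimited N x N numeric table, no header, row order equal
#' to the node-table order.  Asymmetries up to 1e-6 (absolute) are
#' symmetrized by averaging; larger asymmetry is an error, guarding
#' against directed inputs.
#'
#' @param path matrix file.
#' @param nodeTable optional node table (see \code{\link{readNodeTable}});
#'   its length must match the matrix dimension and supplies node ids.
#' @param subjectId subject identifier for the result.
#' @return A \linkS4class{ConnectomeMatrix}.
#' @export
readConnectome <- function(path, nodeTable = NULL, subjectId = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  W <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(W) <- NULL
  if (!is.numeric(W) || anyNA(W))
    stop("matrix file contains non-numeric or NaN entries: ", path)
  if (nrow(W) != ncol(W)) stop("matrix file is not square: ", path)
  if (any(W < 0)) stop("negative weights in ", path)
  asym <- max(abs(W - t(W)))
  if (asym > 1e-6)
    stop("matrix asymmetry ", format(asym),
         " exceeds 1e-6; directed input? (", path, ")")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  ids <- if (!is.null(nodeTable)) {
    if (nrow(nodeTable) != nrow(W))
      stop("dimension mismatch: matrix has ", nrow(W),
           " nodes but node table has ", nrow(nodeTable))
    nodeTable$node_id
  } else paste0("n", seq_len(nrow(W)))
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  ConnectomeMatrix(W, nodeIds = ids, subjectId = subjectId)
}

#' Read a cohort from a manifest
#'
#' The manifest is a TSV with columns \code{subject_id},
#' \code{matrix_path} (relative to the manifest directory or absolute),
#' \code{group}, plus covariate and score columns.
#'
#' @param manifestPath manifest TSV.
#' @param nodeTable node table data.frame.
#' @param covariateCols,scoreCols column names to pull into the covariate
#'   and score tables (missing columns are skipped).
#' @return A \linkS4class{CohortDataset}.
#' @export
readCohort <- function(manifestPath, nodeTable,
                       covariateCols = c("age", "sex", "education", "gmv"),
                       scoreCols = c("HAMD", "HAMA", "SI_severity")) {
  man <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  req <- c("subject_id", "matrix_path", "group")
  if (!all(req %in% names(man)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  base <- dirname(manifestPath)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$matrix_path),
                  man$matrix_path, file.path(base, man$matrix_path))
  subjects <- mapply(readConnectome, paths, subjectId = man$subject_id,
                     MoreArgs = list(nodeTable = nodeTable),
                     SIMPLIFY = FALSE, USE.NAMES = FALSE)
  covariateCols <- intersect(covariateCols, names(man))
  scoreCols <- intersect(scoreCols, names(man))
  CohortDataset(subjects, group = man$group,
                covariates = man[, covariateCols, drop = FALSE],
                scores = man[, scoreCols, drop = FALSE],
                subjectIds = man$subject_id)
}

#' Path to the bundled AAL-90 node table
#' @return File path inside the installed package.
#' @export
aalNodeTablePath <- function() {
  system.file("extdata", "aal90_nodes.tsv", package = "richclubnet",
              mustWork = TRUE)
}
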
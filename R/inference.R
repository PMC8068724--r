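# Covariate-adjusted permutation inference, partial correlation and the
# network-based statistic.

.designMatrix <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) &&
                              ncol(covariates) == 0L))
    return(matrix(1, n, 1L))
  X <- cbind(1, as.matrix(covariates))
  storage.mode(X) <- "double"
  X
}

#' Residualize values on covariates
#'
#' Least-squares residuals of \code{values} on an intercept plus the
#' covariate columns; the standard nuisance-removal step before
#' permutation inference (residualize-then-permute).
#'
#' @param values numeric response, or a matrix with one response per
#'   column.
#' @param covariates data.frame or matrix of per-subject covariates (NULL
#'   for centering only).
#' @return Residuals with the shape of \code{values}.
#' @export
residualize <- function(values, covariates = NULL) {
  Y <- as.matrix(values)
  X <- .designMatrix(covariates, nrow(Y))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient covariate design (rank ", qrX$rank, " < ",
         ncol(X), ")")
  R <- Y - X %*% qr.coef(qrX, Y)
  if (is.vector(values)) drop(R) else R
}

#' Covariate-adjusted permutation test for group differences
#'
#' Values are residualized on the covariates, then group labels are
#' permuted.  The statistic is the mean difference for two groups and the
#' one-way F statistic for three or more; the p-value uses the
#' add-one estimator p = (1 + #\{|null| >= |observed|\}) / (1 + nPerm)
#' (two-sided for the mean difference, upper tail for F).  Covariates are
#' never permuted.
#'
#' @param values per-subject metric.
#' @param groups per-subject labels (2 or more levels, >= 2 subjects per
#'   group).
#' @param nPerm number of permutations (default 10000; below 100 warns).
#' @param covariates optional covariate data.frame/matrix.
#' @param seed RNG seed.
#' @return list: statistic, p_perm, n_perm, design ("two-group" or
#'   "k-group"), covariates_used, seed.
#' @export
permTest <- function(values, groups, nPerm = 10000, covariates = NULL,
                     seed = NULL) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2L) stop("at least two groups required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 subjects")
  if (nPerm < 100) warning("nPerm below 100 gives coarse p-values")
  x <- residualize(values, covariates)
  n <- length(x)
  stat <- if (length(lv) == 2L) {
    g1 <- groups == lv[1L]
    function(xx, gg1) mean(xx[gg1]) - mean(xx[!gg1])
  } else NULL

  if (length(lv) == 2L) {
    g1 <- groups == lv[1L]
    obs <- stat(x, g1)
    null <- withSeed(seed, vapply(seq_len(nPerm), function(p) {
      stat(x, sample(g1)) }, numeric(1)))
    p <- (1 + sum(abs(null) >= abs(obs))) / (1 + nPerm)
    design <- "two-group"
  } else {
    f <- factor(groups)
    fstat <- function(xx, ff) {
      gm <- tapply(xx, ff, mean)
      ng <- tabulate(ff)
      ssb <- sum(ng * (gm - mean(xx))^2)
      ssw <- sum((xx - gm[ff])^2)
      (ssb / (nlevels(ff) - 1)) / (ssw / (length(xx) - nlevels(ff)))
    }
    obs <- fstat(x, f)
    null <- withSeed(seed, vapply(seq_len(nPerm), function(p) {
      fstat(x, f[sample.int(n)]) }, numeric(1)))
    p <- (1 + sum(null >= obs)) / (1 + nPerm)
    design <- "k-group"
  }
  list(statistic = obs, p_perm = p, n_perm = nPerm, design = design,
       covariates_used = if (is.null(covariates)) character(0) else
         colnames(as.data.frame(covariates)),
       seed = seed)
}

#' Bonferroni-significant nodes
#'
#' A node is significant iff its p-value is strictly below alpha divided
#' by the number of nodes (0.05/90 at the defaults of a 90-node atlas).
#'
#' @param pValues named per-node p-values.
#' @param alpha family-wise level (default 0.05).
#' @return Indices (or names) of significant nodes.
#' @export
bonferroniNodes <- function(pValues, alpha = 0.05) {
  if (length(pValues) == 0L) stop("empty p-value vector")
  stopifnot(alpha > 0, alpha < 1)
  thr <- alpha / length(pValues)
  sig <- which(pValues < thr)
  if (!is.null(names(pValues))) names(pValues)[sig] else sig
}

#' Partial correlation with covariate control
#'
#' Pearson correlation of the residuals of x and y on the covariates;
#' two-sided p from the t distribution with n - n_covariates - 2 degrees
#' of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of controls (NULL for plain
#'   correlation).
#' @return list: r, p, df.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  df <- length(x) - ncov - 2L
  if (df < 1L) stop("insufficient degrees of freedom")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  r <- stats::cor(rx, ry)
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}

# Subjects x upper-tri-edges weight matrix for a subset of subjects.
.edgeWeightMatrix <- function(cohort, idx) {
  n <- nNodes(cohort)
  ut <- .upperTri(n)
  Y <- t(vapply(cohort@subjects[idx],
                function(s) s@weights[ut], numeric(nrow(ut))))
  list(Y = Y, ut = ut)
}

#' Network-based statistic (NBS)
#'
#' Edge-wise two-sample pooled t-tests on (covariate-residualized)
#' connection weights between two groups; edges with p below
#' \code{pEdge} form the supra-threshold graph, whose connected
#' components are the candidate subnetworks.  Family-wise corrected
#' significance per component is the fraction of label-permuted cohorts
#' whose largest component size reaches the observed size (add-one
#' estimator).  Component size is the edge count (extent statistic) by
#' default; the intensity statistic (sum of |t| - t_crit) is available.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param contrast length-2 character: the two group labels to compare.
#' @param pEdge per-edge p threshold (default 0.01).
#' @param nPerm number of permutations (default 10000).
#' @param covariates covariate column names in the cohort (NULL = none).
#' @param seed RNG seed.
#' @param statistic "extent" (edge count) or "intensity".
#' @return An \linkS4class{NBSResult}; empty components when no edge
#'   survives the threshold.
#' @export
nbs <- function(cohort, contrast, pEdge = 0.01, nPerm = 10000,
                covariates = NULL, seed = NULL,
                statistic = c("extent", "intensity")) {
  stopifnot(is(cohort, "CohortDataset"), length(contrast) == 2L)
  statistic <- match.arg(statistic)
  idx <- which(cohort@group %in% contrast)
  if (length(idx) < 4L) stop("need >= 2 subjects per group")
  grp <- cohort@group[idx]
  ew <- .edgeWeightMatrix(cohort, idx)
  Y <- ew$Y; ut <- ew$ut
  if (!is.null(covariates)) {
    cv <- cohort@covariates[idx, covariates, drop = FALSE]
    Y <- residualize(Y, cv)
  }
  z <- grp == contrast[1L]
  n <- length(z); n1 <- sum(z); n2 <- n - n1
  dfree <- n - 2L
  tcrit <- stats::qt(1 - pEdge / 2, dfree)

  # Precompute sufficient statistics; per permutation only the group-1
  # sums change.
  S <- colSums(Y); S2 <- colSums(Y * Y)
  Y2 <- Y * Y
  tFromZ <- function(zz) {
    S1 <- crossprod(Y, zz)[, 1L]
    S21 <- crossprod(Y2, zz)[, 1L]
    m1 <- S1 / n1; m2 <- (S - S1) / n2
    sp2 <- ((S21 - n1 * m1 * m1) + ((S2 - S21) - n2 * m2 * m2)) / dfree
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    tt[!is.finite(tt)] <- 0
    tt
  }
  zNum <- as.numeric(z)
  tObs <- tFromZ(zNum)
  supra <- abs(tObs) > tcrit
  compSize <- function(tt, keep) {
    if (!any(keep)) return(0)
    w <- if (statistic == "extent") NULL else abs(tt[keep]) - tcrit
    .maxComponent(ut[keep, "i"], ut[keep, "j"], w)
  }

  # Observed components (via igraph for the full component structure).
  components <- list(); sizes <- numeric(0)
  if (any(supra)) {
    g <- igraph::graph_from_edgelist(
      cbind(ut[supra, "i"], ut[supra, "j"]), directed = FALSE)
    mem <- igraph::components(g)$membership
    emem <- mem[ut[supra, "i"]]
    esplit <- split(which(supra), emem)
    components <- lapply(esplit, function(e) {
      data.frame(node_i = cohort@nodeIds[ut[e, "i"]],
                 node_j = cohort@nodeIds[ut[e, "j"]],
                 stat = tObs[e], stringsAsFactors = FALSE)
    })
    sizes <- vapply(esplit, function(e) {
      if (statistic == "extent") length(e) else
        sum(abs(tObs[e]) - tcrit)
    }, numeric(1))
    ord <- order(-sizes)
    components <- components[ord]; sizes <- sizes[ord]
  }

  nullMax <- withSeed(seed, vapply(seq_len(nPerm), function(p) {
    zz <- zNum[sample.int(n)]
    tt <- tFromZ(zz)
    compSize(tt, abs(tt) > tcrit)
  }, numeric(1)))
  pFwe <- vapply(sizes, function(s)
    (1 + sum(nullMax >= s)) / (1 + nPerm), numeric(1))

  edgeStats <- data.frame(node_i = cohort@nodeIds[ut[, "i"]],
                          node_j = cohort@nodeIds[ut[, "j"]],
                          stat = tObs,
                          p = 2 * stats::pt(-abs(tObs), dfree),
                          supra = supra, stringsAsFactors = FALSE)
  new("NBSResult", edgeStats = edgeStats, pEdge = pEdge,
      components = components, componentSizes = as.numeric(sizes),
      pFwe = pFwe, nPerm = as.integer(nPerm),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nullMaxSizes = nullMax)
}
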
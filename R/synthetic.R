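# Synthetic three-group connectome cohorts with planted rich-club
# topology and class-specific group effects; ground truth for every
# pipeline stage.

#' Synthetic cohort specification
#'
#' Defaults emulate the study design the package targets: 90 AAL-style
#' nodes, three groups of 50/58/69 subjects (CN / MDDNSI / MDDSI), a
#' planted hub set of 11/90 nodes whose mutual connections are denser and
#' heavier by \code{hubCoreBoost}, group effects concentrated on feeder
#' and local connections plus one weakened non-hub node in the MDDSI
#' group, log-normal weight noise and a small Bernoulli edge
#' presence-flip rate.
#'
#' @param nNodes number of regions (default 90).
#' @param nPerGroup named subject counts per group.
#' @param hubFraction fraction of nodes planted as hubs (default 11/90).
#' @param baseDensity target overall edge density of the template.
#' @param hubCoreBoost multiplicative presence/weight factor on hub-hub
#'   edges (1 = no rich club planted).
#' @param effectMap per-group list of multiplicative weight shifts per
#'   edge class (\code{rich}, \code{feeder}, \code{local}) and an
#'   optional \code{node_factor} applied to all edges of one
#'   generator-chosen non-hub node.
#' @param noiseSd log-normal weight dispersion (sdlog).
#' @param presenceNoise per-edge Bernoulli flip rate.
#' @param scoreModel list: \code{slope} (weight of mean nodal efficiency
#'   of two designated hub nodes in the HAMD link, negative association),
#'   \code{intercepts} per group, \code{noiseSd}, \code{sparsity}.
#' @param confound optional list(group, covariate, shift) injecting a
#'   covariate-group association for adjustment testing.
#' @param seed RNG seed.
#' @return A validated spec list of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(nNodes = 90,
                          nPerGroup = c(CN = 50, MDDNSI = 58, MDDSI = 69),
                          hubFraction = 11 / 90,
                          baseDensity = 0.25,
                          hubCoreBoost = 3,
                          effectMap = list(
                            CN = list(rich = 1, feeder = 1, local = 1),
                            MDDNSI = list(rich = 1, feeder = 0.88,
                                          local = 0.92),
                            MDDSI = list(rich = 1, feeder = 0.80,
                                         local = 0.85,
                                         node_factor = 0.7)),
                          noiseSd = 0.3,
                          presenceNoise = 0.02,
                          scoreModel = list(slope = 500,
                                            intercepts = c(CN = 314,
                                                           MDDNSI = 340,
                                                           MDDSI = 342),
                                            noiseSd = 3, sparsity = 0.15),
                          confound = NULL,
                          seed = 1L) {
  stopifnot(nNodes >= 3, baseDensity > 0, baseDensity < 1,
            hubFraction >= 0, hubFraction < 1, hubCoreBoost > 0,
            noiseSd >= 0, presenceNoise >= 0, presenceNoise < 1,
            all(nPerGroup >= 1), !is.null(names(nPerGroup)))
  shifts <- unlist(lapply(effectMap, function(e)
    unlist(e[c("rich", "feeder", "local")])))
  stopifnot(all(shifts > 0))
  # effect entries for groups absent from nPerGroup are simply unused
  effectMap <- effectMap[names(effectMap) %in% names(nPerGroup)]
  structure(list(nNodes = nNodes, nPerGroup = nPerGroup,
                 hubFraction = hubFraction, baseDensity = baseDensity,
                 hubCoreBoost = hubCoreBoost, effectMap = effectMap,
                 noiseSd = noiseSd, presenceNoise = presenceNoise,
                 scoreModel = scoreModel, confound = confound,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate the base network template with a planted hub core
#'
#' Builds a degree-heterogeneous weighted template in which hub-hub
#' edges are both more probable and heavier by \code{hubCoreBoost} (via a
#' sqrt-boost on hub-nonhub presence), so a rich-club regime exists by
#' construction; at boost 1 presence is uniform and no rich club is
#' planted.  The non-hub local presence probability is solved so the
#' overall template density matches \code{baseDensity}.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param nodeIds optional node identifiers (default n1..nN).
#' @return list: template (\linkS4class{ConnectomeMatrix}), hubs
#'   (node ids), classPairs (rich/feeder/local pair index lists).
#' @export
generateBaseNetwork <- function(spec, nodeIds = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$nNodes
  if (is.null(nodeIds)) nodeIds <- paste0("n", seq_len(n))
  nh <- round(spec$hubFraction * n)
  b <- spec$hubCoreBoost
  ut <- .upperTri(n)

  withSeed(spec$seed, {
    hubs <- if (nh > 0) sort(sample.int(n, nh)) else integer(0)
    ih <- ut[, "i"] %in% hubs
    jh <- ut[, "j"] %in% hubs
    cls <- ifelse(ih & jh, "rich", ifelse(ih | jh, "feeder", "local"))
    nr <- sum(cls == "rich"); nf <- sum(cls == "feeder")
    nl <- sum(cls == "local")
    # Presence probabilities: hub-hub pairs are strongly densified
    # (factor b^1.5, capped) while hub-nonhub pairs rise only mildly
    # (b^0.25), so hub degrees stay moderate and the hub core is denser
    # than its degrees alone would predict under a degree-preserving
    # null -- a genuine rich club, not just a degree effect.  The local
    # presence p0 is solved so the overall density hits baseDensity.
    fac <- c(rich = b^1.5, feeder = b^0.5, local = 1)[cls]
    target <- spec$baseDensity * nrow(ut)
    dens <- function(p0) sum(pmin(0.92, p0 * fac)) - target
    if (dens(0.92) < 0)
      stop("infeasible density/boost combination")
    p0 <- stats::uniroot(dens, c(1e-6, 0.92), tol = 1e-10)$root
    pvec <- pmin(0.92, p0 * fac)
    present <- stats::runif(nrow(ut)) < pvec
    w <- numeric(nrow(ut))
    w[present] <- stats::rlnorm(sum(present), meanlog = 3, sdlog = 0.8)
    w[present & cls == "rich"] <- w[present & cls == "rich"] * b
    W <- matrix(0, n, n)
    W[ut] <- w
    W <- W + t(W)
    list(template = ConnectomeMatrix(W, nodeIds = nodeIds,
                                     subjectId = "template"),
         hubs = nodeIds[hubs],
         classPairs = split(seq_len(nrow(ut)), cls))
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' Per subject: template weights times the group's per-class effect
#' factors (and the non-hub node factor where configured), times
#' log-normal noise; edge presence flipped at \code{presenceNoise}
#' (existing edges dropped, absent pairs added at a density-scaled rate).
#' Covariates are drawn independent of group unless a confound is
#' injected; HAMD/HAMA scores follow a negative link to the nodal
#' efficiency of two designated hub nodes.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param nodeIds optional node identifiers.
#' @return list: cohort (\linkS4class{CohortDataset}), truth (list with
#'   hubs, affected node, per-class pair indices, effect map, seed).
#' @export
generateCohort <- function(spec, nodeIds = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  base <- generateBaseNetwork(spec, nodeIds = nodeIds)
  tmpl <- base$template
  W0 <- weightMatrix(tmpl)
  ids <- nodeIds(tmpl)
  n <- spec$nNodes
  ut <- .upperTri(n)
  clsPairs <- base$classPairs
  pairClass <- rep("local", nrow(ut))
  for (cl in names(clsPairs)) pairClass[clsPairs[[cl]]] <- cl

  withSeed(spec$seed + 1L, {
    nonHub <- setdiff(ids, base$hubs)
    affectedNode <- if (length(nonHub)) sample(nonHub, 1L) else NA_character_

    groupsOut <- character(0); subjects <- list(); sid <- character(0)
    for (g in names(spec$nPerGroup)) {
      eff <- spec$effectMap[[g]]
      if (is.null(eff)) eff <- list(rich = 1, feeder = 1, local = 1)
      fac <- c(rich = eff$rich %||% 1, feeder = eff$feeder %||% 1,
               local = eff$local %||% 1)[pairClass]
      if (!is.null(eff$node_factor) && !is.na(affectedNode)) {
        touch <- ids[ut[, "i"]] == affectedNode |
          ids[ut[, "j"]] == affectedNode
        fac[touch] <- fac[touch] * eff$node_factor
      }
      w0 <- W0[ut] * fac
      for (s in seq_len(spec$nPerGroup[[g]])) {
        w <- w0
        if (spec$noiseSd > 0)
          w <- w * exp(stats::rnorm(length(w), 0, spec$noiseSd))
        if (spec$presenceNoise > 0) {
          on <- w > 0
          drop <- on & stats::runif(length(w)) < spec$presenceNoise
          add <- !on & stats::runif(length(w)) <
            spec$presenceNoise * spec$baseDensity
          w[drop] <- 0
          w[add] <- stats::rlnorm(sum(add), meanlog = 2, sdlog = 0.5)
        }
        W <- matrix(0, n, n)
        W[ut] <- w
        W <- W + t(W)
        id <- sprintf("%s_%03d", g, s)
        subjects[[length(subjects) + 1L]] <-
          ConnectomeMatrix(W, nodeIds = ids, subjectId = id)
        sid <- c(sid, id)
        groupsOut <- c(groupsOut, g)
      }
    }

    ns <- length(subjects)
    covs <- data.frame(
      age = stats::rnorm(ns, 40, 11),
      sex = stats::rbinom(ns, 1, 0.5),
      education = pmax(0, stats::rnorm(ns, 10, 3.5)),
      gmv = stats::rnorm(ns, 600, 55))
    cf <- spec$confound
    if (!is.null(cf))
      covs[[cf$covariate]] <- covs[[cf$covariate]] +
        cf$shift * (groupsOut == cf$group)

    sm <- spec$scoreModel
    scoreNodes <- if (length(base$hubs) >= 2L) base$hubs[1:2] else ids[1:2]
    neTwo <- vapply(subjects, function(su) {
      nm <- nodalMetrics(suppressWarnings(
        sparsityBinarize(su, sm$sparsity)))
      mean(nm$Ne[match(scoreNodes, nm$node_id)])
    }, numeric(1))
    icept <- sm$intercepts[groupsOut]
    icept[is.na(icept)] <- mean(sm$intercepts)
    hamd <- pmax(0, icept - sm$slope * neTwo +
                   stats::rnorm(ns, 0, sm$noiseSd))
    hama <- pmax(0, 0.55 * (icept - sm$slope * neTwo) +
                   stats::rnorm(ns, 0, sm$noiseSd))
    si <- ifelse(groupsOut == "MDDSI",
                 sample(1:3, ns, replace = TRUE), NA_integer_)
    scoresDf <- data.frame(HAMD = hamd, HAMA = hama, SI_severity = si)

    cohort <- CohortDataset(subjects, group = groupsOut,
                            covariates = covs, scores = scoresDf,
                            subjectIds = sid)
    list(cohort = cohort,
         truth = list(hubs = base$hubs, affected_node = affectedNode,
                      class_pairs = clsPairs, score_nodes = scoreNodes,
                      effect_map = spec$effectMap, seed = spec$seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to disk in the package's input formats
#'
#' Emits one delimited matrix file per subject, a manifest TSV
#' (subject_id, matrix_path, group, covariates, scores) and a node table
#' TSV, exactly the formats \code{\link{readCohort}} consumes; optionally
#' a ground-truth JSON.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth list to serialize as JSON.
#' @return The manifest path, invisibly.
#' @export
writeCohortFiles <- function(cohort, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mdir <- file.path(dir, "matrices")
  dir.create(mdir, showWarnings = FALSE)
  paths <- vapply(cohort@subjects, function(s) {
    p <- file.path("matrices", paste0(s@subjectId, ".tsv"))
    utils::write.table(s@weights, file.path(dir, p), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    p
  }, character(1))
  man <- data.frame(subject_id = cohort@subjectIds, matrix_path = paths,
                    group = cohort@group)
  if (ncol(cohort@covariates)) man <- cbind(man, cohort@covariates)
  if (ncol(cohort@scores)) man <- cbind(man, cohort@scores)
  .writeTsv(man, file.path(dir, "manifest.tsv"))
  ids <- cohort@nodeIds
  n <- length(ids)
  hemi <- rep(c("left", "right"), length.out = n)
  hom <- ids[ifelse(seq_len(n) %% 2 == 1, seq_len(n) + 1, seq_len(n) - 1)]
  hom[seq_len(n) + ifelse(seq_len(n) %% 2 == 1, 1, -1) > n |
        seq_len(n) + ifelse(seq_len(n) %% 2 == 1, 1, -1) < 1] <- NA
  .writeTsv(data.frame(node_id = ids, label = ids, hemisphere = hemi,
                       homologue_id = hom),
            file.path(dir, "nodes.tsv"))
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.tsv"))
}
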
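# End-to-end orchestration: simulate / metrics / richclub / compare /
# nbs / circuits / classify, sharing one config and one seed.

#' Default run configuration
#'
#' Every analysis knob defaults to the study's stated value: streamline
#' filter 3, sparsity sweep 0.05-0.20 step 0.01, 1000 matched random
#' networks, 80\% group-average occurrence, 10000 permutations, NBS edge
#' p 0.01, Bonferroni alpha 0.05, RBF-SVM under LOOCV.  Override any
#' entry via \code{\link{loadRunConfig}} or by editing the returned list;
#' reduce \code{n_random} / \code{n_perm} for quick runs.
#'
#' @return Named list of configuration defaults.
#' @export
runConfigDefaults <- function() {
  list(
    seed = 1L,
    outdir = "richclubnet_run",
    manifest = NULL,            # path to a cohort manifest (NULL: simulate)
    node_table = NULL,          # path to a node table TSV
    circuit_config = NULL,      # NULL: bundled AAL-90 config when N = 90
    synthetic = list(),         # overrides for syntheticSpec()
    min_streamlines = 3,
    s_min = 0.05, s_max = 0.20, step = 0.01,
    occurrence = 0.8,
    n_random = 1000,
    n_perm = 10000,
    p_edge = 0.01,
    alpha = 0.05,
    nodal_sparsity = 0.20,
    contrast = c("MDDSI", "MDDNSI"),
    covariates = c("age", "sex", "education"),
    svm = list(cost = 1, gamma = NULL, filter_alpha = 0.05)
  )
}

#' Load a run configuration
#'
#' Merges a YAML file or list of overrides over
#' \code{\link{runConfigDefaults}} (config file entries win).
#'
#' @param config YAML path, named list of overrides, or NULL.
#' @return Complete configuration list.
#' @export
loadRunConfig <- function(config = NULL) {
  base <- runConfigDefaults()
  if (is.null(config)) return(base)
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  base
}

.stageMsg <- function(stage, t0) {
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

.runStage <- function(stage, expr) {
  t0 <- as.numeric(Sys.time())
  out <- tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
  .stageMsg(stage, t0)
  out
}

# Cohort, filtered subjects and per-subject max-sparsity graphs are
# cached in `state` so stages can run independently or chained.
.stateCohort <- function(state, config) {
  if (!is.null(state$cohort)) return(state$cohort)
  if (is.null(config$manifest))
    stop("no cohort loaded; run the 'simulate' stage or set `manifest`")
  nt <- readNodeTable(config$node_table)
  state$cohort <- readCohort(config$manifest, nt)
  state$cohort
}

.stateFiltered <- function(state, config) {
  if (is.null(state$filtered)) {
    ch <- .stateCohort(state, config)
    state$filtered <- lapply(ch@subjects, streamlineFilter,
                             minStreamlines = config$min_streamlines)
  }
  state$filtered
}

.stateMaxGraphs <- function(state, config) {
  if (is.null(state$maxGraphs))
    state$maxGraphs <- lapply(.stateFiltered(state, config),
                              sparsityBinarize, sparsity = config$s_max)
  state$maxGraphs
}

.stateHubs <- function(state, config) {
  if (!is.null(state$hubs)) return(state$hubs)
  ch <- .stateCohort(state, config)
  graphs <- .stateMaxGraphs(state, config)
  hubsByGroup <- lapply(unique(ch@group), function(g) {
    avg <- groupAverageNetwork(graphs[ch@group == g],
                               occurrence = config$occurrence)
    prof <- richClubProfile(avg, nRandom = config$n_random,
                            seed = config$seed + 11L)
    tryCatch(identifyHubs(avg, prof, kStar = "auto"),
             error = function(e)
               identifyHubs(avg, rule = "meanSD"))
  })
  state$hubs <- Reduce(intersect, hubsByGroup)
  state$avgAll <- groupAverageNetwork(graphs,
                                      occurrence = config$occurrence)
  state$hubs
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order with one config and
#' one seed; every stage writes plain TSV/JSON into \code{outdir} and a
#' run manifest records the full configuration, so identical
#' config + seed reproduce byte-identical outputs.
#'
#' Stages: \code{simulate} (synthetic cohort written in the package's
#' input formats), \code{metrics} (global/nodal metrics over the
#' sparsity sweep with small-world normalization), \code{richclub}
#' (group-average profiles, hubs, edge classes, integrated strengths),
#' \code{compare} (covariate-adjusted permutation tests with Bonferroni
#' node control and score partial correlations), \code{nbs}
#' (network-based statistic for the configured contrast),
#' \code{circuits} (differential edges mapped onto circuit modules),
#' \code{classify} (edge-class and nodal LOOCV-SVM reports).
#'
#' @param config list or YAML path (see \code{\link{loadRunConfig}}).
#' @param stages character vector of stages, or "all".
#' @return The output directory, invisibly.
#' @export
runPipeline <- function(config = NULL, stages = "all") {
  config <- loadRunConfig(config)
  all <- c("simulate", "metrics", "richclub", "compare", "nbs",
           "circuits", "classify")
  if (identical(stages, "all")) stages <- all
  bad <- setdiff(stages, all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- all[all %in% stages]
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())

  if ("simulate" %in% stages) .runStage("simulate", {
    args <- config$synthetic
    args$seed <- config$seed
    spec <- do.call(syntheticSpec, args)
    ids <- NULL
    if (spec$nNodes == 90 && is.null(config$node_table)) {
      nt <- readNodeTable(aalNodeTablePath())
      ids <- nt$node_id
    }
    gen <- generateCohort(spec, nodeIds = ids)
    state$cohort <- gen$cohort
    state$truth <- gen$truth
    writeCohortFiles(gen$cohort, file.path(out, "cohort"),
                     truth = gen$truth)
  })

  if ("metrics" %in% stages) .runStage("metrics", {
    ch <- .stateCohort(state, config)
    filtered <- .stateFiltered(state, config)
    gtab <- list(); ntab <- list(); itab <- list()
    for (k in seq_along(filtered)) {
      sw <- suppressWarnings(
        sparsitySweep(filtered[[k]], config$s_min, config$s_max,
                      config$step))
      gm <- do.call(rbind, lapply(sw@graphs, globalMetrics,
                                  nRandom = config$n_random,
                                  seed = config$seed + 101L + k))
      gm$subject_id <- ch@subjectIds[k]
      gtab[[k]] <- gm
      ntab[[k]] <- nodalMetrics(sparsityBinarize(filtered[[k]],
                                                 config$nodal_sparsity))
      ints <- vapply(c("sigma", "Eg", "Eloc", "Q"), function(m)
        integrateCurve(gm[[m]], step = config$step), numeric(1))
      itab[[k]] <- data.frame(subject_id = ch@subjectIds[k],
                              metric = names(ints), integrated = ints)
    }
    gtab <- do.call(rbind, gtab)
    .writeTsv(gtab, file.path(out, "global_metrics.tsv"))
    .writeTsv(do.call(rbind, ntab), file.path(out, "nodal_metrics.tsv"))
    .writeTsv(do.call(rbind, itab),
              file.path(out, "integrated_global.tsv"))
    sig <- gtab$sigma[gtab$sparsity == max(gtab$sparsity)]
    sw <- smallWorldCheck(sig, ch@subjectIds[
      match(gtab$subject_id[gtab$sparsity == max(gtab$sparsity)],
            ch@subjectIds)])
    jsonlite::write_json(sw, file.path(out, "smallworld_check.json"),
                         auto_unbox = TRUE, digits = NA)
    state$integrated <- do.call(rbind, itab)
  })

  if ("richclub" %in% stages) .runStage("richclub", {
    ch <- .stateCohort(state, config)
    hubs <- .stateHubs(state, config)
    prof <- richClubProfile(state$avgAll, nRandom = config$n_random,
                            seed = config$seed + 21L)
    .writeTsv(phiTable(prof), file.path(out, "richclub_profile.tsv"))
    .writeTsv(data.frame(node_id = hubs),
              file.path(out, "hubs.tsv"))
    dec <- classifyEdges(state$avgAll, hubs)
    .writeTsv(edgeTable(dec), file.path(out, "edge_classes.tsv"))
    filtered <- .stateFiltered(state, config)
    strengths <- do.call(rbind, lapply(seq_along(filtered), function(k) {
      sw <- suppressWarnings(
        sparsitySweep(filtered[[k]], config$s_min, config$s_max,
                      config$step))
      ic <- integratedClassStrengths(filtered[[k]], sw, hubs)
      data.frame(subject_id = ch@subjectIds[k], group = ch@group[k],
                 class = names(ic), integrated_strength = unname(ic))
    }))
    .writeTsv(strengths, file.path(out, "class_strengths.tsv"))
  })

  if ("compare" %in% stages) .runStage("compare", {
    ch <- .stateCohort(state, config)
    covs <- ch@covariates[, intersect(config$covariates,
                                      names(ch@covariates)),
                          drop = FALSE]
    filtered <- .stateFiltered(state, config)
    nodal <- do.call(rbind, lapply(filtered, function(s)
      nodalMetrics(sparsityBinarize(s, config$nodal_sparsity))))
    rows <- list()
    for (metric in c("Ne", "Dc", "Bc")) {
      vals <- matrix(nodal[[metric]], nrow = length(filtered),
                     byrow = TRUE)
      p <- vapply(seq_len(ncol(vals)), function(j) {
        permTest(vals[, j], ch@group, nPerm = config$n_perm,
                 covariates = covs,
                 seed = config$seed + 31L + j)$p_perm
      }, numeric(1))
      sig <- bonferroniNodes(stats::setNames(p, ch@nodeIds),
                             alpha = config$alpha)
      rows[[metric]] <- data.frame(metric = metric,
                                   node_id = ch@nodeIds, p_perm = p,
                                   significant = ch@nodeIds %in% sig)
    }
    .writeTsv(do.call(rbind, rows),
              file.path(out, "nodal_comparisons.tsv"))
    if (ncol(ch@scores)) {
      hubs <- .stateHubs(state, config)
      neMat <- matrix(nodal$Ne, nrow = length(filtered), byrow = TRUE)
      pc <- do.call(rbind, lapply(intersect(c("HAMD", "HAMA"),
                                            names(ch@scores)),
        function(sc) {
          do.call(rbind, lapply(hubs, function(h) {
            r <- partialCorrelation(neMat[, match(h, ch@nodeIds)],
                                    ch@scores[[sc]],
                                    covariates = ch@covariates)
            data.frame(score = sc, node_id = h, metric = "Ne",
                       r = r$r, p = r$p)
          }))
        }))
      .writeTsv(pc, file.path(out, "score_correlations.tsv"))
    }
  })

  if ("nbs" %in% stages) .runStage("nbs", {
    ch <- .stateCohort(state, config)
    covs <- ch@covariates[, intersect(config$covariates,
                                      names(ch@covariates)),
                          drop = FALSE]
    fch <- CohortDataset(.stateFiltered(state, config), ch@group,
                         covariates = covs, scores = ch@scores,
                         subjectIds = ch@subjectIds)
    res <- nbs(fch, contrast = config$contrast, pEdge = config$p_edge,
               nPerm = config$n_perm,
               covariates = names(covs), seed = config$seed + 41L)
    state$nbs <- res
    .writeTsv(edgeTable(res), file.path(out, "nbs_edges.tsv"))
    comp <- if (length(res@components)) do.call(rbind,
      lapply(seq_along(res@components), function(k)
        cbind(component = k, res@components[[k]],
              size = res@componentSizes[k], p_fwe = res@pFwe[k])))
      else data.frame(component = integer(0))
    .writeTsv(comp, file.path(out, "nbs_components.tsv"))
  })

  if ("circuits" %in% stages) .runStage("circuits", {
    ch <- .stateCohort(state, config)
    cfg <- config$circuit_config
    if (is.null(cfg)) {
      if (all(ch@nodeIds %in%
                readNodeTable(aalNodeTablePath())$node_id))
        cfg <- defaultCircuitConfig()
      else stop("no circuit config supplied and node ids are not AAL-90")
    }
    nt <- if (!is.null(config$node_table))
      readNodeTable(config$node_table)
    else data.frame(node_id = ch@nodeIds, label = ch@nodeIds,
                    hemisphere = NA, homologue_id = NA)
    atlas <- loadCircuitAtlas(cfg, nt)
    if (is.null(state$nbs))
      stop("circuits stage needs NBS results; run the 'nbs' stage")
    et <- edgeTable(state$nbs)
    diffEdges <- et[et$supra, c("node_i", "node_j", "stat")]
    mapped <- if (nrow(diffEdges))
      mapEdgesToCircuits(diffEdges, atlas)
    else cbind(diffEdges, circuit = character(0))
    .writeTsv(mapped, file.path(out, "circuit_edges.tsv"))
  })

  if ("classify" %in% stages) .runStage("classify", {
    ch <- .stateCohort(state, config)
    hubs <- .stateHubs(state, config)
    idx <- ch@group %in% config$contrast
    sub <- CohortDataset(ch@subjects[idx], ch@group[idx],
                         covariates = ch@covariates[idx, , drop = FALSE],
                         scores = ch@scores[idx, , drop = FALSE],
                         subjectIds = ch@subjectIds[idx])
    labels <- factor(sub@group, levels = config$contrast)
    reports <- list()
    for (cl in c("rich", "feeder", "local")) {
      X <- edgeFeatureMatrix(sub, hubs, class = cl,
                             sparsity = config$nodal_sparsity)
      if (ncol(X) < 2L) next   # degenerate hub set leaves no features
      reports[[cl]] <- loocvSvm(X, labels, cost = config$svm$cost,
                                gamma = config$svm$gamma,
                                filterAlpha = config$svm$filter_alpha)
    }
    Xn <- nodalFeatureMatrix(sub, sparsity = config$nodal_sparsity,
                             metric = "Ne")
    reports[["nodal_Ne"]] <- loocvSvm(Xn, labels,
                                      cost = config$svm$cost,
                                      gamma = config$svm$gamma,
                                      filterAlpha =
                                        config$svm$filter_alpha)
    summary <- lapply(reports, function(r)
      r[c("accuracy", "sensitivity", "specificity", "auc")])
    jsonlite::write_json(summary,
                         file.path(out, "classification.json"),
                         auto_unbox = TRUE, digits = NA)
    for (nm in names(reports))
      .writeTsv(reports[[nm]]$roc_points,
                file.path(out, paste0("roc_", nm, ".tsv")))
  })

  manifest <- list(package = "richclubnet",
                   version = "0.1.0",
                   stages = stages, config = config)
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
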
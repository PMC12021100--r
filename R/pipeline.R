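#' Run the multi-omics analysis pipeline
#'
#' Chains the analysis stages on a cohort (generated or supplied):
#' `generate`, `stats`, `stratify`, `dpa`, `select`, `drivers`,
#' `network`, `flux`. Each stage writes a `ResultBundle` directory under
#' `outdir` (tabular outputs plus a `provenance.json` with the seed,
#' stage parameters and output digests). Stage dependencies are
#' enforced: `select` needs `stratify`; `drivers` needs `select`;
#' `dpa`/`network`/`flux` need `stratify`.
#'
#' @param config an [AnalysisConfig-class].
#' @param outdir output directory (created).
#' @param cohort optional cohort list as returned by [generateCohort()];
#'   when `NULL`, the `generate` stage is implied.
#' @param stages character vector of stages to run, in any order
#'   (canonical order is enforced).
#' @param spec [cohortSpec()] used when generating.
#' @return named list of stage result objects (invisibly also written
#'   to disk).
#' @export
runPipeline <- function(config = analysisConfig(), outdir,
                        cohort = NULL,
                        stages = c("stats", "stratify", "dpa", "select",
                                   "drivers", "network", "flux"),
                        spec = NULL) {
  canonical <- c("generate", "stats", "stratify", "dpa", "select",
                 "drivers", "network", "flux")
  bad <- setdiff(stages, canonical)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- canonical[canonical %in% stages]
  deps <- list(select = "stratify", drivers = "select", dpa = "stratify",
               network = "stratify", flux = "stratify")
  for (s in stages)
    for (d in deps[[s]])
      if (!d %in% stages)
        stop(sprintf("stage '%s' requires upstream stage '%s'", s, d))
  p <- configParams(config)
  seed <- p$seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  if (is.null(cohort)) {
    if (is.null(spec)) spec <- cohortSpec(seed = seed)
    cohort <- generateCohort(spec)
    if ("generate" %in% stages || TRUE) {
      d <- .bundleDir(outdir, "generate")
      for (nm in names(cohort$layers))
        writeLayer(cohort$layers[[nm]], file.path(d, paste0(nm, ".tsv")))
      writeSampleTable(cohort$samples, file.path(d, "samples.tsv"))
      jsonlite::write_json(cohort$truth[c("drivers", "senescence")],
                           file.path(d, "truth.json"))
      .writeProvenance(d, "generate", seed, spec)
      results$generate <- cohort
    }
  }
  stages <- setdiff(stages, "generate")
  layers <- cohort$layers
  samples <- cohort$samples

  if ("stats" %in% stages) {
    d <- .bundleDir(outdir, "stats")
    tests <- c(hypertension = "categorical", central_obesity = "categorical",
               age = "continuous-nonnormal")
    tests <- tests[names(tests) %in% colnames(covariates(samples))]
    t1 <- buildTableOne(samples, tests = tests)
    utils::write.table(t1, file.path(d, "table_one.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .writeProvenance(d, "stats", seed, tests)
    results$stats <- t1
  }

  assignment <- NULL
  if ("stratify" %in% stages) {
    d <- .bundleDir(outdir, "stratify")
    assignment <- snfStratify(layers, config)
    utils::write.table(
      data.frame(sample_id = sampleIDs(assignment),
                 cluster = clusterLabels(assignment)),
      file.path(d, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(fusedAffinity(assignment),
                       file.path(d, "fused_affinity.tsv"), sep = "\t",
                       quote = FALSE)
    jsonlite::write_json(
      list(k = assignment@k,
           diagnostics = diagnostics(assignment)$diagnostics,
           nmi = as.list(assignment@nmi)),
      file.path(d, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
    .writeProvenance(d, "stratify", seed, p$snf)
    results$stratify <- assignment
  }
  labels <- if (!is.null(assignment)) clusterLabels(assignment) else NULL

  fitP <- NULL
  if ("dpa" %in% stages) {
    d <- .bundleDir(outdir, "dpa")
    design <- makeDesign(samples, labels, model = p$dpa$model)
    fitP <- fitModerated(layers$proteomics, design)
    utils::write.table(fitP, file.path(d, "proteomics_dpa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .writeProvenance(d, "dpa", seed, p$dpa)
    results$dpa <- fitP
  }

  trace <- NULL
  if ("select" %in% stages) {
    d <- .bundleDir(outdir, "select")
    sp <- p$selection
    trace <- consensusSelect(assayValues(layers$proteomics),
                             factor(labels), n_iter = sp$n_iter,
                             subset_size = sp$subset_size,
                             vote = sp$vote,
                             min_support = sp$min_support,
                             seed = seed, rounds = sp$shadow_rounds,
                             num_trees = sp$shadow_trees,
                             alpha = sp$alpha)
    utils::write.table(trace, file.path(d, "selection_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sel <- trace$feature[trace$selected]
    if (length(sel) >= 2L) {
      ev <- finalEvaluate(assayValues(layers$proteomics)[, sel,
                                                         drop = FALSE],
                          factor(labels), seed = seed,
                          mtry_grid = 1:min(15L, length(sel)))
      jsonlite::write_json(
        list(accuracy = ev$accuracy, sensitivity = ev$sensitivity,
             specificity = ev$specificity, oob_error = ev$oob_error,
             mtry = ev$mtry),
        file.path(d, "evaluation.json"), auto_unbox = TRUE, digits = NA)
      results$evaluation <- ev
    }
    .writeProvenance(d, "select", seed, sp)
    results$select <- trace
  }

  if ("drivers" %in% stages) {
    d <- .bundleDir(outdir, "drivers")
    sel <- trace$feature[trace$selected]
    if (length(sel) < 3L)
      stop("stage 'drivers': fewer than 3 selected features from 'select'")
    cons <- consensusDAG(assayValues(layers$proteomics)[, sel,
                                                        drop = FALSE],
                         n_starts = p$bn$n_starts,
                         refine_iters = p$bn$refine_iters,
                         max_parents = p$bn$max_parents, seed = seed)
    ds <- driverScores(cons$dag, assayValues(layers$proteomics)[, sel,
                                                                drop = FALSE])
    utils::write.table(as.data.frame(dagEdges(cons$dag)),
                       file.path(d, "consensus_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ds, file.path(d, "driver_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .writeProvenance(d, "drivers", seed, p$bn)
    results$drivers <- list(dag = cons$dag, scores = ds)
  }

  if ("network" %in% stages) {
    d <- .bundleDir(outdir, "network")
    np <- p$network
    assoc <- consensusAssociations(layers, n_iter = np$n_iter,
                                   per_layer = np$per_layer,
                                   fdr_within = np$fdr_within,
                                   vote = np$vote, seed = seed)
    if (nrow(assoc)) {
      net <- finalizeNetwork(assoc, layers, final_fdr = np$final_fdr,
                             dpa = fitP)
      net <- leidenCommunities(net, min_size = np$min_community,
                               seed = seed)
      writeNetwork(net, file.path(d, "edges.tsv"),
                   graphml = file.path(d, "network.graphml"))
      utils::write.table(communityTable(net),
                         file.path(d, "communities.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      results$network <- net
    } else results$network <- NULL
    .writeProvenance(d, "network", seed, np)
  }

  if ("flux" %in% stages) {
    d <- .bundleDir(outdir, "flux")
    model <- toyMetabolicModel()
    # contexts: scale glucose/tryptophan availability by group means of
    # the first two metabolite features (abstract plasma levels)
    M <- assayValues(layers$metabolomics)
    lv <- function(v) exp(mean(v)) # log-like scale back to positive level
    ctxs <- c("HC-like", "at-risk")
    groups <- groupLabels(samples)[rownames(M)]
    fluxes <- sapply(ctxs, function(gr) {
      lev <- c(glc = lv(M[groups == gr, 1L]),
               trp = lv(M[groups == gr, 2L]))
      cm <- contextualize(model, metabolites = lev, reference = 1)
      fba(cm)$fluxes
    })
    fluxes <- cbind(fluxes, control = fba(model)$fluxes)
    ft <- FluxTable(fluxes, subsystem = model@subsystem,
                    eps = p$flux$flux_eps)
    writeFluxTable(ft, file.path(d, "fluxes.tsv"))
    cmp <- groupSpecificFluxes(ft)
    utils::write.table(cmp, file.path(d, "comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .writeProvenance(d, "flux", seed, p$flux)
    results$flux <- list(table = ft, comparison = cmp)
  }
  invisible(results)
}

.bundleDir <- function(outdir, stage) {
  d <- file.path(outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.writeProvenance <- function(dir, stage, seed, params) {
  files <- setdiff(list.files(dir), "provenance.json")
  digests <- tools::md5sum(file.path(dir, files))
  names(digests) <- files
  jsonlite::write_json(
    list(stage = stage, seed = seed, params = params,
         outputs = as.list(digests)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
}
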
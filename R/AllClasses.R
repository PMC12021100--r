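#' @import methods
NULL

.LAYER_KINDS <- c("transcriptomics", "proteomics", "metabolomics")

#' OmicsLayer: one samples-by-features abundance matrix
#'
#' Container for a single omics data layer. Rows are samples, columns are
#' features; values live on the layer's natural scale (integer counts for
#' transcripts, continuous log-like units for proteins and metabolites).
#'
#' @slot kind one of `"transcriptomics"`, `"proteomics"`, `"metabolomics"`.
#' @slot values numeric matrix, samples x features, with unique dimnames.
#' @slot annotations per-feature annotation `data.frame` (may be empty);
#'   row names are feature identifiers.
#'
#' @seealso [OmicsLayer()], [readLayer()], [varianceFilter()]
#' @export
setClass("OmicsLayer",
  representation(kind = "character", values = "matrix",
                 annotations = "data.frame"),
  prototype(kind = "proteomics",
            values = matrix(numeric(0), 0, 0),
            annotations = data.frame()))

setValidity("OmicsLayer", function(object) {
  msg <- character(0)
  if (length(object@kind) != 1L || !object@kind %in% .LAYER_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(.LAYER_KINDS, collapse = ", ")))
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry sample (row) and feature (column) names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, sprintf("duplicated sample id: %s",
                            rownames(v)[duplicated(rownames(v))][1L]))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, sprintf("duplicated feature id: %s",
                            colnames(v)[duplicated(colnames(v))][1L]))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsLayer
#'
#' @param values numeric matrix (samples x features) with dimnames.
#' @param kind layer kind.
#' @param annotations optional per-feature data.frame.
#' @return an [OmicsLayer-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' OmicsLayer(m, "proteomics")
#' @export
OmicsLayer <- function(values, kind = "proteomics", annotations = NULL) {
  values <- as.matrix(values)
  if (is.null(annotations))
    annotations <- data.frame(row.names = colnames(values))
  new("OmicsLayer", kind = kind, values = values, annotations = annotations)
}

#' SampleTable: sample metadata with optional group labels
#'
#' @slot data `data.frame` of clinical covariates; row names are sample ids.
#' @slot group named character vector of group labels (may be empty);
#'   names must be sample ids present in `data`.
#' @export
setClass("SampleTable",
  representation(data = "data.frame", group = "character"),
  prototype(data = data.frame(), group = character(0)))

setValidity("SampleTable", function(object) {
  msg <- character(0)
  if (anyDuplicated(rownames(object@data)))
    msg <- c(msg, "duplicated sample ids")
  if (length(object@group)) {
    if (is.null(names(object@group)))
      msg <- c(msg, "group labels must be named by sample id")
    else if (!all(names(object@group) %in% rownames(object@data)))
      msg <- c(msg, "group labels refer to unknown sample ids")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SampleTable
#' @param data covariate data.frame with sample ids as row names.
#' @param group optional group labels (character), named by sample id or
#'   aligned with `rownames(data)`.
#' @export
SampleTable <- function(data, group = NULL) {
  if (is.null(group)) group <- character(0)
  else {
    group <- as.character(group)
    if (is.null(names(group))) names(group) <- rownames(data)
  }
  new("SampleTable", data = data, group = group)
}

#' GeneSetCollection: named feature-identifier sets
#'
#' @slot sets named list of character vectors.
#' @slot source provenance tag (e.g. "KEGG-metabolism", "CellAge").
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", source = "character"),
  prototype(sets = list(), source = NA_character_))

setValidity("GeneSetCollection", function(object) {
  msg <- character(0)
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "set names must be present and unique")
    if (any(lengths(object@sets) == 0L))
      msg <- c(msg, "empty sets are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' @param sets named list of character vectors.
#' @param source provenance tag.
#' @rdname GeneSetCollection-class
#' @export
GeneSetCollection <- function(sets, source = NA_character_) {
  new("GeneSetCollection", sets = lapply(sets, as.character), source = source)
}

#' AnalysisConfig: per-stage parameter blocks
#'
#' Holds the tunable parameters of every pipeline stage, with defaults
#' matching the reference analysis (SNF K = 30, alpha = 0.7, T = 20;
#' selection 1000 iterations x 1000-feature subsets at a 0.70 vote;
#' 150 network restarts / 1000 refinement iterations; association network
#' 1000 x 400 at within-iteration FDR < 1e-6, 0.90 vote, final FDR < 5e-5,
#' minimum community size 30; flux epsilon 1e-7, display cut 250).
#'
#' @slot params named list of per-stage blocks.
#' @export
setClass("AnalysisConfig", representation(params = "list"))

.configDefaults <- function() list(
  seed = 1L,
  snf = list(K = 30L, alpha = 0.7, T = 20L, c_range = 2:10,
             var_threshold = 0.2),
  validation = list(train_frac = 0.8, n_splits = 20L),
  dpa = list(fdr = 0.05, enrich_fdr = 0.2, model = 2L),
  selection = list(n_iter = 1000L, subset_size = 1000L, vote = 0.70,
                   min_support = 20L, shadow_rounds = 20L,
                   shadow_trees = 100L, alpha = 0.05),
  bn = list(n_starts = 150L, refine_iters = 1000L, max_parents = 5L),
  network = list(n_iter = 1000L, per_layer = 400L, fdr_within = 1e-6,
                 vote = 0.90, final_fdr = 5e-5, min_community = 30L),
  flux = list(flux_eps = 1e-7, display_cut = 250)
)

setValidity("AnalysisConfig", function(object) {
  p <- object@params
  msg <- character(0)
  frac <- c(p$selection$vote, p$network$vote, p$network$fdr_within,
            p$network$final_fdr, p$dpa$fdr, p$validation$train_frac)
  if (any(frac <= 0 | frac > 1)) msg <- c(msg, "fractional thresholds must lie in (0, 1]")
  iters <- c(p$snf$T, p$selection$n_iter, p$bn$n_starts, p$network$n_iter)
  if (any(iters < 1)) msg <- c(msg, "iteration counts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Build an AnalysisConfig, overriding defaults by stage
#'
#' @param ... named stage blocks (lists) or `seed`; entries replace the
#'   corresponding defaults, e.g. `analysisConfig(snf = list(K = 10))`.
#' @return an [AnalysisConfig-class].
#' @export
analysisConfig <- function(...) {
  params <- .configDefaults()
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(params[[nm]]))
      params[[nm]][names(over[[nm]])] <- over[[nm]]
    else params[[nm]] <- over[[nm]]
  }
  new("AnalysisConfig", params = params)
}

#' ClusterAssignment: stratification labels plus diagnostics
#'
#' @slot labels integer cluster labels named by sample id.
#' @slot k chosen number of clusters.
#' @slot fused fused affinity matrix.
#' @slot diagnostics list with per-candidate `eigengap` and
#'   `rotation_cost`, and the selected values.
#' @slot nmi per-layer normalized mutual information against the fused
#'   clustering (may be empty).
#' @export
setClass("ClusterAssignment",
  representation(labels = "integer", k = "integer", fused = "matrix",
                 diagnostics = "list", nmi = "numeric"),
  prototype(nmi = numeric(0), diagnostics = list()))

setValidity("ClusterAssignment", function(object) {
  msg <- character(0)
  if (length(object@labels)) {
    if (is.null(names(object@labels))) msg <- c(msg, "labels must be named")
    if (!setequal(unique(object@labels), seq_len(object@k)))
      msg <- c(msg, "labels must cover 1..k")
  }
  if (length(msg)) msg else TRUE
})

#' DAGModel: directed acyclic graph with linear-Gaussian node fits
#'
#' @slot nodes node (feature) identifiers.
#' @slot parents named list: per node, character vector of parent nodes.
#' @slot nodeScores per-node decomposable score contributions.
#' @slot score total network score (sum of node scores).
#' @slot n number of observations the model was fitted on.
#' @export
setClass("DAGModel",
  representation(nodes = "character", parents = "list",
                 nodeScores = "numeric", score = "numeric", n = "integer"))

setValidity("DAGModel", function(object) {
  msg <- character(0)
  if (!setequal(names(object@parents), object@nodes))
    msg <- c(msg, "parents list must be named by every node")
  if (.hasCycle(object@parents, object@nodes))
    msg <- c(msg, "graph must be acyclic")
  if (length(object@nodeScores) &&
      is.finite(object@score) &&
      abs(sum(object@nodeScores) - object@score) > 1e-6)
    msg <- c(msg, "total score must equal the sum of node scores")
  if (length(msg)) msg else TRUE
})

#' ConsensusNetwork: weighted feature-feature association graph
#'
#' @slot edges data.frame with columns `from`, `to`, `rho`, `sign`,
#'   `freq`, `fdr`, `polarity`.
#' @slot nodes data.frame with columns `feature`, `layer`, `regulation`.
#' @slot membership integer community id per node (0 = unreported).
#' @slot communities data.frame with `community`, `size`, `mean_degree`.
#' @export
setClass("ConsensusNetwork",
  representation(edges = "data.frame", nodes = "data.frame",
                 membership = "integer", communities = "data.frame"),
  prototype(membership = integer(0), communities = data.frame()))

setValidity("ConsensusNetwork", function(object) {
  msg <- character(0)
  e <- object@edges
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$freq < 0 | e$freq > 1)) msg <- c(msg, "freq must lie in [0,1]")
    if (any(abs(e$rho) > 1 + 1e-12)) msg <- c(msg, "|rho| must be <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' MetabolicModel: stoichiometric model for flux balance analysis
#'
#' @slot mets metabolite ids (compartment-tagged, e.g. `"glc[c]"`).
#' @slot rxns reaction ids.
#' @slot S stoichiometric matrix, metabolites x reactions.
#' @slot lb,ub flux bounds (mmol gDCW^-1 h^-1).
#' @slot obj objective coefficients (biomass reaction = 1).
#' @slot rules gene-reaction rules, simple `and`/`or` expressions.
#' @slot subsystem subsystem label per reaction.
#' @slot exchange logical flag per reaction (boundary exchange/uptake).
#' @slot tasks list of metabolic task definitions, each a list with
#'   `name`, `objective` (reaction id), optional `bounds` overrides and
#'   `min` (required objective value).
#' @export
setClass("MetabolicModel",
  representation(mets = "character", rxns = "character", S = "matrix",
                 lb = "numeric", ub = "numeric", obj = "numeric",
                 rules = "character", subsystem = "character",
                 exchange = "logical", tasks = "list"),
  prototype(tasks = list()))

setValidity("MetabolicModel", function(object) {
  msg <- character(0)
  nr <- length(object@rxns)
  if (ncol(object@S) != nr) msg <- c(msg, "S columns must align with reactions")
  if (nrow(object@S) != length(object@mets))
    msg <- c(msg, "S rows must align with metabolites")
  if (any(object@lb > object@ub)) msg <- c(msg, "lb must be <= ub")
  for (sl in c("lb", "ub", "obj", "rules", "subsystem", "exchange"))
    if (length(slot(object, sl)) != nr)
      msg <- c(msg, sprintf("%s length must equal number of reactions", sl))
  if (sum(object@obj != 0) < 1L) msg <- c(msg, "an objective reaction is required")
  if (length(msg)) msg else TRUE
})

#' FluxTable: reactions x contexts flux values with activity flags
#'
#' @slot fluxes numeric matrix, reactions x contexts.
#' @slot subsystem subsystem label per reaction.
#' @slot eps activity threshold: |v| >= eps counts as active.
#' @export
setClass("FluxTable",
  representation(fluxes = "matrix", subsystem = "character", eps = "numeric"),
  prototype(eps = 1e-7))

setValidity("FluxTable", function(object) {
  msg <- character(0)
  if (length(object@subsystem) &&
      length(object@subsystem) != nrow(object@fluxes))
    msg <- c(msg, "subsystem length must equal number of reactions")
  if (length(msg)) msg else TRUE
})

#' @param fluxes reactions x contexts matrix with dimnames.
#' @param subsystem subsystem label per reaction.
#' @param eps activity threshold.
#' @rdname FluxTable-class
#' @export
FluxTable <- function(fluxes, subsystem = character(0), eps = 1e-7) {
  new("FluxTable", fluxes = as.matrix(fluxes), subsystem = subsystem,
      eps = eps)
}
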
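#' @name accessors
#' @title Accessors for stratomics data classes
#' @description Small generic accessors so user code never touches slots.
#' @param object an object from this package
#' @param x an object from this package
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("featureIDs", function(object) standardGeneric("featureIDs"))
#' @rdname accessors
#' @export
setGeneric("layerKind", function(object) standardGeneric("layerKind"))
#' @rdname accessors
#' @export
setGeneric("assayValues", function(object) standardGeneric("assayValues"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("configParams", function(object) standardGeneric("configParams"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("fusedAffinity", function(object) standardGeneric("fusedAffinity"))
#' @rdname accessors
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))
#' @rdname accessors
#' @export
setGeneric("dagParents", function(object) standardGeneric("dagParents"))
#' @rdname accessors
#' @export
setGeneric("dagEdges", function(object) standardGeneric("dagEdges"))
#' @rdname accessors
#' @export
setGeneric("dagScore", function(object) standardGeneric("dagScore"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("communityTable", function(object) standardGeneric("communityTable"))
#' @rdname accessors
#' @export
setGeneric("fluxValues", function(object) standardGeneric("fluxValues"))
#' @rdname accessors
#' @export
setGeneric("activityFlags", function(object) standardGeneric("activityFlags"))
#' @rdname accessors
#' @export
setGeneric("reactionIDs", function(object) standardGeneric("reactionIDs"))

#' @rdname accessors
setMethod("sampleIDs", "OmicsLayer", function(object) rownames(object@values))
#' @rdname accessors
setMethod("featureIDs", "OmicsLayer", function(object) colnames(object@values))
#' @rdname accessors
setMethod("layerKind", "OmicsLayer", function(object) object@kind)
#' @rdname accessors
setMethod("assayValues", "OmicsLayer", function(object) object@values)

#' @rdname accessors
setMethod("sampleIDs", "SampleTable", function(object) rownames(object@data))
#' @rdname accessors
setMethod("groupLabels", "SampleTable", function(object) object@group)
#' @rdname accessors
setMethod("covariates", "SampleTable", function(object) object@data)

#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)
#' @rdname accessors
setMethod("featureIDs", "GeneSetCollection",
          function(object) unique(unlist(object@sets, use.names = FALSE)))

#' @rdname accessors
setMethod("configParams", "AnalysisConfig", function(object) object@params)

#' @rdname accessors
setMethod("sampleIDs", "ClusterAssignment", function(object) names(object@labels))
#' @rdname accessors
setMethod("clusterLabels", "ClusterAssignment", function(object) object@labels)
#' @rdname accessors
setMethod("fusedAffinity", "ClusterAssignment", function(object) object@fused)
#' @rdname accessors
setMethod("diagnostics", "ClusterAssignment", function(object) object@diagnostics)

#' @rdname accessors
setMethod("dagParents", "DAGModel", function(object) object@parents)
#' @rdname accessors
setMethod("dagScore", "DAGModel", function(object) object@score)
#' @rdname accessors
setMethod("dagEdges", "DAGModel", function(object) {
  ps <- object@parents
  from <- unlist(ps, use.names = FALSE)
  to <- rep(names(ps), lengths(ps))
  cbind(from = from, to = to)
})

#' @rdname accessors
setMethod("networkEdges", "ConsensusNetwork", function(object) object@edges)
#' @rdname accessors
setMethod("networkNodes", "ConsensusNetwork", function(object) object@nodes)
#' @rdname accessors
setMethod("communityTable", "ConsensusNetwork", function(object) object@communities)

#' @rdname accessors
setMethod("fluxValues", "FluxTable", function(object) object@fluxes)
#' @rdname accessors
setMethod("reactionIDs", "FluxTable", function(object) rownames(object@fluxes))
#' @rdname accessors
setMethod("activityFlags", "FluxTable",
          function(object) abs(object@fluxes) >= object@eps)
#' @rdname accessors
setMethod("reactionIDs", "MetabolicModel", function(object) object@rxns)

#' @describeIn accessors number of samples in a layer
#' @export
setMethod("dim", "OmicsLayer", function(x) dim(x@values))

setMethod("show", "OmicsLayer", function(object) {
  cat(sprintf("OmicsLayer [%s]: %d samples x %d features\n", object@kind,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "SampleTable", function(object) {
  cat(sprintf("SampleTable: %d samples, %d covariates", nrow(object@data),
              ncol(object@data)))
  if (length(object@group)) {
    tb <- table(object@group)
    cat(sprintf("; groups: %s",
                paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  }
  cat("\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection [%s]: %d sets (sizes %s)\n", object@source,
              length(object@sets),
              paste(range(lengths(object@sets)), collapse = "-")))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig with stages:",
      paste(setdiff(names(object@params), "seed"), collapse = ", "),
      sprintf("(seed %d)\n", object@params$seed))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d samples in %d clusters (%s)\n",
              length(object@labels), object@k,
              paste(table(object@labels), collapse = "/")))
})

setMethod("show", "DAGModel", function(object) {
  cat(sprintf("DAGModel: %d nodes, %d edges, score %.3f (n = %d)\n",
              length(object@nodes), sum(lengths(object@parents)),
              object@score, object@n))
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat(sprintf("ConsensusNetwork: %d nodes, %d edges", nrow(object@nodes),
              nrow(object@edges)))
  if (nrow(object@communities))
    cat(sprintf(", %d reported communities", nrow(object@communities)))
  cat("\n")
})

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel: %d metabolites x %d reactions, objective '%s'\n",
              length(object@mets), length(object@rxns),
              object@rxns[which(object@obj != 0)[1L]]))
})

setMethod("show", "FluxTable", function(object) {
  cat(sprintf("FluxTable: %d reactions x %d contexts (eps = %g)\n",
              nrow(object@fluxes), ncol(object@fluxes), object@eps))
})
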
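#' Read an omics layer from a delimited text matrix
#'
#' Expects sample identifiers in the first column and feature identifiers
#' in the header row; use `orientation = "features"` when the file stores
#' features in rows. Missing values may be empty or `NA`. All-missing rows
#' and columns are dropped with a message.
#'
#' @param path file path.
#' @param kind layer kind (`"transcriptomics"`, `"proteomics"`,
#'   `"metabolomics"`).
#' @param sep field separator; tab by default, `","` accepted.
#' @param orientation `"samples"` (default, samples in rows) or
#'   `"features"`.
#' @return an [OmicsLayer-class].
#' @export
readLayer <- function(path, kind = "proteomics", sep = "\t",
                      orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, row.names = NULL,
                          colClasses = "character",
                          na.strings = c("", "NA"), quote = "")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated ", if (orientation == "samples") "sample" else "feature",
         " id: ", ids[duplicated(ids)][1L])
  hdr <- colnames(df)[-1L]
  if (anyDuplicated(hdr))
    stop("duplicated ", if (orientation == "samples") "feature" else "sample",
         " id: ", hdr[duplicated(hdr)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m)))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 m[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                 hdr[bad[1L, 2L]]))
  dimnames(num) <- list(ids, hdr)
  if (orientation == "features") num <- t(num)
  dropR <- rowSums(!is.na(num)) == 0L
  dropC <- colSums(!is.na(num)) == 0L
  if (any(dropR) || any(dropC))
    message(sprintf("dropped %d all-missing sample(s) and %d all-missing feature(s)",
                    sum(dropR), sum(dropC)))
  OmicsLayer(num[!dropR, !dropC, drop = FALSE], kind = kind)
}

#' Write an omics layer as tab-delimited text (samples in rows)
#' @param layer an [OmicsLayer-class].
#' @param path output path.
#' @param sep field separator.
#' @export
writeLayer <- function(layer, path, sep = "\t") {
  m <- assayValues(layer)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimum-impute missing values per feature
#'
#' Replaces missing entries of each feature with that feature's observed
#' minimum (the convention of minimum-imputed metabolomics pipelines).
#' Features missing everywhere are dropped.
#'
#' @param layer an [OmicsLayer-class].
#' @return imputed [OmicsLayer-class]; number of imputed cells is logged
#'   via `message()`.
#' @export
imputeMinimum <- function(layer) {
  m <- assayValues(layer)
  nimp <- sum(is.na(m))
  if (nimp > 0) {
    keep <- colSums(!is.na(m)) > 0L
    m <- m[, keep, drop = FALSE]
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- min(m[, j], na.rm = TRUE)
    }
    message(sprintf("minimum-imputed %d missing value(s) in %s layer",
                    nimp, layerKind(layer)))
  }
  OmicsLayer(m, kind = layerKind(layer), annotations = layer@annotations)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Membership is preserved exactly as given.
#'
#' @param path GMT file path.
#' @param source provenance tag stored on the collection.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path, source = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); at least 3 required",
                   i, length(f)))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("GMT line %d: empty member list", i))
    sets[[f[1L]]] <- members
  }
  GeneSetCollection(sets, source = source)
}

#' Write a GeneSetCollection to GMT
#' @param gsc a [GeneSetCollection-class].
#' @param path output path.
#' @param description description field (recycled).
#' @export
writeGMT <- function(gsc, path, description = "na") {
  sets <- geneSets(gsc)
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a sample metadata table
#'
#' Tab-delimited with sample ids in the first column; an optional `group`
#' column becomes the group label.
#' @param path file path.
#' @param sep separator.
#' @return a [SampleTable-class].
#' @export
readSampleTable <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), quote = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated sample id: ",
                               ids[duplicated(ids)][1L])
  df <- df[, -1L, drop = FALSE]
  rownames(df) <- ids
  group <- NULL
  if ("group" %in% colnames(df)) {
    group <- stats::setNames(as.character(df$group), ids)
    df$group <- NULL
  }
  SampleTable(df, group = group)
}

#' @param st a [SampleTable-class].
#' @rdname readSampleTable
#' @export
writeSampleTable <- function(st, path, sep = "\t") {
  df <- covariates(st)
  out <- data.frame(sample_id = rownames(df), df, check.names = FALSE)
  g <- groupLabels(st)
  if (length(g)) out$group <- g[rownames(df)]
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Unknown keys are rejected; provided keys override stage defaults.
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return an [AnalysisConfig-class].
#' @export
readConfig <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(.configDefaults())
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  do.call(analysisConfig, raw)
}

#' Serialize a consensus network
#'
#' Writes both an edge-list TSV (`source`, `target`, `weight`, `sign`,
#' `frequency`, `community`) and, when `graphml` is given, a GraphML file.
#'
#' @param net a [ConsensusNetwork-class].
#' @param path edge-list TSV path.
#' @param graphml optional GraphML path.
#' @export
writeNetwork <- function(net, path, graphml = NULL) {
  e <- networkEdges(net)
  memb <- net@membership
  comm <- if (length(memb)) {
    ec <- ifelse(memb[e$from] == memb[e$to], memb[e$from], 0L)
    as.integer(ec)
  } else rep(NA_integer_, nrow(e))
  out <- data.frame(source = e$from, target = e$to, weight = e$rho,
                    sign = e$sign, frequency = e$freq, community = comm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    g <- .networkToIgraph(net)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' Read a consensus network edge list written by [writeNetwork()]
#' @param path edge-list TSV path.
#' @return a [ConsensusNetwork-class] (nodes reconstructed from edges).
#' @export
readNetwork <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  edges <- data.frame(from = df$source, to = df$target, rho = df$weight,
                      sign = df$sign, freq = df$frequency,
                      fdr = if ("fdr" %in% names(df)) df$fdr else NA_real_,
                      polarity = ifelse(df$weight >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  feats <- unique(c(edges$from, edges$to))
  nodes <- data.frame(feature = feats, layer = NA_character_,
                      regulation = NA_character_, stringsAsFactors = FALSE)
  memb <- integer(0)
  if ("community" %in% names(df) && !all(is.na(df$community))) {
    memb <- stats::setNames(rep(0L, length(feats)), feats)
    ok <- !is.na(df$community) & df$community > 0L
    memb[df$source[ok]] <- as.integer(df$community[ok])
    memb[df$target[ok]] <- as.integer(df$community[ok])
  }
  new("ConsensusNetwork", edges = edges, nodes = nodes, membership = memb,
      communities = data.frame())
}

.networkToIgraph <- function(net) {
  e <- networkEdges(net)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to, weight = abs(e$rho), rho = e$rho,
               sign = e$sign, freq = e$freq),
    directed = FALSE, vertices = networkNodes(net)$feature)
  if (length(net@membership))
    igraph::V(g)$community <- as.integer(net@membership[igraph::V(g)$name])
  g
}

#' Read/write a flux table (reactions x contexts TSV)
#' @param ft a [FluxTable-class].
#' @param path file path.
#' @export
writeFluxTable <- function(ft, path) {
  m <- fluxValues(ft)
  df <- data.frame(reaction = rownames(m),
                   subsystem = if (length(ft@subsystem)) ft@subsystem else NA,
                   m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param eps activity threshold stored on the reloaded table.
#' @rdname writeFluxTable
#' @export
readFluxTable <- function(path, eps = 1e-7) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  m <- as.matrix(df[, setdiff(colnames(df), c("reaction", "subsystem")),
                    drop = FALSE])
  rownames(m) <- df$reaction
  FluxTable(m, subsystem = if ("subsystem" %in% names(df))
    as.character(df$subsystem) else character(0), eps = eps)
}
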
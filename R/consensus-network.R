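#' Resampled Spearman consensus associations across omics layers
#'
#' Per iteration, `per_layer` features are sampled from each layer,
#' pooled, and all pairwise Spearman correlations computed (average
#' ranks for ties; p by the t approximation); pairs with
#' within-iteration BH FDR below `fdr_within` are recorded. A pair's
#' consensus frequency is the fraction of iterations in which both
#' members were co-sampled that found it significant; pairs reaching
#' `vote` are kept.
#'
#' @param layers named list of [OmicsLayer-class] with aligned samples.
#' @param n_iter iterations (default 1000).
#' @param per_layer features sampled per layer (default 400; capped at
#'   the layer's feature count with a warning).
#' @param fdr_within within-iteration FDR threshold (default 1e-6).
#' @param vote consensus frequency threshold (default 0.90).
#' @param seed integer seed.
#' @return `AssociationEdge` data.frame: from, to, freq, n_sig,
#'   n_cosampled.
#' @export
consensusAssociations <- function(layers, n_iter = 1000L, per_layer = 400L,
                                  fdr_within = 1e-6, vote = 0.90,
                                  seed = 1L) {
  mats <- lapply(layers, function(l)
    if (is(l, "OmicsLayer")) assayValues(l) else as.matrix(l))
  ids <- rownames(mats[[1L]])
  n <- length(ids)
  if (n < 5L) stop("need at least 5 samples for rank correlation")
  for (m in mats) if (!identical(rownames(m), ids))
    stop("sample mismatch across layers")
  sizes <- vapply(mats, ncol, integer(1))
  take <- pmin(per_layer, sizes)
  if (any(take < per_layer))
    warning("per_layer capped at layer feature count for: ",
            paste(names(mats)[take < per_layer], collapse = ", "))
  set.seed(seed)
  sampledSets <- vector("list", n_iter)
  sigPairs <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    cols <- unlist(lapply(seq_along(mats), function(v)
      colnames(mats[[v]])[sample.int(sizes[v], take[v])]))
    pool <- do.call(cbind, lapply(seq_along(mats), function(v)
      mats[[v]][, intersect(cols, colnames(mats[[v]])), drop = FALSE]))
    rho <- stats::cor(pool, method = "spearman")
    ut <- upper.tri(rho)
    pv <- .spearmanP(rho[ut], n)
    fdr <- stats::p.adjust(pv, method = "BH")
    hit <- which(ut, arr.ind = TRUE)[fdr < fdr_within, , drop = FALSE]
    sampledSets[[it]] <- cols
    sigPairs[[it]] <- .pairKey(colnames(pool)[hit[, 1L]],
                               colnames(pool)[hit[, 2L]])
  }
  cand <- unique(unlist(sigPairs))
  if (!length(cand))
    return(data.frame(from = character(0), to = character(0),
                      freq = numeric(0), n_sig = integer(0),
                      n_cosampled = integer(0)))
  nsig <- table(factor(unlist(sigPairs), levels = cand))
  parts <- strsplit(cand, "\r", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1L)
  b <- vapply(parts, `[`, character(1), 2L)
  ncos <- integer(length(cand))
  for (it in seq_len(n_iter)) {
    inIt <- a %in% sampledSets[[it]] & b %in% sampledSets[[it]]
    ncos <- ncos + inIt
  }
  freq <- as.integer(nsig) / pmax(ncos, 1L)
  out <- data.frame(from = a, to = b, freq = freq,
                    n_sig = as.integer(nsig), n_cosampled = ncos,
                    row.names = NULL)
  out[out$freq >= vote, , drop = FALSE]
}

#' Finalize the consensus network at a stricter full-data FDR
#'
#' Recomputes Spearman correlations of the consensus pairs on the full
#' data, applies a global BH adjustment, keeps pairs below `final_fdr`,
#' and splits them by sign into positive and negative subnetworks. Nodes
#' are layer-tagged and, when differential-abundance results are given,
#' flagged up/down.
#'
#' @param assoc `AssociationEdge` data.frame from
#'   [consensusAssociations()].
#' @param layers named list of [OmicsLayer-class].
#' @param final_fdr full-data FDR threshold (default 5e-5).
#' @param dpa optional `ModeratedFit` (or data.frame with `feature`,
#'   `t`, `fdr`) used for regulation flags.
#' @param dpa_fdr significance cut for the regulation flag.
#' @return a [ConsensusNetwork-class].
#' @export
finalizeNetwork <- function(assoc, layers, final_fdr = 5e-5, dpa = NULL,
                            dpa_fdr = 0.05) {
  if (!nrow(assoc)) stop("no consensus edges to finalize")
  mats <- lapply(layers, function(l)
    if (is(l, "OmicsLayer")) assayValues(l) else as.matrix(l))
  pool <- do.call(cbind, mats)
  n <- nrow(pool)
  rho <- vapply(seq_len(nrow(assoc)), function(k)
    stats::cor(pool[, assoc$from[k]], pool[, assoc$to[k]],
               method = "spearman"), numeric(1))
  pv <- .spearmanP(rho, n)
  fdr <- bhAdjust(pv)
  keep <- fdr < final_fdr
  if (!any(keep)) warning("all consensus edges filtered at final FDR")
  edges <- data.frame(from = assoc$from[keep], to = assoc$to[keep],
                      rho = rho[keep],
                      sign = ifelse(rho[keep] >= 0, 1L, -1L),
                      freq = assoc$freq[keep], fdr = fdr[keep],
                      polarity = ifelse(rho[keep] >= 0, "positive",
                                        "negative"),
                      stringsAsFactors = FALSE)
  feats <- unique(c(edges$from, edges$to))
  layerOf <- stats::setNames(rep(names(mats), vapply(mats, ncol, integer(1))),
                             unlist(lapply(mats, colnames)))
  reg <- stats::setNames(rep("none", length(feats)), feats)
  if (!is.null(dpa)) {
    sig <- dpa$fdr < dpa_fdr
    up <- dpa$feature[sig & dpa$t > 0]
    dn <- dpa$feature[sig & dpa$t < 0]
    reg[feats %in% up] <- "up"
    reg[feats %in% dn] <- "down"
  }
  nodes <- data.frame(feature = feats,
                      layer = unname(layerOf[feats]),
                      regulation = unname(reg), stringsAsFactors = FALSE)
  new("ConsensusNetwork", edges = edges, nodes = nodes,
      membership = integer(0), communities = data.frame())
}

#' Compare a network's topology to size-matched random graphs
#'
#' Density, global clustering coefficient and degree-distribution
#' summary against 100 Erdos-Renyi graphs with identical node and edge
#' counts; z-scores are reported (density z is 0 by construction).
#'
#' @param net a [ConsensusNetwork-class] or igraph object.
#' @param n_random number of random graphs.
#' @param seed integer seed.
#' @return list of observed metrics and z-scores.
#' @export
compareToRandom <- function(net, n_random = 100L, seed = 1L) {
  g <- if (is(net, "ConsensusNetwork")) .networkToIgraph(net) else net
  nv <- igraph::vcount(g); ne <- igraph::ecount(g)
  if (nv < 10L) stop("need at least 10 nodes")
  obs <- list(density = igraph::edge_density(g),
              clustering = igraph::transitivity(g, type = "global"),
              mean_degree = mean(igraph::degree(g)),
              sd_degree = stats::sd(igraph::degree(g)))
  set.seed(seed)
  rnd <- replicate(n_random, {
    r <- igraph::sample_gnm(nv, ne)
    c(clustering = igraph::transitivity(r, type = "global"),
      sd_degree = stats::sd(igraph::degree(r)))
  })
  z <- function(x, v) (x - mean(v, na.rm = TRUE)) /
    max(stats::sd(v, na.rm = TRUE), 1e-12)
  list(observed = obs,
       z_clustering = z(obs$clustering, rnd["clustering", ]),
       z_sd_degree = z(obs$sd_degree, rnd["sd_degree", ]),
       z_density = 0)
}

#' Leiden community detection with mean-degree centrality
#'
#' Modularity-optimizing Leiden partition (resolution 1, seeded);
#' communities with more than `min_size` members are reported with their
#' mean within-community degree, and the community with the largest mean
#' degree is flagged most central.
#'
#' @param net a [ConsensusNetwork-class].
#' @param min_size strict size threshold: only communities with *more*
#'   than this many features are reported (default 30).
#' @param seed integer seed.
#' @return the input network with `membership` (0 for members of
#'   unreported communities) and a `communities` table; the most central
#'   community id is attached as attribute `"most_central"` of the table.
#' @export
leidenCommunities <- function(net, min_size = 30L, seed = 1L) {
  if (!nrow(networkEdges(net))) {
    net@membership <- integer(0)
    net@communities <- data.frame()
    return(net)
  }
  g <- .networkToIgraph(net)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = 1, n_iterations = 5L)
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  reported <- as.integer(names(sizes)[sizes > min_size])
  rows <- lapply(reported, function(cid) {
    vs <- names(memb)[memb == cid]
    sub <- igraph::induced_subgraph(g, vs)
    data.frame(community = cid, size = length(vs),
               mean_degree = mean(igraph::degree(sub)))
  })
  commTab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(community = integer(0), size = integer(0),
               mean_degree = numeric(0))
  out <- stats::setNames(as.integer(memb), names(memb))
  out[!out %in% reported] <- 0L
  if (nrow(commTab))
    attr(commTab, "most_central") <-
      commTab$community[which.max(commTab$mean_degree)]
  net@membership <- out
  net@communities <- commTab
  net
}

#' Senescence-marker overlay on the most central community
#'
#' The senescence-associated protein (SAP) universe is the union of the
#' collection's sources intersected with the measured proteins;
#' significant SAP are those below the differential-abundance FDR cut.
#' Reports how many significant SAP fall inside the most central
#' community.
#'
#' @param dpa `ModeratedFit` results for the protein layer.
#' @param gsc senescence [GeneSetCollection-class] (e.g. CellAge, CSgene,
#'   SASP sources).
#' @param net a [ConsensusNetwork-class] with communities assigned.
#' @param fdr significance threshold (default 0.05).
#' @return list: sap_universe, significant, n_in, n_out, fraction
#'   (NA when no SAP is significant), central_community.
#' @export
senescenceOverlay <- function(dpa, gsc, net, fdr = 0.05) {
  measured <- dpa$feature
  sap <- intersect(featureIDs(gsc), measured)
  if (!length(sap)) stop("no senescence-annotated protein was measured")
  sig <- intersect(sap, dpa$feature[dpa$fdr < fdr])
  commTab <- communityTable(net)
  central <- attr(commTab, "most_central")
  if (is.null(central)) stop("network has no reported communities")
  members <- names(net@membership)[net@membership == central]
  nin <- length(intersect(sig, members))
  nout <- length(sig) - nin
  list(sap_universe = sap, significant = sig, n_in = nin, n_out = nout,
       fraction = if (length(sig)) nin / length(sig) else NA_real_,
       central_community = central)
}

#' Hierarchical clustering retention check on senescence markers
#'
#' Z-scores the given senescence-associated features, clusters samples
#' (Euclidean distance, Ward linkage), cuts at two, and reports the
#' adjusted Rand index against the stratification labels.
#'
#' @param layer protein [OmicsLayer-class].
#' @param features senescence-associated feature ids.
#' @param labels named stratification labels.
#' @return list: `order` (dendrogram leaf order), `cut2` (2-cut labels),
#'   `ari`.
#' @export
sapHCA <- function(layer, features, labels) {
  m <- assayValues(layer)
  features <- intersect(features, colnames(m))
  if (length(features) < 2L) stop("need at least 2 senescence features")
  if (nrow(m) < 3L) stop("need at least 3 samples")
  z <- .zscore(m[, features, drop = FALSE], strict = FALSE)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cut2 <- stats::cutree(hc, k = 2L)
  list(order = hc$order, cut2 = cut2,
       ari = mclust::adjustedRandIndex(cut2[names(labels)], labels))
}
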
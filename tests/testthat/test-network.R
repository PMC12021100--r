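blockLayers <- function(n = 158, seed = 1) {
  # 12 features in two 4-feature correlated blocks plus 4 noise features
  set.seed(seed)
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function(f, k) sapply(seq_len(k), function(i)
    0.95 * f + sqrt(1 - 0.95^2) * rnorm(n))
  m <- cbind(mk(f1, 4), mk(f2, 4), matrix(rnorm(n * 4), n))
  dimnames(m) <- list(sprintf("s%03d", 1:n), sprintf("b%02d", 1:12))
  OmicsLayer(m, "proteomics")
}

test_that("degenerate consensus equals one full all-pairs pass", {
  lay <- blockLayers(seed = 61)
  assoc <- consensusAssociations(list(p = lay), n_iter = 1,
                                 per_layer = 12, fdr_within = 1e-6,
                                 vote = 0.9, seed = 1)
  # brute-force oracle: all-pairs Spearman + BH at the same threshold
  m <- assayValues(lay)
  rho <- cor(m, method = "spearman")
  ut <- upper.tri(rho)
  tstat <- rho[ut] * sqrt((nrow(m) - 2) / (1 - rho[ut]^2))
  pv <- 2 * pt(-abs(tstat), df = nrow(m) - 2)
  fdr <- p.adjust(pv, "BH")
  idx <- which(ut, arr.ind = TRUE)
  ref <- sort(paste(pmin(rownames(rho)[idx[, 1]], colnames(rho)[idx[, 2]]),
                    pmax(rownames(rho)[idx[, 1]], colnames(rho)[idx[, 2]]))[
                      fdr < 1e-6])
  got <- sort(paste(pmin(assoc$from, assoc$to), pmax(assoc$from, assoc$to)))
  expect_identical(got, ref)
  expect_true(all(assoc$freq == 1))
})

test_that("resampled consensus recovers the all-pairs edge set", {
  lay <- blockLayers(seed = 62)
  full <- consensusAssociations(list(p = lay), n_iter = 1, per_layer = 12,
                                fdr_within = 1e-6, vote = 0.9, seed = 1)
  sub <- consensusAssociations(list(p = lay), n_iter = 150, per_layer = 8,
                               fdr_within = 1e-6, vote = 0.9, seed = 2)
  key <- function(a) sort(paste(pmin(a$from, a$to), pmax(a$from, a$to)))
  expect_identical(key(sub), key(full))
})

test_that("a duplicated feature pair reaches consensus frequency 1", {
  set.seed(63)
  n <- 60
  x <- rnorm(n)
  m <- cbind(dup1 = x, dup2 = x, noise = rnorm(n))
  rownames(m) <- sprintf("s%03d", 1:n)
  assoc <- consensusAssociations(list(p = OmicsLayer(m)), n_iter = 20,
                                 per_layer = 3, fdr_within = 1e-6,
                                 vote = 0.9, seed = 3)
  dup <- assoc[assoc$from == "dup1" & assoc$to == "dup2", ]
  expect_identical(nrow(dup), 1L)
  expect_equal(dup$freq, 1)
  expect_error(consensusAssociations(list(p = OmicsLayer(m[1:3, ]))),
               "5 samples")
})

test_that("finalized networks route by sign and only ever shrink", {
  set.seed(64)
  n <- 100
  x <- rnorm(n)
  m <- cbind(a = x, b = x + rnorm(n, sd = 0.1),
             c = -x + rnorm(n, sd = 0.1), d = rnorm(n))
  rownames(m) <- sprintf("s%03d", 1:n)
  lay <- OmicsLayer(m)
  assoc <- consensusAssociations(list(p = lay), n_iter = 1, per_layer = 4,
                                 fdr_within = 1e-3, vote = 0.9, seed = 1)
  net <- finalizeNetwork(assoc, list(p = lay), final_fdr = 1e-6)
  e <- networkEdges(net)
  expect_lte(nrow(e), nrow(assoc))
  ab <- e[(e$from == "a" & e$to == "b") | (e$from == "b" & e$to == "a"), ]
  ac <- e[(e$from == "a" & e$to == "c") | (e$from == "c" & e$to == "a"), ]
  expect_identical(ab$polarity, "positive")
  expect_identical(ac$polarity, "negative")
  expect_true(all(networkNodes(net)$layer == "p"))
})

test_that("clique fixtures expose community structure and centrality", {
  cliqueEdges <- function(members, rho = 0.9) {
    cmb <- t(combn(members, 2))
    data.frame(from = cmb[, 1], to = cmb[, 2], rho = rho, sign = 1L,
               freq = 1, fdr = 0, polarity = "positive")
  }
  e <- rbind(cliqueEdges(sprintf("a%02d", 1:40)),
             cliqueEdges(sprintf("b%02d", 1:40)))
  feats <- unique(c(e$from, e$to))
  net <- new("ConsensusNetwork", edges = e,
             nodes = data.frame(feature = feats, layer = "p",
                                regulation = "none"),
             membership = integer(0), communities = data.frame())
  out <- leidenCommunities(net, min_size = 30, seed = 1)
  tab <- communityTable(out)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$size, c(40L, 40L))
  expect_equal(tab$mean_degree, c(39, 39))
  memb <- out@membership
  expect_identical(length(unique(memb[sprintf("a%02d", 1:40)])), 1L)
  # strict threshold: a 31-clique is reported, a 30-clique is dropped
  e31 <- cliqueEdges(sprintf("c%02d", 1:31))
  net31 <- new("ConsensusNetwork", edges = e31,
               nodes = data.frame(feature = unique(c(e31$from, e31$to)),
                                  layer = "p", regulation = "none"),
               membership = integer(0), communities = data.frame())
  t31 <- communityTable(leidenCommunities(net31, min_size = 30, seed = 1))
  expect_identical(t31$size, 31L)
  expect_equal(t31$mean_degree, 30)
  e30 <- cliqueEdges(sprintf("d%02d", 1:30))
  net30 <- new("ConsensusNetwork", edges = e30,
               nodes = data.frame(feature = unique(c(e30$from, e30$to)),
                                  layer = "p", regulation = "none"),
               membership = integer(0), communities = data.frame())
  t30 <- communityTable(leidenCommunities(net30, min_size = 30, seed = 1))
  expect_identical(nrow(t30), 0L)
})

test_that("random-graph comparison separates cliquish from ER topology", {
  set.seed(65)
  g <- igraph::sample_gnm(60, 180)
  cmp <- compareToRandom(g, n_random = 60, seed = 1)
  expect_lt(abs(cmp$z_clustering), 2.5)
  expect_identical(cmp$z_density, 0)
  gg <- igraph::disjoint_union(igraph::make_full_graph(20),
                               igraph::make_full_graph(20))
  cmp2 <- compareToRandom(gg, n_random = 60, seed = 1)
  expect_gt(cmp2$z_clustering, 3)
})

test_that("senescence overlay counts SAP membership in the hub community", {
  # constructed fixture: 105 significant SAP, 85 inside the central
  # community
  sap <- sprintf("P%03d", 1:120)
  dpa <- data.frame(feature = sprintf("P%03d", 1:150),
                    t = 2, fdr = c(rep(0.001, 105), rep(0.5, 45)))
  gsc <- GeneSetCollection(list(CellAge = sap[1:80],
                                CSgene = sap[40:120],
                                SASP = sap[100:120]))
  memb <- setNames(rep(2L, 150), sprintf("P%03d", 1:150))
  memb[sprintf("P%03d", 1:85)] <- 1L
  commTab <- data.frame(community = c(1L, 2L), size = c(85L, 65L),
                        mean_degree = c(36, 4))
  attr(commTab, "most_central") <- 1L
  net <- new("ConsensusNetwork",
             edges = data.frame(from = "P001", to = "P002", rho = 0.9,
                                sign = 1L, freq = 1, fdr = 0,
                                polarity = "positive"),
             nodes = data.frame(feature = names(memb), layer = "p",
                                regulation = "none"),
             membership = memb, communities = commTab)
  ov <- senescenceOverlay(dpa, gsc, net, fdr = 0.05)
  expect_identical(length(ov$significant), 105L)
  expect_identical(ov$n_in, 85L)
  expect_equal(ov$fraction, 85 / 105, tolerance = 1e-12)
  expect_equal(round(ov$fraction, 2), 0.81)
  # empty significant set reports NA
  dpa0 <- transform(dpa, fdr = 0.9)
  expect_true(is.na(senescenceOverlay(dpa0, gsc, net)$fraction))
})

test_that("SAP hierarchical clustering retains planted structure", {
  ch <- generateCohort(cohortSpec(n_per_group = c(30L, 25L),
    n_features = c(transcriptomics = 20, proteomics = 100,
                   metabolomics = 20),
    delta = c(transcriptomics = 0, proteomics = 2.5, metabolomics = 0),
    module_size = 2L, seed = 66))
  sap <- ch$truth$affected$proteomics[1:20]
  res <- sapHCA(ch$layers$proteomics, sap, ch$truth$labels)
  expect_equal(res$ari, 1)
  expect_length(res$order, 55)
  perm <- setNames(sample(ch$truth$labels), names(ch$truth$labels))
  resp <- sapHCA(ch$layers$proteomics, sap, perm)
  expect_lt(abs(resp$ari), 0.15)
  expect_error(sapHCA(ch$layers$proteomics, sap[1], ch$truth$labels),
               "at least 2")
})
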
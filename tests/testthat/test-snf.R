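test_that("variance filter is strict-below and counts removals", {
  m <- cbind(matrix(rnorm(40 * 7, sd = 2), 40, 7),
             matrix(rnorm(40 * 3, sd = 0.05), 40, 3))
  dimnames(m) <- list(paste0("s", 1:40), paste0("f", 1:10))
  lay <- OmicsLayer(m)
  expect_message(filt <- varianceFilter(lay, 0.2), "removed 3 of 10")
  expect_identical(ncol(assayValues(filt)), 7L)
  # boundary: a feature with variance exactly at the threshold stays
  x <- rep(c(0, 1), 10)
  x <- x - mean(x)
  x <- x / sd(x) * sqrt(0.2)
  m2 <- cbind(f1 = x + mean(x), f2 = rnorm(20))
  rownames(m2) <- paste0("s", 1:20)
  filt2 <- varianceFilter(OmicsLayer(m2), 0.2)
  expect_true("f1" %in% featureIDs(filt2))
  expect_error(varianceFilter(OmicsLayer(m2), 1e9), "all features")
})

test_that("affinity kernel matches its formula on a small fixture", {
  set.seed(21)
  x <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
  K <- 2; alpha <- 0.7
  W <- buildAffinity(x, K = K, alpha = alpha)
  # direct hand evaluation
  xs <- scale(x)
  d2 <- as.matrix(dist(xs))^2
  mu <- sapply(1:5, function(i) mean(sort(d2[i, -i])[1:K]))
  eps <- (outer(mu, mu, "+") + d2) / 3
  Wref <- exp(-d2 / (alpha * eps))
  Wref <- (Wref + t(Wref)) / 2
  expect_equal(unname(W), unname(Wref), tolerance = 1e-8)
  expect_equal(unname(diag(W)), rep(1, 5))
  # identical samples attract affinity 1
  x2 <- rbind(x, s6 = x[1, ])
  W2 <- buildAffinity(x2, K = 2)
  expect_equal(W2["s1", "s6"], 1)
  expect_error(buildAffinity(x[1:2, ], K = 2), "K \\+ 1")
})

test_that("fusion preserves row-stochastic normalization and symmetry", {
  blobs <- twoBlobAffinity(seed = 2)
  noise <- buildAffinity(matrix(rnorm(60 * 10), 60,
    dimnames = list(rownames(blobs$W), paste0("n", 1:10))), K = 10)
  fused <- snfFuse(list(blobs$W, noise), K = 10, T = 5)
  expect_true(all(fused >= 0))
  expect_equal(fused, t(fused), tolerance = 1e-12)
  expect_true(all(abs(rowSums(fused) - 1) < 0.1))
  expect_error(snfFuse(list(blobs$W), K = 10), "two layers")
  W2 <- noise
  rownames(W2) <- rev(rownames(W2))
  expect_error(snfFuse(list(blobs$W, W2)), "mismatch")
})

test_that("fusing a layer with itself preserves its clustering", {
  blobs <- twoBlobAffinity(seed = 4)
  single <- spectralCluster(blobs$W, 2, seed = 1)
  fused <- snfFuse(list(blobs$W, blobs$W), K = 10, T = 10)
  both <- spectralCluster(fused, 2, seed = 1)
  expect_equal(truthMetrics(both, single)$ari, 1)
})

test_that("fused two-blob cohort is recovered exactly", {
  blobs <- twoBlobAffinity(seed = 6)
  noise <- buildAffinity(matrix(rnorm(60 * 10), 60,
    dimnames = list(rownames(blobs$W), paste0("n", 1:10))), K = 10)
  fused <- snfFuse(list(blobs$W, noise), K = 10, T = 10)
  labs <- spectralCluster(fused, 2, seed = 2)
  expect_equal(truthMetrics(labs,
    setNames(blobs$truth, rownames(blobs$W)))$ari, 1)
})

test_that("spectral clustering recovers blocks and degenerates cleanly", {
  W <- matrix(0.01, 9, 9, dimnames = list(paste0("s", 1:9),
                                          paste0("s", 1:9)))
  W[1:4, 1:4] <- 0.9; W[5:9, 5:9] <- 0.9; diag(W) <- 1
  labs <- spectralCluster(W, 2, seed = 1)
  expect_equal(truthMetrics(labs,
    setNames(rep(1:2, c(4, 5)), rownames(W)))$ari, 1)
  expect_identical(unname(spectralCluster(W, 9, seed = 1)), 1:9)
  expect_error(spectralCluster(W, 1), "C must be")
})

test_that("spectral cut agrees with exhaustive min normalized cut", {
  # 8-sample graphs: enumerate every 2-partition, pick min ncut
  set.seed(8)
  for (rep in 1:3) {
    x <- rbind(matrix(rnorm(4 * 3), 4), matrix(rnorm(4 * 3, 3), 4))
    rownames(x) <- paste0("s", 1:8); colnames(x) <- paste0("f", 1:3)
    W <- buildAffinity(x, K = 3)
    best <- NULL; bestCut <- Inf
    for (code in 1:(2^7 - 1)) {
      memb <- c(1L, as.integer(intToBits(code)[1:7]) + 1L)
      if (length(unique(memb)) < 2) next
      A <- memb == 1
      cut <- sum(W[A, !A])
      ncut <- cut / sum(W[A, ]) + cut / sum(W[!A, ])
      if (ncut < bestCut) { bestCut <- ncut; best <- memb }
    }
    labs <- spectralCluster(W, 2, seed = rep)
    expect_equal(truthMetrics(labs, setNames(best, rownames(W)))$ari, 1)
  }
})

test_that("model selection diagnostics cover the candidate range", {
  W <- matrix(0.002, 30, 30)
  for (b in 0:2) W[b * 10 + 1:10, b * 10 + 1:10] <- 0.9
  diag(W) <- 1
  dimnames(W) <- list(paste0("s", 1:30), paste0("s", 1:30))
  sel <- estimateNumClusters(W, 2:6)
  expect_identical(sel$best_by_eigengap, 3L)
  expect_identical(nrow(sel$diagnostics), 5L)
  expect_identical(sel$diagnostics$C, 2:6)
  expect_true(all(is.finite(sel$diagnostics$rotation_cost)))
})

test_that("NMI concordance is 1 for the fused layer itself, ~0 for noise", {
  blobs <- twoBlobAffinity(seed = 9)
  nmis <- nmiConcordance(blobs$W, list(self = blobs$W), 2, seed = 1)
  expect_equal(unname(nmis["self"]), 1)
  set.seed(10)
  vals <- replicate(30, {
    a <- sample(rep(1:2, c(88, 70)))
    b <- sample(rep(1:2, c(88, 70)))
    stratomics:::.nmi(a, b)
  })
  expect_lt(mean(vals), 0.05)
})

test_that("split validation is perfect on separated data, null on noise", {
  ch <- generateCohort(cohortSpec(n_per_group = c(30L, 25L),
    n_features = c(transcriptomics = 20, proteomics = 100,
                   metabolomics = 20),
    delta = c(transcriptomics = 0, proteomics = 3, metabolomics = 0),
    module_size = 2L, seed = 12))
  v <- validateClusters(ch$layers["proteomics"], ch$samples,
                        ch$truth$labels, n_splits = 5, seed = 1)
  expect_equal(v$accuracy, 1)
  expect_gte(v$auroc, 0.99)
  # confusion rows sum to per-split test counts
  expect_equal(unname(rowSums(v$confusion)),
               unname(c(30 - round(0.8 * 30), 25 - round(0.8 * 25))))
  # null simulation: accuracy under permuted labels stays at the class
  # prior on average
  set.seed(2)
  nullAcc <- vapply(1:5, function(i) {
    perm <- setNames(sample(ch$truth$labels), names(ch$truth$labels))
    validateClusters(ch$layers["proteomics"], ch$samples, perm,
                     n_splits = 5, seed = i)$accuracy
  }, numeric(1))
  prior <- max(table(ch$truth$labels)) / length(ch$truth$labels)
  expect_lt(abs(mean(nullAcc) - prior), 0.1)
})
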
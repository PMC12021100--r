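#' Remove low-variance features from a layer
#'
#' Features with variance strictly below `threshold` are removed (a
#' feature at exactly the threshold is retained).
#'
#' @param layer an [OmicsLayer-class].
#' @param threshold variance cut-off (default 0.2).
#' @return filtered [OmicsLayer-class]; the number removed is logged.
#' @export
varianceFilter <- function(layer, threshold = 0.2) {
  v <- apply(assayValues(layer), 2L, stats::var)
  keep <- v >= threshold
  if (!any(keep)) stop("variance filter removed all features")
  if (any(!keep))
    message(sprintf("variance filter removed %d of %d %s features",
                    sum(!keep), length(keep), layerKind(layer)))
  OmicsLayer(assayValues(layer)[, keep, drop = FALSE],
             kind = layerKind(layer))
}

#' Build a per-layer sample affinity matrix
#'
#' Features are z-scored, squared Euclidean distances d2 computed, and
#' the locally scaled kernel
#' `W(i,j) = exp(-d2(i,j) / (alpha * eps(i,j)))` applied, where
#' `eps(i,j)` averages the mean d2 over i's K nearest neighbours, the
#' mean over j's, and d2(i,j) itself.
#'
#' @param layer an [OmicsLayer-class] or numeric samples x features matrix.
#' @param K neighbourhood size (default 30).
#' @param alpha kernel scale hyperparameter (default 0.7).
#' @return symmetric nonnegative affinity matrix with unit diagonal.
#' @export
buildAffinity <- function(layer, K = 30L, alpha = 0.7) {
  x <- if (is(layer, "OmicsLayer")) assayValues(layer) else as.matrix(layer)
  n <- nrow(x)
  if (n < K + 1L) stop("need at least K + 1 samples")
  if (alpha <= 0) stop("alpha must be positive")
  xs <- .zscore(x)
  d2 <- as.matrix(stats::dist(xs))^2
  # mean squared distance to the K nearest neighbours (self excluded)
  knnMean <- apply(d2, 1L, function(r) mean(sort(r[-which.min(r)])[seq_len(K)]))
  eps <- (outer(knnMean, knnMean, "+") + d2) / 3
  W <- exp(-d2 / (alpha * eps))
  dimnames(W) <- list(rownames(x), rownames(x))
  (W + t(W)) / 2
}

# full-kernel normalization: diagonal 1/2, off-diagonal mass 1/2 per row
.normalizeP <- function(W) {
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

# sparse kernel: keep each row's K nearest neighbours, renormalized
.knnKernel <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    # ties broken by sample order (order() is stable)
    nb <- order(w, decreasing = TRUE)[seq_len(K)]
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  S
}

#' Fuse per-layer affinities by cross-diffusion
#'
#' Iterates `P_v <- S_v %*% mean(P_u, u != v) %*% t(S_v)` for `T` rounds
#' with symmetrization and row re-normalization each round, then averages
#' the layer matrices and renormalizes.
#'
#' @param affinities list of >= 2 aligned affinity matrices.
#' @param K neighbourhood size of the sparse kernel.
#' @param T number of diffusion iterations.
#' @return fused affinity matrix (symmetric, nonnegative).
#' @export
snfFuse <- function(affinities, K = 30L, T = 20L) {
  if (length(affinities) < 2L) stop("need at least two layers to fuse")
  ids <- rownames(affinities[[1L]])
  for (W in affinities)
    if (!identical(rownames(W), ids)) stop("sample mismatch across layers")
  if (T < 1L) stop("T must be >= 1")
  P <- lapply(affinities, .normalizeP)
  S <- lapply(affinities, .knnKernel, K = K)
  m <- length(P)
  for (t in seq_len(T)) {
    Pnew <- vector("list", m)
    for (v in seq_len(m)) {
      other <- Reduce(`+`, P[-v]) / (m - 1L)
      Q <- S[[v]] %*% other %*% t(S[[v]])
      Q <- (Q + t(Q)) / 2
      Pnew[[v]] <- .normalizeP(Q)
    }
    P <- Pnew
  }
  W <- Reduce(`+`, P) / m
  W <- .normalizeP(W)
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(affinities[[1L]])
  W
}

# eigen-decomposition of the symmetric normalized Laplacian
.laplacianEigen <- function(W) {
  d <- rowSums(W)
  d[d == 0] <- 1
  Dh <- 1 / sqrt(d)
  L <- diag(nrow(W)) - (Dh * W) * rep(Dh, each = nrow(W))
  eigen((L + t(L)) / 2, symmetric = TRUE)
}

#' Normalized-Laplacian spectral clustering
#'
#' Embeds samples in the bottom `C` eigenvectors of the symmetric
#' normalized Laplacian, row-normalizes, and clusters with seeded k-means
#' (20 restarts, best inertia kept).
#'
#' @param W affinity matrix.
#' @param C number of clusters (>= 2; `C = n` returns singletons).
#' @param seed integer seed making the k-means initialisation
#'   deterministic.
#' @return integer labels named by sample id.
#' @export
spectralCluster <- function(W, C, seed = 1L) {
  n <- nrow(W)
  if (C < 2L) stop("C must be >= 2")
  if (C >= n) return(stats::setNames(seq_len(n), rownames(W)))
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    W > 1e-12, mode = "undirected", diag = FALSE))
  if (comp$no > C) {
    warning(sprintf("graph has %d components > C = %d; labelling by component",
                    comp$no, C))
    return(stats::setNames(as.integer(comp$membership), rownames(W)))
  }
  ev <- .laplacianEigen(W)
  X <- ev$vectors[, n - seq_len(C) + 1L, drop = FALSE]
  rn <- sqrt(rowSums(X^2))
  rn[rn == 0] <- 1
  X <- X / rn
  set.seed(seed)
  km <- stats::kmeans(X, centers = C, nstart = 20L, iter.max = 100L)
  stats::setNames(as.integer(km$cluster), rownames(W))
}

# Zelnik-Manor/Perona alignment cost of the first C eigenvectors:
# J(theta) = sum_i sum_j Z_ij^2 / max_j Z_ij^2 for Z = X R(theta),
# minimized over Givens rotations
.rotationCost <- function(X) {
  C <- ncol(X)
  if (C < 2L) return(nrow(X))
  idx <- utils::combn(C, 2L)
  costFn <- function(theta) {
    R <- diag(C)
    for (k in seq_len(ncol(idx))) {
      G <- diag(C)
      i <- idx[1L, k]; j <- idx[2L, k]
      G[i, i] <- cos(theta[k]); G[j, j] <- cos(theta[k])
      G[i, j] <- -sin(theta[k]); G[j, i] <- sin(theta[k])
      R <- R %*% G
    }
    Z2 <- (X %*% R)^2
    sum(Z2 / pmax(apply(Z2, 1L, max), .Machine$double.eps))
  }
  opt <- stats::optim(rep(0, ncol(idx)), costFn, method = "BFGS",
                      control = list(maxit = 50L))
  opt$value
}

#' Choose the number of clusters by eigengap and rotation cost
#'
#' The eigengap at candidate C is the difference between consecutive
#' sorted normalized-Laplacian eigenvalues; the rotation cost is the
#' eigenvector-alignment cost of self-tuning spectral clustering.
#'
#' @param W affinity matrix.
#' @param range candidate cluster numbers (within `[2, n - 1]`).
#' @return list with `best_by_eigengap`, `best_by_rotation_cost`, and a
#'   `diagnostics` data.frame (one row per candidate).
#' @export
estimateNumClusters <- function(W, range = 2:10) {
  n <- nrow(W)
  range <- range[range >= 2L & range <= n - 1L]
  if (!length(range)) stop("empty candidate range")
  ev <- .laplacianEigen(W)
  lam <- sort(ev$values) # ascending
  gaps <- vapply(range, function(C) lam[C + 1L] - lam[C], numeric(1))
  vecs <- ev$vectors[, n:1, drop = FALSE] # ascending eigenvalue order
  costs <- vapply(range, function(C)
    .rotationCost(vecs[, seq_len(C), drop = FALSE]), numeric(1))
  diag_df <- data.frame(C = range, eigengap = gaps, rotation_cost = costs)
  list(best_by_eigengap = range[which.max(gaps)],
       best_by_rotation_cost = range[which.min(costs)],
       diagnostics = diag_df)
}

#' Stratify a cohort by similarity network fusion
#'
#' End-to-end convenience wrapper: variance-filter each layer, build
#' per-layer affinities, fuse, select the cluster number (eigengap), and
#' spectrally cluster the fused network; per-layer NMI concordance is
#' attached.
#'
#' @param layers named list of [OmicsLayer-class].
#' @param config an [AnalysisConfig-class].
#' @param C optional fixed cluster number; overrides model selection.
#' @return a [ClusterAssignment-class].
#' @export
snfStratify <- function(layers, config = analysisConfig(), C = NULL) {
  p <- configParams(config)$snf
  seed <- configParams(config)$seed
  filtered <- lapply(layers, varianceFilter, threshold = p$var_threshold)
  affs <- lapply(filtered, buildAffinity, K = p$K, alpha = p$alpha)
  fused <- snfFuse(affs, K = p$K, T = p$T)
  sel <- estimateNumClusters(fused, p$c_range)
  k <- if (is.null(C)) sel$best_by_eigengap else as.integer(C)
  labels <- spectralCluster(fused, k, seed = seed)
  nmi <- nmiConcordance(fused, affs, k, seed = seed)
  new("ClusterAssignment", labels = labels, k = as.integer(k),
      fused = fused,
      diagnostics = c(sel, list(params = p)), nmi = nmi)
}

#' Per-layer NMI concordance with the fused clustering
#'
#' Spectrally clusters the fused matrix and each single-layer affinity at
#' the same C and reports normalized mutual information (arithmetic-mean
#' normalization) of each layer's labels against the fused labels.
#'
#' @param fused fused affinity matrix.
#' @param single_layers named list of per-layer affinity matrices.
#' @param C number of clusters.
#' @param seed seed passed to [spectralCluster()].
#' @return named numeric vector of NMI values.
#' @export
nmiConcordance <- function(fused, single_layers, C, seed = 1L) {
  ref <- spectralCluster(fused, C, seed = seed)
  vapply(single_layers, function(W)
    .nmi(ref, spectralCluster(W, C, seed = seed)), numeric(1))
}

#' Split-based cluster validation by nearest-cluster similarity
#'
#' A simplified similarity classifier: for each of `n_splits` stratified
#' train/test splits, a test sample is scored per cluster by its mean
#' Pearson correlation to the cluster's training members (omics views)
#' and by negative range-normalized absolute difference (continuous
#' clinical covariates), averaged across views; the argmax wins. ROC and
#' PR curves are computed from the pooled score margins with the second
#' cluster as positive class.
#'
#' @param layers named list of [OmicsLayer-class].
#' @param samples a [SampleTable-class] (continuous covariates are used
#'   as a clinical view; may be NULL).
#' @param labels named integer cluster labels.
#' @param train_frac training fraction per split.
#' @param n_splits number of train/test splits.
#' @param seed integer seed.
#' @return list with `auroc`, `aupr`, `roc` and `pr` curves, `accuracy`,
#'   and the mean `confusion` matrix (rows = true clusters).
#' @export
validateClusters <- function(layers, samples = NULL, labels,
                             train_frac = 0.8, n_splits = 20L, seed = 1L) {
  ids <- names(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2L || any(table(labels) < 5L))
    stop("need >= 2 clusters with >= 5 members each")
  # center each feature so correlations discriminate one-sided shifts
  views <- lapply(layers, function(l)
    scale(assayValues(l)[ids, , drop = FALSE], center = TRUE,
          scale = FALSE))
  clin <- NULL
  if (!is.null(samples)) {
    cv <- covariates(samples)[ids, , drop = FALSE]
    num <- cv[, vapply(cv, is.numeric, logical(1)), drop = FALSE]
    if (ncol(num)) clin <- as.matrix(num)
  }
  set.seed(seed)
  conf <- matrix(0, length(cl), length(cl),
                 dimnames = list(true = cl, predicted = cl))
  acc <- numeric(n_splits)
  margins <- truthPos <- numeric(0)
  for (s in seq_len(n_splits)) {
    train <- unlist(lapply(cl, function(k) {
      members <- ids[labels == k]
      sample(members, max(1L, round(train_frac * length(members))))
    }))
    test <- setdiff(ids, train)
    scores <- matrix(0, length(test), length(cl))
    nviews <- 0L
    for (V in views) {
      cc <- suppressWarnings(stats::cor(t(V[test, , drop = FALSE]),
                                        t(V[train, , drop = FALSE])))
      cc[is.na(cc)] <- 0
      for (j in seq_along(cl))
        scores[, j] <- scores[, j] +
          rowMeans(cc[, labels[train] == cl[j], drop = FALSE])
      nviews <- nviews + 1L
    }
    if (!is.null(clin)) {
      rng <- apply(clin, 2L, function(z) diff(range(z, na.rm = TRUE)))
      rng[rng == 0 | is.na(rng)] <- 1
      sim <- matrix(0, length(test), length(train))
      for (k in seq_len(ncol(clin)))
        sim <- sim - abs(outer(clin[test, k], clin[train, k], "-")) / rng[k]
      sim <- sim / ncol(clin)
      for (j in seq_along(cl))
        scores[, j] <- scores[, j] +
          rowMeans(sim[, labels[train] == cl[j], drop = FALSE])
      nviews <- nviews + 1L
    }
    scores <- scores / nviews
    pred <- cl[max.col(scores, ties.method = "first")]
    truth <- labels[test]
    conf <- conf + table(factor(truth, cl), factor(pred, cl))
    acc[s] <- mean(pred == truth)
    margins <- c(margins, scores[, 2L] - scores[, 1L])
    truthPos <- c(truthPos, as.numeric(truth == cl[2L]))
  }
  roc <- .rocCurve(margins, truthPos)
  pr <- .prCurve(margins, truthPos)
  list(auroc = roc$auc, aupr = pr$auc, roc = roc$curve, pr = pr$curve,
       accuracy = mean(acc), confusion = conf / n_splits)
}

.rocCurve <- function(score, pos) {
  o <- order(score, decreasing = TRUE)
  tp <- cumsum(pos[o]); fp <- cumsum(1 - pos[o])
  tpr <- tp / sum(pos); fpr <- fp / sum(1 - pos)
  # rank-based AUROC (Mann-Whitney)
  r <- rank(score)
  auc <- (sum(r[pos == 1]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(1 - pos))
  list(curve = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)), auc = auc)
}

.prCurve <- function(score, pos) {
  o <- order(score, decreasing = TRUE)
  tp <- cumsum(pos[o])
  prec <- tp / seq_along(tp)
  rec <- tp / sum(pos)
  auc <- sum(diff(c(0, rec)) * prec)
  list(curve = data.frame(recall = rec, precision = prec), auc = auc)
}
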
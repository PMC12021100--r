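# shared fixtures and memoized heavy computations

.fixtureEnv <- new.env(parent = emptyenv())

# small two-blob cohort for clustering fixtures
twoBlobAffinity <- function(n1 = 30, n2 = 30, sep = 6, seed = 1, K = 10) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * 10), n1),
             matrix(rnorm(n2 * 10, mean = sep / sqrt(10)), n2))
  rownames(x) <- sprintf("s%02d", seq_len(n1 + n2))
  colnames(x) <- sprintf("f%02d", 1:10)
  list(W = buildAffinity(x, K = K), truth = rep(1:2, c(n1, n2)), x = x)
}

randomLayer <- function(n = 20, p = 10, kind = "proteomics", seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  OmicsLayer(m, kind)
}

# memoized 20-seed SNF run under the planted-cohort study conditions
# (n = 158, deltas 0 / 1.0 / 0.3); shared by the recovery and NMI
# concordance checks
snfRecoveryRuns <- function(n_seeds = 20) {
  key <- paste0("snf", n_seeds)
  if (!is.null(.fixtureEnv[[key]])) return(.fixtureEnv[[key]])
  runs <- lapply(seq_len(n_seeds), function(s) {
    ch <- generateCohort(cohortSpec(seed = s))
    filt <- suppressMessages(lapply(ch$layers, varianceFilter))
    affs <- lapply(filt, buildAffinity)
    fused <- snfFuse(affs)
    sel <- estimateNumClusters(fused, 2:10)
    labels <- spectralCluster(fused, 2L, seed = s)
    nmi <- nmiConcordance(fused, affs, 2L, seed = s)
    list(ari = truthMetrics(labels, ch$truth$labels)$ari,
         best_c = sel$best_by_eigengap, nmi = nmi)
  })
  .fixtureEnv[[key]] <- runs
  runs
}

# independent two-sided Fisher oracle: full hypergeometric enumeration
fisherEnumOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pobs <- dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# enumerate all DAGs on `p` labelled nodes as parent lists
enumerateDAGs <- function(p) {
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  # each unordered pair can be absent, i->j, or j->i
  states <- expand.grid(rep(list(0:2), nrow(pairs)))
  out <- list()
  for (r in seq_len(nrow(states))) {
    A <- matrix(FALSE, p, p)
    for (k in seq_len(nrow(pairs))) {
      s <- states[r, k]
      if (s == 1) A[pairs[k, 1], pairs[k, 2]] <- TRUE
      if (s == 2) A[pairs[k, 2], pairs[k, 1]] <- TRUE
    }
    if (!.fixtureHasCycle(A)) out[[length(out) + 1L]] <- A
  }
  out
}

.fixtureHasCycle <- function(A) {
  p <- nrow(A)
  color <- integer(p)
  cyc <- FALSE
  visit <- function(u) {
    if (cyc) return()
    color[u] <<- 1L
    for (w in which(A[u, ])) {
      if (color[w] == 1L) { cyc <<- TRUE; return() }
      if (color[w] == 0L) visit(w)
    }
    color[u] <<- 2L
  }
  for (u in seq_len(p)) if (color[u] == 0L) visit(u)
  cyc
}

# linear-Gaussian data with a planted hub structure
plantedDriverData <- function(n = 158, n_drivers = 5, children = 3,
                              n_noise = 0, beta = 0.8, seed = 1) {
  set.seed(seed)
  p <- n_drivers * (1 + children) + n_noise
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("N%02d", seq_len(p))))
  drivers <- sprintf("N%02d", seq_len(n_drivers))
  for (d in seq_len(n_drivers)) for (k in seq_len(children)) {
    ch <- n_drivers + (d - 1) * children + k
    X[, ch] <- beta * X[, d] + sqrt(1 - beta^2) * rnorm(n)
  }
  list(X = X, drivers = drivers)
}
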
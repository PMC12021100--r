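# internal helpers shared across modules

# cycle check on a parents list (names = children)
.hasCycle <- function(parents, nodes) {
  if (!length(nodes)) return(FALSE)
  indeg <- vapply(parents[nodes], length, integer(1))
  children <- lapply(stats::setNames(nodes, nodes), function(u)
    nodes[vapply(parents[nodes], function(p) u %in% p, logical(1))])
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in children[[u]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen < length(nodes)
}

# column z-scoring; zero-variance columns are an error when strict
.zscore <- function(x, strict = TRUE) {
  s <- apply(x, 2L, stats::sd)
  if (any(s == 0)) {
    if (strict)
      stop("cannot z-score zero-variance feature(s): ",
           paste(utils::head(colnames(x)[s == 0], 3L), collapse = ", "))
    s[s == 0] <- 1
  }
  scale(x, center = TRUE, scale = s)
}

# two-sided p-value for a Spearman rho via the t approximation
.spearmanP <- function(rho, n) {
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  p
}

# normalized mutual information, arithmetic-mean normalization
.nmi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  pjk <- tab / n
  ha <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  hb <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  nz <- pjk > 0
  mi <- sum(pjk[nz] * log(pjk[nz] / outer(pj, pk)[nz]))
  denom <- (ha + hb) / 2
  if (denom <= 0) return(if (mi <= 0) 1 else 0)
  mi / denom
}

# canonical undirected pair key
.pairKey <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

.seedFrom <- function(seed, offset = 0L) {
  s <- (as.numeric(seed) * 1000003 + as.numeric(offset)) %% 2147483647
  as.integer(s)
}

.stopifnotNamedMatrix <- function(m, what = "matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must have row and column names")
  invisible(m)
}
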
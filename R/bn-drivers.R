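# Consensus Gaussian Bayesian-network structure learning and
# BIC-drop driver scoring.
#
# The network score is the decomposable Gaussian BIC: per node j an OLS
# regression on its parents gives logLik_j, and
# score_j = logLik_j - (k_j / 2) * log(n), k_j = |parents| + 2
# (intercept and residual variance). Higher is better. Data are z-scored
# before fitting so scores are comparable across nodes.

# scoring context: z-scored data plus a memo of local scores
.bnContext <- function(data) {
  x <- as.matrix(data)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  s <- apply(x, 2L, stats::sd)
  s[s == 0] <- 1
  x <- scale(x, center = TRUE, scale = s)
  env <- new.env(parent = emptyenv())
  list(x = x, n = nrow(x), nodes = colnames(x), memo = env)
}

# local score of child j given integer parent set
.localScore <- function(ctx, j, parents) {
  key <- paste0(j, "|", paste(sort(parents), collapse = ","))
  hit <- ctx$memo[[key]]
  if (!is.null(hit)) return(hit)
  y <- ctx$x[, j]
  n <- ctx$n
  if (!length(parents)) {
    rss <- sum((y - mean(y))^2)
  } else {
    X <- cbind(1, ctx$x[, parents, drop = FALSE])
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      ctx$memo[[key]] <- -Inf
      return(-Inf)
    }
    rss <- sum(qr.resid(qrX, y)^2)
  }
  sig2 <- max(rss / n, 1e-300)
  ll <- -n / 2 * (log(2 * pi * sig2) + 1)
  val <- ll - (length(parents) + 2) / 2 * log(n)
  ctx$memo[[key]] <- val
  val
}

.parentsToDAG <- function(ctx, parents) {
  nodes <- ctx$nodes
  ps <- lapply(parents, function(p) nodes[p])
  names(ps) <- nodes
  sc <- vapply(seq_along(nodes), function(j)
    .localScore(ctx, j, parents[[j]]), numeric(1))
  names(sc) <- nodes
  new("DAGModel", nodes = nodes, parents = ps,
      nodeScores = sc, score = sum(sc), n = as.integer(ctx$n))
}

.dagToParents <- function(dag, nodes) {
  lapply(nodes, function(nm) match(dag@parents[[nm]], nodes))
}

# reachability (paths of length >= 1) via boolean matrix squaring
.reach <- function(A) {
  R <- A
  repeat {
    R2 <- (R | (R %*% A) > 0)
    if (all(R2 == R)) return(R)
    R <- R2
  }
}

# DFS: is there a path from u to v in adjacency A?
.hasPath <- function(A, u, v) {
  stack <- which(A[u, ])
  seen <- logical(nrow(A))
  while (length(stack)) {
    w <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (w == v) return(TRUE)
    if (!seen[w]) {
      seen[w] <- TRUE
      stack <- c(stack, which(A[w, ] & !seen))
    }
  }
  FALSE
}

#' Score a DAG with the decomposable Gaussian BIC
#'
#' @param dag a [DAGModel-class] (only its structure is used) or a named
#'   list of parent sets.
#' @param data samples x nodes numeric matrix covering all nodes.
#' @return a refitted [DAGModel-class] carrying per-node scores and the
#'   total; a node with a singular parent design scores `-Inf`.
#' @export
gaussianBIC <- function(dag, data) {
  ctx <- .bnContext(data)
  parents <- if (is(dag, "DAGModel")) .dagToParents(dag, ctx$nodes)
             else lapply(ctx$nodes, function(nm)
               match(dag[[nm]], ctx$nodes))
  .parentsToDAG(ctx, parents)
}

.bestImprovement <- function(ctx, A, parents, scores, max_parents) {
  p <- length(parents)
  R <- .reach(A)
  best <- list(delta = 1e-10, type = NULL)
  for (j in seq_len(p)) {
    pj <- parents[[j]]
    # additions i -> j
    if (length(pj) < max_parents) {
      cand <- which(!A[, j] & !R[j, ] & seq_len(p) != j)
      for (i in cand) {
        d <- .localScore(ctx, j, c(pj, i)) - scores[j]
        if (d > best$delta) best <- list(delta = d, type = "add", i = i, j = j)
      }
    }
    # deletions i -> j
    for (i in pj) {
      d <- .localScore(ctx, j, setdiff(pj, i)) - scores[j]
      if (d > best$delta) best <- list(delta = d, type = "del", i = i, j = j)
    }
    # reversals i -> j becomes j -> i
    for (i in pj) {
      if (length(parents[[i]]) >= max_parents) next
      A2 <- A; A2[i, j] <- FALSE
      if (.hasPath(A2, i, j)) next
      d <- (.localScore(ctx, j, setdiff(pj, i)) - scores[j]) +
           (.localScore(ctx, i, c(parents[[i]], j)) - scores[i])
      if (d > best$delta) best <- list(delta = d, type = "rev", i = i, j = j)
    }
  }
  best
}

.applyMove <- function(state, move, ctx) {
  i <- move$i; j <- move$j
  if (move$type == "add") {
    state$A[i, j] <- TRUE
    state$parents[[j]] <- c(state$parents[[j]], i)
  } else if (move$type == "del") {
    state$A[i, j] <- FALSE
    state$parents[[j]] <- setdiff(state$parents[[j]], i)
  } else {
    state$A[i, j] <- FALSE; state$A[j, i] <- TRUE
    state$parents[[j]] <- setdiff(state$parents[[j]], i)
    state$parents[[i]] <- c(state$parents[[i]], j)
    state$scores[i] <- .localScore(ctx, i, state$parents[[i]])
  }
  state$scores[j] <- .localScore(ctx, j, state$parents[[j]])
  state
}

.hillClimbCtx <- function(ctx, startParents, max_parents) {
  p <- length(ctx$nodes)
  A <- matrix(FALSE, p, p)
  for (j in seq_len(p)) A[startParents[[j]], j] <- TRUE
  scores <- vapply(seq_len(p), function(j)
    .localScore(ctx, j, startParents[[j]]), numeric(1))
  state <- list(A = A, parents = startParents, scores = scores)
  repeat {
    move <- .bestImprovement(ctx, state$A, state$parents, state$scores,
                             max_parents)
    if (is.null(move$type)) break
    state <- .applyMove(state, move, ctx)
  }
  state$parents
}

.randomStart <- function(p, max_parents, edge_prob = 0.15) {
  ord <- sample.int(p)
  parents <- rep(list(integer(0)), p)
  for (k in seq_along(ord)[-1L]) {
    j <- ord[k]
    pool <- ord[seq_len(k - 1L)]
    take <- pool[stats::runif(length(pool)) < edge_prob]
    if (length(take) > max_parents) take <- take[seq_len(max_parents)]
    parents[[j]] <- take
  }
  parents
}

#' Greedy hill-climbing DAG search
#'
#' Best-improvement search over add/delete/reverse moves subject to
#' acyclicity and a parent-count cap; terminates when no move improves
#' the Gaussian BIC. Deterministic given the start (`start = NULL` means
#' the empty graph; `random_start = TRUE` draws a seeded random DAG).
#'
#' @param data samples x nodes matrix.
#' @param start optional starting [DAGModel-class] or named parent list.
#' @param max_parents parent-count cap (default 5).
#' @param random_start draw a random acyclic start instead of empty.
#' @param seed seed for the random start.
#' @return a [DAGModel-class].
#' @export
hillClimb <- function(data, start = NULL, max_parents = 5L,
                      random_start = FALSE, seed = 1L) {
  ctx <- .bnContext(data)
  p <- length(ctx$nodes)
  startParents <- if (!is.null(start)) {
    if (is(start, "DAGModel")) .dagToParents(start, ctx$nodes)
    else lapply(ctx$nodes, function(nm) match(start[[nm]], ctx$nodes))
  } else if (random_start) {
    set.seed(seed)
    .randomStart(p, max_parents)
  } else rep(list(integer(0)), p)
  .parentsToDAG(ctx, .hillClimbCtx(ctx, startParents, max_parents))
}

#' Consensus DAG over random-restart hill climbs
#'
#' Runs `n_starts` hill climbs from random acyclic starts (the first
#' start is the empty graph); an edge `u -> v` is retained when that
#' direction is supported by more than half of the runs and the reverse
#' is not (edges supported in both directions are removed as
#' undirected). Cycles arising in assembly are broken by removing the
#' lowest-support edge per cycle. The assembled graph is then refined by
#' `refine_iters` random single-edge perturbations accepted only when
#' they improve the score.
#'
#' @param data samples x nodes matrix.
#' @param n_starts number of restarts (default 150).
#' @param refine_iters refinement perturbations (default 1000).
#' @param max_parents parent cap.
#' @param seed integer seed.
#' @return list with `dag` (a [DAGModel-class]) and `support` (directed
#'   edge support fractions).
#' @export
consensusDAG <- function(data, n_starts = 150L, refine_iters = 1000L,
                         max_parents = 5L, seed = 1L) {
  if (n_starts < 1L) stop("n_starts must be >= 1")
  ctx <- .bnContext(data)
  p <- length(ctx$nodes)
  count <- matrix(0, p, p, dimnames = list(ctx$nodes, ctx$nodes))
  set.seed(seed)
  startSeeds <- sample.int(2^30, n_starts)
  for (s in seq_len(n_starts)) {
    startParents <- if (s == 1L) rep(list(integer(0)), p) else {
      set.seed(startSeeds[s])
      .randomStart(p, max_parents)
    }
    res <- .hillClimbCtx(ctx, startParents, max_parents)
    for (j in seq_len(p)) count[res[[j]], j] <- count[res[[j]], j] + 1
  }
  support <- count / n_starts
  keep <- support > 0.5 & t(support) <= 0.5
  # cycle breaking: drop the weakest edge of any remaining cycle
  A <- keep
  repeat {
    R <- .reach(A)
    cyc <- which(A & t(R), arr.ind = TRUE) # edges on a cycle
    if (!nrow(cyc)) break
    sup <- support[cyc]
    drop <- cyc[which.min(sup), , drop = FALSE]
    A[drop] <- FALSE
    message(sprintf("consensus cycle broken: removed %s -> %s",
                    ctx$nodes[drop[1L]], ctx$nodes[drop[2L]]))
  }
  parents <- lapply(seq_len(p), function(j) which(A[, j]))
  scores <- vapply(seq_len(p), function(j)
    .localScore(ctx, j, parents[[j]]), numeric(1))
  state <- list(A = A, parents = parents, scores = scores)
  if (refine_iters > 0L) {
    set.seed(.seedFrom(seed, 7L))
    for (it in seq_len(refine_iters)) {
      i <- sample.int(p, 1L); j <- sample.int(p, 1L)
      if (i == j) next
      if (!state$A[i, j]) {
        # propose addition (or skip if reverse edge exists: try reversal)
        if (state$A[j, i]) {
          if (length(state$parents[[j]]) >= max_parents) next
          A2 <- state$A; A2[j, i] <- FALSE
          if (.hasPath(A2, j, i)) next
          d <- (.localScore(ctx, i, setdiff(state$parents[[i]], j)) -
                  state$scores[i]) +
               (.localScore(ctx, j, c(state$parents[[j]], i)) -
                  state$scores[j])
          if (d > 1e-10)
            state <- .applyMove(state, list(type = "rev", i = j, j = i), ctx)
        } else {
          if (length(state$parents[[j]]) >= max_parents) next
          if (.hasPath(state$A, j, i)) next
          d <- .localScore(ctx, j, c(state$parents[[j]], i)) - state$scores[j]
          if (d > 1e-10)
            state <- .applyMove(state, list(type = "add", i = i, j = j), ctx)
        }
      } else {
        d <- .localScore(ctx, j, setdiff(state$parents[[j]], i)) -
          state$scores[j]
        if (d > 1e-10)
          state <- .applyMove(state, list(type = "del", i = i, j = j), ctx)
      }
    }
  }
  list(dag = .parentsToDAG(ctx, state$parents), support = support)
}

#' BIC-drop driver scores
#'
#' For each node g, removing g and its incident edges changes only the
#' local scores of g's children; the driver score is
#' `DBIC_g = sum_j [score_j(G) - score_j(G - g)]` over those children
#' (g's own term is excluded from both sides). Isolated nodes score 0.
#'
#' @param dag a fitted [DAGModel-class] (consensus network).
#' @param data samples x nodes matrix the network was learned from.
#' @return `DriverScore` data.frame: node, dbic, n_children, rank
#'   (descending dbic).
#' @export
driverScores <- function(dag, data) {
  ctx <- .bnContext(data)
  parents <- .dagToParents(dag, ctx$nodes)
  p <- length(ctx$nodes)
  base <- vapply(seq_len(p), function(j)
    .localScore(ctx, j, parents[[j]]), numeric(1))
  dbic <- vapply(seq_len(p), function(g) {
    ch <- which(vapply(parents, function(pp) g %in% pp, logical(1)))
    if (!length(ch)) return(0)
    sum(vapply(ch, function(j)
      base[j] - .localScore(ctx, j, setdiff(parents[[j]], g)),
      numeric(1)))
  }, numeric(1))
  out <- data.frame(node = ctx$nodes, dbic = dbic,
                    n_children = vapply(seq_len(p), function(g)
                      sum(vapply(parents, function(pp) g %in% pp,
                                 logical(1))), integer(1)),
                    row.names = NULL)
  out$rank <- rank(-out$dbic, ties.method = "min")
  out[order(out$rank), ]
}

#' Empirical validation of a driver against random nodes
#'
#' Per iteration draws `n_random` random non-candidate nodes and records
#' whether the largest of their BIC-drop scores reaches the candidate's;
#' the empirical p is `(1 + #exceed) / (iters + 1)`.
#'
#' @param node candidate driver id.
#' @param dag the consensus [DAGModel-class].
#' @param data samples x nodes matrix.
#' @param n_random random nodes per iteration (default 5).
#' @param iters iterations (default 1000).
#' @param seed integer seed.
#' @return empirical p-value in `[1/(iters+1), 1]`.
#' @export
validateDriver <- function(node, dag, data, n_random = 5L, iters = 1000L,
                           seed = 1L) {
  if (!node %in% dag@nodes) stop("node not in graph: ", node)
  ds <- driverScores(dag, data)
  target <- ds$dbic[ds$node == node]
  pool <- ds$dbic[ds$node != node]
  if (length(pool) < n_random) stop("not enough non-candidate nodes")
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(iters))
    if (max(sample(pool, n_random)) >= target) exceed <- exceed + 1L
  (1 + exceed) / (iters + 1)
}
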
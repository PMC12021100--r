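#' One shadow-feature relevance run
#'
#' Appends a permuted "shadow" copy of every column, repeatedly fits a
#' random-forest importance learner (permutation importance, the
#' mean-decrease-accuracy analogue), and counts a hit whenever a real
#' feature's importance exceeds the round's maximum shadow importance.
#' Features are confirmed or rejected by a two-sided binomial test of the
#' hit count against probability 0.5 at level `alpha`; features still
#' undecided after `rounds` are not confirmed. Rounds stop early once
#' every feature is decided.
#'
#' @param X samples x features numeric matrix.
#' @param y two-level factor (or coercible) outcome.
#' @param seed integer seed.
#' @param rounds maximum importance rounds.
#' @param num_trees trees per forest.
#' @param alpha binomial confirmation level.
#' @return list with `confirmed` (character), `hits`, `rounds_used` and
#'   the per-feature `status` (`confirmed`/`rejected`/`undecided`).
#' @export
shadowRun <- function(X, y, seed = 1L, rounds = 20L, num_trees = 100L,
                      alpha = 0.05) {
  X <- as.matrix(X)
  if (!ncol(X)) stop("empty feature subset")
  y <- factor(y)
  if (nlevels(y) < 2L) stop("outcome must have >= 2 classes")
  set.seed(seed)
  p <- ncol(X)
  hits <- stats::setNames(integer(p), colnames(X))
  status <- stats::setNames(rep("undecided", p), colnames(X))
  used <- 0L
  for (r in seq_len(rounds)) {
    used <- r
    shadow <- apply(X, 2L, sample)
    colnames(shadow) <- paste0(".shadow", seq_len(p))
    fit <- ranger::ranger(x = cbind(X, shadow), y = y,
                          num.trees = num_trees,
                          importance = "permutation", num.threads = 1L,
                          seed = .seedFrom(seed, r))
    imp <- fit$variable.importance
    hits <- hits + (imp[seq_len(p)] > max(imp[p + seq_len(p)]))
    if (r >= 5L) {
      pbin <- vapply(hits, function(h)
        min(1, 2 * min(stats::pbinom(h, r, 0.5),
                       stats::pbinom(h - 1L, r, 0.5, lower.tail = FALSE))),
        numeric(1))
      status[pbin < alpha & hits / r > 0.5] <- "confirmed"
      status[pbin < alpha & hits / r < 0.5] <- "rejected"
      if (!any(status == "undecided")) break
    }
  }
  list(confirmed = names(status)[status == "confirmed"], hits = hits,
       rounds_used = used, status = status)
}

#' Consensus feature selection over random subsets
#'
#' Each iteration samples `subset_size` features uniformly without
#' replacement and runs [shadowRun()]; a feature's selection frequency is
#' the fraction of iterations *in which it was sampled* that confirmed
#' it. Features are selected when that frequency reaches `vote` with at
#' least `min_support` sampled iterations.
#'
#' @param X samples x features matrix.
#' @param y outcome.
#' @param n_iter iterations (default 1000).
#' @param subset_size features per iteration (default 1000, capped at
#'   the feature count).
#' @param vote selection frequency threshold (default 0.70).
#' @param min_support minimum sampled iterations for eligibility.
#' @param seed integer seed.
#' @param ... passed to [shadowRun()] (`rounds`, `num_trees`, `alpha`).
#' @return `SelectionTrace` data.frame: feature, times_sampled,
#'   times_confirmed, frequency, selected.
#' @export
consensusSelect <- function(X, y, n_iter = 1000L, subset_size = 1000L,
                            vote = 0.70, min_support = 20L, seed = 1L,
                            ...) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  X <- as.matrix(X)
  subset_size <- min(subset_size, ncol(X))
  feats <- colnames(X)
  sampled <- confirmed <- stats::setNames(integer(length(feats)), feats)
  set.seed(seed)
  iterSeeds <- sample.int(2^30, n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(iterSeeds[i])
    sub <- sample(feats, subset_size)
    res <- shadowRun(X[, sub, drop = FALSE], y, seed = iterSeeds[i], ...)
    sampled[sub] <- sampled[sub] + 1L
    confirmed[res$confirmed] <- confirmed[res$confirmed] + 1L
  }
  freq <- ifelse(sampled > 0L, confirmed / sampled, NA_real_)
  out <- data.frame(feature = feats, times_sampled = sampled,
                    times_confirmed = confirmed, frequency = freq,
                    selected = !is.na(freq) & freq >= vote &
                      sampled >= min(min_support, n_iter),
                    row.names = NULL)
  class(out) <- c("SelectionTrace", "data.frame")
  out
}

#' Final cross-validated random-forest evaluation
#'
#' Repeated stratified cross-validation over an `mtry` grid; the best
#' `mtry` (mean accuracy) supplies the pooled CV predictions from which
#' confusion matrix, accuracy, sensitivity and specificity are computed,
#' with the at-risk cluster as positive class when present. OOB error
#' comes from a final full fit.
#'
#' @param X samples x selected-features matrix.
#' @param y outcome (two classes).
#' @param n_trees trees (default 700).
#' @param repeats CV repetitions (default 3).
#' @param folds folds (default 10; reduced with a warning when a class
#'   is smaller).
#' @param mtry_grid candidate `mtry` values (default 1..15, capped).
#' @param positive positive class for sensitivity (default
#'   `"at-risk"` when present, else the second level).
#' @param seed integer seed.
#' @return `RFEvaluation` list: confusion, accuracy, sensitivity,
#'   specificity, oob_error, mtry.
#' @export
finalEvaluate <- function(X, y, n_trees = 700L, repeats = 3L, folds = 10L,
                          mtry_grid = 1:15, positive = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (!ncol(X)) stop("no selected features to evaluate")
  y <- factor(y)
  minClass <- min(table(y))
  if (minClass < folds) {
    warning(sprintf("smallest class (%d) < folds; reducing folds", minClass))
    folds <- max(2L, minClass)
  }
  mtry_grid <- unique(pmin(mtry_grid, ncol(X)))
  if (is.null(positive))
    positive <- if ("at-risk" %in% levels(y)) "at-risk" else levels(y)[2L]
  set.seed(seed)
  foldSets <- replicate(repeats, {
    f <- integer(length(y))
    for (lv in levels(y)) {
      i <- which(y == lv)
      f[i] <- sample(rep(seq_len(folds), length.out = length(i)))
    }
    f
  }, simplify = FALSE)
  cvAcc <- matrix(NA_real_, length(mtry_grid), repeats * folds)
  preds <- array(NA_character_, c(length(mtry_grid), length(y), repeats))
  for (mi in seq_along(mtry_grid)) {
    k <- 0L
    for (r in seq_len(repeats)) {
      f <- foldSets[[r]]
      for (fold in seq_len(folds)) {
        k <- k + 1L
        te <- f == fold
        fit <- ranger::ranger(x = X[!te, , drop = FALSE], y = y[!te],
                              num.trees = n_trees, mtry = mtry_grid[mi],
                              num.threads = 1L,
                              seed = .seedFrom(seed, mi * 1000L + k))
        pr <- stats::predict(fit, X[te, , drop = FALSE])$predictions
        preds[mi, te, r] <- as.character(pr)
        cvAcc[mi, k] <- mean(pr == y[te])
      }
    }
  }
  best <- which.max(rowMeans(cvAcc))
  pooled <- factor(c(preds[best, , ]), levels = levels(y))
  truthRep <- factor(rep(as.character(y), repeats), levels = levels(y))
  conf <- table(true = truthRep, predicted = pooled)
  tp <- conf[positive, positive]
  neg <- setdiff(levels(y), positive)
  sens <- tp / sum(conf[positive, ])
  spec <- sum(conf[neg, neg]) / sum(conf[neg, ])
  finalFit <- ranger::ranger(x = X, y = y, num.trees = n_trees,
                             mtry = mtry_grid[best], num.threads = 1L,
                             seed = .seedFrom(seed, 999999L))
  structure(list(confusion = conf, accuracy = mean(pooled == truthRep),
                 sensitivity = sens, specificity = spec,
                 oob_error = finalFit$prediction.error,
                 mtry = mtry_grid[best]),
            class = "RFEvaluation")
}

#' @export
print.RFEvaluation <- function(x, ...) {
  cat(sprintf(
    "RFEvaluation: accuracy %.3f, sensitivity %.3f, specificity %.3f, OOB %.3f (mtry %d)\n",
    x$accuracy, x$sensitivity, x$specificity, x$oob_error, x$mtry))
  invisible(x)
}
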
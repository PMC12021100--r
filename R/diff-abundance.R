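#' Build a design matrix for differential abundance
#'
#' Three model tiers: 1 = unadjusted two-group contrast, 2 = between
#' clusters, 3 = clusters plus clinical covariates. Categorical
#' covariates are reference-coded with the first observed level as
#' reference; ordinal intake variables enter as ordered numeric.
#'
#' @param samples a [SampleTable-class].
#' @param labels named group labels (two levels; second level is the
#'   contrast).
#' @param covariates character vector of covariate names for model 3.
#' @param model tier (1, 2 or 3).
#' @return design matrix with an `"assign"`-style `"contrast"` attribute
#'   naming the group column.
#' @export
makeDesign <- function(samples, labels, covariates = character(0),
                       model = 2L) {
  ids <- names(labels)
  g <- factor(labels, levels = sort(unique(labels)))
  df <- data.frame(group = g, row.names = ids)
  if (model >= 3L && length(covariates)) {
    cv <- covariates(samples)[ids, covariates, drop = FALSE]
    for (nm in colnames(cv)) {
      if (is.character(cv[[nm]])) cv[[nm]] <- factor(cv[[nm]])
      df[[nm]] <- cv[[nm]]
    }
  }
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  attr(X, "contrast") <- colnames(X)[2L]
  X
}

#' Moderated linear-model differential abundance
#'
#' Ordinary least squares per feature followed by empirical-Bayes
#' variance shrinkage: the posterior variance
#' `s2_tilde = (d0 * s0^2 + d * s^2) / (d0 + d)` uses a prior `(d0,
#' s0^2)` estimated by method of moments on `log(s^2)`; the moderated t
#' is referred to a t distribution on `d0 + d` degrees of freedom and
#' adjusted by Benjamini-Hochberg.
#'
#' @param layer an [OmicsLayer-class] or samples x features matrix.
#' @param design design matrix from [makeDesign()].
#' @param coef column to test (default the group contrast).
#' @param prior_df `NULL` to estimate `d0`; `0` forces the ordinary t.
#' @return `ModeratedFit`: data.frame (feature, coef, t, p.value, fdr,
#'   s2, s2_post) with the prior `(d0, s0_2)` attached as attributes.
#' @export
fitModerated <- function(layer, design, coef = NULL, prior_df = NULL) {
  Y <- if (is(layer, "OmicsLayer")) assayValues(layer) else as.matrix(layer)
  Y <- Y[rownames(design), , drop = FALSE]
  n <- nrow(Y); p <- ncol(design)
  if (n <= p) stop("need more samples than design columns")
  if (is.null(coef)) coef <- attr(design, "contrast")
  if (is.null(coef)) coef <- colnames(design)[2L]
  qrX <- qr(design)
  B <- qr.coef(qrX, Y)                       # p x features
  res <- Y - design %*% B
  d <- n - p
  s2 <- colSums(res^2) / d
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(design), colnames(design))
  unscaled <- sqrt(XtXinv[coef, coef])
  prior <- if (is.null(prior_df)) .fitFDistMoments(s2, d)
           else list(d0 = prior_df, s0_2 = mean(s2))
  d0 <- prior$d0
  s2post <- if (is.infinite(d0)) rep(prior$s0_2, length(s2))
            else (d0 * prior$s0_2 + d * s2) / (d0 + d)
  tmod <- B[coef, ] / (unscaled * sqrt(s2post))
  dft <- if (is.infinite(d0)) Inf else d0 + d
  pv <- 2 * stats::pt(-abs(tmod), df = dft)
  pv[s2post == 0] <- 1 # identically zero residuals and coefficient
  pv[s2post == 0 & abs(B[coef, ]) > 1e-12] <- 0
  out <- data.frame(feature = colnames(Y), coef = B[coef, ], t = tmod,
                    p.value = pv, fdr = bhAdjust(pv), s2 = s2,
                    s2_post = s2post, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- prior$s0_2
  attr(out, "df_residual") <- d
  attr(out, "coef") <- coef
  class(out) <- c("ModeratedFit", "data.frame")
  out
}

# method-of-moments fit of a scaled F prior to sample variances
# (moment matching on log s^2, trigamma inversion by Newton)
.fitFDistMoments <- function(s2, d) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s0_2 = exp(ebar)))
  d0 <- 2 * .trigammaInverse(evar)
  s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`; `NaN`/`NA` propagate with a
#'   warning.
#' @return monotone adjusted values capped at 1.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p))) warning("NA/NaN p-values propagated")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis by the hypergeometric test
#'
#' Upper-tail hypergeometric p per set with BH adjustment across sets.
#'
#' @param query character vector of significant features (subset of
#'   `universe`).
#' @param gsc a [GeneSetCollection-class].
#' @param universe character vector of measured features.
#' @param fdr significance threshold recorded in the output.
#' @return data.frame (set, size, overlap, p.value, fdr, significant,
#'   direction).
#' @export
oraHypergeometric <- function(query, gsc, universe, fdr = 0.2) {
  if (!length(universe)) stop("empty universe")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  sets <- lapply(geneSets(gsc), intersect, universe)
  q <- length(query)
  res <- lapply(names(sets), function(nm) {
    m <- length(sets[[nm]])
    ov <- length(intersect(query, sets[[nm]]))
    p <- if (m == 0L) 1 else
      stats::phyper(ov - 1L, m, length(universe) - m, q, lower.tail = FALSE)
    data.frame(set = nm, size = m, overlap = ov, p.value = p)
  })
  out <- do.call(rbind, res)
  out$fdr <- bhAdjust(out$p.value)
  out$significant <- out$fdr < fdr
  out$direction <- "none"
  out
}

#' Directional (signed-statistic) set enrichment
#'
#' Per-set mean signed statistic with an empirical two-sided p obtained
#' by permuting feature labels; direction is the sign of the observed
#' mean. Sets with no measured members are skipped with a warning.
#'
#' @param statistics named signed per-feature statistics (e.g. moderated
#'   t).
#' @param gsc a [GeneSetCollection-class].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param fdr significance threshold recorded in the output.
#' @return data.frame (set, size, stat, p.value, fdr, direction).
#' @export
directionalEnrichment <- function(statistics, gsc, n_perm = 1000L,
                                  seed = 1L, fdr = 0.2) {
  feats <- names(statistics)
  sets <- geneSets(gsc)
  keep <- vapply(sets, function(s) length(intersect(s, feats)) > 0L,
                 logical(1))
  if (any(!keep))
    warning("skipped set(s) with no measured features: ",
            paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  if (!length(sets))
    return(data.frame(set = character(0), size = integer(0),
                      stat = numeric(0), p.value = numeric(0),
                      fdr = numeric(0), direction = character(0)))
  idx <- lapply(sets, function(s) which(feats %in% s))
  obs <- vapply(idx, function(i) mean(statistics[i]), numeric(1))
  set.seed(seed)
  exceed <- integer(length(idx))
  x <- as.numeric(statistics)
  for (b in seq_len(n_perm)) {
    xb <- sample(x)
    pm <- vapply(idx, function(i) mean(xb[i]), numeric(1))
    exceed <- exceed + (abs(pm) >= abs(obs))
  }
  p <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(set = names(sets), size = lengths(idx), stat = obs,
                    p.value = p, row.names = NULL)
  out$fdr <- bhAdjust(out$p.value)
  out$direction <- ifelse(abs(obs) < 1e-12, "none",
                          ifelse(obs > 0, "up", "down"))
  out$significant <- out$fdr < fdr
  out
}

#' log-CPM transform for transcript counts
#'
#' Documented approximation used before linear modelling of count
#' layers: `log2((count + 0.5) / (libsize + 1) * 1e6)`.
#'
#' @param layer a transcriptomics [OmicsLayer-class].
#' @return an [OmicsLayer-class] on the log-CPM scale.
#' @export
logCPM <- function(layer) {
  m <- assayValues(layer)
  lib <- rowSums(m)
  out <- log2((m + 0.5) / (lib + 1) * 1e6)
  OmicsLayer(out, kind = layerKind(layer))
}
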
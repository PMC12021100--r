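nullDesign <- function(n = 20) {
  labels <- setNames(rep(c("HC-like", "at-risk"), each = n / 2),
                     sprintf("s%03d", seq_len(n)))
  st <- SampleTable(data.frame(row.names = names(labels)))
  makeDesign(st, labels, model = 2L)
}

test_that("moderated fit matches a hand-computed OLS + shrinkage oracle", {
  set.seed(31)
  n <- 12
  X <- nullDesign(n)
  # heterogeneous true variances so the variance prior is finite
  sds <- c(0.2, 0.7, 1, 2.5, 6)
  Y <- matrix(rnorm(n * 5, sd = rep(sds, each = n)), n, 5,
              dimnames = list(rownames(X), paste0("f", 1:5)))
  Y[, 1] <- Y[, 1] + (X[, 2] == 1) * 2
  fit <- fitModerated(Y, X)
  expect_true(is.finite(attr(fit, "d0")))
  # independent per-feature computation with lm() and explicit formulas
  s2 <- coefs <- numeric(5)
  for (j in 1:5) {
    lmf <- lm(Y[, j] ~ X[, 2])
    coefs[j] <- coef(lmf)[2]
    s2[j] <- sum(residuals(lmf)^2) / lmf$df.residual
  }
  expect_equal(unname(fit$coef), coefs, tolerance = 1e-8)
  expect_equal(unname(fit$s2), s2, tolerance = 1e-8)
  d <- n - 2
  d0 <- attr(fit, "d0"); s02 <- attr(fit, "s0_2")
  s2post <- (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2post * (1 / (n / 2) + 1 / (n / 2)))
  tref <- coefs / se
  expect_equal(unname(fit$t), tref, tolerance = 1e-8)
  expect_equal(unname(fit$p.value),
               2 * pt(-abs(tref), df = d0 + d), tolerance = 1e-8)
})

test_that("zero prior df reduces the moderated t to the ordinary t", {
  set.seed(32)
  n <- 16
  X <- nullDesign(n)
  Y <- matrix(rnorm(n * 50), n, 50,
              dimnames = list(rownames(X), paste0("f", 1:50)))
  fit0 <- fitModerated(Y, X, prior_df = 0)
  tord <- vapply(seq_len(ncol(Y)), function(j) {
    g <- X[, 2] == 1
    t.test(Y[g, j], Y[!g, j], var.equal = TRUE)$statistic
  }, numeric(1))
  expect_equal(unname(fit0$t), tord, tolerance = 1e-10)
})

test_that("a feature identical in both groups is a clean null", {
  n <- 10
  X <- nullDesign(n)
  Y <- cbind(flat = rep(rep(c(0.3, -0.7, 1, 2, 0), 2), length.out = n),
             other = rnorm(n))
  rownames(Y) <- rownames(X)
  fit <- fitModerated(Y, X)
  expect_equal(fit$coef[fit$feature == "flat"], 0, tolerance = 1e-12)
  expect_equal(fit$p.value[fit$feature == "flat"], 1)
})

test_that("moderated fit agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(33)
  n <- 18
  X <- nullDesign(n)
  Y <- matrix(rnorm(n * 200, sd = rep(sqrt(rchisq(200, 8) / 8),
                                      each = n)), n, 200,
              dimnames = list(rownames(X), paste0("f", 1:200)))
  Y[, 1:20] <- Y[, 1:20] + (X[, 2] == 1) * 1.5
  fit <- fitModerated(Y, X)
  lf <- limma::eBayes(limma::lmFit(t(Y), X))
  expect_equal(unname(fit$coef), unname(lf$coefficients[, 2]),
               tolerance = 1e-8)
  expect_gt(cor(fit$t, lf$t[, 2]), 0.9999)
  expect_equal(attr(fit, "d0"), lf$df.prior, tolerance = 0.2)
})

test_that("rank-deficient designs name the aliased columns", {
  labels <- setNames(rep(c("a", "b"), each = 6), sprintf("s%03d", 1:12))
  st <- SampleTable(data.frame(dup = rep(c(0, 1), each = 6),
                               row.names = names(labels)))
  expect_error(makeDesign(st, labels, covariates = "dup", model = 3L),
               "aliased")
})

test_that("global null keeps the raw p-value rate at its nominal level", {
  set.seed(34)
  n <- 40
  X <- nullDesign(n)
  Y <- matrix(rnorm(n * 1000), n, 1000,
              dimnames = list(rownames(X), paste0("f", 1:1000)))
  fit <- fitModerated(Y, X)
  expect_gt(mean(fit$p.value < 0.05), 0.03)
  expect_lt(mean(fit$p.value < 0.05), 0.07)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.42), 0.42)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  bruteBH <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(35)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
  }
  expect_warning(out <- bhAdjust(c(0.1, NA)), "propagated")
  expect_true(is.na(out[2]))
})

test_that("hypergeometric ORA matches enumeration on closed cases", {
  gsc <- GeneSetCollection(list(all = paste0("g", 1:20),
                                hit = paste0("g", 1:5),
                                miss = paste0("g", 16:20)))
  universe <- paste0("g", 1:20)
  res <- oraHypergeometric(paste0("g", 1:5), gsc, universe)
  expect_equal(res$p.value[res$set == "all"], 1)
  expect_equal(res$p.value[res$set == "hit"], 1 / choose(20, 5),
               tolerance = 1e-10)
  expect_gt(res$p.value[res$set == "miss"], 0.5)
  expect_error(oraHypergeometric("g1", gsc, character(0)), "universe")
  expect_error(oraHypergeometric("zz", gsc, universe), "subset")
})

test_that("directional enrichment detects planted shifts with sane bounds", {
  set.seed(36)
  stats <- setNames(rnorm(300), paste0("g", 1:300))
  stats[1:20] <- stats[1:20] + 2
  gsc <- GeneSetCollection(list(planted = paste0("g", 1:20),
                                null = paste0("g", 101:130),
                                ghost = paste0("x", 1:5)))
  expect_warning(res <- directionalEnrichment(stats, gsc,
                                              n_perm = 1000, seed = 1),
                 "ghost")
  expect_lte(res$p.value[res$set == "planted"], 0.01)
  expect_identical(res$direction[res$set == "planted"], "up")
  expect_true(all(res$p.value >= 1 / 1001 & res$p.value <= 1))
  zeros <- setNames(rep(0, 50), paste0("g", 1:50))
  rz <- directionalEnrichment(zeros,
    GeneSetCollection(list(s = paste0("g", 1:10))), n_perm = 200, seed = 2)
  expect_gte(rz$p.value, 0.99)
  expect_identical(rz$direction, "none")
})

test_that("log-CPM transform maps counts to the documented scale", {
  m <- matrix(c(100L, 900L, 400L, 600L), 2, 2,
              dimnames = list(c("s1", "s2"), c("g1", "g2")))
  lc <- logCPM(OmicsLayer(m, "transcriptomics"))
  expect_equal(assayValues(lc)[1, 1],
               log2((100 + 0.5) / (500 + 1) * 1e6), tolerance = 1e-12)
})
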
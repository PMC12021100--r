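#' Group-comparison tests for clinical tables
#'
#' The table-one engine: Pearson chi-square with Yates continuity
#' correction on 2x2 tables (no correction for larger tables), Fisher's
#' exact test when expected counts fall below five, Mann-Whitney U for
#' non-normal continuous variables and pooled-variance Student t for
#' normal ones. All tests are two-sided.
#'
#' @param table integer contingency matrix (levels x groups), at least 2x2.
#' @return a `TestResult`: list with `test`, `statistic`, `df`, `p.value`
#'   and an `effect` summary.
#' @examples
#' chisqTest(matrix(c(35, 53, 43, 27), 2, 2)) # Yates-corrected
#' fisherExact(matrix(c(3, 1, 1, 3), 2, 2))
#' @export
chisqTest <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("table must be at least 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  is2x2 <- nrow(table) == 2L && ncol(table) == 2L
  ht <- suppressWarnings(stats::chisq.test(table, correct = is2x2))
  .testResult(if (is2x2) "chi-square (Yates)" else "chi-square",
              unname(ht$statistic), unname(ht$parameter), ht$p.value,
              effect = prop.table(table, margin = 2L))
}

#' @rdname chisqTest
#' @export
fisherExact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("Fisher exact test requires a 2x2 table")
  ht <- stats::fisher.test(table)
  .testResult("Fisher exact", NA_real_, NA_real_, ht$p.value,
              effect = prop.table(table, margin = 2L))
}

#' @param x,y numeric sample vectors.
#' @rdname chisqTest
#' @export
mannWhitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  exact <- length(x) <= 8L && length(y) <= 8L &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  .testResult("Mann-Whitney U", unname(ht$statistic), NA_real_, ht$p.value,
              effect = list(median = c(stats::median(x), stats::median(y)),
                            iqr = rbind(stats::quantile(x, c(.25, .75)),
                                        stats::quantile(y, c(.25, .75)))))
}

#' @rdname chisqTest
#' @export
studentT <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2L)
  if (sp2 == 0) {
    if (mean(x) == mean(y))
      return(.testResult("Student t", 0, length(x) + length(y) - 2L, 1,
                         effect = list(mean = c(mean(x), mean(y)))))
    stop("zero pooled variance with unequal means")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  .testResult("Student t", unname(ht$statistic), unname(ht$parameter),
              ht$p.value, effect = list(mean = c(mean(x), mean(y))))
}

.testResult <- function(test, statistic, df, p, effect = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p.value = p, effect = effect), class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %.4g\n", x$test,
              format(x$statistic, digits = 4), format(x$df), x$p.value))
  invisible(x)
}

#' Build a table-one: per-variable group comparisons
#'
#' Applies the declared test per variable: `"continuous-normal"` (Student
#' t), `"continuous-nonnormal"` (Mann-Whitney U) or `"categorical"`
#' (chi-square, falling back to Fisher's exact test when any expected
#' count of a 2x2 table is below five). Constant variables are skipped
#' with a warning.
#'
#' @param samples a [SampleTable-class].
#' @param labels named group labels (defaults to the table's own groups).
#' @param tests named character vector mapping variable -> test kind.
#' @return data.frame with variable, test used, per-group summary and
#'   p-value.
#' @export
buildTableOne <- function(samples, labels = groupLabels(samples), tests) {
  df <- covariates(samples)
  if (!length(labels)) stop("group labels are required")
  labels <- labels[rownames(df)]
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stop("table-one requires exactly two groups")
  rows <- lapply(names(tests), function(v) {
    if (!v %in% colnames(df)) stop("variable missing from sample table: ", v)
    kind <- tests[[v]]
    val <- df[[v]]
    if (length(unique(val[!is.na(val)])) < 2L) {
      warning("variable '", v, "' is constant; skipped")
      return(data.frame(variable = v, test = "skipped", summary1 = NA,
                        summary2 = NA, p.value = NA_real_))
    }
    if (kind == "categorical") {
      tab <- table(val, labels)[, groups, drop = FALSE]
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      res <- if (any(expd < 5) && all(dim(tab) == 2L)) fisherExact(tab)
             else {
               if (any(expd < 5))
                 warning("expected count < 5 in non-2x2 table for '", v,
                         "'; chi-square used")
               chisqTest(tab)
             }
      smry <- apply(tab, 2L, function(cc)
        paste(sprintf("%d (%.0f%%)", cc, 100 * cc / sum(cc)),
              collapse = " / "))
    } else {
      x <- val[labels == groups[1L]]; y <- val[labels == groups[2L]]
      res <- if (kind == "continuous-normal") studentT(x, y)
             else mannWhitney(x, y)
      smry <- vapply(list(x, y), function(z)
        sprintf("%.2f (%.2f-%.2f)", stats::median(z, na.rm = TRUE),
                stats::quantile(z, .25, na.rm = TRUE),
                stats::quantile(z, .75, na.rm = TRUE)), character(1))
    }
    data.frame(variable = v, test = res$test, summary1 = smry[1L],
               summary2 = smry[2L], p.value = res$p.value)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  out
}
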
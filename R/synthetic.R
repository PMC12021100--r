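#' Specify a synthetic two-cluster cohort
#'
#' Defines the generative conditions of the emulated cohort: group sizes,
#' per-layer feature counts, standardized group mean shifts on affected
#' features (strong in the protein layer, weak in metabolites, absent in
#' transcripts by default), a planted driver DAG among proteins,
#' cross-layer latent-factor modules, senescence annotations and
#' clinically flavoured covariates.
#'
#' @param n_per_group two group sizes (HC-like, at-risk).
#' @param n_features features per layer (transcripts, proteins,
#'   metabolites).
#' @param delta standardized mean shifts per layer (t, p, m) applied to
#'   affected features in group 2.
#' @param affected_frac fraction of each layer's features affected.
#' @param n_drivers planted driver proteins.
#' @param children_per_driver children per driver in the planted DAG.
#' @param beta path coefficient of driver -> child edges.
#' @param n_modules cross-layer correlated modules.
#' @param module_size features per layer per module.
#' @param lambda latent-factor loading of module features (|lambda| < 1
#'   keeps unit marginal variance).
#' @param senescence_frac fraction of proteins carrying senescence
#'   annotations.
#' @param nb_dispersion negative-binomial dispersion of transcript counts.
#' @param covariate_rates named list of per-group binary covariate rates.
#' @param seed integer seed.
#' @return a `CohortSpec` (named list, class `"CohortSpec"`).
#' @export
cohortSpec <- function(n_per_group = c(88L, 70L),
                       n_features = c(transcriptomics = 2000L,
                                      proteomics = 2500L,
                                      metabolomics = 900L),
                       delta = c(transcriptomics = 0,
                                 proteomics = 1.0,
                                 metabolomics = 0.3),
                       affected_frac = c(transcriptomics = 0.10,
                                         proteomics = 0.40,
                                         metabolomics = 0.40),
                       n_drivers = 5L, children_per_driver = 4L,
                       beta = 0.8, n_modules = 2L, module_size = 20L,
                       lambda = 0.6, senescence_frac = 0.05,
                       nb_dispersion = 0.2,
                       covariate_rates = list(
                         hypertension = c(0.40, 0.61),
                         central_obesity = c(0.57, 0.73),
                         ethnicity_caucasian = c(0.80, 0.97),
                         sex_male = c(0.83, 0.94)),
                       seed = 1L) {
  stopifnot(all(n_per_group > 0), all(n_features > 0), all(delta >= 0),
            abs(lambda) < 1, all(affected_frac >= 0 & affected_frac <= 1))
  spec <- list(n_per_group = as.integer(n_per_group),
               n_features = n_features, delta = delta,
               affected_frac = affected_frac, n_drivers = as.integer(n_drivers),
               children_per_driver = as.integer(children_per_driver),
               beta = beta, n_modules = as.integer(n_modules),
               module_size = as.integer(module_size), lambda = lambda,
               senescence_frac = senescence_frac,
               nb_dispersion = nb_dispersion,
               covariate_rates = covariate_rates, seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  spec
}

#' Generate a synthetic multi-omics cohort with ground truth
#'
#' Transcript counts are negative-binomial with log-mean shifted by the
#' transcript delta on affected features; proteins and metabolites are
#' Gaussian on a log-like scale with unit variance and the layer's delta
#' as a group-2 mean shift. A planted DAG over driver proteins is realized
#' as a linear-Gaussian structural model; each cross-layer module is
#' driven by one latent factor shared by features of all three layers.
#'
#' @param spec a [cohortSpec()].
#' @return list with elements `layers` (named list of three
#'   [OmicsLayer-class]), `samples` (a [SampleTable-class]),
#'   `gene_sets` (senescence [GeneSetCollection-class] sources) and
#'   `truth` (labels, affected/driver/module feature lists, DAG edges,
#'   covariate rates).
#' @examples
#' ch <- generateCohort(cohortSpec(n_per_group = c(20, 15),
#'   n_features = c(transcriptomics = 50, proteomics = 60,
#'                  metabolomics = 30)))
#' ch$samples
#' @export
generateCohort <- function(spec = cohortSpec()) {
  set.seed(spec$seed)
  n1 <- spec$n_per_group[1L]; n2 <- spec$n_per_group[2L]
  n <- n1 + n2
  ids <- sprintf("S%03d", seq_len(n))
  grp <- rep(c("HC-like", "at-risk"), c(n1, n2))
  g2 <- grp == "at-risk"

  nf <- spec$n_features
  featnames <- list(
    transcriptomics = sprintf("T%04d", seq_len(nf[["transcriptomics"]])),
    proteomics = sprintf("P%04d", seq_len(nf[["proteomics"]])),
    metabolomics = sprintf("M%04d", seq_len(nf[["metabolomics"]])))

  nAff <- vapply(names(nf), function(k)
    as.integer(round(spec$affected_frac[[k]] * nf[[k]])), integer(1))
  if (any(nAff > unlist(nf))) stop("n_affected exceeds feature count")
  nMod <- spec$n_modules * spec$module_size
  if (spec$n_drivers + spec$n_drivers * spec$children_per_driver + nMod >
      nf[["proteomics"]])
    stop("protein layer too small for the driver and module blocks")
  if (nMod > nf[["transcriptomics"]] || nMod > nf[["metabolomics"]])
    stop("module block exceeds a layer's feature count")

  # reserve disjoint protein blocks: drivers+children first, then modules,
  # affected features drawn from the remainder so recovery is unambiguous
  np <- nf[["proteomics"]]
  ndrv <- spec$n_drivers
  nchild <- ndrv * spec$children_per_driver
  drivers <- featnames$proteomics[seq_len(ndrv)]
  childpool <- featnames$proteomics[ndrv + seq_len(nchild)]
  modP <- featnames$proteomics[ndrv + nchild +
                               seq_len(spec$n_modules * spec$module_size)]
  restP <- setdiff(featnames$proteomics, c(drivers, childpool, modP))

  restM <- setdiff(featnames$metabolomics,
                   featnames$metabolomics[seq_len(min(
                     spec$n_modules * spec$module_size,
                     length(featnames$metabolomics)))])
  affected <- list(
    transcriptomics = sample(featnames$transcriptomics,
                             nAff[["transcriptomics"]]),
    proteomics = sample(restP, min(nAff[["proteomics"]], length(restP))),
    metabolomics = if (length(restM))
      sample(restM, min(nAff[["metabolomics"]], length(restM)))
    else character(0))

  # latent module factors, shared across layers
  lam <- spec$lambda
  factors <- matrix(stats::rnorm(n * spec$n_modules), n, spec$n_modules)
  moduleMembers <- vector("list", spec$n_modules)
  modT <- featnames$transcriptomics[seq_len(spec$n_modules * spec$module_size)]
  modM <- featnames$metabolomics[seq_len(spec$n_modules * spec$module_size)]
  moduleLoad <- function(mat, feats) {
    for (k in seq_len(spec$n_modules)) {
      cols <- feats[(k - 1L) * spec$module_size + seq_len(spec$module_size)]
      mat[, cols] <- lam * factors[, k] +
        sqrt(1 - lam^2) * matrix(stats::rnorm(n * length(cols)), n)
      moduleMembers[[k]] <<- c(moduleMembers[[k]], cols)
    }
    mat
  }

  # proteins: N(0,1) noise, module loadings, planted DAG, group shift
  P <- matrix(stats::rnorm(n * np), n, np,
              dimnames = list(ids, featnames$proteomics))
  P <- moduleLoad(P, modP)
  dagEdges <- NULL
  for (d in seq_len(ndrv)) {
    ch <- childpool[(d - 1L) * spec$children_per_driver +
                    seq_len(spec$children_per_driver)]
    P[, ch] <- spec$beta * P[, drivers[d]] +
      sqrt(1 - spec$beta^2) * matrix(stats::rnorm(n * length(ch)), n)
    dagEdges <- rbind(dagEdges, cbind(from = drivers[d], to = ch))
  }
  P[g2, affected$proteomics] <- P[g2, affected$proteomics] +
    spec$delta[["proteomics"]]

  # metabolites: N(0,1), module loadings, weak group shift
  M <- matrix(stats::rnorm(n * nf[["metabolomics"]]), n,
              nf[["metabolomics"]],
              dimnames = list(ids, featnames$metabolomics))
  M <- moduleLoad(M, modM)
  M[g2, affected$metabolomics] <- M[g2, affected$metabolomics] +
    spec$delta[["metabolomics"]]

  # transcripts: NB counts; latent modules act on the log-mean
  nt <- nf[["transcriptomics"]]
  basemu <- exp(stats::rnorm(nt, log(100), 1))
  logmu <- matrix(log(basemu), n, nt, byrow = TRUE,
                  dimnames = list(ids, featnames$transcriptomics))
  for (k in seq_len(spec$n_modules)) {
    cols <- modT[(k - 1L) * spec$module_size + seq_len(spec$module_size)]
    logmu[, cols] <- logmu[, cols] + lam * factors[, k]
    moduleMembers[[k]] <- c(moduleMembers[[k]], cols)
  }
  logmu[g2, affected$transcriptomics] <-
    logmu[g2, affected$transcriptomics] + spec$delta[["transcriptomics"]]
  Tc <- matrix(stats::rnbinom(n * nt, mu = exp(logmu),
                              size = 1 / spec$nb_dispersion), n, nt,
               dimnames = list(ids, featnames$transcriptomics))

  # covariates: group-rate binaries plus continuous age and ordinal intake
  cov <- data.frame(row.names = ids)
  for (nm in names(spec$covariate_rates)) {
    r <- spec$covariate_rates[[nm]]
    cov[[nm]] <- stats::rbinom(n, 1L, ifelse(g2, r[2L], r[1L]))
  }
  cov$age <- round(stats::rnorm(n, 54, 8), 1)
  cov$fruit_intake <- sample(1:3, n, TRUE) # ordinal: <1/month, >1/week, >1/day
  cov$beef_intake <- pmax(0L, stats::rpois(n, ifelse(g2, 1.3, 1.8)))
  cov$smoking <- sample(c("never", "ex", "current"), n, TRUE,
                        prob = c(0.45, 0.35, 0.20))

  # senescence annotations on proteins, split into three overlapping sources
  sap <- sample(featnames$proteomics,
                max(3L, round(spec$senescence_frac * np)))
  third <- ceiling(length(sap) / 3)
  gsc <- GeneSetCollection(list(
    CellAge = sap[seq_len(min(2L * third, length(sap)))],
    CSgene = sap[seq(from = third, to = length(sap))],
    `Reactome-SASP` = sap[seq(1L, length(sap), by = 2L)]),
    source = "synthetic-senescence")

  layers <- list(
    transcriptomics = OmicsLayer(Tc, "transcriptomics"),
    proteomics = OmicsLayer(P, "proteomics"),
    metabolomics = OmicsLayer(M, "metabolomics"))
  truth <- list(labels = stats::setNames(ifelse(g2, 2L, 1L), ids),
                affected = affected, drivers = drivers,
                dag_edges = dagEdges,
                modules = moduleMembers, senescence = sap,
                covariate_rates = spec$covariate_rates)
  list(layers = layers,
       samples = SampleTable(cov, group = stats::setNames(grp, ids)),
       gene_sets = gsc, truth = truth)
}

#' External-validity metrics against synthetic ground truth
#'
#' For partitions (named label vectors) returns the adjusted Rand index;
#' for sets (character vectors) returns Jaccard, sensitivity and
#' precision against the truth set.
#'
#' @param predicted named label vector or character set.
#' @param truth named label vector or character set of the same kind.
#' @param universe optional id universe used to check comparability for
#'   set inputs.
#' @return named list of indices.
#' @export
truthMetrics <- function(predicted, truth, universe = NULL) {
  if (!is.null(names(predicted)) && !is.null(names(truth)) &&
      !is.character(predicted)) {
    common <- intersect(names(predicted), names(truth))
    if (!length(common)) stop("disjoint id universes")
    list(ari = mclust::adjustedRandIndex(predicted[common], truth[common]))
  } else {
    predicted <- as.character(predicted); truth <- as.character(truth)
    if (!is.null(universe) &&
        (!all(predicted %in% universe) || !all(truth %in% universe)))
      stop("ids outside the declared universe")
    if (!length(intersect(union(predicted, truth), union(predicted, truth))))
      stop("disjoint id universes")
    ov <- length(intersect(predicted, truth))
    list(jaccard = ov / length(union(predicted, truth)),
         sensitivity = if (length(truth)) ov / length(truth) else NA_real_,
         precision = if (length(predicted)) ov / length(predicted) else NA_real_)
  }
}
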
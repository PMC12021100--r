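#' Construct a MetabolicModel from parts
#'
#' @param S stoichiometric matrix (metabolites x reactions, dimnames
#'   required).
#' @param lb,ub flux bounds per reaction.
#' @param obj objective coefficients (exactly one nonzero by default).
#' @param rules gene-reaction rules (`""` = always open); simple
#'   `and`/`or` expressions with parentheses.
#' @param subsystem subsystem label per reaction.
#' @param exchange logical exchange/uptake flag per reaction.
#' @param tasks list of task definitions (`name`, `objective`, optional
#'   `bounds` named list of `c(lb, ub)` overrides, `min` required value).
#' @return a [MetabolicModel-class].
#' @export
metabolicModel <- function(S, lb, ub, obj, rules = NULL, subsystem = NULL,
                           exchange = NULL, tasks = list()) {
  .stopifnotNamedMatrix(S, "stoichiometric matrix")
  nr <- ncol(S)
  if (is.null(rules)) rules <- rep("", nr)
  if (is.null(subsystem)) subsystem <- rep("unassigned", nr)
  if (is.null(exchange)) exchange <- rowSums(abs(t(S)) > 0) == 1L
  new("MetabolicModel", mets = rownames(S), rxns = colnames(S),
      S = S, lb = as.numeric(lb), ub = as.numeric(ub),
      obj = as.numeric(obj), rules = as.character(rules),
      subsystem = as.character(subsystem), exchange = as.logical(exchange),
      tasks = tasks)
}

#' Read a tabular stoichiometric model
#'
#' `stoich` is a TSV with columns `reaction`, `metabolite`,
#' `coefficient`; `bounds` a TSV with `reaction`, `lb`, `ub`, and
#' optional `objective`, `rule`, `subsystem`, `exchange` columns.
#'
#' @param stoich path to the stoichiometry TSV.
#' @param bounds path to the bounds TSV.
#' @return a [MetabolicModel-class].
#' @export
readStoichModel <- function(stoich, bounds) {
  st <- utils::read.table(stoich, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  bd <- utils::read.table(bounds, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  rxns <- bd$reaction
  mets <- unique(st$metabolite)
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  for (k in seq_len(nrow(st)))
    S[st$metabolite[k], st$reaction[k]] <- st$coefficient[k]
  metabolicModel(S, lb = bd$lb, ub = bd$ub,
                 obj = if ("objective" %in% names(bd)) bd$objective
                       else as.numeric(rxns == rxns[length(rxns)]),
                 rules = if ("rule" %in% names(bd)) bd$rule else NULL,
                 subsystem = if ("subsystem" %in% names(bd)) bd$subsystem
                             else NULL,
                 exchange = if ("exchange" %in% names(bd))
                   as.logical(bd$exchange) else NULL)
}

#' @rdname readStoichModel
#' @param model a [MetabolicModel-class].
#' @param stoich_path,bounds_path output paths.
#' @export
writeStoichModel <- function(model, stoich_path, bounds_path) {
  idx <- which(model@S != 0, arr.ind = TRUE)
  st <- data.frame(reaction = model@rxns[idx[, 2L]],
                   metabolite = model@mets[idx[, 1L]],
                   coefficient = model@S[idx])
  utils::write.table(st[order(match(st$reaction, model@rxns)), ],
                     stoich_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bd <- data.frame(reaction = model@rxns, lb = model@lb, ub = model@ub,
                   objective = model@obj, rule = model@rules,
                   subsystem = model@subsystem, exchange = model@exchange)
  utils::write.table(bd, bounds_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(stoich_path)
}

#' Packaged glycolysis-like toy metabolic model
#'
#' A ~25-reaction toy network: a glucose uptake/transport chain through
#' glycolysis-like steps to pyruvate and ATP, an amino-acid transport
#' block (tryptophan-like uptake feeding a serotonin-like sink), an
#' oxygen-independent redox balance, and a biomass objective. Three
#' metabolic tasks (biomass production, ATP generation from glucose,
#' amino-acid assimilation) stand in for full task sets of genome-scale
#' reconstructions.
#'
#' @return a [MetabolicModel-class].
#' @export
toyMetabolicModel <- function() {
  rxn <- function(id, mets, coef, lb, ub, rule = "", sub = "transport",
                  ex = FALSE)
    list(id = id, mets = mets, coef = coef, lb = lb, ub = ub, rule = rule,
         sub = sub, ex = ex)
  rxns <- list(
    rxn("EX_glc", "glc[e]", 1, 0, 5, sub = "exchange", ex = TRUE),
    rxn("EX_trp", "trp[e]", 1, 0, 1, sub = "exchange", ex = TRUE),
    rxn("EX_pi", "pi[e]", 1, 0, 10, sub = "exchange", ex = TRUE),
    rxn("EX_co2", "co2[e]", -1, 0, 100, sub = "exchange", ex = TRUE),
    rxn("EX_lac", "lac[e]", -1, 0, 100, sub = "exchange", ex = TRUE),
    rxn("EX_srtn", "srtn[e]", -1, 0, 100, sub = "exchange", ex = TRUE),
    rxn("GLCt", c("glc[e]", "glc[c]"), c(-1, 1), 0, 10, "G_GLUT1",
        "transport"),
    rxn("TRPt", c("trp[e]", "trp[c]"), c(-1, 1), 0, 10, "G_TAT1",
        "transport"),
    rxn("PIt", c("pi[e]", "pi[c]"), c(-1, 1), 0, 20, "", "transport"),
    rxn("HK", c("glc[c]", "atp[c]", "g6p[c]", "adp[c]"),
        c(-1, -1, 1, 1), 0, 10, "G_HK1", "glycolysis"),
    rxn("PGI", c("g6p[c]", "f6p[c]"), c(-1, 1), -10, 10, "G_GPI",
        "glycolysis"),
    rxn("PFK", c("f6p[c]", "atp[c]", "fdp[c]", "adp[c]"),
        c(-1, -1, 1, 1), 0, 10, "G_PFKL or G_PFKM", "glycolysis"),
    rxn("ALD_TPI", c("fdp[c]", "g3p[c]"), c(-1, 2), 0, 10,
        "G_ALDOA and G_TPI1", "glycolysis"),
    rxn("GAPDH_PGK", c("g3p[c]", "adp[c]", "pi[c]", "pg3[c]", "atp[c]",
                       "nadh[c]"),
        c(-1, -1, -1, 1, 1, 1), 0, 20, "G_GAPDH and G_PGK1",
        "glycolysis"),
    rxn("ENO_PYK", c("pg3[c]", "adp[c]", "pyr[c]", "atp[c]"),
        c(-1, -1, 1, 1), 0, 20, "G_ENO1 and G_PKM", "glycolysis"),
    rxn("LDH", c("pyr[c]", "nadh[c]", "lac[c]"), c(-1, -1, 1), 0, 20,
        "G_LDHA", "fermentation"),
    rxn("LACt", c("lac[c]", "lac[e]"), c(-1, 1), 0, 20, "G_MCT1",
        "transport"),
    rxn("PDH_TCA", c("pyr[c]", "atp_mito[c]", "co2[c]"),
        c(-1, 5, 3), 0, 20, "G_PDHA1", "central carbon"),
    rxn("ATP_mix", c("atp_mito[c]", "adp[c]", "atp[c]"), c(-1, -1, 1),
        0, 100, "", "central carbon"),
    rxn("NADHOX", c("nadh[c]", "atp_mito[c]"), c(-1, 2), 0, 100, "",
        "central carbon"),
    rxn("CO2t", c("co2[c]", "co2[e]"), c(-1, 1), 0, 100, "", "transport"),
    rxn("TRPHYD", c("trp[c]", "srtn[c]"), c(-1, 1), 0, 10, "G_TPH1",
        "tryptophan metabolism"),
    rxn("SRTNt", c("srtn[c]", "srtn[e]"), c(-1, 1), 0, 10, "G_SLC6A4",
        "transport"),
    rxn("ATPM", c("atp[c]", "adp[c]"), c(-1, 1), 0.5, 100, "",
        "maintenance"),
    rxn("BIOMASS", c("pyr[c]", "atp[c]", "trp[c]", "adp[c]"),
        c(-1, -2, -0.1, 2), 0, 100, "", "biomass"))
  mets <- unique(unlist(lapply(rxns, `[[`, "mets")))
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, vapply(rxns, `[[`, character(1), "id")))
  for (r in rxns) S[r$mets, r$id] <- r$coef
  # adp is regenerated by BIOMASS/ATPM; keep the adp/atp pair balanced
  model <- metabolicModel(
    S,
    lb = vapply(rxns, `[[`, numeric(1), "lb"),
    ub = vapply(rxns, `[[`, numeric(1), "ub"),
    obj = as.numeric(vapply(rxns, `[[`, character(1), "id") == "BIOMASS"),
    rules = vapply(rxns, `[[`, character(1), "rule"),
    subsystem = vapply(rxns, `[[`, character(1), "sub"),
    exchange = vapply(rxns, `[[`, logical(1), "ex"),
    tasks = list(
      list(name = "biomass_production", objective = "BIOMASS",
           min = 1e-6),
      list(name = "atp_from_glucose", objective = "ATP_mix",
           bounds = list(EX_trp = c(0, 0)), min = 1e-6),
      list(name = "aa_assimilation", objective = "TRPt", min = 1e-6)))
  model
}

#' Flux balance analysis
#'
#' Solves `maximize c'v` subject to `S v = 0`, `lb <= v <= ub` with a
#' deterministic two-phase simplex (Bland's rule) and returns the
#' optimum with one optimal vertex. With degenerate optima only the
#' objective value is contract-level.
#'
#' @param model a [MetabolicModel-class].
#' @return list: `objective`, `fluxes` (named), `status`
#'   (`"optimal"`/`"infeasible"`).
#' @export
fba <- function(model) {
  lb <- model@lb; ub <- model@ub
  big <- 1e6
  ubf <- ifelse(is.finite(ub), ub, big)
  lbf <- ifelse(is.finite(lb), lb, -big)
  res <- .lpSolve(model@obj, model@S, numeric(length(model@mets)),
                  lbf, ubf)
  if (identical(res$status, "unbounded"))
    stop("unbounded objective (no finite optimum for reaction set: ",
         paste(model@rxns[model@obj != 0], collapse = ", "), ")")
  if (!identical(res$status, "optimal"))
    return(list(objective = NA_real_, fluxes = NULL,
                status = "infeasible"))
  v <- res$v
  names(v) <- model@rxns
  atCap <- names(v)[!is.finite(ub) & v > 0.5 * big]
  if (length(atCap))
    stop("unbounded objective through reaction(s): ",
         paste(atCap, collapse = ", "))
  list(objective = res$objective, fluxes = v, status = "optimal")
}

# evaluate a gene-reaction rule: and = min, or = max over expression
.evalRule <- function(rule, expr) {
  rule <- trimws(rule)
  if (!nzchar(rule)) return(Inf)
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^() \t]+", rule))[[1L]]
  pos <- 1L
  parseOr <- function() {
    v <- parseAnd()
    while (pos <= length(toks) && tolower(toks[pos]) == "or") {
      pos <<- pos + 1L
      v <- max(v, parseAnd())
    }
    v
  }
  parseAnd <- function() {
    v <- parseAtom()
    while (pos <= length(toks) && tolower(toks[pos]) == "and") {
      pos <<- pos + 1L
      v <- min(v, parseAtom())
    }
    v
  }
  parseAtom <- function() {
    tk <- toks[pos]
    if (tk == "(") {
      pos <<- pos + 1L
      v <- parseOr()
      if (pos > length(toks) || toks[pos] != ")")
        stop("unbalanced parentheses in rule: ", rule)
      pos <<- pos + 1L
      return(v)
    }
    pos <<- pos + 1L
    if (!tk %in% names(expr)) return(Inf) # unmeasured gene never closes
    unname(expr[tk])
  }
  parseOr()
}

#' Contextualize a model with expression and metabolite levels
#'
#' Closes reactions whose gene-reaction rule evaluates below
#' `expr_threshold` (`and` = min, `or` = max over gene expression) and
#' scales the upper bounds of exchange reactions of measured metabolites
#' proportionally to their relative level
#' (`bound_scale * level / reference`). The contextualized model is
#' retained only if all packaged tasks pass.
#'
#' @param model a [MetabolicModel-class].
#' @param expression named gene expression vector.
#' @param metabolites named metabolite level vector; names must match
#'   exchange-metabolite ids without compartment tag (e.g. `"glc"`).
#' @param expr_threshold expression gate (reactions below it close).
#' @param bound_scale multiplier applied to relative levels.
#' @param reference reference level (default the median of
#'   `metabolites`).
#' @return contextualized [MetabolicModel-class].
#' @export
contextualize <- function(model, expression = NULL, metabolites = NULL,
                          expr_threshold = 1, bound_scale = 1,
                          reference = NULL) {
  out <- model
  if (!is.null(expression)) {
    act <- vapply(model@rules, .evalRule, numeric(1), expr = expression)
    close <- act < expr_threshold
    out@lb[close] <- 0
    out@ub[close] <- 0
  }
  if (!is.null(metabolites)) {
    if (is.null(reference)) reference <- stats::median(metabolites)
    base <- gsub("\\[.*\\]$", "", model@mets)
    for (nm in names(metabolites)) {
      metIdx <- which(base == nm)
      if (!length(metIdx)) next
      exIdx <- which(model@exchange &
                       colSums(abs(model@S[metIdx, , drop = FALSE]) > 0) > 0 &
                       model@ub > 0)
      out@ub[exIdx] <- model@ub[exIdx] * bound_scale *
        metabolites[[nm]] / reference
    }
  }
  failed <- character(0)
  for (task in model@tasks) {
    tm <- out
    tm@obj <- as.numeric(tm@rxns == task$objective)
    if (!is.null(task$bounds))
      for (rx in names(task$bounds)) {
        k <- match(rx, tm@rxns)
        tm@lb[k] <- task$bounds[[rx]][1L]
        tm@ub[k] <- task$bounds[[rx]][2L]
      }
    sol <- fba(tm)
    need <- if (is.null(task$min)) 1e-6 else task$min
    if (sol$status != "optimal" || sol$objective < need)
      failed <- c(failed, task$name)
  }
  if (length(failed))
    stop("contextualized model rejected; failed task(s): ",
         paste(failed, collapse = ", "))
  out
}

#' Filter and annotate a flux vector
#'
#' Drops fluxes with `|v| < flux_eps`, flags the display set
#' (`|v| >= display_cut`), and attaches `log2(|v|)` for transport
#' reactions.
#'
#' @param fluxes named flux vector.
#' @param model the [MetabolicModel-class] the fluxes belong to (for
#'   subsystem and transport annotation).
#' @param flux_eps activity threshold (default 1e-7).
#' @param display_cut display threshold (default 250).
#' @return data.frame: reaction, flux, sign, subsystem, display,
#'   log2_transport.
#' @export
filterFluxes <- function(fluxes, model = NULL, flux_eps = 1e-7,
                         display_cut = 250) {
  keep <- abs(fluxes) >= flux_eps
  v <- fluxes[keep]
  sub <- if (!is.null(model))
    model@subsystem[match(names(v), model@rxns)] else NA_character_
  transp <- !is.null(model) & grepl("transport", sub)
  data.frame(reaction = names(v), flux = unname(v),
             sign = sign(unname(v)), subsystem = sub,
             display = abs(unname(v)) >= display_cut,
             log2_transport = ifelse(transp, log2(abs(unname(v))),
                                     NA_real_),
             row.names = NULL)
}

#' Classify reactions by group-specific flux activity
#'
#' A reaction is `target-only` when active (|v| >= eps) in the target
#' context and inactive in both others; `direction-flipped` when active
#' in all three with the target's sign opposite to both others;
#' otherwise `shared` (or `absent` when inactive in the target).
#'
#' @param ft a [FluxTable-class] whose contexts include `target` and two
#'   reference contexts.
#' @param target target context name (default `"at-risk"`).
#' @return `GroupFluxComparison` data.frame: reaction, class.
#' @export
groupSpecificFluxes <- function(ft, target = "at-risk") {
  m <- fluxValues(ft)
  if (!target %in% colnames(m)) stop("missing group: ", target)
  others <- setdiff(colnames(m), target)
  if (length(others) < 2L) stop("need two reference contexts")
  act <- activityFlags(ft)
  cls <- vapply(seq_len(nrow(m)), function(r) {
    tA <- act[r, target]; oA <- act[r, others]
    if (tA && !any(oA)) return("target-only")
    if (tA && all(oA) &&
        all(sign(m[r, others]) == -sign(m[r, target]))) return("direction-flipped")
    if (tA) "shared" else "absent"
  }, character(1))
  data.frame(reaction = rownames(m), class = cls, row.names = NULL)
}

#' Per-reaction Fisher test of individual-level flux activity
#'
#' For each reaction, a 2x2 table of activity (|v| >= eps) against group
#' membership is tested with the two-sided Fisher exact test and BH
#' adjusted across reactions. Reactions active in nobody are skipped.
#'
#' @param ft a [FluxTable-class] whose contexts are individuals.
#' @param labels named group labels for the individuals (two groups).
#' @return data.frame: reaction, n_active per group, p.value, fdr.
#' @export
individualFluxTest <- function(ft, labels) {
  act <- activityFlags(ft)
  ids <- colnames(act)
  labels <- labels[ids]
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stop("need exactly two groups")
  if (any(table(labels) < 2L)) stop("need >= 2 individuals per group")
  rows <- lapply(rownames(act), function(r) {
    a <- act[r, ]
    if (!any(a)) return(NULL) # active in nobody
    tab <- table(factor(a, c(FALSE, TRUE)), factor(labels, groups))
    data.frame(reaction = r,
               active_1 = sum(a[labels == groups[1L]]),
               active_2 = sum(a[labels == groups[2L]]),
               p.value = stats::fisher.test(tab)$p.value)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(reaction = character(0),
                                      active_1 = integer(0),
                                      active_2 = integer(0),
                                      p.value = numeric(0),
                                      fdr = numeric(0)))
  out$fdr <- bhAdjust(out$p.value)
  out
}
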
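# minimal linear chain: uptake (ub = 5) -> A -> biomass
chainModel <- function(uptake_ub = 5) {
  S <- matrix(c(1, -1, 0,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("A[e]", "A[c]"),
                              c("EX_A", "At", "BIOMASS")))
  metabolicModel(S, lb = c(0, 0, 0), ub = c(uptake_ub, 100, 100),
                 obj = c(0, 0, 1), rules = c("", "G_T1", ""),
                 subsystem = c("exchange", "transport", "biomass"),
                 exchange = c(TRUE, FALSE, FALSE),
                 tasks = list(list(name = "grow", objective = "BIOMASS",
                                   min = 1e-6)))
}

test_that("chain objective equals the uptake bound; starvation gives 0", {
  sol <- fba(chainModel())
  expect_equal(sol$objective, 5)
  expect_equal(unname(sol$fluxes), c(5, 5, 5))
  expect_equal(fba(chainModel(0))$objective, 0)
})

test_that("a duplicated parallel path leaves the optimum unchanged", {
  S <- matrix(c(1, -1, -1, 0,
                0, 1, 1, -1), 2, 4, byrow = TRUE,
              dimnames = list(c("A[e]", "A[c]"),
                              c("EX_A", "T1", "T2", "BIOMASS")))
  m <- metabolicModel(S, lb = rep(0, 4), ub = c(5, 10, 10, 10),
                      obj = c(0, 0, 0, 1))
  sol <- fba(m)
  expect_equal(sol$objective, 5) # objective asserted, not the split
  expect_equal(sol$fluxes[["T1"]] + sol$fluxes[["T2"]], 5)
})

test_that("the packaged toy model solves at its bottleneck optimum", {
  m <- toyMetabolicModel()
  sol <- fba(m)
  expect_identical(sol$status, "optimal")
  # closed form: biomass is limited jointly by pyruvate supply
  # (2 per glucose, EX_glc <= 5) and tryptophan (0.1 per unit,
  # EX_trp <= 1): max = min(10, 10) = 10
  expect_equal(sol$objective, 10, tolerance = 1e-8)
  expect_lt(max(abs(m@S %*% sol$fluxes)), 1e-8)
  expect_true(all(sol$fluxes >= m@lb - 1e-9 & sol$fluxes <= m@ub + 1e-9))
})

test_that("scaling all exchange bounds scales the optimum linearly", {
  m <- chainModel()
  for (k in c(0.5, 2, 3)) {
    mk <- m
    mk@ub[mk@exchange] <- mk@ub[mk@exchange] * k
    expect_equal(fba(mk)$objective, 5 * k, tolerance = 1e-9)
  }
})

test_that("unbounded objectives are reported as errors", {
  S <- matrix(c(1, -1), 1, 2,
              dimnames = list("A[c]", c("MAKE", "BURN")))
  m <- metabolicModel(S, lb = c(0, 0), ub = c(Inf, Inf), obj = c(0, 1))
  expect_error(fba(m), "unbounded")
})

test_that("gene rules gate reactions: and = min, or = max", {
  expect_equal(stratomics:::.evalRule("G1 and G2", c(G1 = 5, G2 = 2)), 2)
  expect_equal(stratomics:::.evalRule("G1 or G2", c(G1 = 5, G2 = 2)), 5)
  expect_equal(stratomics:::.evalRule("(G1 and G2) or G3",
                                      c(G1 = 5, G2 = 0, G3 = 3)), 3)
  expect_equal(stratomics:::.evalRule("", c(G1 = 1)), Inf)
  expect_error(stratomics:::.evalRule("(G1 and G2", c(G1 = 1, G2 = 1)),
               "parentheses")
})

test_that("contextualization is the identity at reference conditions", {
  m <- toyMetabolicModel()
  genes <- unique(unlist(regmatches(m@rules,
                                    gregexpr("G_[A-Za-z0-9]+", m@rules))))
  expr <- setNames(rep(10, length(genes)), genes)
  cm <- contextualize(m, expression = expr,
                      metabolites = c(glc = 1, trp = 1),
                      expr_threshold = 1, reference = 1)
  expect_equal(cm@ub, m@ub)
  expect_equal(fba(cm)$objective, fba(m)$objective)
})

test_that("closing an essential gene fails the task check", {
  m <- toyMetabolicModel()
  genes <- unique(unlist(regmatches(m@rules,
                                    gregexpr("G_[A-Za-z0-9]+", m@rules))))
  expr <- setNames(rep(10, length(genes)), genes)
  expr["G_HK1"] <- 0 # hexokinase off: no glycolysis, no biomass
  expect_error(contextualize(m, expression = expr, expr_threshold = 1),
               "failed task")
})

test_that("doubling a limiting metabolite bound doubles the chain optimum", {
  m <- chainModel()
  c1 <- contextualize(m, metabolites = c(A = 1), reference = 1)
  c2 <- contextualize(m, metabolites = c(A = 2), reference = 1)
  expect_equal(fba(c2)$objective, 2 * fba(c1)$objective)
})

test_that("flux filtering applies thresholds and transport log2", {
  m <- toyMetabolicModel()
  v <- setNames(rep(0, length(m@rxns)), m@rxns)
  v["GLCt"] <- 300; v["HK"] <- 1e-8; v["PGI"] <- -5
  ff <- filterFluxes(v, m, flux_eps = 1e-7, display_cut = 250)
  expect_false("HK" %in% ff$reaction) # below activity threshold
  glct <- ff[ff$reaction == "GLCt", ]
  expect_true(glct$display)
  expect_equal(glct$log2_transport, log2(300), tolerance = 1e-9)
  expect_equal(round(glct$log2_transport, 2), 8.23)
  pgi <- ff[ff$reaction == "PGI", ]
  expect_identical(pgi$sign, -1)
  expect_false(pgi$display)
})

test_that("group flux classification follows its definitions", {
  m <- matrix(c(3, 0, 0,
                3, -2, -2,
                2, 2, 2,
                0, 1, 1), 4, 3, byrow = TRUE,
              dimnames = list(c("R1", "R2", "R3", "R4"),
                              c("at-risk", "HC-like", "control")))
  cmp <- groupSpecificFluxes(FluxTable(m))
  expect_identical(cmp$class,
                   c("target-only", "direction-flipped", "shared",
                     "absent"))
  expect_error(groupSpecificFluxes(FluxTable(m[, 1:2, drop = FALSE])),
               "two reference")
  expect_error(groupSpecificFluxes(FluxTable(m), target = "nope"),
               "missing group")
})

test_that("individual-level Fisher activity tests match enumeration", {
  act <- rbind(R1 = c(rep(1, 10), rep(0, 10)),
               R2 = rep(c(1, 0), 10),
               R3 = rep(0, 20)) * 1.0
  colnames(act) <- sprintf("i%02d", 1:20)
  labels <- setNames(rep(c("at-risk", "HC-like"), each = 10),
                     colnames(act))
  res <- individualFluxTest(FluxTable(act, eps = 0.5), labels)
  expect_false("R3" %in% res$reaction) # active in nobody: skipped
  expect_equal(res$p.value[res$reaction == "R1"], 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_gt(res$p.value[res$reaction == "R2"], 0.5)
  expect_true(all(diff(res$fdr[order(res$p.value)]) >= -1e-12))
})

test_that("tabular stoichiometric models round-trip", {
  m <- toyMetabolicModel()
  st <- withr::local_tempfile(fileext = ".tsv")
  bd <- withr::local_tempfile(fileext = ".tsv")
  writeStoichModel(m, st, bd)
  back <- readStoichModel(st, bd)
  expect_setequal(back@rxns, m@rxns)
  expect_equal(fba(back)$objective, fba(m)$objective, tolerance = 1e-9)
})
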
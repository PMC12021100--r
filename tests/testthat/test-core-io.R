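test_that("layer writer/reader round-trips to machine precision", {
  layer <- randomLayer(3, 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLayer(layer, path)
  back <- readLayer(path, kind = "proteomics")
  expect_identical(dim(back), c(3L, 2L))
  expect_equal(assayValues(back), assayValues(layer), tolerance = 1e-12)
  expect_identical(sampleIDs(back), sampleIDs(layer))
})

test_that("malformed layers fail loudly and name the culprit", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tfA\tfA", "s1\t1\t2", "s2\t3\t4"), path)
  expect_error(readLayer(path), "fA")
  writeLines(c("sample_id\tfA\tfB", "s1\t1\tx9", "s2\t3\t4"), path)
  expect_error(readLayer(path), "x9")
  expect_error(OmicsLayer(matrix(1:4, 2,
    dimnames = list(c("s1", "s1"), c("a", "b")))), "duplicated sample")
})

test_that("all-missing rows and columns are dropped with a message", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tfA\tfB", "s1\t1\tNA", "s2\t3\tNA"), path)
  expect_message(l <- readLayer(path), "all-missing")
  expect_identical(featureIDs(l), "fA")
})

test_that("minimum imputation fills per-feature minima", {
  m <- matrix(c(1, NA, 3, 10, 20, NA), 3, 2,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  imp <- suppressMessages(imputeMinimum(OmicsLayer(m)))
  expect_equal(assayValues(imp)[2, "a"], 1)
  expect_equal(assayValues(imp)[3, "b"], 10)
  expect_true(all(is.finite(assayValues(imp))))
})

test_that("GMT reader preserves membership and round-trips", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(paste(c("setA", "na", paste0("g", 1:5)), collapse = "\t"),
               paste(c("setB", "na", paste0("G", 1:81)), collapse = "\t")),
             path)
  gsc <- readGMT(path)
  expect_identical(unname(lengths(geneSets(gsc))), c(5L, 81L))
  expect_identical(geneSets(gsc)$setA, paste0("g", 1:5)) # no case folding
  out <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(gsc, out)
  expect_identical(geneSets(readGMT(out)), geneSets(gsc))
})

test_that("GMT errors carry line numbers; empty sets are rejected", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tna\tg1", "short\tonly2fields"), path)
  expect_error(readGMT(path), "line 2")
  writeLines(c("setA\tna\t\t"), path)
  expect_error(readGMT(path), "empty")
  expect_error(GeneSetCollection(list(a = character(0))), "empty sets")
})

test_that("sample table round-trips with group labels", {
  st <- SampleTable(data.frame(age = c(50, 60), bmi = c(22, 28),
                               row.names = c("s1", "s2")),
                    group = c(s1 = "HC-like", s2 = "at-risk"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSampleTable(st, path)
  back <- readSampleTable(path)
  expect_equal(covariates(back)$age, c(50, 60))
  expect_identical(unname(groupLabels(back)), c("HC-like", "at-risk"))
})

test_that("config files round-trip through YAML and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "snf:", "  K: 12", "  alpha: 0.5"), path)
  cfg <- readConfig(path)
  expect_identical(configParams(cfg)$snf$K, 12L)
  expect_equal(configParams(cfg)$snf$alpha, 0.5)
  expect_equal(configParams(cfg)$snf$T, 20L) # untouched default
  writeLines(c("nonsense:", "  a: 1"), path)
  expect_error(readConfig(path), "unknown config")
})

test_that("config defaults match the reference analysis parameters", {
  p <- configParams(analysisConfig())
  expect_identical(c(p$snf$K, p$snf$T), c(30L, 20L))
  expect_equal(p$snf$alpha, 0.7)
  expect_equal(c(p$selection$n_iter, p$selection$subset_size), c(1000L, 1000L))
  expect_equal(p$selection$vote, 0.70)
  expect_equal(c(p$bn$n_starts, p$bn$refine_iters), c(150L, 1000L))
  expect_equal(p$network$fdr_within, 1e-6)
  expect_equal(p$network$final_fdr, 5e-5)
  expect_equal(c(p$flux$flux_eps, p$flux$display_cut), c(1e-7, 250))
  expect_error(analysisConfig(selection = list(vote = 1.3)),
               "thresholds")
})

test_that("network edge lists round-trip", {
  edges <- data.frame(from = c("a", "b"), to = c("b", "c"),
                      rho = c(0.9, -0.8), sign = c(1L, -1L),
                      freq = c(1, 0.95), fdr = c(1e-8, 1e-7),
                      polarity = c("positive", "negative"))
  nodes <- data.frame(feature = c("a", "b", "c"), layer = "proteomics",
                      regulation = "none")
  net <- new("ConsensusNetwork", edges = edges, nodes = nodes,
             membership = c(a = 1L, b = 1L, c = 1L),
             communities = data.frame())
  path <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeNetwork(net, path, graphml = gml)
  back <- readNetwork(path)
  expect_equal(networkEdges(back)$rho, edges$rho)
  expect_identical(networkEdges(back)$sign, edges$sign)
  expect_true(file.exists(gml))
})

test_that("flux tables round-trip with subsystems", {
  ft <- FluxTable(matrix(c(1.5, -0.2, 0, 3), 2, 2,
                         dimnames = list(c("R1", "R2"), c("c1", "c2"))),
                  subsystem = c("glycolysis", "transport"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFluxTable(ft, path)
  back <- readFluxTable(path)
  expect_equal(fluxValues(back), fluxValues(ft))
  expect_identical(back@subsystem, ft@subsystem)
})
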
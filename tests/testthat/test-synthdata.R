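noiseFreeConfig <- function(...) {
  synthConfig(nProteins = 5L, effectSd = 0, runEffectSd = 0, noiseSd = 0,
              fracCore = 1, seed = 3L, ...)
}

test_that("noise-free null experiment gives pool-relative ratios of exactly 1", {
  sim <- generateExperiment(noiseFreeConfig())
  m <- mergeRuns(lapply(sim$runs, relativeToPool), sim$meta)
  expect_false(anyNA(ratios(m)))
  expect_true(all(ratios(m) == 1))
})

test_that("a planted +1 log2 adult effect shifts ratios by the closed-form factor", {
  # generative model: ratio = 2^(effect_g - mean_g(effect)); a +1 effect in
  # one of six groups contributes 1/6 to the pool mean
  cfg <- noiseFreeConfig()
  E <- matrix(0, 5, 6, dimnames = list(sprintf("P%04d", 1:5), names(cfg@groups)))
  E["P0001", "fresh_adult"] <- 1
  sim <- generateExperiment(cfg, groupEffect = E)
  m <- mergeRuns(lapply(sim$runs, relativeToPool), sim$meta)
  g <- sampleGroups(m)
  expect_equal(unname(ratios(m)["P0001", g == "fresh_adult"]),
               rep(2^(1 - 1 / 6), sum(g == "fresh_adult")))
  expect_equal(unname(ratios(m)["P0001", g != "fresh_adult"]),
               rep(2^(-1 / 6), sum(g != "fresh_adult")))
  expect_true(all(ratios(m)[2:5, ] == 1))
})

test_that("identical configuration reproduces identical experiments", {
  cfg <- synthConfig(nProteins = 60L, seed = 42L)
  a <- generateExperiment(cfg)
  b <- generateExperiment(cfg)
  expect_identical(lapply(a$runs, function(r) r@quant),
                   lapply(b$runs, function(r) r@quant))
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth@groupEffect, b$truth@groupEffect)
  o1 <- generateOntology(15L, 30L, seed = 5L)
  o2 <- generateOntology(15L, 30L, seed = 5L)
  expect_identical(o1$dag@parents, o2$dag@parents)
  expect_identical(o1$direct, o2$direct)
})

test_that("full core fraction forces detection everywhere", {
  cfg <- synthConfig(nProteins = 50L, fracCore = 1, detectMidpoint = 50,
                     seed = 2L)
  sim <- generateExperiment(cfg)
  expect_true(all(vapply(sim$runs, nProteins, numeric(1)) == 50L))
  m <- mergeRuns(lapply(sim$runs, relativeToPool), sim$meta)
  expect_false(anyNA(ratios(m)))
})

test_that("lowering the detection midpoint never loses detected proteins", {
  mids <- c(9, 7, 5, 3)
  detected <- lapply(mids, function(mid) {
    sim <- generateExperiment(synthConfig(nProteins = 120L, fracCore = 0,
                                          detectMidpoint = mid, seed = 8L))
    lapply(sim$runs, function(r) r@evidence$accession)
  })
  for (i in seq_len(length(mids) - 1L)) {
    for (r in seq_along(detected[[i]]))
      expect_true(all(detected[[i]][[r]] %in% detected[[i + 1L]][[r]]))
  }
})

test_that("missingness is run-level: an undetected protein is absent from a whole run", {
  sim <- generateExperiment(synthConfig(nProteins = 150L, fracCore = 0,
                                        detectMidpoint = 7, seed = 9L))
  m <- mergeRuns(lapply(sim$runs, relativeToPool), sim$meta)
  msk <- detectionMask(m)
  runOf <- setNames(sim$meta$run, sim$meta$sample_id)
  for (p in rownames(msk)) {
    byRun <- split(msk[p, ], runOf[colnames(msk)])
    expect_true(all(vapply(byRun, function(v) all(v) || !any(v), logical(1))))
  }
})

test_that("generated ontology is a rooted DAG obeying the true-path rule", {
  o <- generateOntology(25L, 40L, seed = 7L)
  expect_s4_class(o$dag, "OntologyDAG")
  expect_false(is.null(topoOrder(o$dag)))
  prop <- o$annotation@propagated
  for (ch in termIds(o$dag)) {
    for (pa in o$dag@parents[[ch]])
      expect_true(all(prop[[ch]] %in% prop[[pa]]))
  }
  # root covers every annotated protein
  expect_setequal(prop[[o$dag@root]], names(o$direct))
})

test_that("degenerate one-term ontology maps every annotated protein to the root", {
  o <- generateOntology(1L, 10L, seed = 1L)
  expect_identical(termIds(o$dag), o$dag@root)
  expect_setequal(o$annotation@propagated[[o$dag@root]], names(o$direct))
  expect_error(generateOntology(0L, 5L), "positive")
})

test_that("fresh adult samples are spread one per run; layout is feasible", {
  sim <- generateExperiment(synthConfig(nProteins = 10L, seed = 1L))
  adult <- sim$meta[sim$meta$group == "fresh_adult", ]
  expect_equal(sort(adult$run), sprintf("run%d", 1:4))
  expect_false(anyDuplicated(sim$meta[, c("run", "channel")]) > 0)
  expect_error(synthConfig(groups = c(fresh_fetal = 40L)), "fit")
})

test_that("run tables and metadata survive a write/read round trip", {
  sim <- generateExperiment(synthConfig(nProteins = 30L, seed = 4L))
  run <- sim$runs[[1L]]
  tf <- tempfile(fileext = ".tsv")
  writeRunTable(run, tf)
  back <- readRunTable(tf, poolChannel = run@poolChannel, runId = run@runId)
  expect_equal(back@quant, run@quant)
  expect_equal(back@evidence$accession, run@evidence$accession)
  expect_equal(back@evidence$fdrPass, run@evidence$fdrPass)
  tm <- tempfile(fileext = ".tsv")
  writeSampleMeta(sim$meta, tm)
  expect_equal(readSampleMeta(tm), sim$meta)
})

test_that("ontology OBO and annotation TSV round-trip", {
  o <- generateOntology(12L, 20L, seed = 6L)
  tf <- tempfile(fileext = ".obo")
  writeOBO(o$dag, tf)
  back <- readOBO(tf)
  expect_equal(back@terms, o$dag@terms)
  expect_equal(lapply(back@parents, sort), lapply(o$dag@parents, sort))
  ta <- tempfile(fileext = ".tsv")
  writeAnnotations(o$direct, ta)
  back2 <- readAnnotations(ta)
  expect_equal(lapply(back2, sort)[names(o$direct)],
               lapply(o$direct, sort))
})
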
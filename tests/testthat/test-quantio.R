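mkRun <- function(acc, nPep, conf, fdr, quant, pool = "113",
                  chans = c("113", "114", "115")) {
  RunTable("run1", chans, pool,
           data.frame(accession = acc, nPeptides = nPep,
                      bestSingleConf = conf, fdrPass = fdr,
                      stringsAsFactors = FALSE),
           matrix(quant, nrow = length(acc), dimnames = list(acc, chans)))
}

test_that("identification filter applies the two-peptide / 99%-single rule", {
  run <- mkRun(c("A", "B", "C", "D"),
               nPep = c(2L, 1L, 1L, 3L),
               conf = c(90, 99, 95, 92),
               fdr = c(TRUE, TRUE, TRUE, FALSE),
               quant = runif(12, 1, 100))
  out <- filterIdentifications(run)
  # two peptides at 90% kept; single at 99% kept; single at 95% removed;
  # FDR failure removed regardless of evidence
  expect_setequal(out@evidence$accession, c("A", "B"))
  expect_identical(filterIdentifications(out)@evidence, out@evidence)
})

test_that("pool normalisation is plain ratio arithmetic and drops zero-pool records", {
  run <- mkRun(c("A", "B"), c(2L, 2L), c(95, 95), c(TRUE, TRUE),
               c(100, 0, 200, 50, 300, 80))
  out <- relativeToPool(run)
  expect_equal(out@quant["A", "114"], 2.0)
  expect_equal(out@quant["A", "115"], 3.0)
  expect_true(all(out@quant[, "113"] == 1))
  expect_equal(attr(out, "dropped_no_pool"), 1L)
  expect_false("B" %in% out@evidence$accession)
})

test_that("merging runs takes the union of accessions without re-scaling", {
  r1 <- relativeToPool(mkRun(c("A", "B"), c(2L, 2L), c(95, 95), c(TRUE, TRUE),
                             c(10, 20, 20, 60, 30, 10)))
  r2 <- relativeToPool(mkRun("A", 2L, 95, TRUE, c(5, 40, 15)))
  r2@runId <- "run2"
  meta <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                     group = c("fresh_fetal", "hepg2", "fresh_adult", "hepg2"),
                     donor = c("d1", "d2", "d3", "d2"),
                     run = c("run1", "run1", "run2", "run2"),
                     channel = c("114", "115", "114", "115"))
  m <- mergeRuns(list(r1, r2), meta)
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(ratios(m)["A", "s1"], 2)     # 20/10, untouched by merge
  expect_equal(ratios(m)["A", "s3"], 8)     # 40/5 from run2
  expect_true(is.na(ratios(m)["B", "s3"]))  # B undetected in run2
  expect_false(anyNA(ratios(m)["B", c("s1", "s2")]))
  badMeta <- meta; badMeta$run[3] <- "run9"
  expect_error(mergeRuns(list(r1, r2), badMeta), "unknown run")
  poolMeta <- meta; poolMeta$channel[1] <- "113"
  expect_error(mergeRuns(list(r1, r2), poolMeta), "pool channel")
})

test_that("common-protein filter keeps exactly the fully observed rows", {
  set.seed(1)
  for (i in 1:10) {
    v <- matrix(exp(rnorm(60)), 10, 6)
    v[sample(60, sample(0:12, 1))] <- NA
    meta <- data.frame(sample_id = paste0("s", 1:6),
                       group = rep("hepg2", 6), donor = paste0("d", 1:6),
                       run = "run1", channel = paste0("c", 1:6))
    ps <- ProteomeSet(v, meta)
    out <- suppressWarnings(filterCommonProteins(ps))
    bruteForce <- sum(apply(v, 1, function(r) all(!is.na(r))))
    expect_equal(nrow(out), bruteForce)
    expect_equal(ncol(out), 6L)
  }
})

test_that("common-protein filter is the identity on complete matrices", {
  v <- matrix(exp(rnorm(20)), 5, 4)
  meta <- data.frame(sample_id = paste0("s", 1:4), group = "hepg2",
                     donor = "d", run = "run1", channel = paste0("c", 1:4))
  ps <- ProteomeSet(v, meta)
  expect_equal(ratios(filterCommonProteins(ps)), ratios(ps))
})

test_that("mean equalisation sets column means to 1, idempotently, preserving ratios", {
  v <- matrix(c(1, 3, 2, 6, 5, 10), 2, 3)
  meta <- data.frame(sample_id = paste0("s", 1:3), group = "hepg2",
                     donor = "d", run = "run1", channel = paste0("c", 1:3))
  out <- equalizeSampleMeans(ProteomeSet(v, meta))
  expect_equal(unname(ratios(out)[, "s1"]), c(0.5, 1.5))
  expect_equal(unname(colMeans(ratios(out))), rep(1, 3))
  # within-column ratios preserved exactly
  expect_equal(ratios(out)[2, ] / ratios(out)[1, ], v[2, ] / v[1, ],
               ignore_attr = TRUE)
  again <- equalizeSampleMeans(out)
  expect_equal(ratios(again), ratios(out), tolerance = 1e-12)
  expect_equal(unname(metadata(out)$pre_normalisation_means), colMeans(v))
})

test_that("run table reader enforces its format contract", {
  sim <- generateExperiment(synthConfig(nProteins = 10L, seed = 5L))
  tf <- tempfile(fileext = ".tsv")
  writeRunTable(sim$runs[[1L]], tf)
  expect_error(readRunTable(tf, poolChannel = "999"), "pool channel '999'")
  expect_error(readRunTable(tempfile(), poolChannel = "113"), "no such")
  d <- read.delim(tf, colClasses = "character")
  dup <- rbind(d, d[1, ])
  tf2 <- tempfile(fileext = ".tsv")
  write.table(dup, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readRunTable(tf2, poolChannel = "113"), "duplicate accession")
  d$area_113[2] <- "not-a-number"
  tf3 <- tempfile(fileext = ".tsv")
  write.table(d, tf3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readRunTable(tf3, poolChannel = "113"), "line\\(s\\) 3")
})

test_that("sample metadata vocabulary is closed", {
  m <- data.frame(sample_id = "s1", group = "hela", donor = "d",
                  run = "run1", channel = "114")
  tf <- tempfile(); writeSampleMeta(m, tf)
  expect_error(readSampleMeta(tf), "unknown sample group")
})
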
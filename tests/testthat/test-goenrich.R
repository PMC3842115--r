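test_that("annotation propagation is the transitive closure under is_a", {
  dag <- chainDAG(3L)   # T1 (root) <- T2 <- T3
  ann <- propagateAnnotations(list(p1 = "T3", p2 = "T2", p3 = "T1"), dag)
  expect_setequal(annotatedProteins(ann, "T3"), "p1")
  expect_setequal(annotatedProteins(ann, "T2"), c("p1", "p2"))
  expect_setequal(annotatedProteins(ann, "T1"), c("p1", "p2", "p3"))
  # a protein annotated only to the root appears only in the root set
  expect_false("p3" %in% annotatedProteins(ann, "T2"))
  expect_error(propagateAnnotations(list(p1 = "T9"), dag), "unknown term")
})

test_that("detection test equals the exact hypergeometric tail and the enumeration oracle", {
  # the worked example: N = 50 background, K = 10 annotated, n = 5
  # foreground, 3 observed
  universe <- sprintf("u%02d", 1:50)
  members <- universe[1:10]
  fa <- flatAnnotation(universe, members)
  fg <- c(universe[1:3], universe[21:22])
  res <- detectionTest(fg, fa$ann, fa$dag, minSize = 1L)
  pT2 <- res$p[res$term == "T2"]
  expect_equal(pT2, sum(dhyper(3:5, 10, 40, 5)), tolerance = 1e-12)
  # exhaustive subset enumeration on reduced universes (N <= 12)
  set.seed(9)
  for (i in 1:8) {
    N <- sample(6:12, 1)
    uni <- sprintf("p%02d", seq_len(N))
    mem <- sample(uni, sample(2:(N - 2), 1))
    fgs <- sample(uni, sample(2:(N - 1), 1))
    fa2 <- flatAnnotation(uni, mem)
    r2 <- detectionTest(fgs, fa2$ann, fa2$dag, minSize = 1L)
    expect_equal(r2$p[r2$term == "T2"],
                 enumHyperP(N, match(mem, uni), length(fgs),
                            length(intersect(fgs, mem))),
                 tolerance = 1e-12)
  }
})

test_that("detection test degenerate cases give p = 1", {
  universe <- sprintf("u%02d", 1:20)
  fa <- flatAnnotation(universe, universe[1:6])
  # no foreground annotation to the term
  r <- detectionTest(universe[10:14], fa$ann, fa$dag, minSize = 1L)
  expect_equal(r$p[r$term == "T2"], 1)
  # foreground = background: no enrichment possible anywhere
  r2 <- detectionTest(universe, fa$ann, fa$dag, minSize = 1L)
  expect_true(all(r2$p == 1))
  expect_error(detectionTest(character(), fa$ann, fa$dag), "empty")
})

test_that("absWilcox p-values are exact for small groups", {
  scores <- c(a = 2.0, b = 1.8, c = 0.1, d = 0.2)
  expect_equal(pcScoreTest(scores, c("a", "b"), "absWilcox"), 1 / 6)
  expect_equal(enumAbsWilcoxP(scores, c("a", "b")), 1 / 6)
  set.seed(12)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    s <- setNames(rnorm(n), paste0("p", seq_len(n)))
    ann <- sample(names(s), sample(2:min(8, n - 1), 1))
    expect_equal(pcScoreTest(s, ann, "absWilcox"), enumAbsWilcoxP(s, ann),
                 tolerance = 1e-12)
  }
})

test_that("rank tests behave as rank tests", {
  set.seed(3)
  s <- setNames(rnorm(30), paste0("p", 1:30))
  ann <- paste0("p", 1:6)
  # wilcox is invariant under strictly monotone transforms
  expect_equal(pcScoreTest(s, ann, "wilcox"),
               pcScoreTest(exp(s) + 2, ann, "wilcox"))
  # ks on identical value lists: D = 0, p = 1
  sid <- setNames(rep(c(1, 2, 3), times = 10), paste0("q", 1:30))
  expect_equal(pcScoreTest(sid, paste0("q", c(1, 2, 3)), "ks"), 1)
  expect_error(pcScoreTest(s, names(s), "wilcox"), "undefined")
  expect_error(pcScoreTest(s, character(), "wilcox"), "no annotated")
})

test_that("elimination removes a specific term's proteins from its ancestors", {
  # hand-simulated two-node chain: the child's proteins are the extreme
  # ones and the root has nothing else, so after elimination the root
  # drops below the minimum testable size
  dag <- chainDAG(2L)
  extreme <- setNames(c(10, 9.5, 9, 8.5), paste0("e", 1:4))
  bulk <- setNames(seq(0.01, 0.2, length.out = 20), paste0("b", 1:20))
  scores <- c(extreme, bulk)
  direct <- setNames(as.list(rep("T2", 4)), names(extreme))
  ann <- propagateAnnotations(direct, dag)
  res <- elimEnrichment(scores, dag, ann, method = "absWilcox",
                        elimThreshold = 0.01, reportThreshold = 0.01,
                        minSize = 3L)
  expect_identical(res$term, "T2")
  tested <- attr(res, "tested")
  expect_false("T1" %in% tested$term)   # root emptied, below minSize
  # with elimination disabled the root inherits the signal and is tested
  resFlat <- elimEnrichment(scores, dag, ann, method = "absWilcox",
                            elimThreshold = 0, reportThreshold = 0.01,
                            minSize = 3L)
  testedFlat <- attr(resFlat, "tested")
  expect_true("T1" %in% testedFlat$term)
  expect_equal(testedFlat[testedFlat$term == "T2", "n_eliminated"], 0L)
})

test_that("elimThreshold = 0 reproduces flat per-term testing", {
  o <- generateOntology(15L, 60L, seed = 4L)
  scores <- setNames(rnorm(60), sprintf("P%04d", 1:60))
  res <- elimEnrichment(scores, o$dag, o$annotation, method = "absWilcox",
                        elimThreshold = 0, reportThreshold = 1.0001,
                        minSize = 3L)
  tested <- attr(res, "tested")
  for (i in seq_len(nrow(tested))) {
    t <- tested$term[i]
    cur <- intersect(annotatedProteins(o$annotation, t), names(scores))
    expect_equal(tested$p[i], pcScoreTest(scores, cur, "absWilcox"))
    expect_equal(tested$n_eliminated[i], 0L)
  }
})

test_that("elimination never increases an ancestor's annotation count", {
  o <- generateOntology(25L, 80L, seed = 6L)
  scores <- setNames(rnorm(80), sprintf("P%04d", 1:80))
  scores[annotatedProteins(o$annotation, termIds(o$dag)[10])] <- rnorm(
    length(annotatedProteins(o$annotation, termIds(o$dag)[10])), 0, 8)
  res <- elimEnrichment(scores, o$dag, o$annotation, elimThreshold = 0.05,
                        reportThreshold = 1.0001, minSize = 2L)
  tested <- attr(res, "tested")
  for (i in seq_len(nrow(tested))) {
    orig <- length(intersect(annotatedProteins(o$annotation, tested$term[i]),
                             names(scores)))
    expect_lte(tested$n_annotated[i], orig)
    expect_equal(tested$n_annotated[i] + tested$n_eliminated[i], orig)
  }
})

test_that("term clustering is single-linkage on Jaccard overlap", {
  rec <- data.frame(term = c("A", "B", "C"), name = c("a", "b", "c"),
                    test = "absWilcox", n_annotated = 3L, n_eliminated = 0L,
                    p = 1e-4, q = 1e-4, median_score = 0)
  sets <- list(A = c("p1", "p2", "p3"), B = c("p2", "p3", "p4"),
               C = c("p4", "p5", "p6"))
  # A~B = 2/4, B~C = 1/5, A~C = 0: chain at 0.2 links all three
  out <- clusterTerms(rec, sets, jaccardMin = 0.2)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_proteins, 6L)
  # identical sets collapse; disjoint sets stay singletons
  out2 <- clusterTerms(rec, list(A = c("p1"), B = c("p1"), C = c("p9")),
                       jaccardMin = 0.5)
  expect_equal(nrow(out2), 2L)
  expect_error(clusterTerms(rec[0, ], sets), "no enrichment")
})

test_that("violin tables carry full score lists and consistent medians", {
  scores <- setNames(c(5, 4, 3, -1, 0, 1), paste0("p", 1:6))
  rec <- data.frame(term = "A", name = "a", test = "absWilcox",
                    n_annotated = 3L, n_eliminated = 0L, p = 1e-4, q = 1e-4,
                    median_score = 4)
  vt <- violinTable(rec, scores, sets = list(A = c("p1", "p2", "p3")))
  base <- vt[vt$label == "All Proteins", ]
  expect_setequal(base$accession, names(scores))
  expect_equal(unique(base$median_score), median(scores))
  a <- vt[vt$label == "A", ]
  expect_equal(unique(a$median_score), median(a$score))
  expect_equal(unique(a$median_score), 4)
})
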
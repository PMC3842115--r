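#' Hypergeometric detection test for term over-representation
#'
#' Tests each ontology term for over-representation of its annotated
#' proteins among the detected foreground versus the full annotated
#' background universe (one-sided hypergeometric upper tail). The universe
#' is whatever the annotation map covers and is never hard-coded.
#'
#' @param foreground character vector of detected proteins (subset of the
#'   annotated universe).
#' @param annotation an \code{AnnotationMap} over the background universe.
#' @param dag the \code{OntologyDAG} (for term names).
#' @param minSize smallest background annotation count tested (default 3).
#' @return data.frame (one row per tested term, sorted by p): \code{term},
#'   \code{name}, \code{test}, \code{n_annotated}, \code{n_foreground},
#'   \code{p}, \code{q} (Benjamini-Hochberg over tested terms, reported for
#'   convenience; inference in the pipeline uses raw p).
#' @export
detectionTest <- function(foreground, annotation, dag, minSize = 3L) {
  universe <- sort(unique(unlist(annotation@propagated, use.names = FALSE)))
  if (length(foreground) == 0L) stop("empty foreground")
  extra <- setdiff(foreground, universe)
  if (length(extra))
    stop("foreground proteins absent from the annotated universe: ",
         paste(head(extra, 5L), collapse = ", "))
  N <- length(universe)
  n <- length(unique(foreground))
  nm <- termNames(dag)
  rows <- lapply(names(annotation@propagated), function(t) {
    members <- annotation@propagated[[t]]
    K <- length(members)
    if (K < minSize) return(NULL)
    k <- length(intersect(foreground, members))
    data.frame(term = t, name = unname(nm[t]), test = "detection",
               n_annotated = K, n_foreground = k,
               p = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(data.frame())
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), , drop = FALSE]
}

#' Rank test of a term's principal-component scores
#'
#' Tests whether a term's annotated proteins have unusual scores on one
#' principal component. Methods: \code{absWilcox} -- one-sided Wilcoxon
#' rank-sum on absolute scores, alternative that annotated proteins are more
#' extreme; \code{wilcox} -- two-sided rank-sum on raw scores; \code{ks} --
#' two-sample two-sided Kolmogorov-Smirnov on raw scores. Rank-sum p-values
#' are exact (full rank-permutation null) when both group sizes are <= 8 and
#' there are no ties, otherwise the normal approximation with tie correction
#' is used.
#'
#' @param scores named numeric protein -> component score.
#' @param annotated character vector of annotated proteins; must be a
#'   nonempty strict subset of \code{names(scores)}.
#' @param method \code{"absWilcox"}, \code{"wilcox"} or \code{"ks"}.
#' @return p-value.
#' @export
pcScoreTest <- function(scores, annotated, method = c("absWilcox", "wilcox", "ks")) {
  method <- match.arg(method)
  annotated <- intersect(annotated, names(scores))
  if (length(annotated) == 0L) stop("no annotated protein has a score")
  rest <- setdiff(names(scores), annotated)
  if (length(rest) == 0L)
    stop("test undefined: every scored protein is annotated to the term")
  a <- scores[annotated]; b <- scores[rest]
  if (method == "ks")
    return(suppressWarnings(ks.test(a, b))$p.value)
  if (method == "absWilcox") { a <- abs(a); b <- abs(b) }
  useExact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
  alt <- if (method == "absWilcox") "greater" else "two.sided"
  suppressWarnings(
    wilcox.test(a, b, alternative = alt, exact = useExact,
                correct = !useExact)$p.value)
}

#' PC-score enrichment under ontology elimination
#'
#' Visits terms most specific first (reverse topological order, ties broken
#' by term id) and applies \code{\link{pcScoreTest}} to each term's current
#' annotation set. When a term is significant at \code{elimThreshold}, its
#' current proteins are removed from the annotation sets of all its
#' ancestors before those are tested, so generic ancestors are not reported
#' merely because they inherit a specific signal. Terms whose current set is
#' smaller than \code{minSize} (or covers every scored protein) are not
#' tested.
#'
#' @param scores named numeric protein -> component score; must cover every
#'   annotated protein.
#' @param dag an \code{OntologyDAG}.
#' @param annotation an \code{AnnotationMap}.
#' @param method test variant, see \code{\link{pcScoreTest}}.
#' @param elimThreshold p below which a term's proteins are eliminated from
#'   ancestors (default 0.001).
#' @param reportThreshold p below which a tested term is reported
#'   (default 0.001).
#' @param minSize minimum tested annotation-set size (default 3).
#' @return data.frame of reported terms sorted by p (\code{term},
#'   \code{name}, \code{test}, \code{n_annotated} after elimination,
#'   \code{n_eliminated}, \code{p}, \code{q} BH over all tested terms,
#'   \code{median_score}), with the post-elimination protein sets of the
#'   reported terms in \code{attr(, "sets")} and all tested terms in
#'   \code{attr(, "tested")}.
#' @export
elimEnrichment <- function(scores, dag, annotation,
                           method = c("absWilcox", "wilcox", "ks"),
                           elimThreshold = 0.001, reportThreshold = 0.001,
                           minSize = 3L) {
  method <- match.arg(method)
  order <- topoOrder(dag)
  if (is.null(order)) stop("ontology is_a graph contains a cycle")
  annotatedAll <- unique(unlist(annotation@propagated, use.names = FALSE))
  missing <- setdiff(annotatedAll, names(scores))
  if (length(missing))
    stop("scores missing for annotated protein(s): ",
         paste(head(missing, 5L), collapse = ", "))
  current <- lapply(annotation@propagated, function(v) intersect(v, names(scores)))
  nm <- termNames(dag)
  tested <- list()
  for (t in order) {
    cur <- current[[t]]
    if (is.null(cur)) next
    orig <- intersect(annotation@propagated[[t]], names(scores))
    if (length(cur) < minSize || length(cur) >= length(scores)) next
    p <- pcScoreTest(scores, cur, method)
    tested[[t]] <- data.frame(
      term = t, name = unname(nm[t]), test = method,
      n_annotated = length(cur), n_eliminated = length(orig) - length(cur),
      p = p, median_score = median(scores[cur]), stringsAsFactors = FALSE)
    if (p < elimThreshold) {
      for (anc in termAncestors(dag, t))
        if (!is.null(current[[anc]]))
          current[[anc]] <- setdiff(current[[anc]], cur)
    }
  }
  testedDf <- do.call(rbind, unname(tested))
  if (is.null(testedDf))
    testedDf <- data.frame(term = character(), name = character(),
                           test = character(), n_annotated = integer(),
                           n_eliminated = integer(), p = numeric(),
                           median_score = numeric())
  testedDf$q <- p.adjust(testedDf$p, method = "BH")
  out <- testedDf[testedDf$p < reportThreshold, , drop = FALSE]
  out <- out[order(out$p, out$term),
             c("term", "name", "test", "n_annotated", "n_eliminated",
               "p", "q", "median_score")]
  rownames(out) <- NULL
  attr(out, "sets") <- setNames(lapply(out$term, function(t) current[[t]]),
                                out$term)
  attr(out, "tested") <- testedDf
  out
}

#' Group overlapping significant terms
#'
#' Single-linkage grouping of reported terms whose post-elimination protein
#' sets overlap at Jaccard >= \code{jaccardMin}; strongly overlapping terms
#' (e.g. many ribosomal-function terms sharing one protein set) collapse to
#' a single cluster reported with its union protein set.
#'
#' @param records data.frame from \code{\link{elimEnrichment}} (its
#'   \code{"sets"} attribute is used unless \code{sets} is given).
#' @param sets optional named list term -> protein set.
#' @param jaccardMin Jaccard threshold in (0, 1].
#' @return data.frame: \code{cluster}, \code{terms} (comma-joined member
#'   ids), \code{n_terms}, \code{n_proteins}, \code{proteins} (comma-joined
#'   union set).
#' @export
clusterTerms <- function(records, sets = NULL, jaccardMin = 0.5) {
  if (nrow(records) == 0L) stop("no enrichment records to cluster")
  if (is.null(sets)) sets <- attr(records, "sets")
  terms <- records$term
  n <- length(terms)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    a <- sets[[terms[i]]]; b <- sets[[terms[j]]]
    jac <- length(intersect(a, b)) / length(union(a, b))
    if (jac >= jaccardMin) parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ids <- match(comp, unique(comp))
  do.call(rbind, lapply(seq_len(max(ids)), function(cid) {
    member <- terms[ids == cid]
    un <- sort(unique(unlist(sets[member], use.names = FALSE)))
    data.frame(cluster = cid, terms = paste(member, collapse = ","),
               n_terms = length(member), n_proteins = length(un),
               proteins = paste(un, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Score-distribution table for violin plots
#'
#' Emits, for every reported term plus an \code{"All Proteins"} baseline,
#' the full list of member scores with the set median attached to each row,
#' ready for violin plotting of enriched terms along a component.
#'
#' @param records data.frame from \code{\link{elimEnrichment}}.
#' @param scores named numeric protein -> score.
#' @param sets optional named list term -> protein set (defaults to the
#'   records' \code{"sets"} attribute).
#' @return long data.frame: \code{label}, \code{accession}, \code{score},
#'   \code{median_score}.
#' @export
violinTable <- function(records, scores, sets = NULL) {
  if (is.null(sets)) sets <- attr(records, "sets")
  blocks <- list(data.frame(label = "All Proteins",
                            accession = names(scores),
                            score = unname(scores),
                            median_score = median(scores),
                            stringsAsFactors = FALSE))
  for (t in records$term) {
    member <- sets[[t]]
    blocks[[length(blocks) + 1L]] <- data.frame(
      label = t, accession = member, score = unname(scores[member]),
      median_score = median(scores[member]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
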
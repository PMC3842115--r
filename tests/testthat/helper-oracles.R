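# Independent oracles, kept deliberately naive so they share no code path
# with the implementation they check.

# O(n^3) agglomeration recomputing the linkage over every active cluster
# pair at each step, from the original distances. Returns the cophenetic
# matrix, which identifies dendrogram topology and merge heights.
naiveCophenetic <- function(d, linkage = "complete") {
  d <- as.matrix(d)
  n <- nrow(d)
  linkfun <- switch(linkage, complete = max, single = min, average = mean)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      h <- linkfun(d[clusters[[i]], clusters[[j]]])
      if (h < best[1L]) best <- c(h, i, j)
    }
    coph[clusters[[best[2L]]], clusters[[best[3L]]]] <- best[1L]
    coph[clusters[[best[3L]]], clusters[[best[2L]]]] <- best[1L]
    clusters[[best[2L]]] <- c(clusters[[best[2L]]], clusters[[best[3L]]])
    clusters[[best[3L]]] <- NULL
  }
  coph
}

# Brute-force PCA via eigendecomposition of the sample covariance matrix.
eigenPCAOracle <- function(x) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  e <- eigen(cov(xc), symmetric = TRUE)
  list(varfrac = e$values / sum(e$values),
       scores = xc %*% e$vectors)
}

# Exact one-sided p for the rank-sum of |scores| of the annotated set:
# enumerate every equally likely assignment of the annotated labels to the
# pooled ranks.
enumAbsWilcoxP <- function(scores, annotated) {
  a <- abs(scores[annotated])
  b <- abs(scores[setdiff(names(scores), annotated)])
  r <- rank(c(a, b))
  obs <- sum(r[seq_along(a)])
  subs <- combn(length(r), length(a))
  mean(apply(subs, 2L, function(ix) sum(r[ix])) >= obs)
}

# Exhaustive hypergeometric tail: fraction of all foreground subsets with at
# least the observed member count.
enumHyperP <- function(universeSize, memberIdx, fgSize, kObs) {
  subs <- combn(universeSize, fgSize)
  mean(apply(subs, 2L, function(ix) sum(ix %in% memberIdx)) >= kObs)
}

# Chain ontology T1 (root) <- T2 <- ... <- Tn.
chainDAG <- function(n) {
  ids <- paste0("T", seq_len(n))
  OntologyDAG(
    data.frame(id = ids, name = paste("chain term", seq_len(n)),
               stringsAsFactors = FALSE),
    setNames(lapply(seq_len(n), function(i)
      if (i == 1L) character() else ids[i - 1L]), ids))
}

# Two-term ontology: a root and one child annotated with `members`; all
# other proteins are annotated directly to the root.
flatAnnotation <- function(universe, members) {
  dag <- chainDAG(2L)
  direct <- setNames(lapply(universe, function(p)
    if (p %in% members) "T2" else "T1"), universe)
  list(dag = dag, ann = propagateAnnotations(direct, dag))
}

# Standard integration: identification filter, pool normalisation, merge,
# common-protein filter, mean equalisation.
integrateSim <- function(sim) {
  runs <- lapply(lapply(sim$runs, filterIdentifications), relativeToPool)
  equalizeSampleMeans(filterCommonProteins(mergeRuns(runs, sim$meta)))
}

adultGroups <- c("fresh_adult", "adult_ali3d", "adult_ecm")

# Planted adult-vs-rest per-protein effect implied by a truth object.
plantedAdultEffect <- function(truth) {
  E <- truth@groupEffect
  rowMeans(E[, adultGroups, drop = FALSE]) -
    rowMeans(E[, setdiff(colnames(E), adultGroups), drop = FALSE])
}
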
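#' Principal component analysis with proteins as observations
#'
#' Decomposes the common-protein matrix with proteins as observations and
#' samples as variables: protein scores are the coordinates of each protein
#' on a component, sample loadings the orthonormal weights defining it.
#' Columns (samples) are mean-centred after the chosen transform; no
#' variance scaling is applied, so the reported variance fractions decompose
#' the actual between-sample variance. The solver is a full deterministic
#' SVD; the number of components is \code{min(nProteins - 1, nSamples)}.
#'
#' @param x a complete \code{ProteomeSet} or proteins x samples matrix.
#' @param transform \code{"log2"} (default) or \code{"none"}.
#' @return a \code{PCAResult}.
#' @export
runPCA <- function(x, transform = c("log2", "none")) {
  transform <- match.arg(transform)
  v <- if (is(x, "ProteomeSet")) assay(x, "ratio") else x
  if (anyNA(v)) stop("PCA requires a complete matrix")
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("PCA needs >= 2 proteins and >= 2 samples")
  if (transform == "log2") v <- log2(v)
  if (all(abs(sweep(v, 2L, colMeans(v))) < 1e-12))
    stop("degenerate input: matrix is constant within every sample")
  fit <- prcomp(v, center = TRUE, scale. = FALSE)
  k <- min(nrow(v) - 1L, ncol(v))
  ev <- fit$sdev[seq_len(k)]^2
  new("PCAResult",
      proteinScores = fit$x[, seq_len(k), drop = FALSE],
      sampleLoadings = fit$rotation[, seq_len(k), drop = FALSE],
      varianceFraction = ev / sum(fit$sdev^2),
      center = fit$center,
      transform = transform)
}

#' Orient principal components by anchor groups
#'
#' PC signs are arbitrary; anchors fix them to a convention (e.g. adult
#' hepatocytes positive on PC1) by negating a component's loadings and
#' scores whenever the mean loading of the anchor group has the wrong sign.
#' Variance fractions are untouched. An anchor whose group mean loading is
#' exactly zero cannot orient the component: a warning is issued and the
#' component left as computed.
#'
#' @param r a \code{PCAResult}.
#' @param groups named sample -> group vector.
#' @param anchors list of \code{list(component =, group =, sign =)} with
#'   sign +1 or -1.
#' @return oriented \code{PCAResult}.
#' @export
orientComponents <- function(r, groups, anchors) {
  for (a in anchors) {
    comp <- a$component
    sel <- names(groups)[groups == a$group]
    if (!length(sel) || !all(sel %in% rownames(r@sampleLoadings)))
      stop("anchor group absent from loadings: ", a$group)
    m <- mean(r@sampleLoadings[sel, comp])
    if (m == 0) {
      warning(sprintf("component %d orientation unresolved: anchor group %s has zero mean loading",
                      comp, a$group))
      next
    }
    if (sign(m) != sign(a$sign)) {
      r@sampleLoadings[, comp] <- -r@sampleLoadings[, comp]
      r@proteinScores[, comp] <- -r@proteinScores[, comp]
    }
  }
  r
}

#' Write a PCAResult as three TSV files
#'
#' Emits \code{<prefix>_scores.tsv} (protein scores),
#' \code{<prefix>_loadings.tsv} (sample loadings) and
#' \code{<prefix>_variance.tsv}; components are labelled \code{PC1}, ...
#'
#' @param r a \code{PCAResult}.
#' @param prefix output path prefix.
#' @export
writePCAResult <- function(r, prefix) {
  k <- length(r@varianceFraction)
  pcs <- sprintf("PC%d", seq_len(k))
  sc <- r@proteinScores; colnames(sc) <- pcs
  ld <- r@sampleLoadings; colnames(ld) <- pcs
  write.table(data.frame(accession = rownames(sc), sc, check.names = FALSE),
              paste0(prefix, "_scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = rownames(ld), ld, check.names = FALSE),
              paste0(prefix, "_loadings.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(component = pcs,
                         variance_fraction = r@varianceFraction),
              paste0(prefix, "_variance.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
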
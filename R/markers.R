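#' Top-k proteins of a signed score ranking
#'
#' Ranks proteins by a component score in the requested direction and
#' returns the first k. Ties at any rank are broken by accession
#' (lexicographic); when the tie straddles the k-th rank the occurrence is
#' recorded in the \code{"tie_at_k"} attribute, since the chosen membership
#' is then convention, not data.
#'
#' @param scores named numeric protein -> score.
#' @param direction \code{"most_negative"} or \code{"most_positive"}.
#' @param k list length (default 75, the pipeline's signature size).
#' @return character vector of k accessions, ranked.
#' @export
topK <- function(scores, direction = c("most_negative", "most_positive"),
                 k = 75L) {
  direction <- match.arg(direction)
  if (k <= 0L) stop("k must be positive")
  if (k > length(scores)) stop("k exceeds the number of proteins")
  s <- if (direction == "most_negative") scores else -scores
  ord <- order(s, names(s))
  out <- names(s)[ord[seq_len(k)]]
  tie <- k < length(s) && s[ord[k]] == s[ord[k + 1L]]
  attr(out, "tie_at_k") <- tie
  out
}

#' Marker signature from intersecting top-k score lists
#'
#' Derives a cell-type signature as the intersection of top-k protein lists
#' taken from signed component rankings (e.g. most-negative PC1 with
#' most-positive PC2 for fresh fetal hepatocytes). An empty intersection is
#' a valid empty signature.
#'
#' @param scoresets matrix or data.frame of protein scores with one column
#'   per component (e.g. \code{proteinScores(pca)}), or named list of score
#'   vectors.
#' @param criteria data.frame with columns \code{component} (integer index)
#'   and \code{direction}.
#' @param k per-list length (default 75).
#' @param name signature label.
#' @return a \code{MarkerSet}.
#' @export
markerSignature <- function(scoresets, criteria, k = 75L, name = "signature") {
  getScores <- function(comp) {
    if (is.list(scoresets) && !is.data.frame(scoresets)) scoresets[[comp]]
    else setNames(scoresets[, comp], rownames(scoresets))
  }
  lists <- vector("list", nrow(criteria))
  for (i in seq_len(nrow(criteria))) {
    comp <- criteria$component[i]
    if (comp > (if (is.list(scoresets) && !is.data.frame(scoresets))
                  length(scoresets) else ncol(scoresets)))
      stop("criterion references unknown component PC", comp)
    lists[[i]] <- topK(getScores(comp), criteria$direction[i], k)
  }
  common <- Reduce(intersect, lists)
  prot <- data.frame(accession = common, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(criteria))) {
    comp <- criteria$component[i]
    prot[[sprintf("PC%d_score", comp)]] <- unname(getScores(comp)[common])
    prot[[sprintf("PC%d_rank", comp)]] <- match(common, lists[[i]])
  }
  new("MarkerSet", name = name, criteria = criteria, k = as.integer(k),
      proteins = prot)
}

#' Single extreme protein under sign constraints
#'
#' Among proteins satisfying every sign constraint on other components,
#' returns the protein optimal in the primary direction (e.g. the protein
#' with the lowest PC1 score among those with positive PC2 scores). Ties
#' are broken by accession.
#'
#' @param scoresets as in \code{\link{markerSignature}}.
#' @param primary list \code{(component =, direction =)}.
#' @param constraints list of \code{list(component =, sign =)} with sign
#'   \code{"positive"} or \code{"negative"}.
#' @return single accession.
#' @export
extremeProtein <- function(scoresets, primary, constraints = list()) {
  getScores <- function(comp) {
    if (is.list(scoresets) && !is.data.frame(scoresets)) scoresets[[comp]]
    else setNames(scoresets[, comp], rownames(scoresets))
  }
  s <- getScores(primary$component)
  ok <- rep(TRUE, length(s))
  for (con in constraints) {
    cs <- getScores(con$component)[names(s)]
    ok <- ok & if (con$sign == "positive") cs > 0 else cs < 0
  }
  if (!any(ok)) stop("no protein satisfies the sign constraints")
  s <- s[ok]
  v <- if (primary$direction == "most_negative") s else -s
  names(v)[order(v, names(v))][1L]
}

#' Write a MarkerSet as TSV
#' @param ms a \code{MarkerSet}.
#' @param path output path.
#' @export
writeMarkerSet <- function(ms, path) {
  write.table(ms@proteins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
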
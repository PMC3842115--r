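#' @import methods
#' @importFrom stats median prcomp hclust as.dist cutree cor dist cov
#'   phyper wilcox.test ks.test p.adjust rnorm runif rbinom plogis setNames
#' @importFrom utils read.delim write.table head combn
#' @importFrom tools md5sum
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @import SummarizedExperiment
NULL

#' Sample group vocabulary
#'
#' The six sample groups of the comparative hepatocyte study design: fresh
#' fetal hepatocytes, fresh adult hepatocytes, HepG2 cells, and the cultured
#' formats (fetal air-liquid-interface 3D, adult air-liquid-interface 3D,
#' adult extracellular-matrix sandwich).
#' @export
SAMPLE_GROUPS <- c("fresh_fetal", "fresh_adult", "hepg2",
                   "fetal_ali3d", "adult_ali3d", "adult_ecm")

#' One isobaric labelling run
#'
#' Holds one 8-plex run's per-protein channel quantities together with the
#' identification evidence used by the confidence filter: number of peptides
#' at >= 90% confidence, best single-peptide confidence, and the run-level
#' FDR flag.
#'
#' @slot runId single run identifier.
#' @slot channelLabels ordered reporter-channel labels.
#' @slot poolChannel which channel carries the common reference pool.
#' @slot evidence data.frame with columns \code{accession}, \code{nPeptides},
#'   \code{bestSingleConf}, \code{fdrPass}.
#' @slot quant numeric matrix (proteins x channels) of reporter quantities;
#'   \code{NA} marks a channel not quantified.
#' @export
setClass("RunTable", slots = c(
  runId = "character",
  channelLabels = "character",
  poolChannel = "character",
  evidence = "data.frame",
  quant = "matrix"
))

setValidity("RunTable", function(object) {
  msg <- character()
  if (length(object@runId) != 1L) msg <- c(msg, "runId must be a single string")
  if (!(object@poolChannel %in% object@channelLabels))
    msg <- c(msg, sprintf("pool channel '%s' not among channel labels",
                          object@poolChannel))
  need <- c("accession", "nPeptides", "bestSingleConf", "fdrPass")
  if (!all(need %in% names(object@evidence)))
    msg <- c(msg, paste("evidence must have columns:", paste(need, collapse = ", ")))
  else if (anyDuplicated(object@evidence$accession))
    msg <- c(msg, "duplicate accession in run table")
  if (nrow(object@quant) != nrow(object@evidence))
    msg <- c(msg, "quant rows must match evidence rows")
  if (!identical(colnames(object@quant), object@channelLabels))
    msg <- c(msg, "quant columns must equal channelLabels")
  if (any(object@quant < 0, na.rm = TRUE))
    msg <- c(msg, "negative reporter quantities are not permitted")
  if (length(msg)) msg else TRUE
})

#' @describeIn RunTable construct a validated run table.
#' @param runId,channelLabels,poolChannel,evidence,quant see slots.
#' @export
RunTable <- function(runId, channelLabels, poolChannel, evidence, quant) {
  rownames(quant) <- evidence$accession
  colnames(quant) <- channelLabels
  new("RunTable", runId = as.character(runId),
      channelLabels = as.character(channelLabels),
      poolChannel = as.character(poolChannel),
      evidence = evidence, quant = quant)
}

setMethod("show", "RunTable", function(object) {
  cat("RunTable '", object@runId, "': ", nrow(object@evidence),
      " proteins x ", length(object@channelLabels), " channels (pool: ",
      object@poolChannel, ")\n", sep = "")
})

#' Number of proteins in a run table
#' @param x a \code{RunTable}.
#' @export
nProteins <- function(x) nrow(x@evidence)

#' Merged proteins-by-samples pool-relative matrix
#'
#' A \code{SummarizedExperiment} subclass carrying the assay \code{"ratio"}
#' (pool-relative quantities, \code{NA} where a protein was not detected in a
#' sample's run) with sample metadata columns \code{group}, \code{donor},
#' \code{run}, \code{channel}. All present ratios are strictly positive.
#' @export
setClass("ProteomeSet", contains = "SummarizedExperiment")

setValidity("ProteomeSet", function(object) {
  msg <- character()
  if (!("ratio" %in% assayNames(object)))
    msg <- c(msg, "assay 'ratio' is required")
  else {
    v <- assay(object, "ratio")
    if (any(v <= 0, na.rm = TRUE))
      msg <- c(msg, "pool-relative quantities must be > 0 where present")
  }
  need <- c("group", "donor", "run", "channel")
  if (!all(need %in% names(colData(object))))
    msg <- c(msg, paste("colData must have columns:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn ProteomeSet construct from a ratio matrix and sample metadata.
#' @param ratio proteins x samples matrix of pool-relative quantities
#'   (\code{NA} = not detected).
#' @param meta data.frame of sample metadata (rows match columns of
#'   \code{ratio}) with columns \code{sample_id}, \code{group}, \code{donor},
#'   \code{run}, \code{channel}.
#' @export
ProteomeSet <- function(ratio, meta) {
  stopifnot(nrow(meta) == ncol(ratio))
  cd <- DataFrame(group = meta$group, donor = meta$donor,
                  run = meta$run, channel = meta$channel,
                  row.names = meta$sample_id)
  colnames(ratio) <- meta$sample_id
  new("ProteomeSet", SummarizedExperiment(
    assays = list(ratio = ratio), colData = cd))
}

setMethod("show", "ProteomeSet", function(object) {
  v <- assay(object, "ratio")
  cat("ProteomeSet: ", nrow(object), " proteins x ", ncol(object),
      " samples; ", sum(is.na(v)), " missing values (",
      sprintf("%.1f%%", 100 * mean(is.na(v))), ")\n", sep = "")
  cat("groups: ", paste(sort(unique(colData(object)$group)), collapse = ", "),
      "\n", sep = "")
})

#' Pool-relative quantity matrix of a ProteomeSet
#' @param x a \code{ProteomeSet}.
#' @export
ratios <- function(x) assay(x, "ratio")

#' Detection mask of a ProteomeSet
#'
#' TRUE where the protein was quantified in the sample's run.
#' @param x a \code{ProteomeSet}.
#' @export
detectionMask <- function(x) !is.na(assay(x, "ratio"))

#' Named sample-to-group vector of a ProteomeSet
#' @param x a \code{ProteomeSet}.
#' @export
sampleGroups <- function(x) setNames(as.character(colData(x)$group), colnames(x))

#' Principal component decomposition of the proteome matrix
#'
#' Proteins are observations and samples are variables: \code{proteinScores}
#' are the observation coordinates on each component, \code{sampleLoadings}
#' the orthonormal variable weights, \code{varianceFraction} the per-component
#' share of total variance (sums to 1).
#'
#' @slot proteinScores proteins x components matrix.
#' @slot sampleLoadings samples x components matrix with orthonormal columns.
#' @slot varianceFraction per-component variance fraction.
#' @slot center per-sample mean removed before decomposition.
#' @slot transform \code{"log2"} or \code{"none"}.
#' @export
setClass("PCAResult", slots = c(
  proteinScores = "matrix",
  sampleLoadings = "matrix",
  varianceFraction = "numeric",
  center = "numeric",
  transform = "character"
))

setValidity("PCAResult", function(object) {
  msg <- character()
  k <- ncol(object@proteinScores)
  if (ncol(object@sampleLoadings) != k || length(object@varianceFraction) != k)
    msg <- c(msg, "component dimensions inconsistent")
  if (abs(sum(object@varianceFraction) - 1) > 1e-8)
    msg <- c(msg, "variance fractions must sum to 1")
  if (is.unsorted(rev(object@varianceFraction), strictly = FALSE))
    msg <- c(msg, "components must be ordered by non-increasing variance")
  if (!(object@transform %in% c("log2", "none")))
    msg <- c(msg, "transform must be 'log2' or 'none'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PCAResult", function(object) {
  k <- min(4L, length(object@varianceFraction))
  cat("PCAResult: ", nrow(object@proteinScores), " proteins, ",
      nrow(object@sampleLoadings), " samples, ",
      length(object@varianceFraction), " components (transform: ",
      object@transform, ")\n", sep = "")
  cat("variance: ",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * object@varianceFraction[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
})

#' Protein score matrix of a PCAResult
#' @param x a \code{PCAResult}.
#' @export
proteinScores <- function(x) x@proteinScores

#' Sample loading matrix of a PCAResult
#' @param x a \code{PCAResult}.
#' @export
sampleLoadings <- function(x) x@sampleLoadings

#' Per-component variance fractions of a PCAResult
#' @param x a \code{PCAResult}.
#' @export
varianceFraction <- function(x) x@varianceFraction

#' Ontology is_a graph
#'
#' A rooted acyclic is_a graph over ontology terms; every non-root term has at
#' least one parent.
#'
#' @slot terms data.frame with columns \code{id}, \code{name}.
#' @slot parents named list mapping each term id to the character vector of
#'   its parent ids (empty for the root).
#' @slot root the single root term id.
#' @export
setClass("OntologyDAG", slots = c(
  terms = "data.frame",
  parents = "list",
  root = "character"
))

setValidity("OntologyDAG", function(object) {
  msg <- character()
  ids <- object@terms$id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate term ids")
  if (!setequal(names(object@parents), ids))
    msg <- c(msg, "parents list must be keyed by every term id")
  allpar <- unlist(object@parents, use.names = FALSE)
  if (length(allpar) && !all(allpar %in% ids))
    msg <- c(msg, "parent references unknown term")
  nroots <- sum(lengths(object@parents) == 0L)
  if (nroots != 1L) msg <- c(msg, "graph must have exactly one root")
  if (length(object@root) != 1L || !(object@root %in% ids) ||
      length(object@parents[[object@root]]) != 0L)
    msg <- c(msg, "root slot must name the parentless term")
  if (length(msg) == 0L && is.null(topoOrder(object)))
    msg <- c(msg, "is_a graph contains a cycle")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OntologyDAG", function(object) {
  cat("OntologyDAG: ", nrow(object@terms), " terms, ",
      sum(lengths(object@parents)), " is_a edges, root ", object@root,
      "\n", sep = "")
})

#' Term ids of an OntologyDAG
#' @param x an \code{OntologyDAG}.
#' @export
termIds <- function(x) x@terms$id

#' Term names of an OntologyDAG
#' @param x an \code{OntologyDAG}.
#' @export
termNames <- function(x) setNames(x@terms$name, x@terms$id)

#' Direct and propagated protein annotation
#'
#' \code{direct} maps each protein to its directly assigned terms;
#' \code{propagated} maps each term to the full set of proteins annotated to
#' it or any descendant (true-path rule: annotation to a term implies
#' annotation to all its ancestors).
#'
#' @slot direct named list protein -> character vector of term ids.
#' @slot propagated named list term id -> character vector of proteins.
#' @export
setClass("AnnotationMap", slots = c(direct = "list", propagated = "list"))

setMethod("show", "AnnotationMap", function(object) {
  cat("AnnotationMap: ", length(object@direct), " annotated proteins, ",
      length(object@propagated), " terms\n", sep = "")
})

#' Proteins annotated (after propagation) to a term
#' @param x an \code{AnnotationMap}.
#' @param term a term id.
#' @export
annotatedProteins <- function(x, term) {
  p <- x@propagated[[term]]
  if (is.null(p)) character() else p
}

#' Cell-type marker signature
#'
#' The intersection of top-k protein lists taken from signed principal
#' component scores; e.g. most-negative PC1 together with most-positive PC2
#' characterises fresh fetal hepatocytes.
#'
#' @slot name signature label.
#' @slot criteria data.frame with columns \code{component},
#'   \code{direction} (\code{most_negative}/\code{most_positive}).
#' @slot k list length per criterion.
#' @slot proteins data.frame: \code{accession}, per-criterion score and rank
#'   columns.
#' @export
setClass("MarkerSet", slots = c(
  name = "character",
  criteria = "data.frame",
  k = "integer",
  proteins = "data.frame"
))

setValidity("MarkerSet", function(object) {
  if (nrow(object@proteins) > object@k)
    "intersection cannot exceed k" else TRUE
})

setMethod("show", "MarkerSet", function(object) {
  crit <- paste(sprintf("PC%d %s", object@criteria$component,
                        object@criteria$direction), collapse = " & ")
  cat("MarkerSet '", object@name, "': ", nrow(object@proteins),
      " proteins from ", crit, " (k = ", object@k, ")\n", sep = "")
})

#' Proteins of a MarkerSet
#' @param x a \code{MarkerSet}.
#' @export
markerProteins <- function(x) x@proteins$accession
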
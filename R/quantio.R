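#' Read a per-run quantification table
#'
#' Parses a tab-separated run table (columns \code{accession},
#' \code{n_peptides}, \code{best_single_peptide_conf}, \code{fdr_pass}, then
#' \code{area_<channel>} quantity columns; \code{NA} for missing) into a
#' validated \code{RunTable}. Malformed numeric fields are reported with
#' their line numbers.
#'
#' @param path TSV path.
#' @param poolChannel reporter-channel label of the common reference pool.
#' @param runId run identifier; defaults to the file name without extension.
#' @return a \code{RunTable}.
#' @export
readRunTable <- function(path, poolChannel, runId = NULL) {
  if (!file.exists(path)) stop("no such run table: ", path)
  if (is.null(runId)) runId <- sub("\\.[^.]*$", "", basename(path))
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("accession", "n_peptides", "best_single_peptide_conf", "fdr_pass")
  if (!all(need %in% names(d)))
    stop("run table must have columns: ", paste(need, collapse = ", "))
  chanCols <- grep("^area_", names(d), value = TRUE)
  channels <- sub("^area_", "", chanCols)
  if (!(poolChannel %in% channels))
    stop(sprintf("pool channel '%s' has no quantity column in %s",
                 poolChannel, path))
  dup <- d$accession[duplicated(d$accession)]
  if (length(dup))
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  asNum <- function(col, what) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.na(d[[col]]) & d[[col]] != "NA" & is.na(v))
    if (length(bad))
      stop(sprintf("malformed %s in %s at line(s) %s", what, path,
                   paste(bad + 1L, collapse = ", ")))  # +1 for header
    v
  }
  quant <- sapply(chanCols, function(cc) asNum(cc, paste("quantity", cc)))
  quant <- matrix(quant, nrow = nrow(d),
                  dimnames = list(d$accession, channels))
  RunTable(runId = runId, channelLabels = channels, poolChannel = poolChannel,
           evidence = data.frame(
             accession = d$accession,
             nPeptides = as.integer(asNum("n_peptides", "n_peptides")),
             bestSingleConf = asNum("best_single_peptide_conf",
                                    "best_single_peptide_conf"),
             fdrPass = toupper(d$fdr_pass) %in% c("TRUE", "T", "1"),
             stringsAsFactors = FALSE),
           quant = quant)
}

#' Identification-confidence filter
#'
#' Retains proteins passing the run-level FDR cutoff and identified either by
#' two or more peptides at >= 90% confidence or by a single peptide at >= 99%
#' confidence. Idempotent.
#'
#' @param run a \code{RunTable}.
#' @return filtered \code{RunTable}.
#' @export
filterIdentifications <- function(run) {
  ev <- run@evidence
  keep <- ev$fdrPass & (ev$nPeptides >= 2L | ev$bestSingleConf >= 99)
  RunTable(run@runId, run@channelLabels, run@poolChannel,
           ev[keep, , drop = FALSE],
           run@quant[keep, , drop = FALSE])
}

#' Normalise a run to its common reference pool
#'
#' Divides every channel quantity by the same protein's pool-channel
#' quantity, making quantities comparable across runs. Proteins whose pool
#' quantity is missing or zero cannot be normalised: they are dropped and
#' counted in the \code{"dropped_no_pool"} attribute of the result.
#'
#' @param run a \code{RunTable}.
#' @return pool-normalised \code{RunTable} (pool column identically 1) with
#'   attribute \code{dropped_no_pool}.
#' @export
relativeToPool <- function(run) {
  pool <- run@quant[, run@poolChannel]
  ok <- !is.na(pool) & pool > 0
  q <- run@quant[ok, , drop = FALSE] / pool[ok]
  out <- RunTable(run@runId, run@channelLabels, run@poolChannel,
                  run@evidence[ok, , drop = FALSE], q)
  attr(out, "dropped_no_pool") <- sum(!ok)
  out
}

#' Merge pool-normalised runs into a proteins-by-samples matrix
#'
#' Takes the union of accessions over runs; the value for (protein, sample)
#' is the sample's pool-relative ratio from its own run, missing where the
#' protein was not detected in that run. Pool channels are reference only
#' and never appear as samples. No re-scaling is applied at merge: the pool
#' normalisation is what makes runs comparable.
#'
#' @param runs list of pool-normalised \code{RunTable}s.
#' @param meta sample metadata data.frame (\code{sample_id}, \code{group},
#'   \code{donor}, \code{run}, \code{channel}); must reference only known
#'   runs/channels and never a pool channel.
#' @return a \code{ProteomeSet}.
#' @export
mergeRuns <- function(runs, meta) {
  runIds <- vapply(runs, function(r) r@runId, character(1))
  names(runs) <- runIds
  bad <- setdiff(unique(meta$run), runIds)
  if (length(bad))
    stop("sample metadata references unknown run(s): ",
         paste(bad, collapse = ", "))
  for (i in seq_len(nrow(meta))) {
    r <- runs[[meta$run[i]]]
    if (!(meta$channel[i] %in% r@channelLabels))
      stop(sprintf("sample %s references unknown channel %s in %s",
                   meta$sample_id[i], meta$channel[i], meta$run[i]))
    if (meta$channel[i] == r@poolChannel)
      stop(sprintf("sample %s is assigned to the pool channel of %s",
                   meta$sample_id[i], meta$run[i]))
  }
  acc <- sort(unique(unlist(lapply(runs, function(r) r@evidence$accession))))
  m <- matrix(NA_real_, length(acc), nrow(meta),
              dimnames = list(acc, meta$sample_id))
  for (i in seq_len(nrow(meta))) {
    r <- runs[[meta$run[i]]]
    m[r@evidence$accession, i] <- r@quant[, meta$channel[i]]
  }
  ProteomeSet(m, meta)
}

#' Filter to proteins quantified in every sample
#'
#' Keeps exactly the rows with no missing value, removing any correlation
#' between protein detection and experimental run; the sample set is
#' unchanged. Downstream clustering and PCA operate on this common set.
#'
#' @param x a \code{ProteomeSet}.
#' @return a \code{ProteomeSet} with complete rows only.
#' @export
filterCommonProteins <- function(x) {
  keep <- rowSums(is.na(assay(x, "ratio"))) == 0L
  if (!any(keep))
    warning("no protein is quantified in every sample; ",
            "downstream stages need >= 2")
  out <- x[keep, ]
  metadata(out)$n_before_common_filter <- nrow(x)
  out
}

#' Equalise per-sample mean quantity
#'
#' Rescales each sample column by a positive factor so its arithmetic mean
#' across proteins equals 1, enforcing the equal total-labelling property
#' expected of pool-relative data. Pre-normalisation means are kept as a QC
#' diagnostic in \code{metadata(x)$pre_normalisation_means}; the factors in
#' \code{metadata(x)$scale_factors}. Within-column value ratios are
#' preserved exactly.
#'
#' @param x a complete \code{ProteomeSet} (post common-protein filter).
#' @return rescaled \code{ProteomeSet}.
#' @export
equalizeSampleMeans <- function(x) {
  v <- assay(x, "ratio")
  if (anyNA(v)) stop("equalizeSampleMeans requires a complete matrix")
  mu <- colMeans(v)
  if (any(mu <= 0)) stop("sample(s) with non-positive mean: ",
                         paste(colnames(v)[mu <= 0], collapse = ", "))
  assay(x, "ratio") <- sweep(v, 2L, mu, "/")
  metadata(x)$pre_normalisation_means <- mu
  metadata(x)$scale_factors <- 1 / mu
  x
}

#' Write a ProteomeSet ratio matrix as TSV
#' @param x a \code{ProteomeSet}.
#' @param path output path.
#' @export
writeProteomeSet <- function(x, path) {
  d <- data.frame(accession = rownames(x), assay(x, "ratio"),
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
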
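#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end analysis.
#' Either \code{synth} is given (simulate mode: inputs are generated, written
#' under \code{outdir/inputs} and then analysed) or the four input paths are
#' given (run mode).
#'
#' @param runTables character vector of run-table TSV paths (run mode).
#' @param sampleMeta sample metadata TSV path (run mode).
#' @param ontology OBO path (run mode).
#' @param annotations annotation TSV path (run mode).
#' @param poolChannel pool channel label (run mode; simulate mode derives it).
#' @param synth a \code{SynthConfig} for simulate mode.
#' @param synthOntologyTerms number of ontology terms generated in simulate
#'   mode.
#' @param plantings optional planted-term data.frame for simulate mode.
#' @param transform \code{"log2"} or \code{"none"}; applied to distances and
#'   PCA.
#' @param linkage clustering linkage.
#' @param anchors PC orientation anchors; default fixes the study's
#'   conventions (adult positive on PC1, fetal positive on PC2,
#'   ECM-sandwich positive on PC3).
#' @param enrichComponents components given PC-score tests.
#' @param enrichMethod PC-score test variant.
#' @param elimThreshold,reportThreshold,minTermSize enrichment thresholds.
#' @param jaccardMin overlap threshold for term clustering.
#' @param markerK top-k list length for signatures.
#' @param markerCriteria named list of criteria data.frames; defaults define
#'   the fetal, HepG2 and fresh-adult signatures.
#' @param outdir output directory.
#' @param seed root seed for every stochastic step.
#' @return validated config list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(runTables = NULL, sampleMeta = NULL,
                           ontology = NULL, annotations = NULL,
                           poolChannel = "113",
                           synth = NULL, synthOntologyTerms = 40L,
                           plantings = NULL,
                           transform = c("log2", "none"),
                           linkage = c("complete", "average", "single"),
                           anchors = list(
                             list(component = 1L, group = "fresh_adult", sign = 1),
                             list(component = 2L, group = "fresh_fetal", sign = 1),
                             list(component = 3L, group = "adult_ecm", sign = 1)),
                           enrichComponents = 1:4,
                           enrichMethod = c("absWilcox", "wilcox", "ks"),
                           elimThreshold = 0.001, reportThreshold = 0.001,
                           minTermSize = 3L, jaccardMin = 0.5,
                           markerK = 75L,
                           markerCriteria = list(
                             fresh_fetal = data.frame(
                               component = c(1L, 2L),
                               direction = c("most_negative", "most_positive")),
                             hepg2 = data.frame(
                               component = c(1L, 2L),
                               direction = c("most_negative", "most_negative")),
                             fresh_adult = data.frame(
                               component = c(1L, 3L),
                               direction = c("most_positive", "most_negative"))),
                           outdir = tempfile("proteopool_"), seed = 1L) {
  cfg <- list(runTables = runTables, sampleMeta = sampleMeta,
              ontology = ontology, annotations = annotations,
              poolChannel = poolChannel, synth = synth,
              synthOntologyTerms = as.integer(synthOntologyTerms),
              plantings = plantings,
              transform = match.arg(transform),
              linkage = match.arg(linkage), anchors = anchors,
              enrichComponents = as.integer(enrichComponents),
              enrichMethod = match.arg(enrichMethod),
              elimThreshold = elimThreshold,
              reportThreshold = reportThreshold,
              minTermSize = as.integer(minTermSize),
              jaccardMin = jaccardMin, markerK = as.integer(markerK),
              markerCriteria = markerCriteria,
              outdir = outdir, seed = as.integer(seed))
  if (is.null(cfg$synth)) {
    paths <- c(cfg$runTables, cfg$sampleMeta, cfg$ontology, cfg$annotations)
    if (is.null(paths) || length(paths) < 4L)
      stop("run mode needs runTables, sampleMeta, ontology and annotations")
    miss <- paths[!file.exists(paths)]
    if (length(miss)) stop("missing input file(s): ", paste(miss, collapse = ", "))
  } else if (!is(cfg$synth, "SynthConfig")) {
    stop("synth must be a SynthConfig")
  }
  if (cfg$elimThreshold < 0 || cfg$elimThreshold > 1 ||
      cfg$reportThreshold <= 0 || cfg$reportThreshold > 1)
    stop("thresholds must lie in (0, 1] (elimThreshold may be 0)")
  if (cfg$markerK < 1L) stop("markerK must be >= 1")
  class(cfg) <- "PipelineConfig"
  cfg
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes identification filtering, pool normalisation, run merging, the
#' common-protein filter, per-sample mean equalisation, hierarchical
#' clustering, PCA with orientation anchors, detection and PC-score
#' enrichment with elimination, and marker-signature derivation. Every
#' intermediate is written as TSV under \code{config$outdir}; a manifest
#' records the seed, a configuration hash, the row/column counts of every
#' stage, and drop/tie events. All randomness derives from
#' \code{config$seed}, so identical configurations give byte-identical
#' output trees.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, the manifest as a named list (also written as
#'   \code{manifest.txt}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  man <- list(seed = config$seed, transform = config$transform,
              linkage = config$linkage)
  cfgFile <- file.path(config$outdir, "config.txt")
  writeLines(deparse(config[setdiff(names(config), "outdir")]), cfgFile)
  man$config_hash <- unname(tools::md5sum(cfgFile))
  set.seed(config$seed)

  if (!is.null(config$synth)) {
    man$mode <- "simulate"
    idir <- file.path(config$outdir, "inputs")
    dir.create(idir, showWarnings = FALSE)
    onto <- withStage("synthdata", generateOntology(
      config$synthOntologyTerms, config$synth@nProteins, seed = config$seed))
    sim <- withStage("synthdata", generateExperiment(
      config$synth, annotation = onto$annotation, plantings = config$plantings))
    writeOBO(onto$dag, file.path(idir, "ontology.obo"))
    writeAnnotations(onto$direct, file.path(idir, "annotations.tsv"))
    writeSampleMeta(sim$meta, file.path(idir, "sample_meta.tsv"))
    writeTruth(sim$truth, file.path(idir, "truth.txt"))
    for (r in sim$runs)
      writeRunTable(r, file.path(idir, paste0(r@runId, ".tsv")))
    runs <- sim$runs
    meta <- sim$meta
    dag <- onto$dag
    direct <- onto$direct
    poolChannel <- runs[[1L]]@poolChannel
  } else {
    man$mode <- "run"
    runs <- withStage("read", lapply(config$runTables, readRunTable,
                                     poolChannel = config$poolChannel))
    meta <- withStage("read", readSampleMeta(config$sampleMeta))
    dag <- withStage("read", readOBO(config$ontology))
    direct <- withStage("read", readAnnotations(config$annotations))
    poolChannel <- config$poolChannel
  }
  man$n_runs <- length(runs)
  man$n_samples <- nrow(meta)
  man$n_identified <- length(unique(unlist(
    lapply(runs, function(r) r@evidence$accession))))

  runs <- withStage("filter_identifications", lapply(runs, filterIdentifications))
  man$n_after_id_filter <- length(unique(unlist(
    lapply(runs, function(r) r@evidence$accession))))
  runs <- withStage("relative_to_pool", lapply(runs, relativeToPool))
  man$n_dropped_no_pool <- sum(vapply(runs, function(r)
    attr(r, "dropped_no_pool"), numeric(1)))

  merged <- withStage("merge_runs", mergeRuns(runs, meta))
  man$n_merged <- nrow(merged)
  writeProteomeSet(merged, file.path(config$outdir, "merged_ratios.tsv"))

  common <- withStage("filter_common_proteins", filterCommonProteins(merged))
  man$n_common <- nrow(common)
  if (nrow(common) < 2L)
    stop("stage pca: fewer than 2 proteins quantified in every sample",
         call. = FALSE)
  norm <- withStage("equalize_sample_means", equalizeSampleMeans(common))
  man$pre_normalisation_mean_range <-
    paste(sprintf("%.4f", range(metadata(norm)$pre_normalisation_means)),
          collapse = "..")
  writeProteomeSet(norm, file.path(config$outdir, "common_ratios.tsv"))

  groups <- sampleGroups(norm)
  dmat <- withStage("cluster", sampleDistanceMatrix(
    norm, logTransform = config$transform == "log2"))
  write.table(data.frame(sample_id = rownames(dmat), dmat, check.names = FALSE),
              file.path(config$outdir, "distances.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dend <- withStage("cluster", hierarchicalCluster(dmat, config$linkage))
  writeDendrogramNewick(dend, file.path(config$outdir, "dendrogram.nwk"))
  k <- length(unique(groups))
  cl <- cutree(dend, k = k)
  write.table(data.frame(sample_id = names(cl), cluster = cl,
                         group = groups[names(cl)]),
              file.path(config$outdir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man$group_purity <- groupPurity(dend, groups, k)

  pca <- withStage("pca", runPCA(norm, transform = config$transform))
  pca <- withStage("pca", orientComponents(pca, groups, config$anchors))
  writePCAResult(pca, file.path(config$outdir, "pca"))
  man$variance_fraction_pc1_4 <- paste(
    sprintf("%.4f", varianceFraction(pca)[1:min(4, length(varianceFraction(pca)))]),
    collapse = ",")

  # enrichment: restrict annotation to the scored (common) background
  scored <- rownames(norm)
  directScored <- direct[intersect(names(direct), scored)]
  annScored <- withStage("goenrich", propagateAnnotations(directScored, dag))
  annAll <- withStage("goenrich", propagateAnnotations(direct, dag))
  fg <- intersect(scored, unlist(annAll@propagated[dag@root]))
  det <- withStage("goenrich", detectionTest(fg, annAll, dag,
                                             minSize = config$minTermSize))
  write.table(det, file.path(config$outdir, "enrichment_detection.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  man$n_detection_tested <- nrow(det)

  for (comp in config$enrichComponents) {
    if (comp > ncol(proteinScores(pca))) next
    sc <- setNames(proteinScores(pca)[, comp], rownames(proteinScores(pca)))
    rec <- withStage("goenrich", elimEnrichment(
      sc, dag, annScored, method = config$enrichMethod,
      elimThreshold = config$elimThreshold,
      reportThreshold = config$reportThreshold,
      minSize = config$minTermSize))
    rec$component <- rep(sprintf("PC%d", comp), nrow(rec))
    write.table(rec[, c("term", "name", "test", "component", "n_annotated",
                        "n_eliminated", "p", "q", "median_score")],
                file.path(config$outdir,
                          sprintf("enrichment_PC%d_%s.tsv", comp,
                                  config$enrichMethod)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    man[[sprintf("n_enriched_PC%d", comp)]] <- nrow(rec)
    if (nrow(rec)) {
      vt <- violinTable(rec, sc)
      write.table(vt, file.path(config$outdir, sprintf("violin_PC%d.tsv", comp)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tc <- clusterTerms(rec, jaccardMin = config$jaccardMin)
      write.table(tc, file.path(config$outdir,
                                sprintf("term_clusters_PC%d.tsv", comp)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  scoreMat <- proteinScores(pca)
  ties <- character()
  for (nmset in names(config$markerCriteria)) {
    ms <- withStage("markers", markerSignature(
      scoreMat, config$markerCriteria[[nmset]],
      k = min(config$markerK, nrow(scoreMat)), name = nmset))
    writeMarkerSet(ms, file.path(config$outdir,
                                 sprintf("markers_%s.tsv", nmset)))
    man[[sprintf("n_markers_%s", nmset)]] <- nrow(ms@proteins)
  }
  if (ncol(scoreMat) >= 2L)
    man$extreme_fetal_protein <- withStage("markers", extremeProtein(
      scoreMat, primary = list(component = 1L, direction = "most_negative"),
      constraints = list(list(component = 2L, sign = "positive"))))

  manLines <- vapply(names(man), function(k)
    paste0(k, ": ", paste(man[[k]], collapse = ",")), character(1))
  writeLines(manLines, file.path(config$outdir, "manifest.txt"))
  invisible(man)
}
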
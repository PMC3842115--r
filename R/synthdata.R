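#' Configuration of the synthetic multi-run isobaric experiment
#'
#' Defines the simulated study: group sample sizes, the run/channel layout
#' with one reference-pool channel per run, log2-scale effect and noise
#' magnitudes, and the abundance-dependent detection model. Defaults encode
#' the comparative hepatocyte design: 24 samples over 4 runs of 8-plex
#' labelling (8 fresh fetal, 4 fresh adult spread one per run, 3 HepG2,
#' 3 fetal ALI-3D, 3 adult ALI-3D, 3 adult ECM-sandwich), ~1500 proteins.
#'
#' @slot nProteins number of simulated proteins.
#' @slot groups named integer vector of per-group sample counts.
#' @slot nRuns number of labelling runs.
#' @slot channelsPerRun reporter channels per run (default 8; one is the pool).
#' @slot effectSd log2 scale of group-effect contrast coefficients.
#' @slot contrasts named numeric: relative weight of each built-in group
#'   contrast (\code{adult_vs_rest}, \code{hepg2_vs_rest},
#'   \code{ecm_vs_fresh_adult}, \code{fetal_ali3d_vs_fresh},
#'   \code{adult_ali3d_vs_fresh}); drawn coefficient sd = effectSd * weight.
#' @slot runEffectSd log2 sd of per-run offsets.
#' @slot noiseSd log2 sd of per-channel measurement noise.
#' @slot baselineMean,baselineSd location/scale of per-protein log2 baseline
#'   abundance.
#' @slot detectMidpoint,detectSlope logistic detection parameters: a
#'   non-core protein is detected in a run with probability
#'   plogis(detectSlope * (baseline - detectMidpoint)).
#' @slot fracCore fraction of proteins always detected in every run.
#' @slot seed random seed.
#' @export
setClass("SynthConfig", slots = c(
  nProteins = "integer", groups = "integer", nRuns = "integer",
  channelsPerRun = "integer", effectSd = "numeric", contrasts = "numeric",
  runEffectSd = "numeric", noiseSd = "numeric",
  baselineMean = "numeric", baselineSd = "numeric",
  detectMidpoint = "numeric", detectSlope = "numeric",
  fracCore = "numeric", seed = "integer"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nProteins < 1L || object@nRuns < 1L || object@channelsPerRun < 2L)
    msg <- c(msg, "counts must be positive (and >= 2 channels per run)")
  if (any(object@groups < 1L)) msg <- c(msg, "each group needs >= 1 sample")
  sds <- c(object@effectSd, object@runEffectSd, object@noiseSd, object@baselineSd)
  if (any(sds < 0)) msg <- c(msg, "sds must be >= 0")
  if (object@fracCore < 0 || object@fracCore > 1)
    msg <- c(msg, "fracCore must be in [0, 1]")
  if (sum(object@groups) > object@nRuns * (object@channelsPerRun - 1L))
    msg <- c(msg, sprintf(
      "%d samples do not fit %d runs x %d non-pool channels",
      sum(object@groups), object@nRuns, object@channelsPerRun - 1L))
  if (length(msg)) msg else TRUE
})

#' @describeIn SynthConfig construct a validated configuration.
#' @param nProteins,groups,nRuns,channelsPerRun,effectSd,contrasts,runEffectSd
#'   see slots.
#' @param noiseSd,baselineMean,baselineSd,detectMidpoint,detectSlope,fracCore,seed
#'   see slots.
#' @export
synthConfig <- function(nProteins = 1500L,
                        groups = c(fresh_fetal = 8L, fresh_adult = 4L,
                                   hepg2 = 3L, fetal_ali3d = 3L,
                                   adult_ali3d = 3L, adult_ecm = 3L),
                        nRuns = 4L, channelsPerRun = 8L,
                        effectSd = 1.0,
                        contrasts = c(adult_vs_rest = 1.0,
                                      hepg2_vs_rest = 0.6,
                                      ecm_vs_fresh_adult = 0.5,
                                      fetal_ali3d_vs_fresh = 0.3,
                                      adult_ali3d_vs_fresh = 0.3),
                        runEffectSd = 0.3, noiseSd = 0.25,
                        baselineMean = 6, baselineSd = 2,
                        detectMidpoint = 6, detectSlope = 1,
                        fracCore = 0.25, seed = 1L) {
  new("SynthConfig", nProteins = as.integer(nProteins),
      groups = setNames(as.integer(groups), names(groups)),
      nRuns = as.integer(nRuns), channelsPerRun = as.integer(channelsPerRun),
      effectSd = effectSd, contrasts = contrasts, runEffectSd = runEffectSd,
      noiseSd = noiseSd, baselineMean = baselineMean, baselineSd = baselineSd,
      detectMidpoint = detectMidpoint, detectSlope = detectSlope,
      fracCore = fracCore, seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig: ", object@nProteins, " proteins, ",
      sum(object@groups), " samples in ", length(object@groups),
      " groups over ", object@nRuns, " runs (seed ", object@seed, ")\n",
      sep = "")
})

#' Ground truth of a synthetic experiment
#'
#' @slot baseline per-protein log2 abundance.
#' @slot groupEffect proteins x groups log2 effect matrix.
#' @slot runEffect per-run log2 offset.
#' @slot coreProteins accessions always detected.
#' @slot enrichedTerms data.frame of planted score-enriched ontology terms
#'   (\code{term}, \code{contrast}, \code{effect}).
#' @slot seed seed used.
#' @export
setClass("SynthTruth", slots = c(
  baseline = "numeric", groupEffect = "matrix", runEffect = "numeric",
  coreProteins = "character", enrichedTerms = "data.frame", seed = "integer"
))

setMethod("show", "SynthTruth", function(object) {
  cat("SynthTruth: ", length(object@baseline), " proteins, ",
      ncol(object@groupEffect), " groups, ", length(object@runEffect),
      " runs, ", nrow(object@enrichedTerms), " planted term(s)\n", sep = "")
})

# Centered indicator contrast over the group labels; sums to zero so a
# contrast does not shift the pool mean.
groupContrast <- function(contrast, groupNames) {
  ind <- switch(contrast,
    adult_vs_rest = as.numeric(groupNames %in%
      c("fresh_adult", "adult_ali3d", "adult_ecm")),
    hepg2_vs_rest = as.numeric(groupNames == "hepg2"),
    ecm_vs_fresh_adult = as.numeric(groupNames == "adult_ecm") -
      as.numeric(groupNames == "fresh_adult"),
    fetal_ali3d_vs_fresh = as.numeric(groupNames == "fetal_ali3d") -
      as.numeric(groupNames == "fresh_fetal"),
    adult_ali3d_vs_fresh = as.numeric(groupNames == "adult_ali3d") -
      as.numeric(groupNames == "fresh_adult"),
    stop("unknown contrast: ", contrast))
  ind - mean(ind)
}

iTRAQchannels <- function(n) {
  if (n == 8L) c("113", "114", "115", "116", "117", "118", "119", "121")
  else sprintf("ch%d", seq_len(n))
}

# Default sample layout: fresh_adult spread one per run (as in the study,
# to decouple that group from run effects); other groups packed run by run.
defaultLayout <- function(config) {
  groups <- config@groups
  gnames <- names(groups)
  cap <- rep(config@channelsPerRun - 1L, config@nRuns)
  rows <- list()
  donorOf <- function(g, i) {
    prefix <- switch(g, fresh_fetal = , fetal_ali3d = "F",
                     fresh_adult = , adult_ali3d = , adult_ecm = "A",
                     hepg2 = "HepG2-", substr(toupper(g), 1, 1))
    paste0(prefix, i)
  }
  if ("fresh_adult" %in% gnames) {
    for (i in seq_len(groups[["fresh_adult"]])) {
      r <- ((i - 1L) %% config@nRuns) + 1L
      if (cap[r] == 0L) stop("infeasible channel assignment for fresh_adult")
      rows[[length(rows) + 1L]] <- data.frame(
        group = "fresh_adult", donor = donorOf("fresh_adult", i), run = r)
      cap[r] <- cap[r] - 1L
    }
  }
  for (g in setdiff(gnames, "fresh_adult")) {
    for (i in seq_len(groups[[g]])) {
      r <- which(cap > 0L)[1L]
      if (is.na(r)) stop("infeasible channel assignment: runs are full")
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, donor = donorOf(g, i), run = r)
      cap[r] <- cap[r] - 1L
    }
  }
  layout <- do.call(rbind, rows)
  layout <- layout[order(layout$run), , drop = FALSE]
  chans <- iTRAQchannels(config@channelsPerRun)
  pool <- chans[1L]
  layout$channel <- unlist(lapply(split(seq_len(nrow(layout)), layout$run),
                                  function(ix) chans[-1L][seq_along(ix)]),
                           use.names = FALSE)
  layout$sample_id <- sprintf("%s_%s_r%d", layout$group, layout$donor, layout$run)
  layout$run <- sprintf("run%d", layout$run)
  layout <- layout[, c("sample_id", "group", "donor", "run", "channel")]
  rownames(layout) <- NULL
  layout
}

#' Generate a random rooted ontology with direct annotations
#'
#' Builds an acyclic is_a graph with a single root (every later term picks
#' one or two earlier terms as parents) and annotates ~90% of the proteins
#' directly to one to three non-root terms. Annotations are propagated so
#' that the true-path rule holds.
#'
#' @param nTerms number of terms (>= 1; 1 gives the degenerate root-only
#'   ontology with every annotated protein mapped to the root).
#' @param nProteinsAnn number of proteins in the annotation universe
#'   (accessions \code{P0001}...).
#' @param seed random seed.
#' @return list with elements \code{dag} (\code{OntologyDAG}),
#'   \code{direct} (protein -> terms) and \code{annotation}
#'   (\code{AnnotationMap}).
#' @export
generateOntology <- function(nTerms, nProteinsAnn, seed = 1L) {
  if (nTerms < 1L || nProteinsAnn < 1L)
    stop("nTerms and nProteinsAnn must be positive")
  set.seed(as.integer(seed))
  ids <- sprintf("T:%04d", seq_len(nTerms))
  terms <- data.frame(id = ids, name = sprintf("synthetic term %d", seq_len(nTerms)),
                      stringsAsFactors = FALSE)
  parents <- list()
  parents[[ids[1L]]] <- character()
  if (nTerms > 1L) for (i in 2:nTerms) {
    npar <- if (i > 3L && runif(1) < 0.2) 2L else 1L
    parents[[ids[i]]] <- ids[sample.int(i - 1L, min(npar, i - 1L))]
  }
  dag <- OntologyDAG(terms, parents)
  prots <- sprintf("P%04d", seq_len(nProteinsAnn))
  annotated <- prots[runif(nProteinsAnn) < 0.9]
  pool <- if (nTerms > 1L) ids[-1L] else ids
  direct <- setNames(lapply(annotated, function(p) {
    sort(pool[sample.int(length(pool), min(length(pool), sample(1:3, 1L)))])
  }), annotated)
  list(dag = dag, direct = direct,
       annotation = propagateAnnotations(direct, dag))
}

#' Generate a synthetic multi-run pooled-reference experiment
#'
#' Simulates reporter quantities under the generative model: the log2
#' quantity of protein p for sample s in run r is
#' \code{baseline_p + effect_{p,g(s)} + runEffect_r + e}, with
#' \code{e ~ N(0, noiseSd)}; quantities are \code{2^log2}. The pool channel
#' of each run carries the equal-weight mean of the group mean abundances
#' (\code{baseline_p + mean_g effect_{p,g} + runEffect_r}) plus its own
#' channel noise. Group effects are sums of centred group contrasts with
#' per-protein coefficients drawn at sd \code{effectSd * weight}; planted
#' ontology terms add an extra contrast effect to their annotated proteins.
#' Detection operates at run level: a non-core protein is missing from an
#' entire run with probability \code{1 - plogis(detectSlope * (baseline -
#' detectMidpoint))}; core proteins are always detected. Undetected proteins
#' are absent from that run's table.
#'
#' @param config a \code{SynthConfig}.
#' @param annotation optional \code{AnnotationMap} (from
#'   \code{generateOntology}) required when \code{plantings} is given.
#' @param plantings optional data.frame with columns \code{term},
#'   \code{contrast}, \code{effect}: proteins annotated to \code{term} gain
#'   \code{effect} times the centred contrast in their group effects.
#' @param groupEffect optional proteins x groups matrix overriding the drawn
#'   group effects entirely (used for closed-form checks).
#' @param layout optional sample layout data.frame (\code{sample_id},
#'   \code{group}, \code{donor}, \code{run} = \code{"run<i>"},
#'   \code{channel}) overriding the default donor/run assignment.
#' @return list with \code{runs} (list of \code{RunTable}), \code{meta}
#'   (sample metadata data.frame) and \code{truth} (\code{SynthTruth}).
#' @export
generateExperiment <- function(config, annotation = NULL, plantings = NULL,
                               groupEffect = NULL, layout = NULL) {
  validObject(config)
  set.seed(config@seed)
  p <- config@nProteins
  gnames <- names(config@groups)
  acc <- sprintf("P%04d", seq_len(p))

  baseline <- rnorm(p, config@baselineMean, config@baselineSd)
  names(baseline) <- acc

  E <- matrix(0, p, length(gnames), dimnames = list(acc, gnames))
  for (k in names(config@contrasts)) {
    a <- rnorm(p, 0, config@effectSd * config@contrasts[[k]])
    E <- E + outer(a, groupContrast(k, gnames))
  }
  enriched <- data.frame(term = character(), contrast = character(),
                         effect = numeric())
  if (!is.null(plantings) && nrow(plantings)) {
    if (is.null(annotation))
      stop("plantings require an annotation map")
    for (i in seq_len(nrow(plantings))) {
      members <- intersect(annotatedProteins(annotation, plantings$term[i]), acc)
      if (!length(members))
        stop("planted term has no annotated proteins: ", plantings$term[i])
      cvec <- groupContrast(plantings$contrast[i], gnames)
      E[members, ] <- E[members, , drop = FALSE] +
        plantings$effect[i] * matrix(cvec, length(members), length(gnames),
                                     byrow = TRUE)
    }
    enriched <- plantings[, c("term", "contrast", "effect")]
  }
  if (!is.null(groupEffect)) {
    stopifnot(identical(dim(groupEffect), dim(E)))
    E <- groupEffect
    dimnames(E) <- list(acc, gnames)
  }

  runEffect <- rnorm(config@nRuns, 0, config@runEffectSd)
  names(runEffect) <- sprintf("run%d", seq_len(config@nRuns))

  nCore <- round(config@fracCore * p)
  core <- if (nCore > 0) sort(sample(acc, nCore)) else character()
  # shared uniforms make detection monotone in the logistic parameters
  u <- matrix(runif(p * config@nRuns), p, config@nRuns,
              dimnames = list(acc, names(runEffect)))
  pdet <- plogis(config@detectSlope * (baseline - config@detectMidpoint))
  detected <- (u < pdet) | (acc %in% core)

  if (is.null(layout)) layout <- defaultLayout(config)
  chans <- iTRAQchannels(config@channelsPerRun)
  poolChan <- chans[1L]
  poolLog <- baseline + rowMeans(E)   # equal-weight mean of group abundances

  runs <- vector("list", config@nRuns)
  for (r in seq_len(config@nRuns)) {
    rid <- sprintf("run%d", r)
    keep <- acc[detected[, rid]]
    smeta <- layout[layout$run == rid, , drop = FALSE]
    quant <- matrix(NA_real_, length(keep), length(chans),
                    dimnames = list(keep, chans))
    quant[, poolChan] <- 2^(poolLog[keep] + runEffect[rid] +
                              rnorm(length(keep), 0, config@noiseSd))
    for (j in seq_len(nrow(smeta))) {
      g <- smeta$group[j]
      quant[, smeta$channel[j]] <-
        2^(baseline[keep] + E[keep, g] + runEffect[rid] +
             rnorm(length(keep), 0, config@noiseSd))
    }
    nPep <- pmax(1L, stats::rpois(length(keep), 3))
    conf <- ifelse(nPep >= 2L, 90 + 10 * runif(length(keep)),
                   ifelse(runif(length(keep)) < 0.8,
                          99 + runif(length(keep)), 90 + 9 * runif(length(keep))))
    fdr <- runif(length(keep)) < 0.99
    runs[[r]] <- RunTable(
      runId = rid, channelLabels = chans, poolChannel = poolChan,
      evidence = data.frame(accession = keep, nPeptides = nPep,
                            bestSingleConf = round(conf, 2), fdrPass = fdr,
                            stringsAsFactors = FALSE),
      quant = quant)
  }
  truth <- new("SynthTruth", baseline = baseline, groupEffect = E,
               runEffect = runEffect, coreProteins = core,
               enrichedTerms = enriched, seed = config@seed)
  list(runs = runs, meta = layout, truth = truth)
}

#' Write a run table as TSV
#'
#' Columns: accession, n_peptides, best_single_peptide_conf, fdr_pass, then
#' one column per reporter channel (prefixed \code{area_}); missing
#' quantities as \code{NA}.
#'
#' @param run a \code{RunTable}.
#' @param path output path.
#' @export
writeRunTable <- function(run, path) {
  d <- data.frame(accession = run@evidence$accession,
                  n_peptides = run@evidence$nPeptides,
                  best_single_peptide_conf = run@evidence$bestSingleConf,
                  fdr_pass = run@evidence$fdrPass,
                  stringsAsFactors = FALSE)
  q <- as.data.frame(run@quant)
  names(q) <- paste0("area_", run@channelLabels)
  write.table(cbind(d, q), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata as TSV
#' @param meta sample metadata data.frame.
#' @param path output path.
#' @export
writeSampleMeta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV
#'
#' Validates the closed group vocabulary (\code{\link{SAMPLE_GROUPS}}) and
#' uniqueness of (run, channel) pairs.
#' @param path TSV path.
#' @export
readSampleMeta <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("sample_id", "group", "donor", "run", "channel")
  if (!all(need %in% names(m)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(m$group), SAMPLE_GROUPS)
  if (length(bad))
    stop("unknown sample group(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(m[, c("run", "channel")]))
    stop("duplicate (run, channel) assignment in sample metadata")
  m
}

#' Write the synthetic ground truth as a key:value sidecar
#' @param truth a \code{SynthTruth}.
#' @param path output path.
#' @export
writeTruth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("seed: ", truth@seed),
    paste0("n_proteins: ", length(truth@baseline)),
    paste0("groups: ", paste(colnames(truth@groupEffect), collapse = ",")),
    paste0("run_effect: ", paste(sprintf("%.6f", truth@runEffect), collapse = ",")),
    paste0("core_proteins: ", paste(truth@coreProteins, collapse = ",")),
    paste0("enriched_terms: ",
           paste(sprintf("%s|%s|%.4f", truth@enrichedTerms$term,
                         truth@enrichedTerms$contrast, truth@enrichedTerms$effect),
                 collapse = ","))), con)
  writeLines("baseline:", con)
  writeLines(sprintf("  %s: %.6f", names(truth@baseline), truth@baseline), con)
  invisible(path)
}
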
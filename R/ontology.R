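#' Construct an OntologyDAG
#'
#' @param terms data.frame with columns \code{id}, \code{name}.
#' @param parents named list: term id -> character vector of parent ids
#'   (the root has none). Terms absent from the list are treated as parentless.
#' @export
OntologyDAG <- function(terms, parents) {
  parents <- parents[intersect(names(parents), terms$id)]
  missing <- setdiff(terms$id, names(parents))
  parents[missing] <- replicate(length(missing), character(), simplify = FALSE)
  parents <- parents[terms$id]
  root <- terms$id[lengths(parents) == 0L]
  if (length(root) != 1L)
    stop("ontology must have exactly one root, found ", length(root))
  new("OntologyDAG", terms = terms, parents = parents, root = root)
}

#' Topological order of an ontology graph
#'
#' Kahn's algorithm over the child-to-parent is_a edges, children first
#' (most specific terms precede their ancestors). Ties within a frontier are
#' broken by term id, which fixes the visiting order of the elimination
#' enrichment. Returns \code{NULL} if the graph is cyclic.
#'
#' @param dag an \code{OntologyDAG} (or list with a \code{parents} element).
#' @return character vector of term ids, most specific first, or \code{NULL}.
#' @export
topoOrder <- function(dag) {
  parents <- if (is(dag, "OntologyDAG")) dag@parents else dag$parents
  ids <- names(parents)
  # out-degree in the child->parent orientation = number of children pending
  nchild <- setNames(integer(length(ids)), ids)
  for (ch in ids) for (pa in parents[[ch]]) nchild[pa] <- nchild[pa] + 1L
  order <- character(0)
  frontier <- sort(ids[nchild == 0L])  # leaves first, ties by id
  remaining <- nchild
  while (length(frontier)) {
    x <- frontier[1L]
    frontier <- frontier[-1L]
    order <- c(order, x)
    for (pa in parents[[x]]) {
      remaining[pa] <- remaining[pa] - 1L
      if (remaining[pa] == 0L)
        frontier <- sort(c(frontier, pa))
    }
  }
  if (length(order) != length(ids)) return(NULL)
  order
}

#' All ancestors of a term
#'
#' @param dag an \code{OntologyDAG}.
#' @param term a term id.
#' @return character vector of ancestor ids (term itself excluded).
#' @export
termAncestors <- function(dag, term) {
  seen <- character(0)
  frontier <- dag@parents[[term]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(dag@parents[frontier], use.names = FALSE))
  }
  unique(seen)
}

#' Propagate direct annotations up the ontology
#'
#' Applies the true-path rule: a protein directly annotated to a term is
#' annotated to every ancestor of that term. Proteins with no direct
#' annotation do not appear in any term set (they remain part of score
#' backgrounds, which are supplied separately to the tests).
#'
#' @param direct named list protein -> character vector of term ids.
#' @param dag an \code{OntologyDAG}.
#' @return an \code{AnnotationMap}.
#' @export
propagateAnnotations <- function(direct, dag) {
  ids <- termIds(dag)
  unknown <- setdiff(unique(unlist(direct, use.names = FALSE)), ids)
  if (length(unknown))
    stop("direct annotation references unknown term(s): ",
         paste(unknown, collapse = ", "))
  anc <- setNames(lapply(ids, function(t) c(t, termAncestors(dag, t))), ids)
  prop <- setNames(replicate(length(ids), character(), simplify = FALSE), ids)
  for (p in names(direct)) {
    terms <- unique(unlist(anc[direct[[p]]], use.names = FALSE))
    for (t in terms) prop[[t]] <- c(prop[[t]], p)
  }
  prop <- lapply(prop, function(v) sort(unique(v)))
  new("AnnotationMap", direct = direct, propagated = prop)
}

#' Read a minimal OBO file
#'
#' Parses \code{[Term]} stanzas for \code{id}, \code{name} and \code{is_a}
#' tags; all other tags are ignored.
#'
#' @param path OBO file path.
#' @return an \code{OntologyDAG}.
#' @export
readOBO <- function(path) {
  lines <- readLines(path)
  ids <- character(); nms <- character(); parents <- list()
  cur <- NULL; curname <- NA_character_; curpar <- character()
  flush <- function() {
    if (!is.null(cur)) {
      ids[[length(ids) + 1L]] <<- cur
      nms[[length(nms) + 1L]] <<- curname
      parents[[cur]] <<- curpar
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- NULL; curname <- NA; curpar <- character(); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) curname <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      curpar <- c(curpar, tgt)
    }
  }
  flush()
  OntologyDAG(data.frame(id = unlist(ids), name = unlist(nms),
                         stringsAsFactors = FALSE), parents)
}

#' Write a minimal OBO file
#'
#' @param dag an \code{OntologyDAG}.
#' @param path output path.
#' @export
writeOBO <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  nm <- termNames(dag)
  for (id in termIds(dag)) {
    pa <- dag@parents[[id]]
    isa <- if (length(pa)) paste0("is_a: ", pa) else character()
    writeLines(c("[Term]", paste0("id: ", id), paste0("name: ", nm[[id]]),
                 isa, ""), con)
  }
  invisible(path)
}

#' Read a two-column protein-to-term annotation table
#'
#' @param path TSV path with columns \code{accession}, \code{term}.
#' @return named list protein -> character vector of term ids.
#' @export
readAnnotations <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "term") %in% names(d)))
    stop("annotation file must have columns 'accession' and 'term'")
  split(d$term, d$accession)
}

#' Write a two-column protein-to-term annotation table
#'
#' @param direct named list protein -> term ids.
#' @param path output TSV path.
#' @export
writeAnnotations <- function(direct, path) {
  d <- data.frame(accession = rep(names(direct), lengths(direct)),
                  term = unlist(direct, use.names = FALSE))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
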
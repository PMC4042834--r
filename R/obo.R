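# OBO parsing and ontology (de)serialization.

# Directed igraph of the IS_A DAG, edges child -> parent, vertex names =
# term ids (sorted for determinism).
.ontologyIgraph <- function(og) {
  igraph::graph_from_data_frame(
    og@edges[, c("child", "parent")],
    directed = TRUE,
    vertices = data.frame(name = sort(og@terms$id), stringsAsFactors = FALSE)
  )
}

.checkAcyclicSingleRoot <- function(terms, edges, context = "ontology") {
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      edges[, c("child", "parent")], directed = TRUE,
      vertices = data.frame(name = sort(terms$id)))
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      bad <- names(comp$membership)[comp$membership %in%
                                      which(comp$csize > 1)]
      if (!length(bad)) { # self-loop case
        el <- edges[edges$child == edges$parent, , drop = FALSE]
        bad <- unique(el$child)
      }
      stop("cycle detected in ", context, " involving terms: ",
           paste(sort(bad), collapse = ", "))
    }
  }
  roots <- setdiff(terms$id, edges$child)
  if (length(roots) == 0L)
    stop("no root term found in ", context)
  if (length(roots) > 1L)
    stop("multiple root terms found in ", context, ": ",
         paste(sort(roots), collapse = ", "))
  roots
}

.newOntology <- function(terms, edges, report = list()) {
  terms <- terms[order(terms$id), , drop = FALSE]
  rownames(terms) <- NULL
  edges <- edges[order(edges$child, edges$parent), , drop = FALSE]
  rownames(edges) <- NULL
  root <- .checkAcyclicSingleRoot(terms, edges)
  empty <- stats::setNames(vector("list", nrow(terms)), terms$id)
  empty[] <- list(character())
  methods::new("OntologyGraph",
    terms = terms, edges = edges, root = root,
    directGenes = empty, cumulativeGenes = empty,
    directDocs = empty, cumulativeDocs = empty,
    descendants = list(), report = report,
    propagated = FALSE, pruned = FALSE)
}

#' Parse an OBO 1.2 flat file into an OntologyGraph
#'
#' Reads `[Term]` stanzas, keeping non-obsolete terms of one namespace and
#' their IS_A relations. Other relationship types (part_of, regulates, ...)
#' are ignored; their count is recorded in the report slot. The result must
#' be an acyclic graph with exactly one root, otherwise parsing fails with
#' an informative error.
#'
#' @param path path to an OBO 1.2 flat file.
#' @param namespace namespace to retain (default `"biological_process"`).
#'   Terms without an explicit `namespace:` tag inherit the file's
#'   `default-namespace`, if any.
#' @return an [OntologyGraph-class] (no annotations attached yet).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "",
#'   "[Term]", "id: GO:1", "name: root", "namespace: biological_process", "",
#'   "[Term]", "id: GO:2", "name: child", "namespace: biological_process",
#'   "is_a: GO:1 ! root"), obo)
#' parseOBO(obo)
#' @export
parseOBO <- function(path, namespace = "biological_process") {
  stopifnot(length(path) == 1L, file.exists(path))
  lines <- readLines(path, warn = FALSE)
  defaultNs <- sub("^default-namespace:\\s*", "",
                   grep("^default-namespace:", lines, value = TRUE)[1])
  if (is.na(defaultNs)) defaultNs <- ""

  # split into stanzas
  starts <- grep("^\\[", lines)
  termRows <- list()
  edgeRows <- list()
  ignoredRelations <- 0L
  obsoleteCount <- 0L
  otherNamespace <- 0L
  if (length(starts)) {
    ends <- c(starts[-1] - 1L, length(lines))
    for (k in seq_along(starts)) {
      if (lines[starts[k]] != "[Term]") next
      block <- lines[(starts[k] + 1L):ends[k]]
      block <- block[nzchar(block)]
      getTag <- function(tag) {
        v <- sub(paste0("^", tag, ":\\s*"), "",
                 grep(paste0("^", tag, ":"), block, value = TRUE))
        sub("\\s+!.*$", "", v)
      }
      id <- getTag("id")[1]
      if (is.na(id)) next
      if (any(getTag("is_obsolete") == "true")) {
        obsoleteCount <- obsoleteCount + 1L
        next
      }
      ns <- getTag("namespace")[1]
      if (is.na(ns)) ns <- defaultNs
      if (!identical(ns, namespace)) {
        otherNamespace <- otherNamespace + 1L
        next
      }
      nm <- getTag("name")[1]
      if (is.na(nm)) nm <- id
      def <- getTag("def")[1]
      if (is.na(def)) def <- ""
      def <- gsub('"', "", sub("\\s*\\[.*\\]\\s*$", "", def))
      ignoredRelations <- ignoredRelations +
        length(grep("^relationship:", block))
      termRows[[length(termRows) + 1L]] <-
        data.frame(id = id, name = nm, namespace = ns, def = def,
                   stringsAsFactors = FALSE)
      parents <- getTag("is_a")
      if (length(parents))
        edgeRows[[length(edgeRows) + 1L]] <-
          data.frame(child = id, parent = parents, stringsAsFactors = FALSE)
    }
  }
  if (!length(termRows))
    stop("no usable [Term] stanzas with namespace '", namespace,
         "' found in ", path)
  terms <- do.call(rbind, termRows)
  terms <- terms[!duplicated(terms$id), , drop = FALSE]
  edges <- if (length(edgeRows)) do.call(rbind, edgeRows) else
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)
  # drop edges to terms outside the retained namespace
  crossEdges <- !(edges$parent %in% terms$id & edges$child %in% terms$id)
  edges <- edges[!crossEdges, , drop = FALSE]
  edges <- edges[!duplicated(edges), , drop = FALSE]
  report <- list(
    ignoredRelations = ignoredRelations,
    obsoleteTerms = obsoleteCount,
    otherNamespaceTerms = otherNamespace,
    crossNamespaceEdges = sum(crossEdges))
  if (ignoredRelations > 0)
    message(ignoredRelations,
            " non-IS_A relationship line(s) ignored (IS_A edges only)")
  .newOntology(terms, edges, report)
}

#' Save or load an ontology as a plain-text JSON cache
#'
#' Serializes every slot of an [OntologyGraph-class] (including attached
#' genes, documents and propagated sets) to a single JSON file, so that
#' parsing and propagation need not be repeated.
#'
#' @param og an [OntologyGraph-class].
#' @param path destination (or source) file path.
#' @return `saveOntology` returns `path` invisibly; `loadOntology` the
#'   restored [OntologyGraph-class].
#' @export
saveOntology <- function(og, path) {
  stopifnot(methods::is(og, "OntologyGraph"))
  payload <- list(
    terms = og@terms, edges = og@edges, root = og@root,
    directGenes = og@directGenes, cumulativeGenes = og@cumulativeGenes,
    directDocs = og@directDocs, cumulativeDocs = og@cumulativeDocs,
    docs = og@docs, descendants = og@descendants, report = og@report,
    propagated = og@propagated, pruned = og@pruned)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname saveOntology
#' @export
loadOntology <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  fixList <- function(l, ids) {
    out <- stats::setNames(vector("list", length(ids)), ids)
    out[] <- list(character())
    for (nm in names(l)) out[[nm]] <- as.character(unlist(l[[nm]]))
    out
  }
  ids <- x$terms$id
  og <- .newOntology(as.data.frame(x$terms), as.data.frame(x$edges),
                     report = x$report)
  og@directGenes <- fixList(x$directGenes, ids)
  og@cumulativeGenes <- fixList(x$cumulativeGenes, ids)
  og@directDocs <- fixList(x$directDocs, ids)
  og@cumulativeDocs <- fixList(x$cumulativeDocs, ids)
  if (!is.null(x$docs) && length(x$docs))
    og@docs <- as.data.frame(x$docs)
  if (!is.null(x$descendants) && length(x$descendants))
    og@descendants <- fixList(x$descendants, ids)
  og@propagated <- isTRUE(x$propagated)
  og@pruned <- isTRUE(x$pruned)
  og
}
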
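# Gene annotation handling: GAF parsing, attachment, true-path propagation,
# pruning of unannotated terms.

#' Read a GAF 2.x gene association file
#'
#' Reads the tab-delimited Gene Association File format: comment lines start
#' with `!`; column 2 is the gene (DB object) id, column 5 the term id,
#' column 7 the evidence code. Gene identifiers are treated as opaque,
#' case-sensitive strings; no symbol mapping is performed.
#'
#' @param path path to a GAF file.
#' @param excludeEvidence evidence codes to drop (e.g. `"IEA"`); none by
#'   default.
#' @return a data.frame with columns `gene`, `term`, `evidence`, one row per
#'   distinct (gene, term) pair (the first evidence code seen is kept).
#' @export
readGAF <- function(path, excludeEvidence = character()) {
  stopifnot(length(path) == 1L, file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines))
    stop("GAF file ", path, " contains no annotation rows")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 7L
  if (any(bad))
    stop(sum(bad), " GAF row(s) have fewer than 7 columns")
  tab <- data.frame(
    gene = vapply(parts, `[[`, character(1), 2L),
    term = vapply(parts, `[[`, character(1), 5L),
    evidence = vapply(parts, `[[`, character(1), 7L),
    stringsAsFactors = FALSE)
  if (length(excludeEvidence))
    tab <- tab[!tab$evidence %in% excludeEvidence, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("GAF file ", path, " is empty after evidence filtering")
  tab <- tab[!duplicated(tab[, c("gene", "term")]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Attach gene annotations to an ontology graph
#'
#' Fills the direct gene sets of the graph from an annotation table.
#' Annotations to terms absent from the graph are counted and reported (via
#' a message and the graph's report slot), not silently dropped.
#'
#' @param og an [OntologyGraph-class].
#' @param table a data.frame with columns `gene`, `term` (and optionally
#'   `evidence`), e.g. from [readGAF()].
#' @param excludeEvidence evidence codes to drop before attaching.
#' @return the graph with `directGenes` populated (cumulative sets are reset;
#'   call [propagateAnnotations()] afterwards).
#' @export
attachAnnotations <- function(og, table, excludeEvidence = character()) {
  stopifnot(methods::is(og, "OntologyGraph"))
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("annotation table is empty; nothing downstream is computable")
  stopifnot(all(c("gene", "term") %in% names(table)))
  if (length(excludeEvidence) && "evidence" %in% names(table))
    table <- table[!table$evidence %in% excludeEvidence, , drop = FALSE]
  if (nrow(table) == 0L)
    stop("annotation table is empty after evidence filtering")
  table <- table[!duplicated(table[, c("gene", "term")]), , drop = FALSE]
  mapped <- table$term %in% og@terms$id
  if (any(!mapped)) {
    unmappedTerms <- sort(unique(table$term[!mapped]))
    message(sum(!mapped), " annotation row(s) reference ",
            length(unmappedTerms),
            " term(s) outside the graph and were set aside")
  } else {
    unmappedTerms <- character()
  }
  kept <- table[mapped, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop("no annotation maps into the ontology graph")
  sets <- split(kept$gene, kept$term)
  dg <- stats::setNames(vector("list", nrow(og@terms)), og@terms$id)
  dg[] <- list(character())
  for (t in names(sets)) dg[[t]] <- sort(unique(sets[[t]]))
  og@directGenes <- dg
  og@cumulativeGenes <- stats::setNames(
    rep(list(character()), nrow(og@terms)), og@terms$id)
  og@report$unmappedAnnotationRows <- sum(!mapped)
  og@report$unmappedAnnotationTerms <- unmappedTerms
  og@propagated <- FALSE
  og
}

#' Attach a document corpus to an ontology graph
#'
#' Associates documents (title + abstract records) with terms via a
#' term-to-document map. Documents mapped to terms outside the graph are
#' reported and set aside.
#'
#' @param og an [OntologyGraph-class].
#' @param docs data.frame with columns `id`, `title`, `abstract` (see
#'   [readCorpus()]).
#' @param termDocMap data.frame with columns `term`, `doc`.
#' @return the graph with `directDocs` and the document store populated
#'   (call [propagateAnnotations()] afterwards).
#' @export
attachDocuments <- function(og, docs, termDocMap) {
  stopifnot(methods::is(og, "OntologyGraph"),
            is.data.frame(docs), all(c("id", "title", "abstract") %in% names(docs)),
            is.data.frame(termDocMap), all(c("term", "doc") %in% names(termDocMap)))
  termDocMap <- termDocMap[!duplicated(termDocMap), , drop = FALSE]
  unknownDoc <- !termDocMap$doc %in% docs$id
  if (any(unknownDoc))
    stop("term-document map references ", sum(unknownDoc),
         " unknown document id(s)")
  mapped <- termDocMap$term %in% og@terms$id
  if (any(!mapped))
    message(sum(!mapped), " document association(s) reference terms outside ",
            "the graph and were set aside")
  kept <- termDocMap[mapped, , drop = FALSE]
  dd <- stats::setNames(vector("list", nrow(og@terms)), og@terms$id)
  dd[] <- list(character())
  sets <- split(kept$doc, kept$term)
  for (t in names(sets)) dd[[t]] <- sort(unique(sets[[t]]))
  og@directDocs <- dd
  og@cumulativeDocs <- stats::setNames(
    rep(list(character()), nrow(og@terms)), og@terms$id)
  og@docs <- docs[, c("id", "title", "abstract")]
  og@report$unmappedDocRows <- sum(!mapped)
  og@propagated <- FALSE
  og
}

# Topological order with children before parents (edges child -> parent).
.childFirstOrder <- function(og) {
  g <- .ontologyIgraph(og)
  ord <- igraph::topo_sort(g, mode = "out")
  names(ord)
}

# children of each term (named list)
.childrenMap <- function(og) {
  out <- stats::setNames(vector("list", nrow(og@terms)), og@terms$id)
  out[] <- list(character())
  if (nrow(og@edges)) {
    sp <- split(og@edges$child, og@edges$parent)
    for (p in names(sp)) out[[p]] <- sp[[p]]
  }
  out
}

# parents of each term (named list)
.parentsMap <- function(og) {
  out <- stats::setNames(vector("list", nrow(og@terms)), og@terms$id)
  out[] <- list(character())
  if (nrow(og@edges)) {
    sp <- split(og@edges$parent, og@edges$child)
    for (ch in names(sp)) out[[ch]] <- sp[[ch]]
  }
  out
}

#' Propagate annotations and documents up the ontology (true-path rule)
#'
#' Computes, for every term, the cumulative gene and document sets: the
#' union of the term's direct set with the cumulative sets of all its
#' children. A gene annotated to a term is thereby implicitly annotated to
#' every ancestor. Descendant term sets (self included) are computed at the
#' same time. The operation is idempotent.
#'
#' @param og an [OntologyGraph-class] with direct sets attached.
#' @return the graph with `cumulativeGenes`, `cumulativeDocs` and
#'   `descendants` filled and `propagated = TRUE`.
#' @export
propagateAnnotations <- function(og) {
  stopifnot(methods::is(og, "OntologyGraph"))
  ord <- .childFirstOrder(og)
  children <- .childrenMap(og)
  cg <- og@directGenes
  cd <- og@directDocs
  de <- stats::setNames(vector("list", length(ord)), og@terms$id)
  for (t in ord) {
    ch <- children[[t]]
    de[[t]] <- t
    if (length(ch)) {
      cg[[t]] <- sort(unique(c(cg[[t]], unlist(cg[ch], use.names = FALSE))))
      cd[[t]] <- sort(unique(c(cd[[t]], unlist(cd[ch], use.names = FALSE))))
      de[[t]] <- sort(unique(c(t, unlist(de[ch], use.names = FALSE))))
    } else {
      cg[[t]] <- sort(unique(cg[[t]]))
      cd[[t]] <- sort(unique(cd[[t]]))
    }
  }
  og@cumulativeGenes <- cg[og@terms$id]
  og@cumulativeDocs <- cd[og@terms$id]
  og@descendants <- de[og@terms$id]
  dg <- og@directGenes
  og@geneIndex <- split(
    rep(names(dg), vapply(dg, length, integer(1))),
    unlist(dg, use.names = FALSE))
  og@propagated <- TRUE
  og
}

#' Remove terms with no annotated gene anywhere beneath them
#'
#' Retains exactly the terms whose cumulative gene set is nonempty (a term
#' survives if it has directly associated genes or any descendant with
#' associated genes). Edges are re-closed: a retained term whose parent was
#' removed is re-attached to the removed parent's nearest retained
#' ancestors, so every retained term still reaches the root. The graph is
#' re-propagated after pruning.
#'
#' @param og a propagated [OntologyGraph-class].
#' @return the pruned, re-propagated graph (`pruned = TRUE`).
#' @export
pruneUnannotated <- function(og) {
  stopifnot(methods::is(og, "OntologyGraph"))
  if (!og@propagated) og <- propagateAnnotations(og)
  keep <- og@terms$id[vapply(og@cumulativeGenes[og@terms$id], length,
                             integer(1)) > 0L]
  if (!og@root %in% keep)
    stop("root term has no annotated gene anywhere beneath it; ",
         "pruning would produce an empty graph")
  parents <- .parentsMap(og)
  keepSet <- stats::setNames(rep(TRUE, length(keep)), keep)
  # nearest retained ancestors, memoized over removed terms
  memo <- new.env(parent = emptyenv())
  nearestKept <- function(t) {
    if (isTRUE(keepSet[t])) return(t)
    if (!is.null(memo[[t]])) return(memo[[t]])
    memo[[t]] <- character() # cycle guard (DAG: unused, but safe)
    res <- unique(unlist(lapply(parents[[t]], nearestKept),
                         use.names = FALSE))
    memo[[t]] <- res
    res
  }
  edgeChild <- character()
  edgeParent <- character()
  for (t in keep) {
    if (t == og@root) next
    np <- unique(unlist(lapply(parents[[t]], nearestKept),
                        use.names = FALSE))
    np <- setdiff(np, t)
    edgeChild <- c(edgeChild, rep(t, length(np)))
    edgeParent <- c(edgeParent, np)
  }
  edges <- data.frame(child = edgeChild, parent = edgeParent,
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges), , drop = FALSE]
  out <- .newOntology(og@terms[og@terms$id %in% keep, , drop = FALSE],
                      edges, report = og@report)
  out@directGenes <- og@directGenes[out@terms$id]
  out@directDocs <- og@directDocs[out@terms$id]
  out@docs <- og@docs
  out <- propagateAnnotations(out)
  out@report$prunedTerms <- setdiff(og@terms$id, keep)
  out@pruned <- TRUE
  out
}

#' Descendant terms and descendant counts
#'
#' `descendantTerms` returns the terms of the subgraph rooted at `term`
#' (including `term` itself); `descendantCount` its size, the |t| quantity
#' entering the information-bottleneck edge weight. With this self-inclusive
#' convention the root has p(t_root) = 1 and leaves have |t| = 1, so the
#' child/parent ratios are always well defined.
#'
#' @param x an [OntologyGraph-class].
#' @param term a term id present in the graph.
#' @return a character vector of term ids, or an integer count.
#' @export
setMethod("descendantTerms", "OntologyGraph", function(x, term) {
  if (length(term) != 1L || !term %in% x@terms$id)
    stop("unknown term: ", paste(term, collapse = ", "))
  if (x@propagated && length(x@descendants)) return(x@descendants[[term]])
  g <- .ontologyIgraph(x)
  sort(names(igraph::subcomponent(g, term, mode = "in")))
})

#' @rdname descendantCount
#' @export
setMethod("descendantCount", "OntologyGraph", function(x, term) {
  length(descendantTerms(x, term))
})

# shortest-path depth of every term from the root (root = 0)
.termDepths <- function(og) {
  g <- .ontologyIgraph(og)
  d <- igraph::distances(g, v = igraph::V(g), to = og@root, mode = "out")
  stats::setNames(as.numeric(d), rownames(d))
}
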
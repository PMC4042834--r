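# The summarizer: iteratively merge leaf terms into parents, least
# information loss first, freezing a lineage when the gene set its
# summarizing term would cover fails the coherence test.

#' Read a gene list file
#'
#' Plain text, one gene id per line; `#` starts a comment; blank lines are
#' skipped.
#'
#' @param path path to the gene list.
#' @return character vector of gene ids.
#' @export
readGeneList <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

# information loss of collapsing `child` into `parent` (which may be a
# re-closed ancestor rather than a direct parent). IC losses are path
# independent; IB losses are recomputed from the stored profiles.
.pairLoss <- function(graph, child, parent) {
  if (graph@metric == "IC")
    return(abs(graph@ic[[child]] - graph@ic[[parent]]))
  hit <- graph@weights$child == child & graph@weights$parent == parent
  if (any(hit)) return(graph@weights$weight[which(hit)[1]])
  ibEdgeWeight(graph@ontology, child, parent, profiles = graph@profiles)
}

# Build the summarizer state: the active graph is the ontology restricted to
# terms covering at least one query gene, with parent edges re-closed
# through removed terms.
.summarizerState <- function(graph, query) {
  og <- graph@ontology
  active <- og@terms$id[vapply(og@cumulativeGenes[og@terms$id],
                               function(g) any(query %in% g), logical(1))]
  activeSet <- stats::setNames(rep(TRUE, length(active)), active)
  parentsFull <- .parentsMap(og)
  memo <- new.env(parent = emptyenv())
  nearestActive <- function(t) {
    if (isTRUE(activeSet[t])) return(t)
    if (!is.null(memo[[t]])) return(memo[[t]])
    memo[[t]] <- character()
    res <- unique(unlist(lapply(parentsFull[[t]], nearestActive),
                         use.names = FALSE))
    memo[[t]] <- res
    res
  }
  parents <- stats::setNames(vector("list", length(active)), active)
  for (t in active) {
    if (t == og@root) { parents[[t]] <- character(); next }
    parents[[t]] <- sort(setdiff(
      unique(unlist(lapply(parentsFull[[t]], nearestActive),
                    use.names = FALSE)), t))
  }
  children <- stats::setNames(vector("list", length(active)), active)
  children[] <- list(character())
  for (t in active) for (p in parents[[t]])
    children[[p]] <- c(children[[p]], t)
  loss <- stats::setNames(vector("list", length(active)), active)
  for (t in active) {
    if (!length(parents[[t]])) { loss[[t]] <- numeric(); next }
    loss[[t]] <- vapply(parents[[t]], function(p)
      as.numeric(.pairLoss(graph, t, p)), numeric(1))
  }
  st <- new.env(parent = emptyenv())
  st$graph <- graph
  st$root <- og@root
  st$active <- activeSet
  st$parents <- parents
  st$children <- children
  st$childCount <- vapply(children, length, integer(1))
  st$loss <- loss
  st$geneSet <- stats::setNames(lapply(active, function(t)
    sort(intersect(og@directGenes[[t]], query))), active)
  # static gate sets: the query genes each term's subgraph annotates
  st$queryCumulative <- stats::setNames(lapply(active, function(t)
    sort(intersect(og@cumulativeGenes[[t]], query))), active)
  st$subsumed <- stats::setNames(rep(list(character()), length(active)),
                                 active)
  st$frozen <- list()
  st$pathCaches <- new.env(parent = emptyenv())
  st
}

# union of query genes carried by the active subtree beneath `term`
# (term included): the genes its summarizing term would cover.
.subtreeGenes <- function(st, term) {
  seen <- character()
  queue <- term
  genes <- list()
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    genes[[t]] <- st$geneSet[[t]]
    kids <- st$children[[t]]
    queue <- c(queue, kids[!kids %in% seen])
  }
  sort(unique(unlist(genes, use.names = FALSE)))
}

# current merge candidates: each active leaf paired with its minimum-loss
# parent, sorted by ascending loss with lexicographic tie-breaks.
.candidateMerges <- function(st) {
  leaves <- names(st$active)[st$active & st$childCount == 0L]
  leaves <- leaves[vapply(st$parents[leaves], length, integer(1)) > 0L]
  if (!length(leaves))
    return(data.frame(child = character(), parent = character(),
                      loss = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(sort(leaves), function(t) {
    l <- st$loss[[t]]
    p <- st$parents[[t]]
    best <- which(l <= min(l) + 1e-15)
    pick <- best[order(p[best])][1] # lexicographic tie-break
    data.frame(child = t, parent = p[pick], loss = as.numeric(l[pick]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$loss, out$child), , drop = FALSE]
}

.removeTerm <- function(st, term) {
  for (p in st$parents[[term]]) {
    st$children[[p]] <- setdiff(st$children[[p]], term)
    st$childCount[[p]] <- length(st$children[[p]])
  }
  st$active[[term]] <- FALSE
}

# collapse child into parent: the parent inherits the child's carried genes
# and records it (and everything it had subsumed) as subsumed.
.applyMerge <- function(st, child, parent) {
  st$geneSet[[parent]] <- sort(unique(c(st$geneSet[[parent]],
                                        st$geneSet[[child]])))
  st$subsumed[[parent]] <- sort(unique(c(st$subsumed[[parent]], child,
                                         st$subsumed[[child]])))
  .removeTerm(st, child)
  invisible(st)
}

# the merge gate: accept (merge child into parent) when the gene set the
# parent would summarize is functionally coherent; otherwise freeze the
# child as a final summarizing term. The tested set is the query genes the
# parent's subgraph annotates (a summarizing term covers all genes beneath
# it, merged or not). Sets smaller than the minimum testable size auto-pass.
.coherenceGate <- function(st, child, parent, null, pCutoff, scheme,
                           minTestable) {
  # the root is definitionally uninformative and cannot serve as a
  # summarizing term: lineages reaching its children freeze there
  if (identical(parent, st$root))
    return(list(accept = FALSE, tested = FALSE,
                n = length(st$queryCumulative[[parent]]), p = NA_real_))
  S <- st$queryCumulative[[parent]]
  n <- length(S)
  if (n < minTestable)
    return(list(accept = TRUE, tested = FALSE, n = n, p = NA_real_))
  y <- geneSetStatistic(S, st$graph, scheme = scheme, within = parent,
                        pathCacheEnv = st$pathCaches)@value
  p <- suppressWarnings(pValue(null, n, y))
  list(accept = p <= pCutoff, tested = TRUE, n = n, p = p, y = y)
}

# deepest term (lexicographic tie-break) within `scope` whose descendant
# subgraph covers all of `terminals`.
.anchorTerm <- function(og, terminals, scope, depths) {
  cover <- scope[vapply(og@descendants[scope], function(d)
    all(terminals %in% d), logical(1))]
  if (!length(cover)) return(scope[1])
  cover <- cover[order(-depths[cover], cover)]
  cover[1]
}

#' Summarize a gene list into coherent functional modules
#'
#' The headline procedure: restrict the ontology to terms covering at least
#' one query gene, then repeatedly merge the active leaf with the smallest
#' information loss into its least-loss parent. A merge is accepted only if
#' the gene set the parent would summarize (all query genes carried by the
#' still-active subgraph beneath it) passes the coherence test at
#' `pCutoff`; otherwise the child is frozen as a final summarizing term
#' covering the genes it had accumulated. The procedure stops when no leaf
#' has an active parent; remaining active terms with genes become final
#' modules. Each final module is reported under the most specific term whose
#' subgraph covers the module's annotation terminals.
#'
#' Modules are non-disjoint: a gene annotated in several lineages can appear
#' in several modules. Every query gene with at least one mapped annotation
#' appears in at least one module. Sets smaller than the smallest trained
#' null size cannot be tested; they pass the gate automatically and are
#' flagged `untested` in the output.
#'
#' @param genes character vector of query gene ids.
#' @param graph a [WeightedOntology-class] or [AugmentedOntology-class]
#'   (propagated, pruned, weighted).
#' @param null a [NullModel-class] fitted on the same graph, metric and
#'   scheme.
#' @param pCutoff coherence p-value cutoff (default 0.01).
#' @param scheme `"plain"` or `"augmented"`; defaults to `"augmented"` when
#'   `graph` is augmented, else `"plain"`.
#' @param minTestable smallest testable set size (default: the smallest
#'   trained null size).
#' @return a [SummaryModules-class].
#' @export
summarizeGenes <- function(genes, graph, null, pCutoff = 0.01,
                           scheme = NULL, minTestable = NULL) {
  stopifnot(methods::is(graph, "WeightedOntology"),
            methods::is(null, "NullModel"))
  if (is.null(scheme))
    scheme <- if (methods::is(graph, "AugmentedOntology")) "augmented"
              else "plain"
  scheme <- match.arg(scheme, c("plain", "augmented"))
  if (!identical(null@scheme, scheme) || !identical(null@metric, graph@metric))
    stop("null model was fitted for ", null@metric, "/", null@scheme,
         " but the graph uses ", graph@metric, "/", scheme)
  if (is.null(minTestable)) minTestable <- min(null@sizes)
  og <- graph@ontology
  universe <- geneUniverse(og)
  query <- sort(unique(genes))
  unmapped <- setdiff(query, universe)
  if (length(unmapped))
    message(length(unmapped), " query gene(s) have no annotation in the ",
            "graph and were dropped: ",
            paste(utils::head(unmapped, 5), collapse = ", "))
  query <- intersect(query, universe)
  if (!length(query))
    stop("no query gene maps into the annotated ontology graph")

  st <- .summarizerState(graph, query)
  repeat {
    cand <- .candidateMerges(st)
    if (!nrow(cand)) break
    child <- cand$child[1]
    parent <- cand$parent[1]
    gate <- .coherenceGate(st, child, parent, null, pCutoff, scheme,
                           minTestable)
    if (gate$accept) {
      .applyMerge(st, child, parent)
    } else {
      if (length(st$geneSet[[child]]))
        st$frozen[[child]] <- list(genes = st$geneSet[[child]],
                                   subsumed = st$subsumed[[child]])
      .removeTerm(st, child)
    }
  }
  # leftover active terms (root and terms orphaned by frozen lineages)
  for (t in sort(names(st$active)[st$active])) {
    if (length(st$geneSet[[t]]))
      st$frozen[[t]] <- list(genes = st$geneSet[[t]],
                             subsumed = st$subsumed[[t]])
  }
  if (!length(st$frozen))
    stop("summarization produced no modules") # unreachable for valid input

  depths <- .termDepths(og)
  nameOf <- termNames(og)
  frozenTerms <- sort(names(st$frozen))
  rows <- vector("list", length(frozenTerms))
  geneSets <- stats::setNames(vector("list", length(frozenTerms)),
                              frozenTerms)
  subsumed <- stats::setNames(vector("list", length(frozenTerms)),
                              frozenTerms)
  for (k in seq_along(frozenTerms)) {
    ft <- frozenTerms[k]
    mod <- st$frozen[[ft]]
    scope <- og@descendants[[ft]]
    terminals <- intersect(terminalsFor(mod$genes, og), scope)
    anchor <- if (length(terminals)) .anchorTerm(og, terminals, scope, depths)
              else ft
    stat <- geneSetStatistic(mod$genes, graph, scheme = scheme,
                             within = anchor, pathCacheEnv = st$pathCaches)
    n <- length(mod$genes)
    tested <- n >= minTestable
    p <- if (tested) suppressWarnings(pValue(null, n, stat@value))
         else NA_real_
    rows[[k]] <- data.frame(
      term = anchor, name = unname(nameOf[anchor]), frozenTerm = ft,
      n = n, statistic = stat@value, p = p, untested = !tested,
      stringsAsFactors = FALSE)
    geneSets[[ft]] <- mod$genes
    subsumed[[ft]] <- mod$subsumed
  }
  modules <- do.call(rbind, rows)
  rownames(modules) <- NULL
  methods::new("SummaryModules",
    modules = modules, geneSets = geneSets, subsumed = subsumed,
    parameters = list(
      pCutoff = pCutoff, metric = graph@metric, scheme = scheme,
      minTestable = minTestable, nQuery = length(query),
      unmappedGenes = unmapped))
}

#' Write summary modules to TSV (and optional JSON provenance)
#'
#' The TSV has one row per module: term id, term name, n, y_s, p and the
#' member genes semicolon-joined. The JSON sidecar records, per module, the
#' frozen term and the original terms subsumed during merging.
#'
#' @param sm a [SummaryModules-class].
#' @param path destination TSV file.
#' @param jsonPath optional destination for the JSON provenance record.
#' @return `path`, invisibly.
#' @export
writeModules <- function(sm, path, jsonPath = NULL) {
  stopifnot(methods::is(sm, "SummaryModules"))
  tab <- sm@modules
  tab$genes <- vapply(sm@geneSets[tab$frozenTerm], paste, character(1),
                      collapse = ";")
  utils::write.table(
    tab[, c("term", "name", "n", "statistic", "p", "genes")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(jsonPath)) {
    payload <- lapply(seq_len(nrow(tab)), function(k) list(
      term = tab$term[k], frozenTerm = tab$frozenTerm[k],
      subsumed = as.list(sm@subsumed[[tab$frozenTerm[k]]]),
      genes = as.list(sm@geneSets[[tab$frozenTerm[k]]])))
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
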
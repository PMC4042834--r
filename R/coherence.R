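# Graph-based coherence statistics: gene-sharing augmentation edges and
# approximate Steiner trees over annotation terminals.

#' Add gene-sharing augmentation edges to a weighted ontology
#'
#' For every pair of terms that directly annotate at least one common gene,
#' an undirected edge of weight `dP5 / |g_ij|` is added, where `dP5` is the
#' 5th percentile (linear interpolation, zeros included) of the base IS_A
#' edge weights and `|g_ij|` the number of shared directly-annotated genes.
#' These shortcuts discount the redundancy of the same gene being annotated
#' to distinct, closely related terms by different curators.
#'
#' @param wg a [WeightedOntology-class].
#' @param minEdges minimum number of base edges for the percentile to be
#'   meaningful (default 20).
#' @return an [AugmentedOntology-class].
#' @export
augmentGraph <- function(wg, minEdges = 20L) {
  stopifnot(methods::is(wg, "WeightedOntology"))
  w <- wg@weights$weight
  if (length(w) < minEdges)
    stop("graph has ", length(w), " base edges; need at least ", minEdges,
         " for a meaningful 5th percentile")
  if (all(w == 0))
    stop("all base edge weights are zero; the 5th percentile is degenerate")
  dP5 <- as.numeric(stats::quantile(w, 0.05, type = 7, names = FALSE))
  og <- wg@ontology
  # gene -> directly annotating terms; count shared genes per term pair
  dg <- og@directGenes
  geneTerms <- split(
    rep(names(dg), vapply(dg, length, integer(1))),
    unlist(dg, use.names = FALSE))
  pairCount <- new.env(parent = emptyenv())
  for (tset in geneTerms) {
    tset <- sort(unique(tset))
    if (length(tset) < 2L) next
    for (a in seq_len(length(tset) - 1L)) {
      for (b in (a + 1L):length(tset)) {
        key <- paste(tset[a], tset[b], sep = "\r")
        prev <- pairCount[[key]]
        pairCount[[key]] <- if (is.null(prev)) 1L else prev + 1L
      }
    }
  }
  keys <- sort(ls(pairCount))
  if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    augEdges <- data.frame(
      i = vapply(parts, `[[`, character(1), 1L),
      j = vapply(parts, `[[`, character(1), 2L),
      shared = vapply(keys, function(k) pairCount[[k]], integer(1)),
      stringsAsFactors = FALSE)
    augEdges$weight <- dP5 / augEdges$shared
    rownames(augEdges) <- NULL
  } else {
    augEdges <- data.frame(i = character(), j = character(),
                           shared = integer(), weight = numeric(),
                           stringsAsFactors = FALSE)
  }
  base <- data.frame(from = wg@weights$child, to = wg@weights$parent,
                     weight = wg@weights$weight, type = "isa",
                     stringsAsFactors = FALSE)
  aug <- data.frame(from = augEdges$i, to = augEdges$j,
                    weight = augEdges$weight, type = "aug",
                    stringsAsFactors = FALSE)
  allEdges <- rbind(base, aug)
  augGraph <- igraph::graph_from_data_frame(
    allEdges, directed = FALSE,
    vertices = data.frame(name = sort(og@terms$id)))
  augPc <- .buildPathCache(allEdges[, c("from", "to", "weight")],
                           og@terms$id)
  methods::new("AugmentedOntology", wg,
               augEdges = augEdges, dP5 = dP5, augGraph = augGraph,
               augPathCache = augPc)
}

#' Terminal terms of a gene set
#'
#' The union of the genes' direct annotation terms (not propagated
#' ancestors); these are the vertices a coherence Steiner tree must connect.
#' Genes without any direct annotation in the graph are reported and
#' excluded.
#'
#' @param genes character vector of gene ids.
#' @param og an [OntologyGraph-class] (or a [WeightedOntology-class], whose
#'   ontology is used).
#' @return sorted character vector of terminal term ids.
#' @export
terminalsFor <- function(genes, og) {
  if (methods::is(og, "WeightedOntology")) og <- og@ontology
  stopifnot(methods::is(og, "OntologyGraph"))
  genes <- unique(genes)
  if (og@propagated && length(og@geneIndex)) {
    geneTerms <- og@geneIndex
  } else {
    dg <- og@directGenes
    geneTerms <- split(
      rep(names(dg), vapply(dg, length, integer(1))),
      unlist(dg, use.names = FALSE))
  }
  found <- genes %in% names(geneTerms)
  if (any(!found))
    warning(sum(!found), " gene(s) have no direct annotation in the graph ",
            "and were excluded: ",
            paste(utils::head(genes[!found], 5), collapse = ", "))
  if (!any(found))
    stop("no gene in the set is annotated in the graph")
  sort(unique(unlist(geneTerms[genes[found]], use.names = FALSE)))
}

# deterministic Prim MST on a symmetric distance matrix with named
# rows/cols; ties broken by lexicographic vertex name (rows/cols are sorted
# first, so the smallest index is the lexicographically smallest id).
# Returns a two-column character matrix of edges.
.primMST <- function(D) {
  ids <- rownames(D)
  k <- length(ids)
  if (k < 2L) return(matrix(character(), ncol = 2L))
  ord <- order(ids)
  D <- D[ord, ord, drop = FALSE]
  ids <- rownames(D)
  inTree <- c(TRUE, rep(FALSE, k - 1L))
  dist <- D[1L, ]
  parent <- rep(1L, k)
  edgesA <- character(k - 1L)
  edgesB <- character(k - 1L)
  for (step in seq_len(k - 1L)) {
    cand <- which(!inTree)
    b <- cand[which.min(dist[cand])] # ties -> smallest index = smallest id
    inTree[b] <- TRUE
    edgesA[step] <- ids[parent[b]]
    edgesB[step] <- ids[b]
    upd <- !inTree & (D[b, ] < dist - 1e-15 |
                        (abs(D[b, ] - dist) <= 1e-15 & ids[b] < ids[parent]))
    dist[upd] <- D[b, upd]
    parent[upd] <- b
  }
  cbind(edgesA, edgesB, deparse.level = 0)
}

# --- shortest-path cache --------------------------------------------------
# The Steiner heuristic is the innermost loop of null-model fitting, so all
# shortest-path information for a graph is computed once: the full distance
# matrix, a sorted adjacency list (parallel edges collapsed to the minimum
# weight) and a per-pair edge-weight lookup.
.buildPathCache <- function(edges, ids) {
  ids <- sort(ids)
  n <- length(ids)
  if (nrow(edges)) {
    u <- match(edges$from, ids)
    v <- match(edges$to, ids)
    if (anyNA(u) || anyNA(v)) stop("edge endpoint missing from vertex set")
    a <- pmin(u, v); b <- pmax(u, v); w <- as.numeric(edges$weight)
    key <- paste0(a, "_", b)
    o <- order(key, w)
    keep <- !duplicated(key[o])
    ea <- a[o][keep]; eb <- b[o][keep]; ew <- w[o][keep]
  } else {
    ea <- integer(); eb <- integer(); ew <- numeric()
  }
  adjN <- rep(list(integer()), n)
  adjW <- rep(list(numeric()), n)
  if (length(ea)) {
    src <- c(ea, eb); nbr <- c(eb, ea); ww <- c(ew, ew)
    sp <- split(seq_along(src), src)
    for (nm in names(sp)) {
      i <- as.integer(nm)
      idx <- sp[[nm]]
      o2 <- order(nbr[idx])
      adjN[[i]] <- nbr[idx][o2]
      adjW[[i]] <- ww[idx][o2]
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[ea], to = ids[eb], weight = ew,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = ids))
  D <- igraph::distances(g, weights = igraph::E(g)$weight)
  D <- D[ids, ids, drop = FALSE]
  dimnames(D) <- NULL
  ewNames <- if (length(ea)) paste0(ea, "_", eb) else character(0)
  list(ids = ids, n = n, D = D, adjN = adjN, adjW = adjW,
       ew = stats::setNames(ew, ewNames))
}

.pathCacheFromIgraph <- function(g) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (is.null(el$weight)) stop("graph has no 'weight' edge attribute")
  .buildPathCache(el[, c("from", "to", "weight")], igraph::V(g)$name)
}

# One shortest path between vertex indices u and v: iterative DFS over the
# shortest-path predicate edges (d(x,v) = w(x,y) + d(y,v)), neighbors
# visited in order of decreasing progress then index, so the result is
# deterministic and zero-weight edges cannot cycle.
.cachePath <- function(pc, u, v) {
  stack <- u
  visited <- logical(pc$n)
  visited[u] <- TRUE
  while (length(stack)) {
    cur <- stack[length(stack)]
    if (cur == v) break
    nb <- pc$adjN[[cur]]
    wn <- pc$adjW[[cur]]
    tol <- 1e-9 * (1 + abs(pc$D[cur, v]))
    cand <- nb[abs(wn + pc$D[nb, v] - pc$D[cur, v]) <= tol]
    cand <- cand[!visited[cand]]
    if (length(cand)) {
      nxt <- cand[order(pc$D[cand, v], cand)][1]
      visited[nxt] <- TRUE
      stack <- c(stack, nxt)
    } else {
      stack <- stack[-length(stack)]
    }
  }
  if (!length(stack))
    stop("shortest-path reconstruction failed (disconnected graph?)")
  cbind(pmin(utils::head(stack, -1), utils::tail(stack, -1)),
        pmax(utils::head(stack, -1), utils::tail(stack, -1)))
}

# Kruskal MST on an integer edge list (deterministic: edges sorted by
# weight, then endpoints). Returns the index of the kept edges.
.kruskalKeep <- function(ea, eb, ew, n) {
  ord <- order(ew, ea, eb)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- integer()
  for (k in ord) {
    ra <- find(ea[k]); rb <- find(eb[k])
    if (ra != rb) {
      parent[ra] <- rb
      keep <- c(keep, k)
    }
  }
  keep
}

# core Steiner-tree heuristic on a path cache: metric-closure
# 2-approximation (MST of the terminal distance closure, expansion to real
# shortest paths, MST of the union, non-terminal leaf pruning).
.steinerOnCache <- function(pc, terminals) {
  terminals <- sort(unique(terminals))
  tIdx <- match(terminals, pc$ids)
  if (anyNA(tIdx))
    stop("terminal term(s) absent from the graph: ",
         paste(utils::head(terminals[is.na(tIdx)], 5), collapse = ", "))
  emptyTree <- data.frame(from = character(), to = character(),
                          weight = numeric(), stringsAsFactors = FALSE)
  if (length(tIdx) <= 1L) return(list(edges = emptyTree, weight = 0))
  D <- pc$D[tIdx, tIdx, drop = FALSE]
  if (any(!is.finite(D)))
    stop("terminal set is disconnected in the graph")
  rownames(D) <- colnames(D) <- pc$ids[tIdx]
  closure <- .primMST(D)
  segs <- vector("list", nrow(closure))
  for (k in seq_len(nrow(closure)))
    segs[[k]] <- .cachePath(pc, match(closure[k, 1], pc$ids),
                            match(closure[k, 2], pc$ids))
  allEdges <- unique(do.call(rbind, segs))
  if (is.null(allEdges) || nrow(allEdges) == 0L)
    return(list(edges = emptyTree, weight = 0))
  ea <- allEdges[, 1]; eb <- allEdges[, 2]
  ew <- unname(pc$ew[paste0(ea, "_", eb)])
  keep <- .kruskalKeep(ea, eb, ew, pc$n)
  ea <- ea[keep]; eb <- eb[keep]; ew <- ew[keep]
  repeat {
    deg <- tabulate(c(ea, eb), pc$n)
    drop <- setdiff(which(deg == 1L), tIdx)
    if (!length(drop)) break
    keep <- !(ea %in% drop | eb %in% drop)
    if (all(keep)) break
    ea <- ea[keep]; eb <- eb[keep]; ew <- ew[keep]
  }
  if (!length(ea)) return(list(edges = emptyTree, weight = 0))
  out <- data.frame(from = pc$ids[ea], to = pc$ids[eb], weight = ew,
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  list(edges = out, weight = sum(out$weight))
}

# convenience wrapper for a raw igraph input
.steinerCore <- function(g, terminals) {
  .steinerOnCache(.pathCacheFromIgraph(g), terminals)
}

# pick the igraph matching the requested scheme
.schemeGraph <- function(graph, scheme) {
  if (scheme == "augmented") {
    if (!methods::is(graph, "AugmentedOntology"))
      stop("scheme 'augmented' requires an AugmentedOntology ",
           "(see augmentGraph())")
    graph@augGraph
  } else {
    graph@graph
  }
}

#' Approximate Steiner tree spanning a set of terminal terms
#'
#' Finds a connected subtree spanning the terminals with the classical
#' metric-closure 2-approximation (Kou-Markowsky-Berman): minimum spanning
#' tree of the terminal distance closure, expanded to shortest paths, with
#' a final spanning-tree/leaf-pruning cleanup. The total weight is at most
#' twice the optimum. Shortest-path and spanning-tree ties are broken
#' lexicographically by term id, so the result is deterministic.
#'
#' @param graph a [WeightedOntology-class], [AugmentedOntology-class], or a
#'   plain undirected igraph with a `weight` edge attribute.
#' @param terminals character vector of terminal term ids.
#' @param scheme `"plain"` (IS_A edges only) or `"augmented"` (include
#'   gene-sharing edges; requires an [AugmentedOntology-class]).
#' @return list with `edges` (data.frame from/to/weight) and `weight` (the
#'   total tree weight).
#' @export
steinerTree <- function(graph, terminals, scheme = c("plain", "augmented")) {
  scheme <- match.arg(scheme)
  if (!length(terminals)) stop("terminal set is empty")
  if (methods::is(graph, "WeightedOntology")) {
    pc <- .schemeCache(graph, scheme)
    return(.steinerOnCache(pc, terminals))
  }
  .steinerCore(graph, terminals)
}

# cached shortest-path structure matching the requested scheme
.schemeCache <- function(graph, scheme) {
  if (scheme == "augmented") {
    if (!methods::is(graph, "AugmentedOntology"))
      stop("scheme 'augmented' requires an AugmentedOntology ",
           "(see augmentGraph())")
    if (length(graph@augPathCache)) return(graph@augPathCache)
    return(.pathCacheFromIgraph(graph@augGraph))
  }
  if (length(graph@pathCache)) return(graph@pathCache)
  .pathCacheFromIgraph(graph@graph)
}

#' Coherence statistic of a gene set
#'
#' The total weight y_s of an approximate Steiner tree connecting the gene
#' set's direct annotation terms, treating IS_A edges as undirected. On the
#' augmented scheme the tree may also traverse gene-sharing shortcut edges,
#' so the augmented statistic never exceeds the plain one. A smaller value
#' means less information is lost when the genes are merged under a common
#' summarizing term, i.e. greater functional coherence.
#'
#' @param genes character vector of gene ids.
#' @param graph a [WeightedOntology-class] (scheme `"plain"`) or
#'   [AugmentedOntology-class] (either scheme).
#' @param scheme `"plain"` or `"augmented"`.
#' @param within optional term id: restrict the computation to the subgraph
#'   beneath this summarizing term (terminals outside it are dropped), as
#'   used by the summarizer's merge gate.
#' @param pathCacheEnv optional environment memoizing the restricted
#'   shortest-path caches across repeated `within` calls (used internally
#'   by the summarizer).
#' @return a [CoherenceStatistic-class].
#' @export
geneSetStatistic <- function(genes, graph,
                             scheme = c("plain", "augmented"),
                             within = NULL, pathCacheEnv = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(methods::is(graph, "WeightedOntology"))
  og <- graph@ontology
  genes <- sort(unique(genes))
  terminals <- terminalsFor(genes, og)
  if (is.null(within)) {
    pc <- .schemeCache(graph, scheme)
  } else {
    scope <- descendantTerms(og, within)
    terminals <- intersect(terminals, scope)
    if (!length(terminals))
      stop("no terminal lies beneath term ", within)
    key <- paste0(scheme, "|", within)
    pc <- if (!is.null(pathCacheEnv)) pathCacheEnv[[key]] else NULL
    if (is.null(pc)) {
      g <- igraph::induced_subgraph(.schemeGraph(graph, scheme), scope)
      pc <- .pathCacheFromIgraph(g)
      if (!is.null(pathCacheEnv)) pathCacheEnv[[key]] <- pc
    }
  }
  st <- .steinerOnCache(pc, terminals)
  methods::new("CoherenceStatistic",
               genes = genes, n = length(genes), terminals = terminals,
               scheme = scheme, metric = graph@metric,
               value = st$weight, tree = st$edges)
}

#' Write coherence statistics to TSV
#'
#' Columns: set, n, metric, scheme, y_s.
#'
#' @param stats named list of [CoherenceStatistic-class] objects (names are
#'   the set ids).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeStatistics <- function(stats, path) {
  tab <- data.frame(
    set = names(stats),
    n = vapply(stats, function(s) s@n, integer(1)),
    metric = vapply(stats, function(s) s@metric, character(1)),
    scheme = vapply(stats, function(s) s@scheme, character(1)),
    y_s = vapply(stats, function(s) s@value, numeric(1)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
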
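# Shared fixtures and independent oracles for the test suite. Everything is
# built in code at test time; no stored data.

# write a minimal OBO file: `terms` is a character vector of ids (names used
# as term names when set), `edges` a data.frame(child, parent)
writeTestOBO <- function(terms, edges = NULL,
                         namespaces = NULL,
                         path = tempfile(fileext = ".obo")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  nms <- names(terms)
  for (k in seq_along(terms)) {
    id <- terms[[k]]
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ",
                      if (!is.null(nms) && nzchar(nms[k])) nms[k] else id),
               con)
    ns <- if (is.null(namespaces)) "biological_process" else namespaces[[k]]
    writeLines(paste0("namespace: ", ns), con)
    if (!is.null(edges)) {
      for (p in edges$parent[edges$child == id])
        writeLines(paste0("is_a: ", p), con)
    }
    writeLines("", con)
  }
  path
}

# chain A <- B <- C (C most specific)
chainOntology <- function() {
  parseOBO(writeTestOBO(
    c("GO:A", "GO:B", "GO:C"),
    data.frame(child = c("GO:B", "GO:C"), parent = c("GO:A", "GO:B"))))
}

# diamond: D has parents B and C, both under A
diamondOntology <- function() {
  parseOBO(writeTestOBO(
    c("GO:A", "GO:B", "GO:C", "GO:D"),
    data.frame(child = c("GO:B", "GO:C", "GO:D", "GO:D"),
               parent = c("GO:A", "GO:A", "GO:B", "GO:C"))))
}

# random rooted DAG with extra cross edges, as an OntologyGraph
randomDAGOntology <- function(nTerms = 20, extraEdges = 4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("GO:R%02d", seq_len(nTerms))
  child <- character()
  parent <- character()
  for (k in 2:nTerms) { # random tree, node k under an earlier node
    child <- c(child, ids[k])
    parent <- c(parent, ids[sample.int(k - 1L, 1L)])
  }
  for (e in seq_len(extraEdges)) { # extra edge keeps acyclicity (j < k)
    k <- sample(3:nTerms, 1L)
    j <- sample.int(k - 1L, 1L)
    if (!any(child == ids[k] & parent == ids[j])) {
      child <- c(child, ids[k])
      parent <- c(parent, ids[j])
    }
  }
  parseOBO(writeTestOBO(ids, data.frame(child = child, parent = parent)))
}

# attach annotations given as a named list term -> genes
withAnnotations <- function(og, sets, propagate = TRUE) {
  tab <- do.call(rbind, lapply(names(sets), function(t)
    data.frame(gene = sets[[t]], term = t, evidence = "IEA",
               stringsAsFactors = FALSE)))
  og <- attachAnnotations(og, tab)
  if (propagate) og <- propagateAnnotations(og)
  og
}

# full pipeline on a generated fixture set; returns the pieces
buildFixturePipeline <- function(spec, metric = "IC", augment = TRUE) {
  dir <- tempfile("fx")
  fx <- suppressWarnings(makeFixtureSet(spec, dir))
  og <- parseOBO(fx$paths$obo)
  og <- suppressMessages(attachAnnotations(og, readGAF(fx$paths$gaf)))
  og <- propagateAnnotations(og)
  og <- pruneUnannotated(og)
  if (metric == "IB") {
    docs <- readCorpus(fx$paths$docs)
    map <- readTermDocMap(fx$paths$termdocs)
    og <- suppressMessages(attachDocuments(og, docs, map))
    og <- propagateAnnotations(og)
  }
  wg <- weightEdges(og, metric)
  list(fx = fx, og = og, wg = wg,
       ag = if (augment) augmentGraph(wg) else NULL)
}

# --- independent oracles ---------------------------------------------------

# brute-force cumulative gene sets: per-term union of direct sets over the
# descendant subgraph, descendants found by path search on the raw edges
oracleCumulative <- function(og) {
  ids <- termIds(og)
  edges <- isaEdges(og)
  reach <- function(t) { # all terms that can reach t via child->parent
    seen <- t
    repeat {
      more <- edges$child[edges$parent %in% seen & !edges$child %in% seen]
      if (!length(more)) break
      seen <- c(seen, unique(more))
    }
    seen
  }
  stats::setNames(lapply(ids, function(t)
    sort(unique(unlist(directGenes(og)[reach(t)], use.names = FALSE)))), ids)
}

# exact Steiner tree weight by enumeration: minimum MST weight over all
# vertex supersets of the terminals (the optimum is the MST of its own
# vertex set)
oracleSteinerWeight <- function(g, terminals) {
  others <- setdiff(igraph::V(g)$name, terminals)
  best <- Inf
  for (mask in 0:(2^length(others) - 1)) {
    extra <- others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0]
    sub <- igraph::induced_subgraph(g, c(terminals, extra))
    if (igraph::components(sub)$no == 1L) {
      w <- sum(igraph::E(
        igraph::mst(sub, weights = igraph::E(sub)$weight))$weight)
      best <- min(best, w)
    }
  }
  best
}

randomConnectedGraph <- function(n, m, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnm(n, m)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("T%02d", seq_len(n))
  igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g), 0.1, 1), 3)
  g
}
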
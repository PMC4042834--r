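# Information-loss edge weights: information-bottleneck (IB) divergence of
# word profiles and information-content (IC) differences of gene annotation
# frequencies. All logarithms are natural, so weights are in nats.

#' Kullback-Leibler divergence between two discrete distributions
#'
#' Computes sum_v p(v) ln(p(v)/q(v)) with the convention 0 ln(0/x) = 0.
#' Distributions may be named vectors (aligned by name) or plain vectors of
#' equal length. The support of `p` must be contained in the support of `q`,
#' otherwise the divergence is infinite and an error identifies the
#' offending symbol.
#'
#' @param p,q numeric probability vectors summing to 1.
#' @param tol tolerance for the sum-to-one check.
#' @return nonnegative divergence in nats.
#' @examples
#' klDivergence(c(1, 0), c(0.5, 0.5))  # ln 2
#' @export
klDivergence <- function(p, q, tol = 1e-6) {
  if (!is.null(names(p)) || !is.null(names(q))) {
    if (is.null(names(p)) || is.null(names(q)))
      stop("either both or neither distribution may be named")
    v <- sort(unique(c(names(p), names(q))))
    pp <- stats::setNames(numeric(length(v)), v); pp[names(p)] <- p
    qq <- stats::setNames(numeric(length(v)), v); qq[names(q)] <- q
    p <- pp; q <- qq
  } else if (length(p) != length(q)) {
    stop("unnamed distributions must have equal length")
  }
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol)
    stop("distributions must sum to 1")
  if (any(p < 0) || any(q < 0)) stop("negative probabilities")
  viol <- p > 0 & q == 0
  if (any(viol)) {
    which <- if (!is.null(names(p))) names(p)[viol] else
      as.character(which(viol))
    stop("support violation: p has mass where q is zero at: ",
         paste(utils::head(which, 5L), collapse = ", "))
  }
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

# cumulative annotation-instance counts: for each term, the number of
# distinct (gene, term) annotation pairs over its descendant subgraph.
.annotationInstanceCounts <- function(og) {
  directCounts <- vapply(og@directGenes[og@terms$id], length, integer(1))
  # sum direct counts over the descendant set (a DAG needs the set, not a
  # recurrence, to avoid double counting through diamonds)
  vapply(og@terms$id, function(t)
    sum(directCounts[descendantTerms(og, t)]), numeric(1))
}

#' Cumulative annotation instances of terms
#'
#' The number of distinct (gene, term) annotation pairs attached to a term's
#' descendant subgraph (the term included). A gene annotated to two terms of
#' the subgraph contributes two instances; duplicate evidence lines for the
#' same (gene, term) pair contribute one.
#'
#' @param og a propagated [OntologyGraph-class].
#' @param term a term id, or NULL for all terms.
#' @return named numeric vector of instance counts.
#' @export
annotationInstances <- function(og, term = NULL) {
  stopifnot(methods::is(og, "OntologyGraph"))
  if (!og@propagated)
    stop("call propagateAnnotations() before counting instances")
  inst <- .annotationInstanceCounts(og)
  if (is.null(term)) return(inst)
  if (!term %in% names(inst)) stop("unknown term: ", term)
  inst[[term]]
}

#' Information content of a term
#'
#' IC(t) = -ln P(t), where P(t) is the term's cumulative annotation
#' instances divided by the total (root) instances. Because instances are
#' propagated, IC is monotone non-decreasing from root to leaves and the
#' root has IC = 0.
#'
#' @param term a term id.
#' @param og a propagated (and normally pruned) [OntologyGraph-class].
#' @param inst optional precomputed result of [annotationInstances()].
#' @return nonnegative information content in nats.
#' @export
informationContent <- function(term, og, inst = NULL) {
  if (is.null(inst)) inst <- annotationInstances(og)
  if (!term %in% names(inst)) stop("unknown term: ", term)
  if (inst[[term]] <= 0)
    stop("term ", term, " has zero annotation instances; ",
         "it should have been pruned")
  -log(inst[[term]] / inst[[rootTerm(og)]])
}

#' Information-loss edge weight between a child term and its parent
#'
#' `icEdgeWeight` measures the loss of gene information when the child
#' concept is collapsed into the parent: the absolute difference of their
#' information contents, which under propagated counts equals
#' IC(child) - IC(parent) >= 0.
#'
#' `ibEdgeWeight` measures the loss of semantic context: the child's
#' descendant-count-weighted divergence between the word distributions of
#' child and parent,
#' (|t_c|/|t_root|) * (|t_c|/|t_p|) * D_KL(p(w|t_c) || p(w|t_p)),
#' where |t| is the self-inclusive descendant count. With `symmetric = TRUE`
#' the single weighted KL term is replaced by the symmetric Jensen-Shannon
#' divergence with mixture weights (|t_c|/|t_p|, 1 - |t_c|/|t_p|), provided
#' for comparison.
#'
#' @param og a propagated [OntologyGraph-class].
#' @param child,parent term ids forming an IS_A (or ancestor) pair.
#' @param inst optional precomputed [annotationInstances()].
#' @param profiles optional named list of [WordProfile-class] objects.
#' @param cache optional profile cache (see [buildProfile()]).
#' @param pseudocount additive smoothing count applied to both profiles over
#'   the parent's support (default 0; the propagation containment guarantee
#'   makes the divergence finite without it).
#' @param symmetric use the symmetric Jensen-Shannon variant (default FALSE).
#' @return nonnegative edge weight in nats.
#' @export
icEdgeWeight <- function(og, child, parent, inst = NULL) {
  if (is.null(inst)) inst <- annotationInstances(og)
  abs(informationContent(child, og, inst) -
      informationContent(parent, og, inst))
}

#' @rdname icEdgeWeight
#' @export
ibEdgeWeight <- function(og, child, parent, profiles = NULL, cache = NULL,
                         pseudocount = 0, symmetric = FALSE) {
  stopifnot(methods::is(og, "OntologyGraph"))
  getProfile <- function(t) {
    if (!is.null(profiles) && !is.null(profiles[[t]])) return(profiles[[t]])
    buildProfile(t, og, cache = cache)
  }
  pc <- getProfile(child)
  pp <- getProfile(parent)
  if (pc@total <= 0 || pp@total <= 0)
    stop("zero-total word profile for term ",
         if (pc@total <= 0) child else parent,
         "; unusable for the information-bottleneck metric")
  countsC <- pc@counts
  countsP <- pp@counts
  if (pseudocount > 0) {
    v <- sort(unique(c(names(countsC), names(countsP))))
    cc <- stats::setNames(rep(pseudocount, length(v)), v)
    cp <- cc
    cc[names(countsC)] <- cc[names(countsC)] + countsC
    cp[names(countsP)] <- cp[names(countsP)] + countsP
    countsC <- cc; countsP <- cp
  }
  distC <- countsC / sum(countsC)
  distP <- countsP / sum(countsP)
  nTot <- descendantCount(og, rootTerm(og))
  nC <- descendantCount(og, child)
  nP <- descendantCount(og, parent)
  pt <- nC / nTot       # p(t_c) = |t_c| / |t_root|
  piC <- nC / nP        # pi = |t_c| / |t_p|
  djs <- if (symmetric) {
    v <- sort(unique(c(names(distC), names(distP))))
    dc <- stats::setNames(numeric(length(v)), v); dc[names(distC)] <- distC
    dp <- stats::setNames(numeric(length(v)), v); dp[names(distP)] <- distP
    m <- piC * dc + (1 - piC) * dp
    piC * klDivergence(dc, m) + (1 - piC) * klDivergence(dp, m)
  } else {
    piC * klDivergence(distC, distP)
  }
  pt * djs
}

#' Weight every IS_A edge of the graph under one information-loss metric
#'
#' Applies [icEdgeWeight()] or [ibEdgeWeight()] to every child-parent edge of
#' the pruned graph and caches the resulting undirected weighted graph for
#' Steiner-tree computations. Per-edge failures are collected and reported
#' in aggregate.
#'
#' @param og a propagated, pruned [OntologyGraph-class] (documents attached
#'   when `metric = "IB"`).
#' @param metric `"IC"` (gene information content, the shipped default) or
#'   `"IB"` (information bottleneck on word profiles).
#' @param pseudocount,symmetric passed to [ibEdgeWeight()].
#' @return a [WeightedOntology-class].
#' @export
weightEdges <- function(og, metric = c("IC", "IB"), pseudocount = 0,
                        symmetric = FALSE) {
  metric <- match.arg(metric)
  stopifnot(methods::is(og, "OntologyGraph"))
  if (!og@propagated)
    stop("call propagateAnnotations() (and pruneUnannotated()) first")
  edges <- og@edges
  ic <- numeric()
  profiles <- list()
  if (metric == "IC") {
    inst <- annotationInstances(og)
    bad <- names(inst)[inst <= 0]
    if (length(bad))
      stop(length(bad), " term(s) have zero annotation instances ",
           "(prune first): ", paste(utils::head(bad, 5), collapse = ", "))
    ic <- -log(inst / inst[[rootTerm(og)]])
    w <- abs(ic[edges$child] - ic[edges$parent])
  } else {
    cache <- .profileCache(og)
    profiles <- stats::setNames(
      lapply(og@terms$id, buildProfile, og = og, cache = cache),
      og@terms$id)
    failures <- character()
    w <- rep(NA_real_, nrow(edges))
    for (k in seq_len(nrow(edges))) {
      res <- tryCatch(
        ibEdgeWeight(og, edges$child[k], edges$parent[k],
                     profiles = profiles, pseudocount = pseudocount,
                     symmetric = symmetric),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        failures <- c(failures,
                      paste0(edges$child[k], "->", edges$parent[k], ": ", res))
      } else {
        w[k] <- res
      }
    }
    if (length(failures))
      stop(length(failures), " edge(s) could not be weighted:\n  ",
           paste(utils::head(failures, 5), collapse = "\n  "))
  }
  weights <- data.frame(child = edges$child, parent = edges$parent,
                        weight = as.numeric(w), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = weights$child, to = weights$parent,
               weight = weights$weight, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sort(og@terms$id)))
  pc <- .buildPathCache(
    data.frame(from = weights$child, to = weights$parent,
               weight = weights$weight, stringsAsFactors = FALSE),
    og@terms$id)
  methods::new("WeightedOntology", ontology = og, metric = metric,
               weights = weights, graph = g, ic = ic, profiles = profiles,
               pathCache = pc)
}

#' Write an edge-weight table to TSV
#'
#' Columns: child, parent, metric, weight. Suitable for histogram-style
#' diagnostics of the weight distribution.
#'
#' @param wg a [WeightedOntology-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeEdgeWeights <- function(wg, path) {
  stopifnot(methods::is(wg, "WeightedOntology"))
  tab <- wg@weights
  tab$metric <- wg@metric
  utils::write.table(tab[, c("child", "parent", "metric", "weight")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
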
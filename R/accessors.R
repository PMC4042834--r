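# Accessors and show() methods for the package classes.

.termSet <- function(og, lst, term) {
  if (is.null(term)) return(lst)
  if (!term %in% og@terms$id) stop("unknown term: ", term)
  v <- lst[[term]]
  if (is.null(v)) character() else v
}

#' Accessors for OntologyGraph objects
#'
#' @param x an [OntologyGraph-class].
#' @param term a term id, or NULL for the full named list.
#' @return `termIds` and `rootTerm` return character vectors; `termNames` a
#'   named character vector (id -> name); `isaEdges` a data.frame of
#'   child/parent pairs; the gene/doc accessors a character vector for one
#'   term or the full named list; `geneUniverse` the sorted set of genes
#'   with at least one direct annotation.
#' @name OntologyGraph-accessors
NULL

#' @rdname OntologyGraph-accessors
#' @export
setMethod("termIds", "OntologyGraph", function(x) x@terms$id)

#' @rdname OntologyGraph-accessors
#' @export
setMethod("rootTerm", "OntologyGraph", function(x) x@root)

#' @rdname OntologyGraph-accessors
#' @export
setMethod("termNames", "OntologyGraph", function(x) {
  stats::setNames(x@terms$name, x@terms$id)
})

#' @rdname OntologyGraph-accessors
#' @export
setMethod("isaEdges", "OntologyGraph", function(x) x@edges)

#' @rdname OntologyGraph-accessors
#' @export
setMethod("directGenes", "OntologyGraph", function(x, term = NULL)
  .termSet(x, x@directGenes, term))

#' @rdname OntologyGraph-accessors
#' @export
setMethod("cumulativeGenes", "OntologyGraph", function(x, term = NULL)
  .termSet(x, x@cumulativeGenes, term))

#' @rdname OntologyGraph-accessors
#' @export
setMethod("directDocs", "OntologyGraph", function(x, term = NULL)
  .termSet(x, x@directDocs, term))

#' @rdname OntologyGraph-accessors
#' @export
setMethod("cumulativeDocs", "OntologyGraph", function(x, term = NULL)
  .termSet(x, x@cumulativeDocs, term))

#' @rdname OntologyGraph-accessors
#' @export
setMethod("geneUniverse", "OntologyGraph", function(x) {
  sort(unique(unlist(x@directGenes, use.names = FALSE)))
})

setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph with", nrow(object@terms), "terms and",
      nrow(object@edges), "IS_A edges\n")
  cat("  root:", object@root, "\n")
  cat("  annotated genes:", length(geneUniverse(object)),
      "| documents:", nrow(object@docs), "\n")
  cat("  propagated:", object@propagated, "| pruned:", object@pruned, "\n")
})

#' Accessors for WeightedOntology objects
#'
#' @param x a [WeightedOntology-class].
#' @return `edgeWeights` returns the child/parent/weight data.frame;
#'   `lossMetric` the metric name.
#' @name WeightedOntology-accessors
NULL

#' @rdname WeightedOntology-accessors
#' @export
setMethod("edgeWeights", "WeightedOntology", function(x) x@weights)

#' @rdname WeightedOntology-accessors
#' @export
setMethod("lossMetric", "WeightedOntology", function(x) x@metric)

setMethod("show", "WeightedOntology", function(object) {
  cat("WeightedOntology (", object@metric, " information loss)\n", sep = "")
  cat("  ", nrow(object@weights), " weighted IS_A edges over ",
      nrow(object@ontology@terms), " terms\n", sep = "")
  w <- object@weights$weight
  cat(sprintf("  weight range: [%.4g, %.4g], median %.4g nats\n",
              min(w), max(w), stats::median(w)))
})

#' Accessors for AugmentedOntology objects
#'
#' @param x an [AugmentedOntology-class].
#' @return `augmentationEdges` returns the data.frame of gene-sharing edges
#'   (`i`, `j`, `shared`, `weight`); `basePercentile` the 5th-percentile base
#'   edge weight d_P5.
#' @name AugmentedOntology-accessors
NULL

#' @rdname AugmentedOntology-accessors
#' @export
setMethod("augmentationEdges", "AugmentedOntology", function(x) x@augEdges)

#' @rdname AugmentedOntology-accessors
#' @export
setMethod("basePercentile", "AugmentedOntology", function(x) x@dP5)

setMethod("show", "AugmentedOntology", function(object) {
  callNextMethod()
  cat("  ", nrow(object@augEdges), " augmentation edges (d_P5 = ",
      sprintf("%.4g", object@dP5), ")\n", sep = "")
})

#' Accessors for WordProfile objects
#'
#' @param x a [WordProfile-class].
#' @return `wordCounts` returns the named count vector; `wordDistribution`
#'   the normalized distribution p(w|t) (error when the profile is empty).
#' @name WordProfile-accessors
NULL

#' @rdname WordProfile-accessors
#' @export
setMethod("wordCounts", "WordProfile", function(x) x@counts)

#' @rdname WordProfile-accessors
#' @export
setMethod("wordDistribution", "WordProfile", function(x) {
  if (x@total <= 0)
    stop("term ", x@term, " has an empty word profile; ",
         "unusable for the information-bottleneck metric")
  x@counts / x@total
})

setMethod("show", "WordProfile", function(object) {
  cat("WordProfile for ", object@term, ": ", length(object@counts),
      " distinct tokens, ", object@total, " total\n", sep = "")
})

setMethod("show", "CoherenceStatistic", function(object) {
  cat("CoherenceStatistic (", object@metric, ", ", object@scheme,
      " scheme)\n", sep = "")
  cat("  ", object@n, " genes, ", length(object@terminals),
      " terminal terms\n", sep = "")
  cat(sprintf("  y_s = %.6g nats\n", object@value))
})

#' Accessors for NullModel objects
#'
#' @param x a [NullModel-class].
#' @return `nullSamples` returns the data.frame of (n, y) records.
#' @name NullModel-accessors
NULL

#' @rdname NullModel-accessors
#' @export
setMethod("nullSamples", "NullModel", function(x) x@samples)

setMethod("show", "NullModel", function(object) {
  cat("NullModel (", object@metric, ", ", object@scheme, " scheme)\n",
      sep = "")
  cat("  ", nrow(object@samples), " random-set statistics, sizes ",
      min(object@sizes), "-", max(object@sizes), ", ", object@reps,
      " replicates per size\n", sep = "")
  cat("  bandwidth h =", object@h, "| seed =", object@seed, "\n")
})

#' Accessors for SummaryModules objects
#'
#' @param x a [SummaryModules-class].
#' @param term a module term id, or NULL for the full named list.
#' @return `moduleTable` returns the per-module data.frame; `moduleGenes`
#'   and `subsumedTerms` the gene/term sets of one module or all modules.
#' @name SummaryModules-accessors
NULL

#' @rdname SummaryModules-accessors
#' @export
setMethod("moduleTable", "SummaryModules", function(x) x@modules)

#' @rdname SummaryModules-accessors
#' @export
setMethod("moduleGenes", "SummaryModules", function(x, term = NULL) {
  if (is.null(term)) return(x@geneSets)
  if (!term %in% names(x@geneSets)) stop("no module for term ", term)
  x@geneSets[[term]]
})

#' @rdname SummaryModules-accessors
#' @export
setMethod("subsumedTerms", "SummaryModules", function(x, term = NULL) {
  if (is.null(term)) return(x@subsumed)
  if (!term %in% names(x@subsumed)) stop("no module for term ", term)
  x@subsumed[[term]]
})

setMethod("show", "SummaryModules", function(object) {
  m <- object@modules
  cat("SummaryModules:", nrow(m), "modules\n")
  cat("  metric:", object@parameters$metric,
      "| scheme:", object@parameters$scheme,
      "| p cutoff:", object@parameters$pCutoff, "\n")
  if (nrow(m)) {
    sizes <- m$n
    cat("  module sizes:", paste(sizes, collapse = ", "), "\n")
  }
})
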
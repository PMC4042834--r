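#' @rdname OntologyGraph-accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("rootTerm", function(x) standardGeneric("rootTerm"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("isaEdges", function(x) standardGeneric("isaEdges"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("directGenes", function(x, term = NULL) standardGeneric("directGenes"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("cumulativeGenes", function(x, term = NULL) standardGeneric("cumulativeGenes"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("directDocs", function(x, term = NULL) standardGeneric("directDocs"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("cumulativeDocs", function(x, term = NULL) standardGeneric("cumulativeDocs"))

#' @rdname OntologyGraph-accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname descendantCount
#' @export
setGeneric("descendantTerms", function(x, term) standardGeneric("descendantTerms"))

#' @rdname descendantCount
#' @export
setGeneric("descendantCount", function(x, term) standardGeneric("descendantCount"))

#' @rdname WeightedOntology-accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname WeightedOntology-accessors
#' @export
setGeneric("lossMetric", function(x) standardGeneric("lossMetric"))

#' @rdname AugmentedOntology-accessors
#' @export
setGeneric("augmentationEdges", function(x) standardGeneric("augmentationEdges"))

#' @rdname AugmentedOntology-accessors
#' @export
setGeneric("basePercentile", function(x) standardGeneric("basePercentile"))

#' @rdname WordProfile-accessors
#' @export
setGeneric("wordCounts", function(x) standardGeneric("wordCounts"))

#' @rdname WordProfile-accessors
#' @export
setGeneric("wordDistribution", function(x) standardGeneric("wordDistribution"))

#' @rdname nwEstimate
#' @export
setGeneric("nwEstimate", function(x, n, h = NULL) standardGeneric("nwEstimate"))

#' @rdname pValue
#' @export
setGeneric("pValue", function(x, n, y) standardGeneric("pValue"))

#' @rdname NullModel-accessors
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))

#' @rdname SummaryModules-accessors
#' @export
setGeneric("moduleTable", function(x) standardGeneric("moduleTable"))

#' @rdname SummaryModules-accessors
#' @export
setGeneric("moduleGenes", function(x, term = NULL) standardGeneric("moduleGenes"))

#' @rdname SummaryModules-accessors
#' @export
setGeneric("subsumedTerms", function(x, term = NULL) standardGeneric("subsumedTerms"))
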
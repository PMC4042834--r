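#' @import methods
NULL

#' OntologyGraph: a rooted DAG of ontology terms with attached genes and
#' documents
#'
#' The central container of the package. Terms are connected by IS_A edges
#' (child -> parent); exactly one term, the root, has no parent. Gene and
#' document associations are stored both as direct assignments and, after
#' [propagateAnnotations()], as cumulative sets obeying the true-path rule:
#' the cumulative set of a term is the union of its direct set and the
#' cumulative sets of its children.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`, `def`.
#' @slot edges data.frame with columns `child`, `parent` (IS_A only).
#' @slot root character scalar, the term id of the unique root.
#' @slot directGenes named list: term id -> character vector of gene ids.
#' @slot cumulativeGenes named list, filled by [propagateAnnotations()].
#' @slot directDocs named list: term id -> character vector of document ids.
#' @slot cumulativeDocs named list, filled by [propagateAnnotations()].
#' @slot docs data.frame with columns `id`, `title`, `abstract`.
#' @slot descendants named list: term id -> descendant term ids (self
#'   included), filled by [propagateAnnotations()].
#' @slot geneIndex named list: gene id -> direct annotation term ids,
#'   filled by [propagateAnnotations()].
#' @slot report list of parser / annotation bookkeeping (ignored relation
#'   counts, unmapped annotation rows, ...).
#' @slot propagated logical, TRUE after [propagateAnnotations()].
#' @slot pruned logical, TRUE after [pruneUnannotated()].
#'
#' @exportClass OntologyGraph
setClass("OntologyGraph",
  representation(
    terms = "data.frame",
    edges = "data.frame",
    root = "character",
    directGenes = "list",
    cumulativeGenes = "list",
    directDocs = "list",
    cumulativeDocs = "list",
    docs = "data.frame",
    descendants = "list",
    geneIndex = "list",
    report = "list",
    propagated = "logical",
    pruned = "logical"
  ),
  prototype(
    docs = data.frame(id = character(), title = character(),
                      abstract = character(), stringsAsFactors = FALSE),
    report = list(),
    propagated = FALSE,
    pruned = FALSE
  )
)

setValidity("OntologyGraph", function(object) {
  msg <- character()
  ids <- object@terms$id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated term ids")
  if (nrow(object@edges) > 0) {
    known <- c(object@edges$child, object@edges$parent) %in% ids
    if (!all(known)) msg <- c(msg, "edge endpoints not in term table")
  }
  if (length(object@root) != 1L || !(object@root %in% ids))
    msg <- c(msg, "root must be a single known term id")
  if (length(msg)) msg else TRUE
})

#' WordProfile: word-frequency profile of a term's semantic context
#'
#' Token counts aggregated from the term's name/definition and the
#' titles/abstracts of all documents cumulatively associated with the term
#' (its own and its descendants'). The normalized counts give the word
#' distribution p(w|t) used by the information-bottleneck edge weight.
#'
#' @slot term character, the term id.
#' @slot counts named numeric vector of token counts.
#' @slot total numeric, sum of counts (0 flags a profile unusable for the
#'   information-bottleneck metric).
#'
#' @exportClass WordProfile
setClass("WordProfile",
  representation(term = "character", counts = "numeric", total = "numeric"))

setValidity("WordProfile", function(object) {
  if (any(object@counts < 0)) return("negative token counts")
  if (abs(object@total - sum(object@counts)) > 1e-9)
    return("total does not match counts")
  TRUE
})

#' WeightedOntology: ontology edges carrying information-loss weights
#'
#' Wraps an [OntologyGraph-class] whose IS_A edges have been weighted under
#' one information-loss metric: `"IC"` (difference in gene information
#' content between child and parent) or `"IB"` (information-bottleneck
#' divergence between word-usage profiles). The undirected weighted igraph
#' used for Steiner-tree computations is cached in the `graph` slot.
#'
#' @slot ontology the underlying [OntologyGraph-class] (propagated, pruned).
#' @slot metric `"IC"` or `"IB"`.
#' @slot weights data.frame with columns `child`, `parent`, `weight` (nats).
#' @slot graph undirected igraph with a `weight` edge attribute.
#' @slot ic named numeric vector of per-term information content (IC metric;
#'   empty for IB).
#' @slot profiles named list of [WordProfile-class] objects (IB metric;
#'   empty for IC).
#'
#' @exportClass WeightedOntology
setClass("WeightedOntology",
  representation(
    ontology = "OntologyGraph",
    metric = "character",
    weights = "data.frame",
    graph = "ANY",
    ic = "numeric",
    profiles = "list",
    pathCache = "list"
  ),
  prototype(ic = numeric(), profiles = list(), pathCache = list())
)

setValidity("WeightedOntology", function(object) {
  msg <- character()
  if (!object@metric %in% c("IC", "IB"))
    msg <- c(msg, "metric must be 'IC' or 'IB'")
  if (nrow(object@weights) != nrow(object@ontology@edges))
    msg <- c(msg, "every IS_A edge must carry exactly one weight")
  if (any(!is.finite(object@weights$weight)) ||
      any(object@weights$weight < 0))
    msg <- c(msg, "edge weights must be finite and nonnegative")
  if (length(msg)) msg else TRUE
})

#' AugmentedOntology: weighted ontology plus gene-sharing augmentation edges
#'
#' Extends [WeightedOntology-class] with one extra edge for every pair of
#' terms sharing at least one directly annotated gene. The augmentation edge
#' weight is `dP5 / |g_ij|`, where `dP5` is the 5th percentile of the base
#' edge weights and `|g_ij|` the number of shared genes, so that redundant
#' annotations of the same gene by different curators no longer inflate the
#' coherence statistic.
#'
#' @slot augEdges data.frame with columns `i`, `j`, `shared`, `weight`.
#' @slot dP5 numeric, the 5th percentile of the base edge weights.
#' @slot augGraph undirected igraph containing base and augmentation edges.
#'
#' @exportClass AugmentedOntology
setClass("AugmentedOntology",
  contains = "WeightedOntology",
  representation(augEdges = "data.frame", dP5 = "numeric", augGraph = "ANY",
                 augPathCache = "list"),
  prototype(augPathCache = list()))

setValidity("AugmentedOntology", function(object) {
  msg <- character()
  if (nrow(object@augEdges) > 0) {
    if (any(object@augEdges$shared < 1))
      msg <- c(msg, "augmentation edges require >= 1 shared gene")
    bad <- abs(object@augEdges$weight -
               object@dP5 / object@augEdges$shared) > 1e-12
    if (any(bad)) msg <- c(msg, "augmentation weight must equal dP5/|g_ij|")
    if (any(object@augEdges$weight > object@dP5 + 1e-12))
      msg <- c(msg, "augmentation weights cannot exceed dP5")
  }
  if (length(msg)) msg else TRUE
})

#' CoherenceStatistic: the graph-based coherence score of one gene set
#'
#' The total weight (nats) of an approximate Steiner tree connecting the
#' direct annotation terms of a gene set, on the plain or augmented weighted
#' ontology graph.
#'
#' @slot genes character vector of gene ids scored.
#' @slot n integer, number of distinct genes.
#' @slot terminals character vector of terminal term ids.
#' @slot scheme `"plain"` or `"augmented"`.
#' @slot metric `"IC"` or `"IB"`.
#' @slot value numeric, the total tree weight y_s.
#' @slot tree data.frame of tree edges (`from`, `to`, `weight`).
#'
#' @exportClass CoherenceStatistic
setClass("CoherenceStatistic",
  representation(
    genes = "character", n = "integer", terminals = "character",
    scheme = "character", metric = "character", value = "numeric",
    tree = "data.frame"
  ))

setValidity("CoherenceStatistic", function(object) {
  if (object@value < 0) return("statistic must be nonnegative")
  TRUE
})

#' NullModel: size-stratified random-set calibration of the statistic
#'
#' Stores the coherence statistics of random gene sets drawn uniformly from
#' the annotated gene universe across a grid of set sizes, together with the
#' Nadaraya-Watson bandwidth used to smooth their mean and variance as
#' functions of set size. [pValue()] converts an observed statistic into a
#' lower-tail Gaussian probability.
#'
#' @slot samples data.frame with columns `n` (set size), `y` (statistic).
#' @slot metric `"IC"` or `"IB"`.
#' @slot scheme `"plain"` or `"augmented"`.
#' @slot h numeric kernel bandwidth (default 10).
#' @slot seed integer seed used for the random draws.
#' @slot sizes integer vector, the trained size grid.
#' @slot reps integer, replicates per size.
#'
#' @exportClass NullModel
setClass("NullModel",
  representation(
    samples = "data.frame", metric = "character", scheme = "character",
    h = "numeric", seed = "integer", sizes = "integer", reps = "integer"
  ))

setValidity("NullModel", function(object) {
  msg <- character()
  if (any(object@samples$y < 0)) msg <- c(msg, "statistics must be >= 0")
  if (object@h <= 0) msg <- c(msg, "bandwidth h must be positive")
  if (length(msg)) msg else TRUE
})

#' SummaryModules: the output of the gene-list summarizer
#'
#' One row per module: a summarizing term, the member genes it covers, the
#' coherence statistic of the member set and its p-value under the null
#' model. Modules may overlap (genes annotated in several lineages appear in
#' several modules). Modules smaller than the smallest trained null size are
#' flagged `untested` (p-value NA).
#'
#' @slot modules data.frame with columns `term`, `name`, `frozenTerm`, `n`,
#'   `statistic`, `p`, `untested`.
#' @slot geneSets named list: module term -> member gene ids.
#' @slot subsumed named list: module term -> original term ids merged into
#'   the module.
#' @slot parameters list of run parameters (cutoff, metric, scheme, ...).
#'
#' @exportClass SummaryModules
setClass("SummaryModules",
  representation(
    modules = "data.frame",
    geneSets = "list",
    subsumed = "list",
    parameters = "list"
  ))
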
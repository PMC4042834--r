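# Evaluation machinery: ROC discrimination of coherent vs random gene sets
# and within-module protein-protein interaction ratios.

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then gene ids, tab-delimited.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (gene sets); descriptions in the
#'   `"description"` attribute.
#' @export
readGMT <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop(sum(bad), " GMT line(s) have fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicated set names in ", path)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Read a protein-protein interaction edge list
#'
#' Accepts a headerless two-column tab-delimited file, or a BioGRID-style
#' tab file whose header names two interactor columns (columns containing
#' "Interactor A"/"Interactor B" are used). Edges are undirected: duplicates
#' (in either orientation) and self-loops are removed.
#'
#' @param path path to the edge file.
#' @return data.frame with columns `a`, `b`, one row per undirected edge,
#'   with `a < b` lexicographically.
#' @export
readPPI <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  header <- grepl("interactor", tolower(first))
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (header) {
    cols <- tolower(names(tab))
    pick <- function(side) {
      hit <- grep(paste0("official symbol interactor ", side), cols)
      if (!length(hit)) hit <- grep(paste0("interactor ", side), cols)
      hit[1]
    }
    ia <- pick("a")
    ib <- pick("b")
    if (is.na(ia) || is.na(ib))
      stop("could not locate interactor columns in ", path)
    tab <- tab[, c(ia, ib)]
  } else {
    tab <- tab[, 1:2]
  }
  names(tab) <- c("a", "b")
  tab$a <- as.character(tab$a)
  tab$b <- as.character(tab$b)
  out <- data.frame(a = pmin(tab$a, tab$b), b = pmax(tab$a, tab$b),
                    stringsAsFactors = FALSE)
  out <- out[out$a != out$b, , drop = FALSE]
  out <- out[!duplicated(out), , drop = FALSE]
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-set protein-protein interaction ratio
#'
#' The fraction of realized interactions among a gene set: the number of
#' interaction edges with both endpoints in the set divided by the maximal
#' possible number of pairs, C(g, 2) = g(g-1)/2.
#'
#' @param genes character vector of gene ids (at least 2 distinct).
#' @param ppi interaction edge data.frame from [readPPI()] (columns `a`,
#'   `b`), or any two-column data.frame of edges (normalized internally).
#' @return list with `g` (gene count), `I` (observed interaction count) and
#'   `ratio` (I / C(g, 2)).
#' @export
ppiRatio <- function(genes, ppi) {
  genes <- unique(genes)
  g <- length(genes)
  if (g < 2L)
    stop("PPI ratio requires at least 2 distinct genes (got ", g, ")")
  stopifnot(is.data.frame(ppi), ncol(ppi) >= 2L)
  a <- as.character(ppi[[1]]); b <- as.character(ppi[[2]])
  e <- unique(data.frame(a = pmin(a, b), b = pmax(a, b),
                         stringsAsFactors = FALSE))
  e <- e[e$a != e$b, , drop = FALSE]
  I <- sum(e$a %in% genes & e$b %in% genes)
  list(g = g, I = I, ratio = I / choose(g, 2))
}

#' ROC analysis of coherent vs random gene sets
#'
#' Scores every labeled gene set with its coherence p-value under the null
#' model, then sweeps the classification threshold over the distinct
#' p-values plus 0 and 1: a set is called coherent when its p-value is at
#' most the threshold. Returns the ROC points and the trapezoid area.
#'
#' @param sets named list of gene-id vectors.
#' @param labels character vector aligned with `sets`, each `"coherent"` or
#'   `"random"`.
#' @param graph a [WeightedOntology-class] or [AugmentedOntology-class].
#' @param null a matching [NullModel-class].
#' @param scheme `"plain"` or `"augmented"`; defaults to the null model's
#'   scheme.
#' @return list with `points` (data.frame threshold/fpr/tpr), `auc`, and
#'   `pvalues` (named vector).
#' @export
rocAnalysis <- function(sets, labels, graph, null, scheme = NULL) {
  stopifnot(length(sets) == length(labels))
  labels <- match.arg(labels, c("coherent", "random"), several.ok = TRUE)
  if (length(unique(labels)) < 2L)
    stop("ROC analysis needs both coherent and random sets")
  if (is.null(scheme)) scheme <- null@scheme
  pvals <- vapply(sets, function(g) {
    stat <- geneSetStatistic(g, graph, scheme = scheme)
    suppressWarnings(pValue(null, stat@n, stat@value))
  }, numeric(1))
  roc <- .rocFromScores(pvals, labels)
  c(roc, list(pvalues = pvals))
}

# threshold sweep on p-value scores; positives are "coherent" sets, called
# coherent when p <= threshold.
.rocFromScores <- function(pvals, labels) {
  thresholds <- sort(unique(c(0, pvals, 1)))
  pos <- labels == "coherent"
  tpr <- vapply(thresholds, function(th) mean(pvals[pos] <= th), numeric(1))
  fpr <- vapply(thresholds, function(th) mean(pvals[!pos] <= th), numeric(1))
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thresholds[ord], fpr = fpr,
                           tpr = tpr),
       auc = auc)
}

#' Mean within-module PPI ratio across summarizer cutoffs
#'
#' Runs the summarizer at each p-value cutoff and computes the mean (and
#' standard error) of the within-module PPI ratio over modules with at
#' least two genes. More stringent cutoffs freeze merging earlier, yielding
#' smaller, purer modules that are expected to show higher interaction
#' density.
#'
#' @param genes query gene list.
#' @param graph a [WeightedOntology-class] or [AugmentedOntology-class].
#' @param null a matching [NullModel-class].
#' @param cutoffs p-value cutoffs (default 0.01, 0.05, 0.1).
#' @param ppi interaction edges from [readPPI()].
#' @param ... further arguments to [summarizeGenes()].
#' @return data.frame with columns `cutoff`, `meanRatio`, `se`, `nModules`.
#' @export
cutoffSweep <- function(genes, graph, null, cutoffs = c(0.01, 0.05, 0.1),
                        ppi, ...) {
  rows <- lapply(cutoffs, function(ct) {
    sm <- summarizeGenes(genes, graph, null, pCutoff = ct, ...)
    ratios <- vapply(sm@geneSets, function(g) {
      if (length(g) < 2L) return(NA_real_)
      ppiRatio(g, ppi)$ratio
    }, numeric(1))
    ratios <- ratios[!is.na(ratios)]
    data.frame(
      cutoff = ct,
      meanRatio = if (length(ratios)) mean(ratios) else 0,
      se = if (length(ratios) > 1L)
        stats::sd(ratios) / sqrt(length(ratios)) else 0,
      nModules = nrow(sm@modules))
  })
  do.call(rbind, rows)
}
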
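# Document corpus handling and per-term word-usage profiles.

#' English stopword list
#'
#' The standard Snowball English stopword list used by [preprocessText()].
#'
#' @return character vector of stopwords.
#' @export
englishStopwords <- function() {
  c("i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his",
    "himself", "she", "her", "hers", "herself", "it", "its", "itself",
    "they", "them", "their", "theirs", "themselves", "what", "which",
    "who", "whom", "this", "that", "these", "those", "am", "is", "are",
    "was", "were", "be", "been", "being", "have", "has", "had", "having",
    "do", "does", "did", "doing", "would", "should", "could", "ought",
    "a", "an", "the", "and", "but", "if", "or", "because", "as", "until",
    "while", "of", "at", "by", "for", "with", "about", "against",
    "between", "into", "through", "during", "before", "after", "above",
    "below", "to", "from", "up", "down", "in", "out", "on", "off",
    "over", "under", "again", "further", "then", "once", "here", "there",
    "when", "where", "why", "how", "all", "any", "both", "each", "few",
    "more", "most", "other", "some", "such", "no", "nor", "not", "only",
    "own", "same", "so", "than", "too", "very", "s", "t", "can", "will",
    "just", "don", "now")
}

#' Tokenize, clean and stem raw text
#'
#' Lowercases, splits on non-alphanumeric boundaries, removes stopwords and
#' applies the Porter stemmer. This fixed, deterministic pipeline defines
#' the token space of all word profiles.
#'
#' @param text character vector of raw text (elements are concatenated).
#' @param stopwords stopword list (default [englishStopwords()]).
#' @param stem apply [porterStem()] (default TRUE).
#' @return character vector of processed tokens (possibly empty).
#' @examples
#' preprocessText("Apoptotic processes")   # "apoptot" "process"
#' @export
preprocessText <- function(text, stopwords = englishStopwords(),
                           stem = TRUE) {
  if (!length(text)) return(character())
  text <- tolower(paste(text, collapse = " "))
  tokens <- strsplit(gsub("[^a-z0-9]+", " ", text), " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!tokens %in% stopwords]
  if (stem) tokens <- porterStem(tokens)
  tokens
}

#' Read a JSONL document corpus
#'
#' One JSON record per line with fields `id`, `title`, `abstract`, emulating
#' title/abstract records of the literature associated with ontology terms.
#'
#' @param path path to a JSONL file.
#' @return data.frame with columns `id`, `title`, `abstract`.
#' @export
readCorpus <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- data.frame(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    title = vapply(recs, function(r) as.character(r$title), character(1)),
    abstract = vapply(recs, function(r) as.character(r$abstract),
                      character(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) stop("duplicated document ids in ", path)
  out
}

#' Read a term-to-document map
#'
#' Two-column tab-delimited file: term id, document id. A header line
#' `term<TAB>doc` is allowed and skipped.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `term`, `doc`.
#' @export
readTermDocMap <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("term", "doc"))
  if (nrow(tab) && tab$term[1] == "term" && tab$doc[1] == "doc")
    tab <- tab[-1, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# token-count vector (named numeric, names sorted) from a token vector
.tokenCounts <- function(tokens) {
  if (!length(tokens)) return(stats::setNames(numeric(), character()))
  tb <- table(tokens)
  stats::setNames(as.numeric(tb), names(tb))
}

# sum a list of named count vectors
.sumCounts <- function(lst) {
  lst <- lst[vapply(lst, length, integer(1)) > 0L]
  if (!length(lst)) return(stats::setNames(numeric(), character()))
  all <- unlist(unname(lst)) # unname: keep token names unmangled
  out <- tapply(all, names(all), sum)
  stats::setNames(as.numeric(out), names(out))
}

# Precompute per-document and per-term-name token counts. A term's
# name/definition tokens are treated as a pseudo-document that propagates to
# ancestors along with the real documents, which guarantees that a child
# profile's support is contained in its parent's (finite KL divergence).
.profileCache <- function(og) {
  docCounts <- stats::setNames(vector("list", nrow(og@docs)), og@docs$id)
  for (k in seq_len(nrow(og@docs)))
    docCounts[[k]] <- .tokenCounts(
      preprocessText(c(og@docs$title[k], og@docs$abstract[k])))
  nameCounts <- stats::setNames(vector("list", nrow(og@terms)), og@terms$id)
  for (k in seq_len(nrow(og@terms)))
    nameCounts[[k]] <- .tokenCounts(
      preprocessText(c(og@terms$name[k], og@terms$def[k])))
  list(docCounts = docCounts, nameCounts = nameCounts)
}

#' Build the word-usage profile of a term
#'
#' Aggregates token counts from the term's name and definition, the names
#' and definitions of all its descendant terms, and the titles/abstracts of
#' all cumulatively associated documents. The normalized counts are the word
#' distribution p(w|t) entering the information-bottleneck edge weight.
#' Profile construction is order-independent; a zero-total profile is valid
#' but flagged unusable when a distribution is requested.
#'
#' @param term a term id.
#' @param og a propagated [OntologyGraph-class] with documents attached.
#' @param cache internal cache from repeated calls (see [weightEdges()]).
#' @return a [WordProfile-class].
#' @export
buildProfile <- function(term, og, cache = NULL) {
  stopifnot(methods::is(og, "OntologyGraph"))
  if (!term %in% og@terms$id) stop("unknown term: ", term)
  if (!og@propagated)
    stop("call propagateAnnotations() before building profiles")
  if (is.null(cache)) cache <- .profileCache(og)
  parts <- c(cache$nameCounts[descendantTerms(og, term)],
             cache$docCounts[cumulativeDocs(og, term)])
  counts <- .sumCounts(parts)
  methods::new("WordProfile", term = term, counts = counts,
               total = sum(counts))
}
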
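# Synthetic fixture generation: toy ontologies, annotations, document
# corpora, benchmark gene sets and interaction networks, so that the whole
# pipeline runs and is testable offline. All artifacts are deterministic
# functions of the spec's seed; each artifact uses its own derived random
# stream, so regenerating one never perturbs the others.

.fixtureSeed <- function(spec, k) {
  as.integer((spec$seed %% 400000000L) * 5L + k)
}

#' Specification of a synthetic fixture set
#'
#' Collects the shape and noise parameters of the generated toy data. The
#' ontology is a complete `branching`-ary IS_A tree with `depth` levels
#' (root = level 0). Genes carry `annotationsPerGene` direct leaf
#' annotations; the genes of each planted module annotate leaves beneath a
#' dedicated anchor term at `anchorDepth`, emulating a functionally coherent
#' gene cluster, while each annotation is relocated to a uniform random leaf
#' with probability `noiseRate` and background genes annotate uniformly.
#' Documents are drawn from per-term topic distributions; a child's topic is
#' a perturbation of its parent's whose magnitude shrinks with depth (and
#' with growing `topicConcentration`), so information-bottleneck edge
#' weights shrink with depth. The benchmark interaction network connects
#' within-module gene pairs with probability `pIn` and all other pairs with
#' probability `pOut`.
#'
#' @param depth number of tree levels including the root (>= 2).
#' @param branching children per internal term (>= 2).
#' @param nGenes total number of genes.
#' @param annotationsPerGene direct leaf annotations per module gene.
#' @param backgroundAnnotations direct leaf annotations per background
#'   gene (default: same as `annotationsPerGene`). Real annotation depth is
#'   heterogeneous: well-studied genes carry several annotations, most
#'   others few.
#' @param nModules number of planted coherent modules.
#' @param moduleSize genes per planted module.
#' @param anchorDepth tree level of the module anchor terms.
#' @param moduleLeafPool number of distinct leaves a planted module's
#'   annotations are drawn from; the pool lies beneath the deepest term of
#'   the anchor subtree that has at least this many leaf descendants, so
#'   module genes are strongly co-annotated, as genes of one biological
#'   process are.
#' @param moduleStrayAnnotations how many of each module gene's annotations
#'   are drawn uniformly from all leaves instead of the pool, emulating the
#'   gene's additional unrelated functions (pleiotropy). Capped at
#'   `annotationsPerGene - 1` so every module gene keeps one in-pool
#'   annotation.
#' @param noiseRate probability that an annotation is relocated to a
#'   uniform random leaf.
#' @param leafPopularitySd standard deviation (log scale) of the lognormal
#'   leaf-popularity weights used for background and stray annotations.
#'   0 gives uniform popularity; larger values give the heavy-tailed
#'   annotation-density profile of real ontologies, which broadens the
#'   edge-weight distribution (many near-zero edges, few large ones).
#' @param vocabSize number of distinct vocabulary words (>= 10).
#' @param docsPerTerm documents generated per term.
#' @param docLength tokens per document.
#' @param topicConcentration how strongly a child topic resembles its
#'   parent's (larger = more similar; Inf = identical).
#' @param topicDecay per-level decay of the topic perturbation (0-1).
#' @param pIn within-module interaction probability.
#' @param pOut background interaction probability.
#' @param diamond add one extra IS_A edge so some term has two parents.
#' @param seed master random seed (mandatory).
#' @return a validated `FixtureSpec` list.
#' @export
fixtureSpec <- function(depth = 5L, branching = 3L, nGenes = 500L,
                        annotationsPerGene = 2L,
                        backgroundAnnotations = annotationsPerGene,
                        nModules = 2L,
                        moduleSize = 10L, anchorDepth = 1L,
                        moduleLeafPool = 3L, moduleStrayAnnotations = 0L,
                        noiseRate = 0.1, leafPopularitySd = 0,
                        vocabSize = 300L,
                        docsPerTerm = 2L, docLength = 40L,
                        topicConcentration = 5, topicDecay = 0.6,
                        pIn = 0.5, pOut = 0.02, diamond = FALSE, seed) {
  if (missing(seed)) stop("a seed is mandatory for fixture generation")
  spec <- list(depth = as.integer(depth), branching = as.integer(branching),
               nGenes = as.integer(nGenes),
               annotationsPerGene = as.integer(annotationsPerGene),
               backgroundAnnotations = as.integer(backgroundAnnotations),
               nModules = as.integer(nModules),
               moduleSize = as.integer(moduleSize),
               anchorDepth = as.integer(anchorDepth),
               moduleLeafPool = as.integer(moduleLeafPool),
               moduleStrayAnnotations = as.integer(moduleStrayAnnotations),
               noiseRate = noiseRate,
               leafPopularitySd = leafPopularitySd,
               vocabSize = as.integer(vocabSize),
               docsPerTerm = as.integer(docsPerTerm),
               docLength = as.integer(docLength),
               topicConcentration = topicConcentration,
               topicDecay = topicDecay, pIn = pIn, pOut = pOut,
               diamond = isTRUE(diamond), seed = as.integer(seed))
  if (spec$depth < 2L) stop("depth must be >= 2")
  if (spec$branching < 2L) stop("branching must be >= 2")
  if (spec$vocabSize < 10L) stop("vocabulary must have >= 10 words")
  probs <- c(spec$noiseRate, spec$pIn, spec$pOut, spec$topicDecay)
  if (any(probs < 0 | probs > 1))
    stop("noiseRate, pIn, pOut and topicDecay must lie in [0, 1]")
  if (spec$leafPopularitySd < 0)
    stop("leafPopularitySd must be >= 0")
  if (spec$nModules * spec$moduleSize > spec$nGenes)
    stop("planted modules require more genes than the gene budget")
  if (spec$anchorDepth < 1L || spec$anchorDepth > spec$depth - 1L)
    stop("anchorDepth must lie between 1 and depth - 1")
  if (spec$moduleLeafPool < 2L)
    stop("moduleLeafPool must be >= 2")
  class(spec) <- "FixtureSpec"
  spec
}

# deterministic pseudo-word vocabulary (own stream: independent of the
# per-artifact streams)
.fixtureVocab <- function(spec) {
  set.seed(.fixtureSeed(spec, 0L))
  syll <- as.vector(outer(
    c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z"),
    c("a", "e", "i", "o", "u"), paste0))
  words <- character(0)
  while (length(words) < spec$vocabSize) {
    need <- spec$vocabSize - length(words)
    fresh <- vapply(seq_len(need), function(i)
      paste(sample(syll, 3L, replace = TRUE), collapse = ""), character(1))
    words <- unique(c(words, fresh))
  }
  words[seq_len(spec$vocabSize)]
}

# tree layout shared by the generators: term ids, level of each term,
# parent of each non-root term (ids in breadth-first order)
.fixtureTree <- function(spec) {
  counts <- spec$branching^(0:(spec$depth - 1L))
  total <- sum(counts)
  ids <- sprintf("GO:%07d", seq_len(total))
  level <- rep(0:(spec$depth - 1L), counts)
  parent <- rep(NA_character_, total)
  offset <- cumsum(c(0, counts))
  for (l in seq_len(spec$depth - 1L)) {
    idx <- (offset[l + 1L] + 1L):offset[l + 2L]
    parent[idx] <- ids[offset[l] + ((seq_along(idx) - 1L) %/%
                                      spec$branching) + 1L]
  }
  list(ids = ids, level = level, parent = parent,
       leaves = ids[level == spec$depth - 1L])
}

#' Generate a synthetic OBO ontology file
#'
#' Writes a complete `branching`-ary tree of the requested depth as an OBO
#' 1.2 file in the biological_process namespace; with `diamond = TRUE` one
#' deep term receives a second parent. The file round-trips through
#' [parseOBO()].
#'
#' @param spec a [fixtureSpec()].
#' @param path destination OBO file.
#' @return `path`, invisibly; the term layout in attribute `"tree"`.
#' @export
makeOntology <- function(spec, path) {
  stopifnot(inherits(spec, "FixtureSpec"))
  tree <- .fixtureTree(spec)
  vocab <- .fixtureVocab(spec)
  set.seed(.fixtureSeed(spec, 1L))
  nameWords <- matrix(sample(vocab, 2L * length(tree$ids), replace = TRUE),
                      ncol = 2L)
  extraParent <- rep(NA_character_, length(tree$ids))
  if (spec$diamond && spec$depth >= 3L) {
    deepest <- which(tree$level == spec$depth - 1L)
    target <- deepest[length(deepest)]
    grand <- which(tree$level == spec$depth - 2L)
    alt <- setdiff(tree$ids[grand], tree$parent[target])[1]
    if (!is.na(alt)) extraParent[target] <- alt
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2",
               "ontology: synthetic-fixture",
               "default-namespace: biological_process", ""), con)
  for (k in seq_along(tree$ids)) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", tree$ids[k]), con)
    writeLines(paste0("name: ", nameWords[k, 1], " ", nameWords[k, 2]), con)
    writeLines("namespace: biological_process", con)
    if (!is.na(tree$parent[k]))
      writeLines(paste0("is_a: ", tree$parent[k], " ! parent"), con)
    if (!is.na(extraParent[k]))
      writeLines(paste0("is_a: ", extraParent[k], " ! extra parent"), con)
    writeLines("", con)
  }
  out <- invisible(path)
  attr(out, "tree") <- tree
  out
}

#' Generate a synthetic GAF annotation file with planted modules
#'
#' Assigns each gene `annotationsPerGene` direct leaf annotations. The first
#' `nModules * moduleSize` genes form planted modules whose annotations
#' concentrate on leaves beneath dedicated anchor terms at `anchorDepth`
#' (distinct anchors while available); every annotation is relocated to a
#' uniform random leaf with probability `noiseRate`. Remaining genes
#' annotate leaves uniformly. Evidence codes are all IEA.
#'
#' @param spec a [fixtureSpec()].
#' @param ontology the OBO path from [makeOntology()] or a parsed
#'   [OntologyGraph-class].
#' @param path destination GAF file.
#' @return invisibly, a list with `path`, `genes`, `modules` (named list of
#'   planted gene sets), `anchors` (named vector of anchor term ids) and the
#'   annotation data.frame.
#' @export
makeAnnotations <- function(spec, ontology, path) {
  stopifnot(inherits(spec, "FixtureSpec"))
  og <- if (methods::is(ontology, "OntologyGraph")) ontology
        else parseOBO(ontology)
  depths <- .termDepths(og)
  leaves <- sort(setdiff(og@terms$id, og@edges$parent))
  anchorsAvail <- sort(names(depths)[depths == spec$anchorDepth])
  set.seed(.fixtureSeed(spec, 2L))
  genes <- sprintf("G%04d", seq_len(spec$nGenes))
  if (spec$nModules > 0L) {
    if (spec$nModules <= length(anchorsAvail)) {
      anchors <- sample(anchorsAvail, spec$nModules)
    } else {
      warning("more planted modules than anchor terms at depth ",
              spec$anchorDepth, "; reusing anchors")
      anchors <- sample(anchorsAvail, spec$nModules, replace = TRUE)
    }
    names(anchors) <- sprintf("M%02d", seq_len(spec$nModules))
    modules <- stats::setNames(
      lapply(seq_len(spec$nModules), function(m)
        genes[((m - 1L) * spec$moduleSize + 1L):(m * spec$moduleSize)]),
      names(anchors))
  } else {
    anchors <- character()
    modules <- list()
  }
  moduleOf <- rep(NA_integer_, spec$nGenes)
  if (spec$nModules > 0L)
    moduleOf[seq_len(spec$nModules * spec$moduleSize)] <-
      rep(seq_len(spec$nModules), each = spec$moduleSize)
  # each module draws its annotations from a small leaf pool beneath the
  # deepest term of its anchor subtree that covers enough leaves, so module
  # genes are strongly co-annotated
  modulePools <- lapply(seq_len(spec$nModules), function(m) {
    sub <- descendantTerms(og, anchors[[m]])
    nLeaf <- vapply(sub, function(t)
      sum(descendantTerms(og, t) %in% leaves), integer(1))
    cand <- sub[nLeaf >= spec$moduleLeafPool]
    focus <- cand[order(-depths[cand], cand)][1]
    sort(sample(intersect(descendantTerms(og, focus), leaves),
                spec$moduleLeafPool))
  })
  # heavy-tailed leaf popularity for background and stray annotations
  pop <- if (spec$leafPopularitySd > 0)
    exp(stats::rnorm(length(leaves), 0, spec$leafPopularitySd))
  else rep(1, length(leaves))
  rows <- vector("list", spec$nGenes)
  for (i in seq_len(spec$nGenes)) {
    m <- moduleOf[i]
    if (!is.na(m)) {
      # module genes take consecutive leaves on the pool ring, so
      # neighbouring genes share annotations pairwise (overlapping
      # co-annotation, as genes of one process show)
      pool <- modulePools[[m]]
      nStray <- min(spec$moduleStrayAnnotations, spec$annotationsPerGene - 1L)
      k <- min(spec$annotationsPerGene - nStray, length(pool))
      start <- sample.int(length(pool), 1L)
      ann <- pool[((start - 1L + seq_len(k) - 1L) %% length(pool)) + 1L]
      if (nStray > 0L)
        ann <- c(ann, sample(leaves, nStray, prob = pop))
      k <- length(ann)
    } else {
      k <- min(spec$backgroundAnnotations, length(leaves))
      ann <- sample(leaves, k, prob = pop)
    }
    relocate <- stats::runif(k) < spec$noiseRate
    if (any(relocate))
      ann[relocate] <- sample(leaves, sum(relocate), replace = TRUE,
                              prob = pop)
    rows[[i]] <- data.frame(gene = genes[i], term = unique(ann),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  gaf <- data.frame(
    db = "SYNT", gene = tab$gene, symbol = tab$gene, qualifier = "",
    term = tab$term, ref = "SYNT_REF:0000001", evidence = "IEA",
    withFrom = "", aspect = "P", name = "", synonym = "",
    type = "protein", taxon = "taxon:0000", date = "20260101",
    assignedBy = "SYNT", extension = "", product = "",
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines("!gaf-version: 2.2", con)
  utils::write.table(gaf, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(list(path = path, genes = genes, modules = modules,
                 anchors = anchors, annotations = tab))
}

#' Generate a synthetic document corpus for an ontology
#'
#' Draws per-term topic distributions over the shared vocabulary: the root
#' topic is random; each child topic mixes its parent's with a fresh random
#' topic, the fresh fraction shrinking geometrically with depth and with
#' `topicConcentration` (infinite concentration makes children identical to
#' parents). Each term receives `docsPerTerm` documents of `docLength`
#' multinomial tokens, written as JSONL plus a term-to-document TSV map.
#'
#' @param spec a [fixtureSpec()].
#' @param ontology the OBO path or a parsed [OntologyGraph-class] (used for
#'   the term set; the tree layout comes from the spec).
#' @param docsPath destination JSONL file.
#' @param mapPath destination term-document map TSV.
#' @return invisibly, a list with the two paths and the per-term topic
#'   matrix.
#' @export
makeCorpus <- function(spec, ontology, docsPath, mapPath) {
  stopifnot(inherits(spec, "FixtureSpec"))
  tree <- .fixtureTree(spec)
  vocab <- .fixtureVocab(spec)
  set.seed(.fixtureSeed(spec, 3L))
  V <- spec$vocabSize
  topics <- matrix(0, nrow = length(tree$ids), ncol = V,
                   dimnames = list(tree$ids, vocab))
  freshTopic <- function() {
    x <- stats::rgamma(V, shape = 1)
    x / sum(x)
  }
  topics[1, ] <- freshTopic()
  parentIdx <- match(tree$parent, tree$ids)
  for (k in 2:length(tree$ids)) {
    eps <- spec$topicDecay^(tree$level[k] - 1L) /
      (1 + spec$topicConcentration)
    topics[k, ] <- (1 - eps) * topics[parentIdx[k], ] + eps * freshTopic()
  }
  docIds <- character(0)
  docTerms <- character(0)
  con <- file(docsPath, "w")
  d <- 0L
  for (k in seq_along(tree$ids)) {
    for (j in seq_len(spec$docsPerTerm)) {
      d <- d + 1L
      id <- sprintf("D%06d", d)
      tokens <- sample(vocab, spec$docLength, replace = TRUE,
                       prob = topics[k, ])
      rec <- list(id = id,
                  title = paste(tokens[1:min(5L, length(tokens))],
                                collapse = " "),
                  abstract = paste(tokens[-(1:min(5L, length(tokens)))],
                                   collapse = " "))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
      docIds <- c(docIds, id)
      docTerms <- c(docTerms, tree$ids[k])
    }
  }
  close(con)
  utils::write.table(data.frame(term = docTerms, doc = docIds),
                     mapPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(docsPath = docsPath, mapPath = mapPath, topics = topics))
}

#' Generate benchmark gene sets (GMT) and an interaction network (PPI)
#'
#' The GMT file contains the planted modules as reference coherent gene
#' sets. The interaction network connects within-module gene pairs with
#' probability `pIn` and all other pairs with probability `pOut`, emulating
#' the elevated interaction density of functionally related genes.
#'
#' @param spec a [fixtureSpec()].
#' @param annot the result of [makeAnnotations()].
#' @param gmtPath destination GMT file.
#' @param ppiPath destination two-column interaction TSV.
#' @return invisibly, a list with the two paths and the edge data.frame.
#' @export
makeBenchmark <- function(spec, annot, gmtPath, ppiPath) {
  stopifnot(inherits(spec, "FixtureSpec"))
  if (spec$pIn < spec$pOut)
    warning("pIn < pOut: the benchmark is uninformative")
  set.seed(.fixtureSeed(spec, 4L))
  gmt <- vapply(names(annot$modules), function(m)
    paste(c(m, "planted", annot$modules[[m]]), collapse = "\t"),
    character(1))
  writeLines(gmt, gmtPath)
  genes <- annot$genes
  moduleOf <- stats::setNames(rep(NA_character_, length(genes)), genes)
  for (m in names(annot$modules)) moduleOf[annot$modules[[m]]] <- m
  pairs <- utils::combn(genes, 2L)
  sameModule <- !is.na(moduleOf[pairs[1, ]]) & !is.na(moduleOf[pairs[2, ]]) &
    moduleOf[pairs[1, ]] == moduleOf[pairs[2, ]]
  prob <- ifelse(sameModule, spec$pIn, spec$pOut)
  keep <- stats::rbinom(ncol(pairs), 1L, prob) == 1L
  edges <- data.frame(a = pairs[1, keep], b = pairs[2, keep],
                      stringsAsFactors = FALSE)
  utils::write.table(edges, ppiPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(gmtPath = gmtPath, ppiPath = ppiPath, edges = edges))
}

#' Generate a complete synthetic fixture set in a directory
#'
#' Writes `synthetic.obo`, `synthetic.gaf`, `synthetic-docs.jsonl`,
#' `synthetic-termdocs.tsv`, `synthetic.gmt` and `synthetic-ppi.tsv` into
#' `dir` and returns the paths plus the planted truth.
#'
#' @param spec a [fixtureSpec()].
#' @param dir destination directory (created if needed).
#' @return list with the artifact `paths`, the planted `modules` and
#'   `anchors`, and the full `genes` vector.
#' @export
makeFixtureSet <- function(spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    obo = file.path(dir, "synthetic.obo"),
    gaf = file.path(dir, "synthetic.gaf"),
    docs = file.path(dir, "synthetic-docs.jsonl"),
    termdocs = file.path(dir, "synthetic-termdocs.tsv"),
    gmt = file.path(dir, "synthetic.gmt"),
    ppi = file.path(dir, "synthetic-ppi.tsv"))
  makeOntology(spec, paths$obo)
  annot <- makeAnnotations(spec, paths$obo, paths$gaf)
  makeCorpus(spec, paths$obo, paths$docs, paths$termdocs)
  makeBenchmark(spec, annot, paths$gmt, paths$ppi)
  list(paths = paths, modules = annot$modules, anchors = annot$anchors,
       genes = annot$genes)
}

#' Canonical synthetic evaluation designs
#'
#' `discriminationBenchmarkSpec` is the fixture used to compare the
#' discriminative power of metric/scheme combinations: 50 planted modules of
#' 10 genes whose members share a small pool of process annotations and each
#' carry one stray (pleiotropic) annotation, embedded in a larger universe
#' of sparsely annotated background genes with heavy-tailed leaf popularity.
#' Under these conditions ontology-path statistics see planted modules as
#' barely different from random sets, while gene-sharing augmentation edges
#' expose their coherence.
#'
#' `interactionBenchmarkSpec` is the fixture used for the within-module
#' interaction-density sweep: 5 planted modules of 10 genes anchored at
#' distinct subtrees plus background genes, with a module-structured
#' interaction network (within-module edge probability `pIn`, background
#' `pOut`).
#'
#' @param seed master random seed.
#' @return a [fixtureSpec()].
#' @export
discriminationBenchmarkSpec <- function(seed) {
  fixtureSpec(depth = 5L, branching = 4L, nGenes = 1500L,
              nModules = 50L, moduleSize = 10L, anchorDepth = 3L,
              moduleLeafPool = 3L, annotationsPerGene = 2L,
              backgroundAnnotations = 1L, moduleStrayAnnotations = 1L,
              noiseRate = 0, leafPopularitySd = 1, seed = seed)
}

#' @rdname discriminationBenchmarkSpec
#' @export
interactionBenchmarkSpec <- function(seed) {
  fixtureSpec(depth = 5L, branching = 3L, nGenes = 300L,
              nModules = 5L, moduleSize = 10L, anchorDepth = 2L,
              moduleLeafPool = 3L, annotationsPerGene = 2L,
              noiseRate = 0.1, pIn = 0.5, pOut = 0.02, seed = seed)
}
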
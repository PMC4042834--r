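smallPipeline <- function(seed = 41, ...) {
  buildFixturePipeline(fixtureSpec(depth = 4, branching = 3, nGenes = 120,
                                   nModules = 2, moduleSize = 8,
                                   anchorDepth = 1, seed = seed, ...))
}

test_that("augmentation edges follow the d_P5 / |g| law", {
  p <- smallPipeline()
  ag <- p$ag
  aug <- augmentationEdges(ag)
  expect_gt(nrow(aug), 0)
  expect_equal(aug$weight, basePercentile(ag) / aug$shared,
               tolerance = 1e-12)
  expect_true(all(aug$weight <= basePercentile(ag) + 1e-12))
  expect_equal(basePercentile(ag),
               unname(quantile(edgeWeights(p$wg)$weight, 0.05)),
               tolerance = 1e-12)
  # augmentation edges exist exactly for pairs sharing direct genes
  dg <- directGenes(p$og)
  g2t <- split(rep(names(dg), lengths(dg)), unlist(dg, use.names = FALSE))
  pairs <- unique(do.call(rbind, lapply(g2t, function(ts) {
    ts <- sort(unique(ts))
    if (length(ts) < 2) return(NULL)
    t(combn(ts, 2))
  })))
  expect_equal(nrow(aug), nrow(pairs))

  # preconditions
  expect_error(augmentGraph(p$wg, minEdges = 10000), "base edges")
  zero <- p$wg
  zero@weights$weight <- 0
  expect_error(augmentGraph(zero), "zero")
})

test_that("terminalsFor returns direct annotation terms, excluding
           unannotated genes", {
  og <- withAnnotations(chainOntology(),
                        list("GO:C" = c("g1", "g2"), "GO:B" = "g2"))
  expect_identical(terminalsFor("g1", og), "GO:C")
  expect_identical(terminalsFor(c("g1", "g2"), og), c("GO:B", "GO:C"))
  expect_warning(ts <- terminalsFor(c("g1", "nope"), og), "no direct")
  expect_identical(ts, "GO:C")
  expect_error(suppressWarnings(terminalsFor("nope", og)), "no gene")
})

test_that("the Steiner heuristic is exact-bounded: >= optimum and <= 2x
           optimum on 50 random small graphs", {
  for (s in 1:50) {
    g <- randomConnectedGraph(sample(6:8, 1), sample(8:12, 1), seed = s)
    set.seed(s + 500)
    terminals <- sample(igraph::V(g)$name, sample(3:4, 1))
    heur <- steinerTree(g, terminals)$weight
    opt <- oracleSteinerWeight(g, terminals)
    expect_gte(heur, opt - 1e-9)
    expect_lte(heur, 2 * opt + 1e-9)
  }
})

test_that("Steiner base cases: single terminal, one edge, determinism,
           disconnection error", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B", weight = 0.7), directed = FALSE)
  expect_equal(steinerTree(g, "A")$weight, 0)
  st <- steinerTree(g, c("A", "B"))
  expect_equal(st$weight, 0.7)
  expect_equal(nrow(st$edges), 1L)

  g2 <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "C"), to = c("B", "D"), weight = 0.5),
    directed = FALSE)
  expect_error(steinerTree(g2, c("A", "C")), "disconnected")

  p <- smallPipeline()
  set.seed(77)
  genes <- sample(geneUniverse(p$og), 12)
  t1 <- steinerTree(p$ag, terminalsFor(genes, p$og), scheme = "augmented")
  t2 <- steinerTree(p$ag, terminalsFor(genes, p$og), scheme = "augmented")
  expect_identical(t1, t2)
})

test_that("gene-set statistics: zero for a single term, hand values on a
           3-node graph, and the augmentation shortcut", {
  # two sibling leaves under one parent, no shared genes -> a + b
  og <- parseOBO(writeTestOBO(
    c("GO:A", "GO:B", "GO:C"),
    data.frame(child = c("GO:B", "GO:C"), parent = c("GO:A", "GO:A"))))
  og <- withAnnotations(og, list("GO:B" = sprintf("b%d", 1:3),
                                 "GO:C" = sprintf("c%d", 1:6)))
  og <- pruneUnannotated(og)
  wg <- weightEdges(og, "IC")
  a <- icEdgeWeight(og, "GO:B", "GO:A")
  b <- icEdgeWeight(og, "GO:C", "GO:A")
  st <- geneSetStatistic(c("b1", "c1"), wg)
  expect_equal(st@value, a + b, tolerance = 1e-12)
  expect_identical(st@terminals, c("GO:B", "GO:C"))

  # all genes on one term -> 0
  expect_equal(geneSetStatistic(c("b1", "b2"), wg)@value, 0)

  # shared gene: the augmentation shortcut replaces the ontology route
  p <- smallPipeline()
  ag <- p$ag
  aug <- augmentationEdges(ag)
  k <- which.max(aug$shared)
  sharedGenes <- intersect(directGenes(p$og, aug$i[k]),
                           directGenes(p$og, aug$j[k]))
  stPlain <- geneSetStatistic(sharedGenes[1], ag, scheme = "plain")
  stAug <- geneSetStatistic(sharedGenes[1], ag, scheme = "augmented")
  expect_lte(stAug@value, stPlain@value + 1e-12)
})

test_that("augmented statistic never exceeds plain; permutation invariance;
           adding an on-tree gene changes nothing", {
  p <- smallPipeline()
  set.seed(99)
  for (r in 1:10) {
    genes <- sample(geneUniverse(p$og), sample(5:15, 1))
    yP <- geneSetStatistic(genes, p$ag, scheme = "plain")@value
    yA <- geneSetStatistic(genes, p$ag, scheme = "augmented")@value
    expect_lte(yA, yP + 1e-9)
    yPerm <- geneSetStatistic(sample(genes), p$ag,
                              scheme = "augmented")@value
    expect_equal(yPerm, yA, tolerance = 1e-12)
  }
  # a gene whose terminals are already on the tree leaves y unchanged
  genes <- sample(geneUniverse(p$og), 10)
  st <- geneSetStatistic(genes, p$ag, scheme = "augmented")
  onTree <- unique(unlist(st@tree[, c("from", "to")]))
  cand <- setdiff(geneUniverse(p$og), genes)
  extra <- cand[vapply(cand, function(g)
    all(terminalsFor(g, p$og) %in% c(onTree, st@terminals)),
    logical(1))]
  if (length(extra)) {
    st2 <- geneSetStatistic(c(genes, extra[1]), p$ag,
                            scheme = "augmented")
    expect_equal(st2@value, st@value, tolerance = 1e-9)
  }
})

test_that("the within-subgraph restriction drops outside terminals and the
           statistics writer emits a well-formed table", {
  p <- smallPipeline()
  anchor <- p$fx$anchors[[1]]
  genes <- p$fx$modules[[1]]
  stFull <- geneSetStatistic(genes, p$ag, scheme = "augmented")
  stIn <- geneSetStatistic(genes, p$ag, scheme = "augmented",
                           within = anchor)
  expect_true(all(stIn@terminals %in% descendantTerms(p$og, anchor)))
  expect_true(all(stIn@terminals %in% stFull@terminals))

  path <- tempfile(fileext = ".tsv")
  writeStatistics(list(full = stFull, within = stIn), path)
  tab <- read.delim(path)
  expect_identical(tab$set, c("full", "within"))
  expect_identical(tab$scheme, c("augmented", "augmented"))
})
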
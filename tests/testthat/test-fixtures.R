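test_that("fixture specs validate their parameters", {
  expect_error(fixtureSpec(depth = 1, seed = 1), "depth")
  expect_error(fixtureSpec(branching = 1, seed = 1), "branching")
  expect_error(fixtureSpec(vocabSize = 5, seed = 1), "vocabulary")
  expect_error(fixtureSpec(noiseRate = 2, seed = 1), "\\[0, 1\\]")
  expect_error(fixtureSpec(nGenes = 10, nModules = 2, moduleSize = 10,
                           seed = 1), "budget")
  expect_error(fixtureSpec(1), "seed")
})

test_that("generated ontologies have the geometric term count, round-trip
           through parseOBO, and the diamond option adds a second parent", {
  spec <- fixtureSpec(depth = 3, branching = 2, nGenes = 10, nModules = 0,
                      seed = 3)
  path <- tempfile(fileext = ".obo")
  makeOntology(spec, path)
  og <- parseOBO(path)
  expect_equal(length(termIds(og)), 7L) # 1 + 2 + 4
  expect_identical(rootTerm(og), "GO:0000001")

  spec2 <- fixtureSpec(depth = 3, branching = 2, nGenes = 10, nModules = 0,
                       diamond = TRUE, seed = 3)
  path2 <- tempfile(fileext = ".obo")
  makeOntology(spec2, path2)
  og2 <- parseOBO(path2)
  parents <- table(isaEdges(og2)$child)
  expect_true(any(parents == 2L))
})

test_that("annotations respect planting: zero noise keeps planted genes in
           their subtree, full noise scatters, seeds are byte-stable", {
  base <- list(depth = 4, branching = 3, nGenes = 60, nModules = 2,
               moduleSize = 6, anchorDepth = 1, seed = 7)
  specClean <- do.call(fixtureSpec, c(base, noiseRate = 0))
  dir <- tempfile(); dir.create(dir)
  obo <- file.path(dir, "o.obo")
  makeOntology(specClean, obo)
  og <- parseOBO(obo)
  annClean <- makeAnnotations(specClean, og, file.path(dir, "clean.gaf"))
  for (m in names(annClean$modules)) {
    sub <- descendantTerms(og, annClean$anchors[[m]])
    tab <- annClean$annotations
    planted <- tab$term[tab$gene %in% annClean$modules[[m]]]
    expect_true(all(planted %in% sub))
  }

  specNoisy <- do.call(fixtureSpec, c(base, noiseRate = 1))
  annNoisy <- makeAnnotations(specNoisy, og, file.path(dir, "noisy.gaf"))
  outside <- vapply(names(annNoisy$modules), function(m) {
    sub <- descendantTerms(og, annNoisy$anchors[[m]])
    tab <- annNoisy$annotations
    planted <- tab$term[tab$gene %in% annNoisy$modules[[m]]]
    mean(!planted %in% sub)
  }, numeric(1))
  expect_gt(mean(outside), 0.5) # scattered over the whole tree

  # determinism: identical seeds give byte-identical artifacts
  dirA <- tempfile(); dirB <- tempfile()
  fxA <- makeFixtureSet(specClean, dirA)
  fxB <- makeFixtureSet(specClean, dirB)
  for (nm in names(fxA$paths)) {
    expect_identical(readLines(fxA$paths[[nm]]),
                     readLines(fxB$paths[[nm]]),
                     info = nm)
  }
})

test_that("corpus topics: infinite concentration makes child profiles match
           parents (vanishing IB weights), siblings stay distinguishable", {
  base <- list(depth = 3, branching = 2, nGenes = 20, nModules = 0,
               vocabSize = 50, docsPerTerm = 3, docLength = 60, seed = 13)
  tight <- do.call(fixtureSpec, c(base, topicConcentration = 1e9))
  dir <- tempfile(); dir.create(dir)
  obo <- file.path(dir, "o.obo")
  makeOntology(tight, obo)
  outT <- makeCorpus(tight, obo, file.path(dir, "t.jsonl"),
                     file.path(dir, "t.tsv"))
  # child topics identical to the root topic in the limit
  expect_equal(outT$topics[2, ], outT$topics[1, ], tolerance = 1e-6)

  loose <- do.call(fixtureSpec, c(base, topicConcentration = 0.5))
  outL <- makeCorpus(loose, obo, file.path(dir, "l.jsonl"),
                     file.path(dir, "l.tsv"))
  tv <- function(p, q) sum(abs(p - q)) / 2
  # sibling terms get distinguishable distributions at finite concentration
  expect_gt(tv(outL$topics[2, ], outL$topics[3, ]), 0.05)

  # downstream: IB edge weights vanish in the identical-topic limit
  og <- parseOBO(obo)
  og <- suppressMessages(attachAnnotations(
    og, makeAnnotations(tight, og, file.path(dir, "g.gaf"))$annotations))
  og <- propagateAnnotations(og)
  og <- pruneUnannotated(og)
  ogT <- suppressMessages(attachDocuments(
    og, readCorpus(file.path(dir, "t.jsonl")),
    readTermDocMap(file.path(dir, "t.tsv"))))
  ogT <- propagateAnnotations(ogT)
  ogL <- suppressMessages(attachDocuments(
    og, readCorpus(file.path(dir, "l.jsonl")),
    readTermDocMap(file.path(dir, "l.tsv"))))
  ogL <- propagateAnnotations(ogL)
  wT <- edgeWeights(weightEdges(ogT, "IB"))$weight
  wL <- edgeWeights(weightEdges(ogL, "IB"))$weight
  expect_lt(mean(wT), mean(wL))
  expect_lt(max(wT), 0.05)
})

test_that("benchmark artifacts: GMT matches the planted modules and the
           interaction network has the expected within-module density", {
  spec <- fixtureSpec(depth = 4, branching = 3, nGenes = 60, nModules = 2,
                      moduleSize = 10, anchorDepth = 1, pIn = 0.5,
                      pOut = 0.02, seed = 19)
  dir <- tempfile()
  fx <- makeFixtureSet(spec, dir)
  gmt <- readGMT(fx$paths$gmt)
  expect_identical(gmt[names(fx$modules)], fx$modules)

  # binomial expectation: within-module edges over 20 regenerations
  counts <- vapply(1:20, function(s) {
    sp <- fixtureSpec(depth = 4, branching = 3, nGenes = 60, nModules = 1,
                      moduleSize = 10, anchorDepth = 1, pIn = 0.5,
                      pOut = 0, seed = 100 + s)
    d2 <- tempfile()
    f2 <- makeFixtureSet(sp, d2)
    nrow(readPPI(f2$paths$ppi))
  }, numeric(1))
  expected <- 0.5 * choose(10, 2) # 22.5
  sigma <- sqrt(45 * 0.5 * 0.5)
  expect_lt(abs(mean(counts) - expected), 3 * sigma / sqrt(20))

  # degenerate designs warn
  expect_warning(
    makeBenchmark(fixtureSpec(depth = 3, branching = 2, nGenes = 20,
                              nModules = 1, moduleSize = 5, anchorDepth = 1,
                              pIn = 0.01, pOut = 0.5, seed = 1),
                  list(modules = list(M01 = sprintf("G%04d", 1:5)),
                       genes = sprintf("G%04d", 1:20)),
                  tempfile(), tempfile()),
    "uninformative")
})

test_that("a zeroed-out design removes downstream discrimination", {
  # no planted structure at all: modules indistinguishable from random
  spec <- fixtureSpec(depth = 4, branching = 3, nGenes = 150, nModules = 3,
                      moduleSize = 8, anchorDepth = 1, noiseRate = 1,
                      pIn = 0.02, pOut = 0.02, seed = 29)
  p <- buildFixturePipeline(spec)
  nm <- fitNullModel(p$ag, sizes = seq(5, 20, 5), reps = 40,
                     scheme = "augmented", seed = 30)
  set.seed(31)
  rand <- lapply(p$fx$modules, function(g)
    sample(geneUniverse(p$og), length(g)))
  names(rand) <- paste0("R", seq_along(rand))
  out <- rocAnalysis(c(p$fx$modules, rand),
                     rep(c("coherent", "random"), each = 3), p$ag, nm)
  expect_lt(abs(out$auc - 0.5), 0.45) # no strong signal either way
})
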
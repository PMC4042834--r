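# A shared small pipeline with a fitted null, reused across blocks.
summarizerSetup <- function(seed = 71) {
  p <- buildFixturePipeline(fixtureSpec(seed = seed))
  nm <- fitNullModel(p$ag, sizes = seq(5, 50, 5), reps = 50,
                     scheme = "augmented", seed = seed + 1)
  c(p, list(nm = nm))
}

test_that("readGeneList strips comments and blanks", {
  path <- tempfile()
  writeLines(c("# query", "g1", "", "g2  ", "g3 # trailing"), path)
  expect_identical(readGeneList(path), c("g1", "g2", "g3"))
})

test_that("candidate merges pair leaves with their minimum-loss parent,
           ties broken lexicographically", {
  # D has parents B (cheap) and C (expensive)
  og <- parseOBO(writeTestOBO(
    c("GO:A", "GO:B", "GO:C", "GO:D"),
    data.frame(child = c("GO:B", "GO:C", "GO:D", "GO:D"),
               parent = c("GO:A", "GO:A", "GO:B", "GO:C"))))
  og <- withAnnotations(og, list("GO:D" = sprintf("d%d", 1:4),
                                 "GO:B" = sprintf("b%d", 1:20),
                                 "GO:C" = "c1"))
  og <- pruneUnannotated(og)
  wg <- weightEdges(og, "IC")
  st <- GOthemes:::.summarizerState(wg, c("d1", "b1", "c1"))
  cand <- GOthemes:::.candidateMerges(st)
  row <- cand[cand$child == "GO:D", ]
  lossB <- icEdgeWeight(og, "GO:D", "GO:B")
  lossC <- icEdgeWeight(og, "GO:D", "GO:C")
  expect_identical(row$parent,
                   if (lossB < lossC) "GO:B" else "GO:C")
  expect_equal(row$loss, min(lossB, lossC), tolerance = 1e-12)
  # candidates are sorted ascending by loss then child id
  expect_true(!is.unsorted(cand$loss))

  # equal losses -> lexicographic child order: two leaves with identical
  # cumulative content under one parent
  og2 <- parseOBO(writeTestOBO(
    c("GO:A", "GO:B", "GO:C"),
    data.frame(child = c("GO:B", "GO:C"), parent = c("GO:A", "GO:A"))))
  og2 <- withAnnotations(og2, list("GO:B" = c("x1", "x2"),
                                   "GO:C" = c("y1", "y2")))
  og2 <- pruneUnannotated(og2)
  wg2 <- weightEdges(og2, "IC")
  st2 <- GOthemes:::.summarizerState(wg2, c("x1", "x2", "y1", "y2"))
  cand2 <- GOthemes:::.candidateMerges(st2)
  expect_identical(cand2$child, c("GO:B", "GO:C"))
})

test_that("applying a merge unions gene sets and records subsumed terms", {
  og <- withAnnotations(chainOntology(),
                        list("GO:C" = c("g1", "g2"),
                             "GO:B" = c("g2", "g3")))
  og <- pruneUnannotated(og)
  wg <- weightEdges(og, "IC")
  st <- GOthemes:::.summarizerState(wg, c("g1", "g2", "g3"))
  GOthemes:::.applyMerge(st, "GO:C", "GO:B")
  expect_identical(st$geneSet[["GO:B"]], c("g1", "g2", "g3"))
  expect_identical(st$subsumed[["GO:B"]], "GO:C")
  GOthemes:::.applyMerge(st, "GO:B", "GO:A")
  expect_identical(st$subsumed[["GO:A"]], c("GO:B", "GO:C")) # chain of 2
  expect_identical(st$geneSet[["GO:A"]], c("g1", "g2", "g3"))
})

test_that("a query confined to one leaf yields a single module re-anchored
           at that leaf", {
  og <- parseOBO(writeTestOBO(
    c("GO:A", "GO:B", "GO:C", "GO:X"),
    data.frame(child = c("GO:B", "GO:C", "GO:X"),
               parent = c("GO:A", "GO:B", "GO:A"))))
  og <- withAnnotations(og, list("GO:C" = sprintf("c%02d", 1:30),
                                 "GO:X" = sprintf("x%02d", 1:10)))
  og <- pruneUnannotated(og)
  wg <- weightEdges(og, "IC")
  nm <- fitNullModel(wg, sizes = c(5, 10, 15), reps = 30,
                     scheme = "plain", seed = 72)
  sm <- summarizeGenes(sprintf("c%02d", 1:10), wg, nm, pCutoff = 0.01)
  tab <- moduleTable(sm)
  expect_equal(nrow(tab), 1L)
  expect_identical(tab$term, "GO:C") # most specific covering term
  expect_equal(tab$statistic, 0)
  expect_equal(tab$n, 10L)
})

test_that("planted clusters are recovered as modules anchored inside their
           planted subtrees", {
  s <- summarizerSetup(seed = 73)
  set.seed(74)
  noise <- sample(setdiff(s$fx$genes, unlist(s$fx$modules)), 2)
  query <- c(unlist(s$fx$modules), noise)
  sm <- suppressMessages(summarizeGenes(query, s$ag, s$nm, pCutoff = 0.01))
  tab <- moduleTable(sm)
  expect_gte(nrow(tab), 2L)
  for (m in names(s$fx$modules)) {
    sub <- descendantTerms(s$og, s$fx$anchors[[m]])
    recovered <- 0
    for (k in which(tab$term %in% sub))
      recovered <- max(recovered,
                       mean(s$fx$modules[[m]] %in%
                              moduleGenes(sm, tab$frozenTerm[k])))
    expect_gte(recovered, 0.9)
  }
  # every mappable query gene is covered by at least one module
  covered <- unique(unlist(sm@geneSets))
  expect_true(all(intersect(query, geneUniverse(s$og)) %in% covered))
  # determinism: identical inputs give identical modules
  sm2 <- suppressMessages(summarizeGenes(query, s$ag, s$nm, pCutoff = 0.01))
  expect_identical(moduleTable(sm2), tab)
})

test_that("relaxing the cutoff merges more: fewer, larger modules; unmapped
           genes are reported; mismatched null is rejected", {
  s <- summarizerSetup(seed = 75)
  set.seed(76)
  query <- c(unlist(s$fx$modules),
             sample(setdiff(s$fx$genes, unlist(s$fx$modules)), 15))
  strict <- summarizeGenes(query, s$ag, s$nm, pCutoff = 0.01)
  relaxed <- summarizeGenes(query, s$ag, s$nm, pCutoff = 0.05)
  expect_lte(nrow(moduleTable(relaxed)), nrow(moduleTable(strict)))

  expect_message(summarizeGenes(c(query, "NOT_A_GENE"), s$ag, s$nm),
                 "no annotation")
  expect_error(suppressMessages(
    summarizeGenes("NOT_A_GENE", s$ag, s$nm)), "no query gene")

  plainNull <- fitNullModel(s$wg, sizes = c(5, 10), reps = 5,
                            scheme = "plain", seed = 1)
  expect_error(summarizeGenes(query, s$ag, plainNull), "null model")
})

test_that("module writer emits the TSV and JSON provenance", {
  s <- summarizerSetup(seed = 77)
  query <- unlist(s$fx$modules)
  sm <- summarizeGenes(query, s$ag, s$nm, pCutoff = 0.01)
  tsv <- tempfile(fileext = ".tsv")
  json <- tempfile(fileext = ".json")
  writeModules(sm, tsv, json)
  tab <- read.delim(tsv)
  expect_identical(names(tab), c("term", "name", "n", "statistic", "p",
                                 "genes"))
  expect_equal(nrow(tab), nrow(moduleTable(sm)))
  prov <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(nrow(prov), nrow(tab))
  genes1 <- strsplit(tab$genes[1], ";")[[1]]
  expect_identical(genes1, moduleGenes(sm, moduleTable(sm)$frozenTerm[1]))
})
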
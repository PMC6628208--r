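# small spec so module tests stay fast; study-scale defaults are exercised
# in the end-to-end acceptance suite
smallOverlap <- function(seed = 1)
  overlapSpec(perCoreSizes = c(60, 80, 40),
              pairwiseOverlaps = c("1+2" = 12, "1+3" = 9, "2+3" = 7),
              fullOverlap = 5, universeSize = 500, seed = seed)

test_that("overlap specs validate by inclusion-exclusion", {
  sp <- smallOverlap()
  expect_equal(sp$exclusiveSizes[["all"]], 5)
  expect_equal(sp$exclusiveSizes[["1+2"]], 7)
  expect_equal(sp$exclusiveSizes[["1"]], 60 - 7 - 4 - 5)
  expect_error(overlapSpec(perCoreSizes = c(5, 5, 5),
                           pairwiseOverlaps = c("1+2" = 5, "1+3" = 5,
                                                "2+3" = 5),
                           fullOverlap = 0, universeSize = 100),
               "negative block")
  expect_error(overlapSpec(perCoreSizes = c(90, 90, 90),
                           pairwiseOverlaps = c("1+2" = 0, "1+3" = 0,
                                                "2+3" = 0),
                           fullOverlap = 0, universeSize = 100),
               "exceed")
  expect_error(expressionSpec(highFractionBackground = 2), "is not TRUE")
})

test_that("generated datasets carry the exact planted block structure", {
  dir <- withr::local_tempdir()
  ds <- generateDatasets(smallOverlap(), dir)
  expect_length(ds$files, 3)
  expect_true(all(file.exists(ds$files)))
  allKey <- paste(sort(ds$coreIds), collapse = "+")
  expect_length(ds$blocks[[allKey]], 5)
  # per-core list sizes recover the spec sizes
  expect_equal(unname(vapply(ds$members, length, integer(1))),
               c(60, 80, 40))
  # exclusive blocks are disjoint
  expect_false(anyDuplicated(unlist(ds$blocks)) > 0)
  # pairwise-overlap bookkeeping: |A∩B| = pair-only + full
  expect_length(intersect(ds$members[[1]], ds$members[[2]]), 12)
})

test_that("disjoint design yields singleton-core blocks only", {
  sp <- overlapSpec(perCoreSizes = c(10, 10, 10),
                    pairwiseOverlaps = c("1+2" = 0, "1+3" = 0, "2+3" = 0),
                    fullOverlap = 0, universeSize = 200, seed = 4)
  ds <- generateDatasets(sp, withr::local_tempdir())
  nonEmpty <- names(ds$blocks)[lengths(ds$blocks) > 0]
  expect_true(all(!grepl("+", nonEmpty, fixed = TRUE)))
})

test_that("generators are byte-identical across reruns of the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generateFixtureSuite(d1, seed = 7, overlap = smallOverlap(7))
  s2 <- generateFixtureSuite(d2, seed = 7, overlap = smallOverlap(7))
  for (i in seq_along(s1$datasets$files))
    expect_identical(readLines(s1$datasets$files[i]),
                     readLines(s2$datasets$files[i]))
  expect_identical(readLines(s1$backend$mappingFile),
                   readLines(s2$backend$mappingFile))
  expect_identical(readLines(s1$expression$path),
                   readLines(s2$expression$path))
})

test_that("expression truth is recovered exactly by threshold classification", {
  dir <- withr::local_tempdir()
  universe <- sprintf("SYN%07d", 1:400)
  planted <- universe[1:23]
  tr <- generateExpressionTable(universe, expressionSpec(seed = 3),
                                planted, file.path(dir, "e.csv"))
  tab <- readTable(tr$path, hasHeader = TRUE)
  vals <- as.numeric(tab@cells[, 2])
  names(vals) <- tab@cells[, 1]
  expect_setequal(highSet(classifyHighExpression(vals)), tr$highSet)
})

test_that("stale aliases resolve back and zero staleness is the identity", {
  dir <- withr::local_tempdir()
  ds <- generateDatasets(smallOverlap(), dir)
  ids <- unique(unlist(ds$members))
  be0 <- generateBackendTables(ids, ds$coreIds, ds$coreSymbols,
                               ds$members, dir, staleFraction = 0,
                               seed = 2)
  expect_true(all(be0$aliases == names(be0$aliases)))
  be <- generateBackendTables(ids, ds$coreIds, ds$coreSymbols,
                              ds$members, dir, staleFraction = 0.3,
                              seed = 2)
  stale <- be$aliases[be$aliases != names(be$aliases)]
  expect_equal(length(stale), round(0.3 * length(ids)))
  backend <- localResolver(be$mappingFile, be$interactionFile,
                           organism = ORG)
  r <- resolveIdentifiers(backend, ORG, unname(stale))
  expect_setequal(r$nodes$primary, names(stale))
})

test_that("planted feedback survives filtration and leaves are pruned", {
  dir <- withr::local_tempdir()
  suite <- generateFixtureSuite(dir, seed = 11, overlap = smallOverlap(11),
                                staleFraction = 0.1, nFeedback = 2,
                                nLeaf = 3)
  backend <- localResolver(suite$backend$mappingFile,
                           suite$backend$interactionFile, organism = ORG)
  wheels <- lapply(seq_along(suite$datasets$files), function(i) {
    tab <- readTable(suite$datasets$files[i], hasHeader = TRUE)
    buildWheel(newDataset(suite$datasets$coreSymbols[i], ORG,
                          suite$datasets$coreSymbols[i], "DamID",
                          extractIdentifiers(tab, "GeneID")), backend)
  })
  net <- mergeNetworks(wheels)
  recs <- fetchInteractions(backend, ORG, nodes(net))
  full <- integrateInteractions(net, recs)
  # leaf partners entered the network ...
  expect_true(all(suite$backend$leaf$id_b %in% nodes(full)$primary))
  fx <- degreeFilter(removeDuplicateEdges(full), fixpoint = TRUE)
  # ... and are pruned, while both ends of each feedback 2-cycle survive
  expect_false(any(suite$backend$leaf$id_b %in% nodes(fx)$primary))
  expect_true(all(suite$backend$feedback$id_a %in% nodes(fx)$primary))
  expect_true(all(suite$backend$feedback$id_b %in% nodes(fx)$primary))
})
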
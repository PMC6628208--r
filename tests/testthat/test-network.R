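test_that("a wheel has the core at the hub and one edge per target", {
  w <- toyWheel(targets = c("t1", "t2"))
  expect_equal(nrow(nodes(w)), 3)
  expect_equal(nrow(edges(w)), 2)
  expect_identical(unique(edges(w)$source), "FBcoreA")
  expect_setequal(edges(w)$target, c("t1", "t2"))
  expect_identical(unique(edges(w)$interaction_type), "DamID")
  expect_identical(cores(w), "FBcoreA")

  degenerate <- toyWheel(targets = character(0))
  expect_equal(nrow(nodes(degenerate)), 1)
  expect_equal(nrow(edges(degenerate)), 0)

  dup <- toyWheel(targets = c("t1", "t1"))
  expect_equal(nrow(edges(dup)), 1)
})

test_that("a core in its own target list is dropped unless selfLoops", {
  be <- toyBackend()
  ds <- newDataset("d", ORG, "esg", "DamID", c("FBcoreA", "t1"))
  expect_warning(w <- buildWheel(ds, be), "self-loop")
  expect_equal(nrow(edges(w)), 1)
  wl <- suppressWarnings(buildWheel(ds, be, selfLoops = TRUE))
  expect_equal(nrow(edges(wl)), 2)
})

test_that("merging unions nodes and edges; shared targets interconnect", {
  a <- toyWheel("esg", c("t1", "t2"))
  b <- toyWheel("cic", c("t2", "t3"), name = "cic-ds")
  m <- mergeNetworks(list(a, b))
  expect_equal(nrow(nodes(m)), 5)   # 2 cores + t1,t2,t3
  expect_equal(nrow(edges(m)), 4)
  expect_equal(sum(edges(m)$target == "t2"), 2)   # in-degree 2
  expect_identical(cores(m), c("FBcoreA", "FBcoreB"))

  # idempotent: merging a wheel with itself
  self <- mergeNetworks(list(a, a))
  expect_identical(nodes(self), nodes(a))
  expect_identical(edges(self), edges(a))

  # one core targeting another core links the two hubs
  ab <- mergeNetworks(list(toyWheel("esg", "FBcoreB"), b))
  expect_true(any(edges(ab)$source == "FBcoreA" &
                  edges(ab)$target == "FBcoreB"))

  mouse <- new("Network", nodes = nodes(a), edges = edges(a),
               cores = cores(a), organism = "Mus musculus")
  expect_error(mergeNetworks(list(a, mouse)), "different organisms")
})

test_that("merge is order-invariant up to canonical sorting", {
  wheels <- list(toyWheel("esg", c("t1", "t2", "t3")),
                 toyWheel("cic", c("t2", "t4"), name = "b"),
                 toyWheel("tis11", c("t3", "t4", "t5"), name = "c"))
  m1 <- mergeNetworks(wheels)
  m2 <- mergeNetworks(wheels[c(3, 1, 2)])
  canon <- function(n) {
    e <- edges(n)[c("source", "target", "interaction_type")]
    e[order(e$source, e$target, e$interaction_type), ]
  }
  expect_equal(canon(m1), canon(m2), ignore_attr = TRUE)
  expect_setequal(nodes(m1)$primary, nodes(m2)$primary)
  # node count = |union of resolved ids and cores| (brute-force set check)
  expect_equal(nrow(nodes(m1)),
               length(unique(c(paste0("t", 1:5), "FBcoreA", "FBcoreB",
                               "FBcoreC"))))
})

test_that("interaction integration is monotone and de-duplicated", {
  net <- toyWheel("esg", "t1")
  rec <- data.frame(query = "t1", partner = "FBcoreA",
                    partner_symbol = "esg", partner_secondary = "CG_A",
                    kind = "genetic", provenance = "local",
                    stringsAsFactors = FALSE)
  out <- integrateInteractions(net, rec)
  expect_equal(nrow(edges(out)), 2)   # feedback 2-cycle t1 -> core
  expect_true(any(edges(out)$source == "t1" &
                  edges(out)$target == "FBcoreA"))

  recNew <- data.frame(query = "t1", partner = "x1",
                       partner_symbol = "x1", partner_secondary = "",
                       kind = "physical", provenance = "local",
                       stringsAsFactors = FALSE)
  out2 <- integrateInteractions(out, recNew)
  expect_equal(nrow(nodes(out2)), nrow(nodes(out)) + 1)
  # duplicating an existing edge changes nothing
  expect_identical(edges(integrateInteractions(out2, rec)), edges(out2))
  expect_true(all(nodes(out)$primary %in% nodes(out2)$primary))
})

test_that("network CSV has the fixed seven-column header and round-trips", {
  m <- mergeNetworks(list(toyWheel("esg", c("t1", "t2")),
                          toyWheel("cic", c("t2", "t3"), name = "b")))
  p <- tempfile(fileext = ".csv")
  writeNetworkCsv(m, p)
  lines <- readLines(p)
  expect_identical(lines[1],
    paste0("Source Symbol,Source Primary Identifier,",
           "Source Secondary Identifier,Interaction Type,Target Symbol,",
           "Target Primary Identifier,Target Secondary Identifier"))
  expect_equal(length(lines), nrow(edges(m)) + 1)

  back <- readNetworkCsv(p)
  key <- function(e) sort(paste(e$source, e$target, e$interaction_type))
  expect_identical(key(edges(back)), key(edges(m)))
  expect_setequal(cores(back), cores(m))   # inferred from technique edges

  empty <- toyWheel(targets = character(0))
  pe <- tempfile(fileext = ".csv")
  writeNetworkCsv(empty, pe)
  expect_equal(length(readLines(pe)), 1)
})
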
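test_that("core symbol validation: exact, negative, case fallback", {
  be <- toyBackend()
  rec <- validateCoreSymbol(be, ORG, "esg")
  expect_identical(rec$primary, "FBcoreA")
  expect_identical(rec$symbol, "esg")
  expect_error(validateCoreSymbol(be, ORG, "esgg"), "unknown core gene")
  expect_warning(rec2 <- validateCoreSymbol(be, ORG, "Esg"),
                 "case-insensitively")
  expect_identical(rec2$primary, "FBcoreA")
  expect_error(validateCoreSymbol(be, ORG, "Esg", caseInsensitive = FALSE),
               "unknown core gene")
  expect_error(validateCoreSymbol(be, "Mus musculus", "esg"),
               "unknown organism")
})

test_that("identifier resolution updates, passes through and de-duplicates", {
  be <- toyBackend()
  r <- resolveIdentifiers(be, ORG, c("OLD_t1", "t2"))
  expect_identical(r$nodes$primary, c("t1", "t2"))
  expect_length(r$unresolved, 0)

  expect_warning(r2 <- resolveIdentifiers(be, ORG, c("OLD_t1", "NOPE")),
                 "could not be resolved")
  expect_identical(r2$nodes$primary, c("t1", "NOPE"))
  expect_identical(r2$unresolved, "NOPE")

  suppressWarnings(
    r3 <- resolveIdentifiers(be, ORG, c("OLD_t1", "NOPE"),
                             passThrough = FALSE))
  expect_identical(r3$nodes$primary, "t1")
  expect_identical(r3$unresolved, "NOPE")

  # duplicates collapse to one record (alias and primary collide too)
  r4 <- resolveIdentifiers(be, ORG, c("OLD_t1", "OLD_t1", "t1"))
  expect_identical(r4$nodes$primary, "t1")
})

test_that("resolution partitions unique inputs exactly", {
  be <- toyBackend()
  set.seed(7)
  for (i in 1:20) {
    ids <- sample(c(paste0("t", 1:9), "OLD_t1", paste0("junk", 1:4)),
                  sample(3:10, 1))
    suppressWarnings({
      on <- resolveIdentifiers(be, ORG, ids, passThrough = TRUE)
      off <- resolveIdentifiers(be, ORG, ids, passThrough = FALSE)
    })
    # every unique input lands in exactly one of (resolved, unresolved)
    resolvable <- unique(ids[ids %in% be@mapping$submitted_id])
    expect_setequal(off$unresolved, setdiff(unique(ids), resolvable))
    expect_equal(nrow(off$nodes) + length(off$unresolved) >=
                   length(unique(c(
                     be@mapping$primary_identifier[
                       match(resolvable, be@mapping$submitted_id)],
                     off$unresolved))), TRUE)
    expect_setequal(on$unresolved, off$unresolved)
    expect_true(all(off$nodes$primary %in% on$nodes$primary))
  }
})

test_that("interaction fetch looks up, de-duplicates unordered pairs", {
  inter <- data.frame(id_a = c("t1", "t2", "t3", "t5"),
                      id_b = c("t2", "t1", "t4", "t6"),
                      kind = c("genetic", "genetic", "physical", "genetic"),
                      stringsAsFactors = FALSE)
  be <- toyBackend(inter)
  q <- data.frame(primary = c("t1", "t2"), symbol = c("t1", "t2"),
                  secondary = "", organism = ORG, stringsAsFactors = FALSE)
  recs <- fetchInteractions(be, ORG, q)
  # (t1,t2,genetic) and (t2,t1,genetic) collapse to one record
  expect_equal(nrow(recs), 1)
  expect_identical(recs$kind, "genetic")
  expect_true(all(recs$kind %in% c("genetic", "physical")))

  none <- fetchInteractions(be, ORG,
    data.frame(primary = "t9", symbol = "t9", secondary = "",
               organism = ORG, stringsAsFactors = FALSE))
  expect_equal(nrow(none), 0)
})

test_that("local backend is deterministic (byte-identical reruns)", {
  inter <- data.frame(id_a = "t1", id_b = "t2", kind = "physical",
                      stringsAsFactors = FALSE)
  be <- toyBackend(inter)
  q <- data.frame(primary = paste0("t", 1:3), symbol = paste0("t", 1:3),
                  secondary = "", organism = ORG, stringsAsFactors = FALSE)
  expect_identical(resolveIdentifiers(be, ORG, c("OLD_t1", "t5")),
                   resolveIdentifiers(be, ORG, c("OLD_t1", "t5")))
  expect_identical(fetchInteractions(be, ORG, q),
                   fetchInteractions(be, ORG, q))
})

test_that("local backend reads its tables from CSV files", {
  mp <- writeCsv(c("submitted_id,primary_identifier,symbol,secondary_identifier",
                   "OLDX,FBX,genx,CGX"))
  it <- writeCsv(c("id_a,id_b,kind", "FBX,FBY,genetic"))
  be <- localResolver(mp, it, organism = ORG)
  expect_identical(resolveIdentifiers(be, ORG, "OLDX")$nodes$primary, "FBX")
  q <- data.frame(primary = "FBX", symbol = "genx", secondary = "",
                  organism = ORG, stringsAsFactors = FALSE)
  expect_equal(nrow(fetchInteractions(be, ORG, q)), 1)
})
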
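test_that("point probability matches direct enumeration on tiny cases", {
  # C(3,2)*C(2,1)/C(5,3) = 3*2/10
  expect_equal(hypergeomPoint(2, 3, 2, 3), 0.6, tolerance = 1e-12)
  expect_equal(hypergeomPoint(0, 0, 10, 5), 1)
  expect_error(hypergeomPoint(4, 3, 2, 3), "support")
  expect_error(hypergeomPoint(1, 3, 2, 9), "population")
  expect_error(hypergeomPoint(1.5, 3, 2, 3), "integers")
})

test_that("upper tail sums the point masses and dominates the point", {
  expect_equal(hypergeomUpperTail(2, 3, 2, 3), 0.7, tolerance = 1e-12)
  expect_equal(hypergeomUpperTail(0, 7, 5, 4), 1, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:50) {
    m <- sample(0:40, 1); n <- sample(0:40, 1)
    k <- sample(0:(m + n), 1)
    xs <- max(0, k - n):min(k, m)
    x <- xs[sample.int(length(xs), 1)]
    expect_gte(hypergeomUpperTail(x, m, n, k) + 1e-14,
               hypergeomPoint(x, m, n, k))
  }
})

test_that("point mass agrees with dhyper and obeys the duality symmetry", {
  set.seed(11)
  for (i in 1:200) {
    m <- sample(0:2000, 1); n <- sample(0:2000, 1)
    k <- sample(0:(m + n), 1)
    xs <- max(0, k - n):min(k, m)
    x <- xs[sample.int(length(xs), 1)]
    p <- hypergeomPoint(x, m, n, k)
    expect_equal(p, dhyper(x, m, n, k), tolerance = 1e-10)
    # point(x; m,n,k) = point(x; k, m+n-k, m)
    expect_equal(p, hypergeomPoint(x, k, m + n - k, m), tolerance = 1e-10)
  }
})

test_that("point masses over the support sum to one", {
  set.seed(5)
  for (i in 1:50) {
    m <- sample(0:5000, 1); n <- sample(0:5000, 1)
    k <- sample(0:(m + n), 1)
    xs <- max(0, k - n):min(k, m)
    expect_equal(sum(hypergeomPoint(xs, m, n, k)), 1, tolerance = 1e-12)
  }
})

test_that("threshold classification includes the boundary", {
  cls <- classifyHighExpression(c(g1 = 60, g2 = 10, g3 = 50))
  expect_setequal(highSet(cls), c("g1", "g3"))
  expect_length(highSet(classifyHighExpression(c(a = 1, b = 2), 50)), 0)
  expect_setequal(highSet(classifyHighExpression(c(a = 1, b = 0), 0)),
                  c("a", "b"))
})

test_that("enrichment report parameterizes wheels and blocks correctly", {
  a <- toyWheel("esg", c("t1", "t2", "t5"))
  b <- toyWheel("cic", c("t2", "t3"), name = "b")
  m <- mergeNetworks(list(a, b))
  part <- coTargetPartition(m)
  vals <- setNames(c(60, 10, 80, 5, 90, 1),
                   c("t1", "t2", "t3", "t5", "t9", "t4"))
  cls <- classifyHighExpression(vals)
  rep <- enrichmentReport(m, part, cls, genomeHigh = 3, genomeLow = 3,
                          blockNames = "FBcoreA+FBcoreB",
                          blockBackground = "genome")
  esg <- rep[rep$subset == "esg wheel", ]
  expect_equal(esg$k, 3)                       # t1, t2, t5
  expect_equal(esg$x, 1)                       # only t1 high
  expect_equal(esg$p, hypergeomPoint(1, 3, 3, 3), tolerance = 1e-12)
  blk <- rep[rep$subset == "FBcoreA+FBcoreB", ]
  expect_equal(blk$k, 1)                       # t2 alone
  expect_equal(blk$x, 0)
  # network background: 4 non-core nodes, 2 high (t1, t3)
  rep2 <- enrichmentReport(m, part, cls, 3, 3,
                           blockNames = "FBcoreA+FBcoreB")
  blk2 <- rep2[rep2$subset == "FBcoreA+FBcoreB", ]
  expect_equal(blk2$m, 2)
  expect_equal(blk2$n, 2)
  # tail flag switches to the upper tail; bonferroni appends a column
  rep3 <- enrichmentReport(m, part, cls, 3, 3, tail = TRUE,
                           bonferroni = TRUE)
  expect_true(all(rep3$p + 1e-14 >= rep$p[match(rep$subset, rep3$subset)]))
  expect_true(all(rep3$p_adjusted <= 1))
  expect_error(enrichmentReport(m, part, cls, 3, 3, blockNames = "nope"),
               "no such")
})

test_that("a planted enriched subset yields a smaller point p than a null draw", {
  set.seed(2024)
  genome <- paste0("g", 1:4000)
  wins <- 0L
  for (rep in 1:30) {
    high <- sample(genome, 320)            # 8% background
    planted <- sample(genome, 23)
    # enrich the planted set: resample its high membership at 35%
    vals <- setNames(ifelse(genome %in% high, 60, 1), genome)
    vals[planted] <- ifelse(runif(23) < 0.35, 60, 1)
    cls <- classifyHighExpression(vals)
    nullSet <- sample(setdiff(genome, planted), 23)
    m <- length(highSet(cls)); n <- length(genome) - m
    pPlanted <- hypergeomPoint(sum(planted %in% highSet(cls)), m, n, 23)
    pNull <- hypergeomPoint(sum(nullSet %in% highSet(cls)), m, n, 23)
    wins <- wins + (pPlanted < pNull)
  }
  expect_gte(wins, 24)   # enrichment detected in the large majority
})
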
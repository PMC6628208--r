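checkHyperArgs <- function(x, m, n, k) {
  if (any(c(x, m, n, k) < 0) || any(c(x, m, n, k) != floor(c(x, m, n, k))))
    stop("x, m, n, k must be non-negative integers")
  if (any(k > m + n)) stop("sample size k cannot exceed the population m + n")
  if (any(x > pmin(k, m)) || any(x < pmax(0, k - n)))
    stop("x outside the hypergeometric support [max(0, k-n), min(k, m)]")
}

# Stirling-series error term: stirlerr(n) = lgamma(n+1) - Stirling(n).
# Log-gamma directly for small n (the values are small, no cancellation);
# the asymptotic series in 1/n^2 beyond, truncated below double precision.
stirlerr <- function(n) {
  out <- numeric(length(n))
  small <- n <= 15
  if (any(small)) {
    ns <- n[small]
    out[small] <- lgamma(ns + 1) - (ns + 0.5) * log(ns) + ns -
      0.5 * log(2 * pi)
  }
  if (any(!small)) {
    nb <- n[!small]
    nn <- nb * nb
    out[!small] <- (1 / 12 -
      (1 / 360 - (1 / 1260 - (1 / 1680 - 1 / (1188 * nn)) / nn) / nn) /
        nn) / nb
  }
  out
}

# binomial deviance x*log(x/np) + np - x, evaluated by series when
# x is close to np so the logarithm's cancellation never surfaces
bd0 <- function(x, np) {
  out <- numeric(length(x))
  near <- abs(x - np) < 0.1 * (x + np)
  if (any(!near))
    out[!near] <- x[!near] * log(x[!near] / np[!near]) + np[!near] -
      x[!near]
  if (any(near)) {
    xx <- x[near]; mp <- np[near]
    v <- (xx - mp) / (xx + mp)
    s <- (xx - mp) * v
    ej <- 2 * xx * v
    v2 <- v * v
    j <- 0
    repeat {
      j <- j + 1
      ej <- ej * v2
      s1 <- s + ej / (2 * j + 1)
      if (isTRUE(all(s1 == s)) || j > 1000) break
      s <- s1
    }
    out[near] <- s
  }
  out
}

# log of the binomial point mass C(n,x) p^x q^(n-x) in saddle-point form:
# all large terms cancel analytically, only stirlerr and bd0 corrections
# are computed numerically
logDbinom <- function(x, n, p, q) {
  out <- numeric(length(x))
  pz <- p == 0
  qz <- q == 0
  out[pz] <- ifelse(x[pz] == 0, 0, -Inf)
  out[qz] <- ifelse(x[qz] == n[qz], 0, -Inf)
  gen <- !pz & !qz
  lo <- gen & x == 0
  hi <- gen & x == n & x > 0
  if (any(lo))
    out[lo] <- ifelse(n[lo] == 0, 0,
                      ifelse(p[lo] < 0.1,
                             -bd0(n[lo], n[lo] * q[lo]) - n[lo] * p[lo],
                             n[lo] * log(q[lo])))
  if (any(hi))
    out[hi] <- ifelse(q[hi] < 0.1,
                      -bd0(n[hi], n[hi] * p[hi]) - n[hi] * q[hi],
                      n[hi] * log(p[hi]))
  mid <- gen & !lo & !hi
  if (any(mid)) {
    xm <- x[mid]; nm <- n[mid]; pm <- p[mid]; qm <- q[mid]
    lc <- stirlerr(nm) - stirlerr(xm) - stirlerr(nm - xm) -
      bd0(xm, nm * pm) - bd0(nm - xm, nm * qm)
    lf <- log(2 * pi) + log(xm) + log1p(-xm / nm)
    out[mid] <- lc - 0.5 * lf
  }
  out
}

logHyperPoint <- function(x, m, n, k) {
  len <- max(length(x), length(m), length(n), length(k))
  x <- rep_len(x, len); m <- rep_len(m, len)
  n <- rep_len(n, len); k <- rep_len(k, len)
  N <- m + n
  out <- numeric(len)
  deg <- N == 0
  out[!deg] <- {
    p <- k[!deg] / N[!deg]
    q <- (N[!deg] - k[!deg]) / N[!deg]
    logDbinom(x[!deg], m[!deg], p, q) +
      logDbinom(k[!deg] - x[!deg], n[!deg], p, q) -
      logDbinom(k[!deg], N[!deg], p, q)
  }
  out
}

#' Exact hypergeometric point probability
#'
#' The probability of drawing exactly `x` successes when `k` items are
#' drawn without replacement from a population of `m` successes and `n`
#' failures: `choose(m, x) * choose(n, k - x) / choose(m + n, k)`.
#' Evaluated in log space; the binomial-coefficient logarithms use
#' log-gamma together with error-corrected Stirling expansions in deviance
#' form, so catastrophic cancellation never occurs and the mass is accurate
#' to better than ten significant digits at genome-scale counts. This is
#' the point mass — the quantity the enrichment report prints — not a tail
#' sum; for the Fisher-style one-sided tail see [hypergeomUpperTail()].
#' Vectorized over all four arguments.
#'
#' @param x observed successes in the sample.
#' @param m successes in the population (e.g. highly expressed genes).
#' @param n failures in the population.
#' @param k sample size (e.g. genes connected to a core gene).
#' @return the point probability.
#' @examples
#' hypergeomPoint(2, 3, 2, 3)          # 0.6 by direct enumeration
#' hypergeomPoint(8, 608, 3850, 23)    # enrichment of a 23-gene subset
#' @export
hypergeomPoint <- function(x, m, n, k) {
  checkHyperArgs(x, m, n, k)
  exp(logHyperPoint(x, m, n, k))
}

#' One-sided upper-tail hypergeometric probability
#'
#' The probability of observing `x` or more successes: the sum of
#' [hypergeomPoint()] over `x' = x .. min(k, m)`.
#'
#' @inheritParams hypergeomPoint
#' @return the upper-tail probability.
#' @export
hypergeomUpperTail <- function(x, m, n, k) {
  checkHyperArgs(x, m, n, k)
  mapply(function(x, m, n, k) {
    xs <- x:min(k, m)
    lp <- logHyperPoint(xs, m, n, k)
    mx <- max(lp)
    exp(mx) * sum(exp(lp - mx))
  }, x, m, n, k)
}

#' Classify genes as highly expressed at a threshold
#'
#' Splits genes at an expression threshold, boundary included: the high set
#' is exactly the identifiers with value greater than or equal to the
#' threshold. The default threshold of 50 is the conventional RPKM cutoff
#' for calling a gene highly expressed in the tissue profiled.
#'
#' @param values named numeric vector, names = primary identifiers, values
#'   = expression levels (RPKM or similar, non-negative).
#' @param threshold classification cutoff (default 50).
#' @return an [ExpressionClassification-class].
#' @export
classifyHighExpression <- function(values, threshold = 50) {
  stopifnot(is.numeric(values), !is.null(names(values)),
            all(values >= 0))
  new("ExpressionClassification", values = values, threshold = threshold,
      highSet = names(values)[values >= threshold])
}

setMethod("highSet", "ExpressionClassification", function(x) x@highSet)

setMethod("show", "ExpressionClassification", function(object) {
  cat("ExpressionClassification: ", length(object@highSet), "/",
      length(object@values), " genes at or above ", object@threshold,
      "\n", sep = "")
})

#' Enrichment of highly expressed genes over network subsets
#'
#' For each core gene's wheel, and for each requested co-target block, asks
#' whether the subset holds more highly expressed genes than expected from
#' its background: per-wheel rows use the genome background (`genomeHigh`
#' highly expressed out of `genomeHigh + genomeLow` genes); block rows use,
#' by default, the whole network as background — the natural question for a
#' co-regulated subset being whether it is enriched beyond the combined
#' wheels. Probabilities are exact hypergeometric point masses
#' ([hypergeomPoint()]); set `tail = TRUE` for upper-tail probabilities
#' instead, and `bonferroni = TRUE` to append a Bonferroni-adjusted column.
#'
#' @param net a [Network-class].
#' @param partition a [CoTargetPartition-class] of `net` (only blocks named
#'   in `blockNames` are reported; default all multi-core blocks).
#' @param classification an [ExpressionClassification-class] covering the
#'   background population.
#' @param genomeHigh,genomeLow highly / not-highly expressed gene counts of
#'   the genome background.
#' @param blockNames names of partition blocks to report.
#' @param blockBackground `"network"` (default) or `"genome"`.
#' @param tail report upper-tail probabilities instead of point masses.
#' @param bonferroni append a `p_adjusted` column (Bonferroni over the
#'   report's rows).
#' @return data.frame with columns `subset`, `x`, `k`, `m`, `n`, `p`.
#' @export
enrichmentReport <- function(net, partition, classification,
                             genomeHigh, genomeLow,
                             blockNames = NULL,
                             blockBackground = c("network", "genome"),
                             tail = FALSE, bonferroni = FALSE) {
  blockBackground <- match.arg(blockBackground)
  pfun <- if (tail) hypergeomUpperTail else hypergeomPoint
  high <- classification@highSet
  rows <- list()
  for (core in net@cores) {
    targets <- unique(net@edges$target[net@edges$source == core])
    targets <- setdiff(targets, core)
    sym <- net@nodes$symbol[match(core, net@nodes$primary)]
    rows[[length(rows) + 1L]] <- data.frame(
      subset = paste0(sym, " wheel"),
      x = sum(targets %in% high), k = length(targets),
      m = genomeHigh, n = genomeLow, stringsAsFactors = FALSE)
  }
  blks <- blocks(partition)
  if (is.null(blockNames))
    blockNames <- names(blks)[vapply(names(blks), function(k)
      length(strsplit(k, "+", fixed = TRUE)[[1]]) > 1, logical(1))]
  netIds <- setdiff(net@nodes$primary, net@cores)
  for (bn in blockNames) {
    b <- blks[[bn]]
    if (is.null(b)) stop("no such partition block: ", bn)
    if (blockBackground == "network") {
      m <- sum(netIds %in% high)
      n <- length(netIds) - m
    } else {
      m <- genomeHigh; n <- genomeLow
    }
    if (length(b) > m + n)
      stop("subset \"", bn, "\" is larger than its background population")
    rows[[length(rows) + 1L]] <- data.frame(
      subset = bn, x = sum(b %in% high), k = length(b),
      m = m, n = n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p <- pfun(out$x, out$m, out$n, out$k)
  if (bonferroni) out$p_adjusted <- pmin(1, out$p * nrow(out))
  out
}
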
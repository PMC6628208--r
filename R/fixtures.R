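#' Specify planted overlaps between core target lists
#'
#' Describes a multi-screen study design with known ground truth: `nCores`
#' core genes, each with a target list of a given size, with controlled
#' pairwise overlaps and one overlap block shared by all cores. Exclusive
#' block sizes are derived by inclusion–exclusion and must all be
#' non-negative. The defaults emulate a three-screen intestinal-stem-cell
#' study: per-core list sizes 1072, 3692 and 309, a three-way co-regulated
#' block of 23 genes, and a genome universe of 15682 genes.
#'
#' @param nCores number of core genes.
#' @param perCoreSizes target-list size per core, `|A_i|`.
#' @param pairwiseOverlaps named numeric vector of `|A_i ∩ A_j|` (including
#'   the full overlap), names `"i+j"` with `i < j` 1-based core indices;
#'   missing pairs default to `fullOverlap`.
#' @param fullOverlap size of the block shared by all cores.
#' @param universeSize number of genes in the universe.
#' @param seed RNG seed; generators are pure functions of spec + seed.
#' @return a list of class `OverlapSpec`.
#' @export
overlapSpec <- function(nCores = 3,
                        perCoreSizes = c(1072, 3692, 309),
                        pairwiseOverlaps = c("1+2" = 150, "1+3" = 70,
                                             "2+3" = 60),
                        fullOverlap = 23,
                        universeSize = 15682,
                        seed = 1) {
  stopifnot(nCores >= 1, length(perCoreSizes) == nCores)
  pairs <- if (nCores >= 2) utils::combn(nCores, 2, simplify = FALSE)
           else list()
  ov <- vapply(pairs, function(p) {
    key <- paste(p, collapse = "+")
    if (key %in% names(pairwiseOverlaps)) pairwiseOverlaps[[key]]
    else fullOverlap
  }, numeric(1))
  names(ov) <- vapply(pairs, paste, character(1), collapse = "+")
  if (any(ov < fullOverlap))
    stop("a pairwise overlap cannot be smaller than the full overlap")
  excl <- exclusiveBlockSizes(nCores, perCoreSizes, ov, fullOverlap)
  if (any(unlist(excl) < 0))
    stop("inconsistent spec: inclusion-exclusion yields a negative block")
  if (sum(unlist(excl)) > universeSize)
    stop("planted blocks exceed the universe size")
  structure(list(nCores = nCores, perCoreSizes = perCoreSizes,
                 pairwiseOverlaps = ov, fullOverlap = fullOverlap,
                 universeSize = universeSize, seed = seed,
                 exclusiveSizes = excl),
            class = "OverlapSpec")
}

# exclusive (disjoint) block sizes: full block, pair-only blocks, and
# single-core remainders
exclusiveBlockSizes <- function(nCores, sizes, pairOv, fullOv) {
  blocks <- list()
  if (nCores >= 2) {
    if (nCores > 2) blocks[["all"]] <- fullOv
    for (key in names(pairOv)) {
      p <- as.integer(strsplit(key, "+", fixed = TRUE)[[1]])
      blocks[[key]] <- if (nCores > 2) pairOv[[key]] - fullOv
                       else pairOv[[key]]
    }
  }
  for (i in seq_len(nCores)) {
    shared <- 0
    for (key in names(pairOv)) {
      p <- as.integer(strsplit(key, "+", fixed = TRUE)[[1]])
      if (i %in% p) shared <- shared + blocks[[key]]
    }
    if (nCores > 2) shared <- shared + fullOv
    blocks[[as.character(i)]] <- sizes[i] - shared
  }
  blocks
}

#' Specify a planted expression structure
#'
#' Describes an expression attribute with a designated enriched
#' subpopulation: background genes are "highly expressed" (at or above the
#' threshold) at `highFractionBackground`, planted genes at
#' `highFractionPlanted`. Values are drawn uniformly on the correct side of
#' the threshold, so threshold classification recovers the planted truth
#' exactly. Defaults emulate a genome in which 1251 of 15682 genes are
#' highly expressed (RPKM at or above 50) and a planted co-regulated set
#' with 8 of 23 highly expressed.
#'
#' @param highFractionBackground probability a background gene is high.
#' @param highFractionPlanted probability a planted gene is high.
#' @param threshold classification threshold (RPKM-like units).
#' @param highMax upper bound of the high value range.
#' @param seed RNG seed.
#' @return a list of class `ExpressionSpec`.
#' @export
expressionSpec <- function(highFractionBackground = 1251 / 15682,
                           highFractionPlanted = 8 / 23,
                           threshold = 50, highMax = 500, seed = 1) {
  stopifnot(highFractionBackground >= 0, highFractionBackground <= 1,
            highFractionPlanted >= 0, highFractionPlanted <= 1,
            threshold > 0, highMax > threshold)
  structure(list(highFractionBackground = highFractionBackground,
                 highFractionPlanted = highFractionPlanted,
                 threshold = threshold, highMax = highMax, seed = seed),
            class = "ExpressionSpec")
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

synId <- function(i) sprintf("SYN%07d", i)

#' Generate per-core target-list CSV files with planted overlaps
#'
#' Draws disjoint exclusive blocks from the universe per the spec, writes
#' one CSV per core (columns `GeneID`, `Score`; `Score` is a uniform decoy
#' so column-selection code paths are exercised), and returns the planted
#' truth: the exact exclusive block memberships, keyed the same way
#' [coTargetPartition()] keys its blocks (sorted core primary identifiers
#' joined with `"+"`). Byte-identical across reruns with the same spec.
#'
#' @param spec an [overlapSpec()].
#' @param dir output directory (created if needed).
#' @param aliases optional named character vector (primary identifier ->
#'   submitted alias) applied when writing files, so the written lists
#'   contain stale aliases the resolver must update.
#' @return list with `files`, `coreIds`, `coreSymbols`, `members` (per-core
#'   primary-identifier lists) and `blocks` (exclusive planted truth).
#' @export
generateDatasets <- function(spec, dir, aliases = NULL) {
  stopifnot(inherits(spec, "OverlapSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nC <- spec$nCores
  coreIds <- sprintf("SYNC%03d", seq_len(nC))
  coreSymbols <- paste0("core", LETTERS[seq_len(nC)])
  withSeed(spec$seed, {
    excl <- spec$exclusiveSizes
    total <- sum(unlist(excl))
    pool <- synId(sample.int(spec$universeSize, total))
    assignment <- list()
    off <- 0
    for (key in names(excl)) {
      assignment[[key]] <- pool[seq_len(excl[[key]]) + off]
      off <- off + excl[[key]]
    }
    members <- lapply(seq_len(nC), function(i) {
      m <- character(0)
      for (key in names(assignment)) {
        inBlock <- if (key == "all") TRUE
          else i %in% as.integer(strsplit(key, "+", fixed = TRUE)[[1]])
        if (inBlock) m <- c(m, assignment[[key]])
      }
      sample(m)   # shuffle so block structure is not row order
    })
    files <- character(nC)
    for (i in seq_len(nC)) {
      ids <- members[[i]]
      submitted <- if (is.null(aliases)) ids else {
        hit <- aliases[ids]
        ifelse(is.na(hit), ids, hit)
      }
      tab <- rawTable(cbind(submitted,
                            formatC(stats::runif(length(ids)), digits = 4,
                                    format = "f")),
                      headers = c("GeneID", "Score"))
      files[i] <- file.path(dir, paste0(coreSymbols[i], "_targets.csv"))
      writeTable(tab, files[i])
    }
  })
  truthBlocks <- list()
  for (key in names(assignment)) {
    idx <- if (key == "all") seq_len(nC)
           else as.integer(strsplit(key, "+", fixed = TRUE)[[1]])
    truthBlocks[[paste(sort(coreIds[idx]), collapse = "+")]] <-
      assignment[[key]]
  }
  list(files = files, coreIds = coreIds, coreSymbols = coreSymbols,
       members = stats::setNames(members, coreSymbols),
       blocks = truthBlocks)
}

#' Generate an expression attribute CSV with a planted enriched set
#'
#' Writes a two-column CSV (`GeneID`, `ISC`) over the universe: planted
#' genes are drawn highly expressed at the planted fraction, background
#' genes at the background fraction, with values uniformly on the correct
#' side of the threshold. The returned truth records the exact high set, so
#' [classifyHighExpression()] on the written values must recover it.
#'
#' @param universe character vector of primary identifiers to cover.
#' @param spec an [expressionSpec()].
#' @param plantedSet identifiers of the planted enriched subpopulation
#'   (must be a subset of `universe`).
#' @param path output CSV path.
#' @return list with `path`, `highSet` (planted truth) and `values`.
#' @export
generateExpressionTable <- function(universe, spec, plantedSet, path) {
  stopifnot(inherits(spec, "ExpressionSpec"),
            all(plantedSet %in% universe))
  withSeed(spec$seed, {
    p <- ifelse(universe %in% plantedSet, spec$highFractionPlanted,
                spec$highFractionBackground)
    high <- stats::runif(length(universe)) < p
    v <- numeric(length(universe))
    v[high] <- stats::runif(sum(high), spec$threshold, spec$highMax)
    v[!high] <- stats::runif(sum(!high), 0, spec$threshold * 0.999)
  })
  tab <- rawTable(cbind(universe, formatC(v, digits = 6, format = "f")),
                  headers = c("GeneID", "ISC"))
  writeTable(tab, path)
  list(path = path, highSet = universe[high],
       values = stats::setNames(v, universe))
}

#' Generate local resolver tables with stale aliases and planted feedback
#'
#' Writes the two CSV tables a [localResolver()] consumes. In the mapping
#' table, a configurable fraction of the submitted identifiers are "stale"
#' aliases (`OLD_` prefix) that the resolver must update back to the
#' primary identifier. The interaction table plants `nFeedback` genetic
#' feedback edges (a wheel target back onto its core, forming a 2-cycle
#' that degree filtration must preserve) and `nLeaf` physical edges from
#' members to outsider genes (degree-1 leaves that the first filtration
#' pass must remove).
#'
#' @param ids primary identifiers to cover in the mapping table (targets).
#' @param coreIds,coreSymbols core gene identifiers and symbols.
#' @param members named list of per-core target identifier vectors (used to
#'   pick feedback edges along existing wheel edges).
#' @param dir output directory.
#' @param staleFraction fraction of `ids` given a stale alias.
#' @param nFeedback number of planted feedback edges.
#' @param nLeaf number of planted leaf edges to outsiders.
#' @param seed RNG seed.
#' @return list with `mappingFile`, `interactionFile`, `aliases` (primary
#'   -> submitted), and planted `feedback` / `leaf` edge data.frames.
#' @export
generateBackendTables <- function(ids, coreIds, coreSymbols, members, dir,
                                  staleFraction = 0.1, nFeedback = 2,
                                  nLeaf = 3, seed = 1) {
  stopifnot(staleFraction >= 0, staleFraction <= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withSeed(seed, {
    nStale <- round(staleFraction * length(ids))
    stale <- sample(ids, nStale)
    submitted <- ifelse(ids %in% stale, paste0("OLD_", ids), ids)
    mapping <- data.frame(
      submitted_id = c(submitted, coreIds),
      primary_identifier = c(ids, coreIds),
      symbol = c(sub("SYN", "s", ids), coreSymbols),
      secondary_identifier = c(sub("SYN", "CG", ids),
                               sub("SYNC", "CGC", coreIds)),
      stringsAsFactors = FALSE)
    feedback <- NULL
    if (nFeedback > 0) {
      wheelEdges <- do.call(rbind, lapply(seq_along(members), function(i)
        data.frame(core = coreIds[i], target = members[[i]],
                   stringsAsFactors = FALSE)))
      pick <- sample.int(nrow(wheelEdges), min(nFeedback, nrow(wheelEdges)))
      feedback <- data.frame(id_a = wheelEdges$target[pick],
                             id_b = wheelEdges$core[pick],
                             kind = "genetic", stringsAsFactors = FALSE)
    }
    leaf <- NULL
    if (nLeaf > 0) {
      leaf <- data.frame(id_a = sample(ids, nLeaf),
                         id_b = sprintf("EXT%04d", seq_len(nLeaf)),
                         kind = "physical", stringsAsFactors = FALSE)
    }
  })
  interactions <- rbind(feedback, leaf)
  if (is.null(interactions))
    interactions <- data.frame(id_a = character(0), id_b = character(0),
                               kind = character(0), stringsAsFactors = FALSE)
  mappingFile <- file.path(dir, "mapping.csv")
  interactionFile <- file.path(dir, "interactions.csv")
  writeTable(rawTable(as.matrix(mapping), headers = names(mapping)),
             mappingFile)
  writeTable(rawTable(as.matrix(interactions),
                      headers = names(interactions)),
             interactionFile)
  list(mappingFile = mappingFile, interactionFile = interactionFile,
       aliases = stats::setNames(submitted, ids),
       feedback = feedback, leaf = leaf)
}

#' Generate a complete offline fixture suite
#'
#' Wires the three generators together: target lists with planted overlaps
#' (written with stale aliases), local resolver tables with planted
#' feedback and leaf interactions, and an expression attribute over the
#' whole universe whose planted enriched set is the block shared by all
#' cores. Everything is a pure function of `seed`.
#'
#' @param dir output directory.
#' @param seed master seed (also used for the component specs unless they
#'   are passed explicitly).
#' @param overlap an [overlapSpec()].
#' @param expression an [expressionSpec()].
#' @param staleFraction,nFeedback,nLeaf see [generateBackendTables()].
#' @return list with the component outputs (`datasets`, `backend`,
#'   `expression`) plus `organism`.
#' @export
generateFixtureSuite <- function(dir, seed = 1,
                                 overlap = overlapSpec(seed = seed),
                                 expression = expressionSpec(seed = seed),
                                 staleFraction = 0.1, nFeedback = 2,
                                 nLeaf = 3) {
  ds0 <- generateDatasets(overlap, dir)
  allMembers <- unique(unlist(ds0$members, use.names = FALSE))
  be <- generateBackendTables(allMembers, ds0$coreIds, ds0$coreSymbols,
                              ds0$members, dir,
                              staleFraction = staleFraction,
                              nFeedback = nFeedback, nLeaf = nLeaf,
                              seed = seed)
  # rewrite the target lists through the alias map (same membership draw)
  ds <- generateDatasets(overlap, dir, aliases = be$aliases)
  fullKey <- paste(sort(ds$coreIds), collapse = "+")
  planted <- if (overlap$nCores > 1) ds$blocks[[fullKey]] else character(0)
  expr <- generateExpressionTable(synId(seq_len(overlap$universeSize)),
                                  expression, planted,
                                  file.path(dir, "expression.csv"))
  list(datasets = ds, backend = be, expression = expr,
       organism = "Drosophila melanogaster")
}
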